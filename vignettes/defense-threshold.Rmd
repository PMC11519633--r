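---
title: "Compartment models of constitutive plant defense against generalist herbivores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment models of constitutive plant defense against generalist herbivores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(plantdefense)
```

## The scientific question

Generalist insect herbivores lay very many eggs — reproduction numbers far
above one — yet in the wild they are rarely endemic to any particular
plant community. One candidate explanation is chemical: nearly all plants
store constitutive defense compounds that deter oviposition. This package
implements two deterministic ODE models that make that argument
quantitative, in direct analogy to SIR epidemic models with and without
vaccination, and asks how large the defended fraction of germinating
plants must be for the insect-free state to be the only stable outcome.

## Models and assumptions

Both models track a plant population of constant total size $N$ and an
insect population $I$. In the **SEI model**, plants are susceptible ($S$,
open to oviposition) or exploited ($E$, already carrying eggs):

$$\frac{dS}{dt} = \mu N - \eta I \frac{S}{N} - \mu S + \alpha E, \qquad
  \frac{dE}{dt} = \eta I \frac{S}{N} - (\mu + \alpha) E, \qquad
  \frac{dI}{dt} = \beta \eta I \frac{S}{N} - \gamma I.$$

The **SEDI model** adds a defended compartment $D$ fed by the fraction
$p = \sigma/\mu$ of germination that carries constitutive defense:

$$\frac{dS}{dt} = (\mu - \sigma) N - \eta I \frac{S}{N} - \mu S + \alpha E,
  \qquad \frac{dD}{dt} = \sigma N - \mu D,$$

with the $E$ and $I$ equations unchanged. Assumptions worth keeping in
mind:

* **Constant plant total.** Germination and death share the rate constant
  $\mu$, so $S + E (+ D) = N$ is conserved exactly ($dN/dt = 0$). The
  models say nothing about growing or shrinking plant communities.
* **Mass-action oviposition with prevalence scaling.** An insect exploits
  $\eta$ plants per day, a fraction $S/N$ of which are susceptible.
* **No insect birth/death structure.** Insects die at rate $\gamma$
  (mean lifespan $1/\gamma$ days) and recruit directly from eggs at rate
  $\beta$ per exploited plant; there is no stage structure, no spatial
  structure, and no demographic noise.
* **Defense is absolute.** Defended plants are never exploited; the cost
  of producing defense compounds is ignored, so undefended "free-riders"
  carry no growth advantage.

## Parameters and units

All rates are per day; compartments are dimensionless counts.

| parameter | meaning | typical value here |
|---|---|---|
| `eta` | plants exploited per insect per day (oviposition number) | 0.05–4 |
| `beta` | eggs per insect per exploited plant per day (deposition number) | 0.5 |
| `gamma` | insect death rate; `1/gamma` = lifespan | 0.05–0.1 |
| `mu` | plant germination-and-death rate | 0.005–0.05 |
| `alpha` | re-susceptibility rate of exploited plants | 0.001–0.01 |
| `sigma` | defended-germination rate, `sigma <= mu` | 0–`mu` |
| `n_total` | total plant count N | 100 |

The derived quantities are the reproduction number $R_0 = \eta\beta/\gamma$
(viable eggs per insect lifetime), the defended fraction $p = \sigma/\mu$,
and the critical threshold $p_c = 1 - 1/R_0$. `model_params()` validates
eagerly: $\gamma > 0$, $N > 0$, $\sigma \le \mu$, and $\mu > 0$ whenever
$\sigma > 0$. The degenerate configuration $\mu = \sigma = 0$ (no vital
dynamics) is allowed and `defended_fraction()` returns 0 for it by
convention.

## Equilibria and the threshold

Closed forms are implemented directly and verified as fixed points:

* SEI free state $H^*_{Free} = (N, 0, 0)$; endemic state
  $H^*_{Endemic} = (N/R_0,\ N(R_0-1)/R_0,\ N(\mu+\alpha)(R_0-1)/\eta)$,
  existing iff $R_0 > 1$.
* SEDI free state $Q^*_{Free} = ((1-p)N, 0, 0)$ with $D^* = pN$; endemic
  state with $S^* = N/R_0$ and $E^*, I^*$ proportional to the margin
  $1 - p - 1/R_0$, existing iff $R_0 > 1$ and $p < p_c$.

Although the published analysis reduces the SEDI system to three
dimensions, the package reports $D^* = pN$ (the steady state of the
decoupled $D$ equation) so that conservation $S^* + E^* + D^* = N$ is
checkable in full. Boundary cases ($R_0 = 1$, $p = p_c$) are flagged
`exists = FALSE` rather than raising errors, because continuity plots
need the coordinates; the existence test uses strict inequalities with an
absolute guard band of `1e-12` on the discriminating quantity so
floating-point noise cannot flip the flag.

```{r equilibria}
p8 <- model_params(eta = 4, beta = 0.5, gamma = 1/20, mu = 0.05,
                   alpha = 0.01, sigma = 0.049, n_total = 100)
equilibria(p8, "sedi")
```

## Stability analysis

Published stability proofs for these models live in symbolic
Routh–Hurwitz calculations that are not reproduced here; the package
instead verifies stability numerically per parameter set. The Jacobian of
the reduced $(S, E, I)$ system is hand-derived — the constant germination
inflows vanish under differentiation, so SEI and SEDI share one reduced
Jacobian — and cross-checked against central finite differences in the
test suite. Eigenvalues come from LAPACK via `eigen()`; classification is
hyperbolicity-aware: any eigenvalue real part within `tol` of zero yields
`"nonhyperbolic"`, otherwise sign patterns give node/focus/saddle, with
the node/focus split decided purely by an imaginary part exceeding `tol`.
The default `tol = 1e-9` per day sits three orders of magnitude below the
smallest rate constant used anywhere (0.001/day). The decoupled defended
direction contributes the eigenvalue $-\mu$ analytically and is reported
separately.

```{r stability}
stability_report(p8, sedi_free_equilibrium(p8))
```

The central theorem this machinery verifies: for $R_0 > 1$ the SEDI free
state is asymptotically stable **iff** $p > 1 - 1/R_0$, and whenever the
endemic state exists it is a stable node or focus. The test suite checks
the equivalence on randomized $(R_0, p)$ grids kept away from the
boundary band $|p - p_c| \le 0.01$, where hyperbolicity degenerates.

## Numerical integration

`simulate_model()` uses `deSolve`'s `lsodar`: adaptive, stiffness-
switching, with root finding used to stop integration once the RHS
infinity norm falls below `equilibrium_tol * N` per day (default
`1e-9`). Defaults `rtol = 1e-8`, `atol = 1e-10`; the systems are not
stiff at the parameter values used here, but the solver tolerates
stiffness at extreme $R_0$. The default horizon of 5000 days covers the
slowest printed rate (0.001/day, a 1000-day timescale). Initial states
must satisfy $S + E + D = N$; the escape hatch
`check_conservation = FALSE` permits off-manifold starts, which the flows
relax back toward $N$ at rate $\mu$. Solver undershoots below zero are
clipped only in the reported table — the raw solution is kept for the
conservation audit (`conservation_error()`), so the audit sees the
integrator's own numbers. A robustness test halves both tolerances and
requires the final state to move by less than the convergence tolerance.

## Figure scenarios and the phase diagram

Eleven scenario presets transcribe published figure captions
(`list_scenarios()`). Two reconstructions were necessary: the total
population $N = 100$ is printed only for the first time-course figure and
is assumed for all others, and one phase-portrait caption prints only
$p = 0.99$, realized here as $\mu = 0.05, \sigma = 0.0495$. All scenarios
start from the invasion state $S_0 = N$, $E_0 = 0$, $D_0 = 0$, $I_0 = 1$:
the sources fix $E_0 = 0$ and require $I_0 > 0$ without printing a value,
so a single founding insect is used. Because the figures' exact time axes
and $I_0$ are not recoverable, scenario verification is regime-level: the
verdict is the eigenvalue classification of the equilibrium each figure
portrays, plus an audit that the trajectory converges onto the stable
attractor. `phase_diagram()` generalizes this to a grid over $(R_0, p)$,
comparing the analytic threshold against long-horizon simulation
(endemic iff the final insect count exceeds `1e-3`); agreement is scored
only outside the declared boundary band.

```{r scenario}
run_scenario("fig8", t_end = 3000)
```

```{r phase, fig.alt = "Analytic endemic/free outcome over the (R0, p) grid"}
pd <- phase_diagram(c(2, 50), c(0, 1), resolution = 8, t_end = 3000)
glance(pd)
autoplot(pd, "analytic")
```

## What the tests do and do not show

The test suite exercises synthetic parameter draws (uniform over
η ∈ [0.01, 5], β ∈ [0.01, 1], γ ∈ [0.01, 0.5], μ ∈ [0.001, 0.2],
α ∈ [0, 0.1], σ ∈ [0, μ], N ∈ [10, 1000]) and the caption presets; grid
sweeps use 10×10 resolution and horizons of 3000–5000 days, sizes chosen
so the full suite runs in well under a minute while still crossing every
qualitative regime. Passing tests show internal consistency — closed
forms are fixed points, classifications match the analytic threshold,
trajectories land on the predicted attractors, conservation holds to
`1e-6 N` — not that the models describe any particular field system.
Real plant–herbivore systems have growing populations, seasonal forcing,
insect stage structure, induced (not only constitutive) defenses, costs
of defense, and tritrophic interactions, all outside scope here.

## Known limitations

* Pointwise reproduction of published time-course figures is impossible
  (initial insect numbers and time axes are not printed); only limiting
  behavior and regime classification are checked.
* The stability surface is numerical-per-parameter-set; no symbolic
  global-stability or Lyapunov machinery is included, and behavior at the
  nonhyperbolic boundary $p = p_c$ is reported, not analyzed.
* Counts are continuous: eradication means $I \to 0$ exponentially, not
  extinction of discrete individuals.
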