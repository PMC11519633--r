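# SEDI run near the eradication threshold: p = 0.98 > 1 - 1/R0 = 0.975
eta: 4
beta: 0.5
gamma: 0.05
mu: 0.05
alpha: 0.01
sigma: 0.049
n_total: 100
s0: 100
e0: 0
d0: 0
i0: 1
t_end: 5000
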