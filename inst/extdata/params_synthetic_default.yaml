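mu_max_ph: 0.2
K_Fe_ph: 2.0
Y_sw2: 1.0e+10
k_d: 2.0
K_I_NO: 1.2e-05
p_tox: 2.0
mu_max_1: 0.6
mu_max_2: 1.6
K_Fe_ndfo: 0.5
K_NO3: 0.05
K_NO: 0.0001
Y_ks1: 2.5e+09
Y_ks2: 2.5e+09
k_tr: 5.0
H_NO: 21.3
H_N2O: 1.7
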