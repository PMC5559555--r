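genotype = V307L
gks = 0.082402954101600007
scale = 2.0478738901156861
a_alpha = 0.00079134428395781487
a_beta = 0.00068011420489025483
a_gamma = 0.0087844492749366409
a_delta = 0.015999223080263966
a_theta = 1.3317039427936734
a_eta = 0.00050199251486460152
a_psi = 4.5080455217241786
a_omega = 3.0576711218799047e-06
b_alpha = 0.012984451982282612
b_beta = 0.051513903740213154
b_gamma = 0.049024417642057283
b_delta = 0.047948975738189278
b_theta = 0.10702194073761276
b_eta = -0.16244246472058818
b_psi = 0.028630045007697412
b_omega = -0.25897693622491924
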