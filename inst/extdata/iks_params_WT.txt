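genotype = WT
gks = 0.082402954101600007
scale = 1
a_alpha = 0.00050101357248268465
a_beta = 4.0198549008304425e-05
a_gamma = 0.010454780905609756
a_delta = 0.0012956699146503782
a_theta = 0.0036312677095578856
a_eta = 0.097850909163287855
a_psi = 0.076114674145708716
a_omega = 0.0044630545685363735
b_alpha = 0.01544948774997726
b_beta = -0.0079109615680484913
b_gamma = 0.04972323884749158
b_delta = -0.011393500852654663
b_theta = -0.03017069346758032
b_eta = 0.0013680056980103566
b_psi = 0.070270159762030313
b_omega = -0.022294013429157881
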