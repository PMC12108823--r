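# Improved Cole-Cole parameters of in vivo rabbit lung tissue by ventilator
# tidal volume (VT). Units as printed: tau in ps, sigma_s in 1e-3 S/m,
# a_coef in 1e-9 s/rad; converted to SI on load.
vt_ml,eps_inf,delta_eps,tau_ps,alpha,sigma_s_mS_per_m,a_coef_1e9
30,3.48,58.52,6.04,0,19.96,-3.66
40,3.22,57.81,5.91,0,17.56,-3.74
50,3.63,58.59,5.15,0,10.48,-3.74
60,2.28,56.43,4.93,0,7.90,-3.68
70,3.81,55.07,5.31,0,6.61,-3.82
80,2.13,54.01,5.02,0,4.55,-3.53
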