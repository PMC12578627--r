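variable,sigma2_res,sigma2_farm,sigma2_site,phi,kappa,scale
wheat_zn,17.5,4.6,14.4,19.6,0.75,linear
teff_zn,8.3,5.2,11.0,15.9,0.50,linear
wheat_se,0.44,0.35,1.10,36.20,0.25,log
teff_se,0.60,0.12,0.40,12.20,2.00,log
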