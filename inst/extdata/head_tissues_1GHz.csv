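name,f_Hz,sigma_Sm,eps_r,tan_delta,lambda_m
blood,1e9,1.580,61.07,0.465,0.0374
cortical_bone,1e9,0.160,12.36,0.233,0.0847
cerebrospinal_fluid,1e9,2.460,68.44,0.646,0.0346
grey_matter,1e9,0.990,52.28,0.340,0.0409
white_matter,1e9,0.620,38.58,0.289,0.0478
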