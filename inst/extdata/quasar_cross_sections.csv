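# absorption cross-sections for the QuasAr1 retinal species
# columns: species, wavelength_nm, sigma_cm2
species,wavelength_nm,sigma_cm2
Ret_580,580,1.593e-16
Ret_500,500,1.25e-16
Ret_500,460,1e-16
Ret_500,405,5.47e-17
Ret_500,340,5.85e-17
Ret_460,500,2.64e-17
Ret_460,460,1e-16
Ret_460,405,5.34e-17
Ret_460,340,4.4e-17
Ret_405,460,1.6e-18
Ret_405,405,8.5e-17
Ret_405,340,3.72e-17
Ret_340,340,1.8e-16
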