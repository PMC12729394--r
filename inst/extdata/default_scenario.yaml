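# Default synthetic-scenario configuration (mirrors scenario_config()
# defaults). Units: time constants and times in hours, coefficients in
# 1/cm, densities in 1/cm^3, wavelengths in nm.
kinetics:
  kappa_I: 0.43
  kappa_II: 0.57
  tau0_I_h: 450
  tauInf_I_h: 80
  delta_I_h: 13
  tau0_II_h: 5000
  tauInf_II_h: 1700
  delta_II_h: 1000
  tau_Ret500_h: 1000
  tau_Ret460_h: 400
  N0_cm3: 1.381e16
backgrounds:
  apoprotein_peak_cm1: 3.0      # band peaking near 280 nm
  residual_peak_cm1: 0.08       # weak retinal shoulder below 450 nm
scattering:
  plateau_cm1: 0.105            # at 750 nm, reached by ~24 h
  final_cm1: 0.05               # at 750 nm at 2424 h
  gamma: 2.5                    # Mie power factor
  lambda0_nm: 900               # model reference wavelength
noise_sd_cm1: 0.005
wavelengths_nm: {from: 250, to: 900, by: 1}
times_h: [0, 6, 10, 24, 48, 95, 117, 168, 240, 336, 456, 600, 800,
          1000, 1200, 1600, 2000, 2424]
seed: 1
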