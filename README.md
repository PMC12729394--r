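# quasarkin

Thermal degradation kinetics of the Archaerhodopsin-3 based fluorescent
voltage sensor **QuasAr1**, reconstructed from UV-Vis attenuation
coefficient spectra.

Stored in the dark at room temperature, QuasAr1's protonated retinal
Schiff base chromophore (absorption band at 580 nm, "Ret_580")
degrades along two parallel branches: a fraction κ_I isomerizes to
Ret_500 and then deprotonates to the neutral Schiff base Ret_405
(time constant τ_Ret500 ≈ 1000 h), while the complementary fraction
κ_II = 1 − κ_I isomerizes slowly to Ret_460 and deprotonates to
Ret_340 (τ_Ret460 ≈ 400 h). The isomerization time constants
themselves relax exponentially,

    τ(t) = (τ⁰ − τ^∞) · exp(−t/δ) + τ^∞,

and simultaneous protein aggregation adds a Mie-scattering background
α_s(λ, t) = α_s(λ₀, t)·(λ₀/λ)^γ(t) to every spectrum. The package
implements the complete analysis chain for this system:

* **spectra** — natural-log transmission↔attenuation conversion
  (α = −ln T / l), a wavelength × time series container, lossless
  delimited-text I/O;
* **scattering** — per-time power-law fits in the 710–900 nm
  transparency window, scattering subtraction, and Rayleigh-limit
  aggregation diagnostics (scattering enhancement factor M_sca,
  degree of aggregation β_m);
* **kinetics** — the six-species ODE system with time-dependent rates
  (`deSolve`), plus a closed-form survival-fraction oracle;
* **observables / decomposition** — difference and double-difference
  spectra and the eight Beer–Lambert time series used for fitting;
* **fitting** — global multi-start Levenberg–Marquardt estimation of
  the ten kinetic parameters (`minpack.lm`);
* **synthetic data** — a seeded generator that emulates the measured
  spectra (anchored species bands, static backgrounds, scattering
  schedule, noise) with full ground truth, so the whole pipeline runs
  without any external data.

The `analysis/` directory holds the workflow as numbered drivers:
`01_simulate.R` → `02_scattering.R` → `03_decompose.R` → `04_fit.R` →
`05_recover.R`, each writing its tables and a small manifest under
`results/`.

## Worked example

```r
library(quasarkin)

cfg <- scenario_config(seed = 1)          # the default study conditions
g   <- generate_scenario(cfg)             # attenuation movie + ground truth
g$attenuation
#> spectral_series [attenuation]: 651 wavelengths (250-900 nm) x 18 times (0-2424 h), l = 0.3 cm

model      <- fit_scattering_window(g$attenuation)   # gamma(t), alpha_s(900, t)
absorption <- subtract_scattering(g$attenuation, model)
eval_scattering(model, 750, 24)           # 0.102 1/cm -- the measured plateau is 0.105 +/- 0.015
aggregation_enhancement(eval_scattering(model, 750, 24), 24,
                        1.381e16, 5e-22)$M_sca
#> 14734                                   # degree of aggregation >= 14000

obs <- extract_observables(absorption, g$components, g$trajectory)
fit <- fit_kinetics(obs, quasar_cross_sections(), quasar_parameters(),
                    n_starts = 4, seed = 1)
fit
#> fit_result: objective = 3.803e-01, converged = TRUE, 54 LM iterations over 4 starts (seed 1)
#> kinetic_parameters:
#>   kappa_I = 0.4259, kappa_II = 0.5741
#>   branch I : tau0 = 407.4 h, tauInf = 74.44 h, delta = 14.9 h
#>   branch II: tau0 = 5194 h, tauInf = 2868 h, delta = 527.7 h
#>   tau_Ret500 = 1016 h, tau_Ret460 = 382.4 h, N0 = 1.381e+16 cm^-3
```

Reading the output: from noisy synthetic spectra the branch split
(κ_I = 0.426 vs 0.43 generated) and the deprotonation constants
(1016 h, 382 h vs 1000 h, 400 h) come back tightly; the exponentially
relaxing isomerization schedules — above all the slow branch II, of
which the 0–2425 h window sees barely one e-folding — are weakly
identified and scatter more. With the noise switched off the fit
recovers all ten generating parameters within their published
uncertainties (`analysis/05_recover.R` prints the PASS table).

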