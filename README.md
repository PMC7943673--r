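# sirtdose

Voxel dosimetry and outcome analysis for selective internal radiation
therapy (SIRT) of liver tumors with ⁹⁰Y microspheres.

## The problem

In SIRT, ⁹⁰Y-loaded microspheres are injected into the hepatic artery and
lodge preferentially in the hypervascularized tumor. The absorbed dose the
tumor actually receives — not the injected activity — drives tumor control
and survival, so treatment teams compute voxel-level dose maps from
pre-treatment ⁹⁹ᵐTc-MAA SPECT/CT (a surrogate for the microsphere
distribution) and post-treatment ⁹⁰Y PET/CT. `sirtdose` implements that
workflow end to end for physicists and analysts studying dose–outcome
relationships:

- **Relative calibration.** Total activity in the field of view is assumed
  proportional to the scintigraphic counts in a liver-plus-lungs region:
  `A_i = A_inj · c_i / Σ_region c_j`. Only count ratios matter, which removes
  the absolute-quantification bias of SPECT/PET systems.
- **Local deposition method (LDM).** The implant is permanent and each
  voxel's decay energy is absorbed in that voxel:
  `D_i = A_i · E_GBq / m_i` (Gy), with
  `E_GBq = 10⁹ · (T½/ln 2) · Ē_β · 1.602×10⁻¹³ ≈ 49.4 J/GBq`
  (T½ = 64.05 h, Ē_β = 0.9267 MeV) and voxel mass from a uniform
  soft-tissue density (1.05 g/mL).
- **Contours.** Two families: anatomy-derived masks (MRI-style liver/tumor
  contours, with Dice-index registration QA at a 0.85 gate and
  inter-operator RMS-of-CV reporting) and 10%-of-maximum threshold targets
  on the scintigraphic image within a VOI surrounding the liver.
- **DVH metrics.** Exact sort-based cumulative dose-volume histograms; mean
  dose `Dm`; `D70`, the minimal dose covering the best-irradiated 70% of a
  contour; and the tumor-to-normal uptake ratio
  `TNR = (CNTS_tum/V_tum) / (CNTS_NL/V_NL)`.
- **Outcome statistics.** Per-sphere-type (resin/glass) median
  dichotomization, univariate logistic regression for 6-month tumor control
  (OR with Wald CI; separation flagged), Kaplan–Meier / log-rank / Cox
  (Breslow ties) for overall survival, Spearman–Wilcoxon–Bland–Altman
  agreement between pre- and post-treatment metrics, and a strict
  `p < 0.05` univariate gate (with declared-redundancy exclusion) into the
  multivariate model.
- **Synthetic phantoms and cohorts.** Ellipsoid-liver/sphere-tumor phantoms
  with prescribed TNR, Gaussian PSF blur, Poisson counts, and a cohort
  generator whose outcome models (logistic in supramedian TNR; exponential
  survival with a proportional hazard on supramedian Dm) have recoverable
  ground truth — so every stage is testable without patient data.

## Worked example

```r
library(sirtdose)

# a 1.8 L liver with a 200 mL tumor at true TNR 10, 1.6 GBq injected
spec <- phantom_spec(tnr_true = 10, injected_activity_gbq = 1.6, seed = 1)
ph <- make_phantom(spec)
#> <phantom_truth> liver 1811 mL, tumor 200.3 mL, true TNR 10

# SPECT-like measurement: 15 mm PSF, 5e6 counts, Poisson noise
cts <- simulate_counts(ph, psf_fwhm_mm = 15, total_counts = 5e6, seed = 2)
round(tnr(cts, ph$tumor, ph$normal_liver), 2)
#> [1] 7.31        # spill-out depresses the measured TNR below the true 10

act  <- relative_calibration(cts, ph$liver, injected_gbq = 1.6)
dose <- ldm_dose(act, y90_constants())
energy_audit(dose, y90_constants(), 1.6)
#> [1] 0           # all administered energy is accounted for

dvh <- cumulative_dvh(dose, ph$tumor)
c(Dm = round(mean_dose(dose, ph$tumor), 1), D70 = round(d_percent(dvh, 70), 1))
#>    Dm   D70
#> 178.9 155.2     # Gy; autoplot(dvh) draws the cumulative DVH

# a 200-patient synthetic cohort with known outcome models
co <- make_cohort(200, seed = 3)
di <- dichotomize(co, "TNR-Pre-C_MRI")
logistic_univariate(di$supramedian, co$tumor_control_6mo)
#> OR = 4.41 (95% CI 2.21-8.83; p = 2.7e-05)

sv <- survival_suite(co$os_months, co$death_observed,
                     dichotomize(co, "Dm-Post-C_MRI")$supramedian)
sv
#> Kaplan-Meier medians (months):
#> inframedian supramedian
#>       11.07       26.85
#> log-rank p = 5.09e-05; Cox HR = 0.509 (95% CI 0.365-0.709; p = 6.79e-05)
```

Patients whose measured TNR and mean tumor dose sit above their sphere
type's median control better and live longer — the generative effects the
cohort was built with, recovered by the analysis chain. `run_pipeline()`
orchestrates the whole loop (phantoms → counts → contours + Dice QA → dose →
metrics → statistics) from a single YAML-serializable `pipeline_config()`,
writing CSV tables and a JSON manifest; identical config and seed give
bit-identical outputs. Fitted objects support `tidy()`/`glance()`, and DVHs
and KM curves have `autoplot()` methods. A thin command-line wrapper lives
at `inst/cli/sirtdose-run.R`.

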