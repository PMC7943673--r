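---
title: "Voxel dosimetry and outcome analysis for 90Y radioembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel dosimetry and outcome analysis for 90Y radioembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtdose)
```

## The dosimetric model

`sirtdose` computes absorbed dose in selective internal radiation therapy
(SIRT) with ⁹⁰Y microspheres from scintigraphic count volumes, under two
modelling steps.

**Relative calibration.** The total microsphere activity in the field of
view is taken proportional to the counts inside a calibration region —
conceptually the liver plus the lungs, so that a lung-shunted fraction is
still accounted for. Each in-region voxel receives

$$A_i = A_{\mathrm{inj}} \frac{c_i}{\sum_{j \in \mathrm{region}} c_j},$$

and voxels outside the region carry zero activity. Because only count
*ratios* enter, the result is invariant to any positive rescaling of the
counts: camera sensitivity and the absolute-quantification accuracy of the
SPECT or PET system cancel out. This is why the same machinery serves both
the ⁹⁹ᵐTc-MAA SPECT surrogate (pre-treatment) and ⁹⁰Y PET (post-treatment)
without cross-calibration. Counts outside the calibration region are
discarded; how extrahepatic activity should be treated is genuinely open,
and zeroing it is the conservative reading of a liver+lungs normalisation.

**Local deposition.** The microsphere implant is permanent — the spheres do
not migrate, and all of the ⁹⁰Y decays in place — and the β range (~2.5 mm
in tissue, below the voxel sizes of interest) justifies depositing each
voxel's decay energy in that voxel:

$$D_i = \frac{A_i \, E_{\mathrm{GBq}}}{m_i}, \qquad
E_{\mathrm{GBq}} = 10^{9} \cdot \frac{T_{1/2}}{\ln 2} \cdot \bar E_\beta
\cdot 1.602\times10^{-13}\,\mathrm{J}.$$

With the defaults $T_{1/2} = 64.05$ h and $\bar E_\beta = 0.9267$ MeV,
$E_{\mathrm{GBq}} \approx 49.4$ J/GBq. Both constants are arguments of
`y90_constants()` because commercial dosimetry systems do not always
disclose theirs. Voxel mass uses a uniform soft-tissue density of
1.05 g/mL: the LDM as commonly deployed works on a uniform medium, and no
CT density map enters this pipeline. Bremsstrahlung and the minute
internal-pair branch are ignored — pure local β deposition.

Energy conservation is not assumed but audited: `energy_audit()` checks
$\sum_i D_i m_i = A_{\mathrm{inj}} E_{\mathrm{GBq}}$ to below $10^{-6}$
relative on every synthetic case in the test suite.

## Contours

Two contour families mirror clinical practice.

*Anatomy-derived* (`C_MRI`): liver and tumor masks as a radiologist would
draw on contrast MRI, transferred to the scintigraphic grid. The transfer
step itself (deformable registration) is out of scope; its quality gate is
not: `registration_qa()` accepts a transfer when the Dice index between the
transferred liver contour and a liver contour drawn on the scintigraphic
CT reaches 0.85. The gate is **inclusive** at the threshold — whether the
boundary case passes is not standardised, and we chose the reading under
which a contour meeting the stated minimum is usable. Inter-operator
variability is summarised by `interoperator_rms_cv()`: per structure, the
coefficient of variation of the two operators' volumes (with the $n-1$
standard deviation, i.e. $|v_A - v_B| / (\sqrt 2\,\bar v)$ for two values),
then the root mean square across structures, in percent.

*Threshold-based* (`C_SPECT`, `C_PET`): all voxels with uptake **strictly
above** 10% of the maximum uptake, the maximum being taken **within a VOI
surrounding the liver** rather than over the whole image. Both choices are
deliberate: ties exactly at the threshold are excluded (configurable), and
a VOI-local maximum keeps extrahepatic hot spots from deflating the
segment. `threshold_contour()` exposes `global_max = TRUE` for the
image-wide alternative. The operation is scale-invariant and monotone in
the fraction (a larger fraction yields a subset), both property-tested.

Masks are voxel-centre based, binary, and resampled between grids by
nearest neighbour only (`resample_mask()`): linear interpolation would
de-binarize a label. Grid alignment is enforced everywhere at a tolerance
of $10^{-6}$ mm; misaligned pairs are an error, never broadcast.

## DVH metrics

`cumulative_dvh()` builds the exact sort-based curve — at every distinct
voxel dose, the fraction of the contour receiving at least that dose. The
exact curve is the reference for all metrics; fixed-width binning (default
0.1 Gy) exists only for export and plotting, because D70 read off a binned
curve inherits the bin width as error.

* `mean_dose()` (Dm) is the arithmetic voxel mean and equals the integral
  of the cumulative DVH; the suite asserts this to $10^{-6}$ relative.
* `d_percent()` (D70 by default) is the minimal dose delivered to the
  best-covered 70% of the volume. On the exact curve this is the largest
  dose whose coverage still reaches 70% — a voxel dose, matching the
  brute-force subset oracle (two equal voxels at 10 and 30 Gy give D70 =
  10 Gy: covering 70% requires the cooler voxel). No interpolation is
  applied by default; `interpolate = TRUE` interpolates dose linearly in
  volume fraction, which is only meaningful on binned curves. On the exact
  curve volume fractions at distinct doses are strictly decreasing, so the
  documented "smallest qualifying dose" tie rule can never actually fire
  there.
* `tnr()` implements
  $\mathrm{TNR} = (CNTS_{tum}/V_{tum}) / (CNTS_{NL}/V_{NL})$ on the count
  volume directly (volumes in mL), errors on overlapping or empty
  contours and on a count-free normal liver, and is computed for
  anatomy-based contours only — a threshold target is itself
  uptake-defined, so a TNR on it would be circular.

Metric rows are named `Dm-Pre-C_MRI`, `D70-Post-C_PET`, `TNR-Pre-C_MRI`,
…, so downstream tables are self-describing about timepoint and contour
provenance.

## The synthetic phantom

`phantom_spec()` / `make_phantom()` build an ellipsoidal liver (defaults:
semi-axes 95 × 80 × 57 mm ≈ 1.8 L, on a 48³ grid of 4.42 mm cubic voxels —
a typical SPECT geometry) containing spherical tumors (default one ~200 mL
sphere) with an optional concentric necrotic core holding zero activity.
Activity concentration is uniform in normal liver and viable tumor at the
prescribed ratio `tnr_true`; the liver total equals the injected activity
times one minus the lung shunt (default shunt 0), enforced to $10^{-9}$
relative. The true dose map comes from the same LDM applied to the
noiseless activity, so "truth" and "measurement" differ only by the imaging
chain.

`simulate_counts()` emulates what reconstruction hands to dosimetry: an
isotropic Gaussian point-spread function (FWHM 15 mm for the SPECT-like
channel, 8 mm for the PET-like channel — representative post-reconstruction
resolutions, both configurable), scaling to a target expected total count,
and per-voxel Poisson noise. The blur is a 3-D FFT circular convolution
with a wrapped, sum-normalised kernel: it conserves total counts exactly,
and since phantom activity vanishes near the grid edge the wraparound has
no practical effect. Scatter, attenuation and reconstruction artefacts are
*not* modelled — in the clinical chain those corrections happen upstream of
the images this pipeline consumes. Consequently, passing tests demonstrate
correctness of the dosimetric and statistical machinery under
resolution-and-noise degradation, not robustness to reconstruction bias in
real data.

Two emergent behaviours of real scintigraphic segmentation are reproduced
and asserted qualitatively: PSF spill-out depresses the measured TNR below
the prescribed one, and the 10% threshold target is systematically larger
than the anatomical tumor. With a modest TNR the normal liver itself sits
near the 10%-of-maximum level once blur flattens the tumor peak, so the
threshold target can approach the whole perfused liver — consistent with
threshold contours representing arterial perfusion of the treated area
rather than the anatomical tumor.

## The synthetic cohort

`make_cohort()` draws patient characteristics from log-normal
distributions whose medians are calibrated loosely to a published
advanced-HCC radioembolization cohort (liver 1813 mL; tumor 203 mL;
injected activity 1.3 GBq resin / 2.3 GBq glass; TNR 7.7 resin / 5.0
glass; anatomy-contour mean tumor dose 115 Gy resin / 153 Gy glass; sphere
mix 25:23). Dispersions are chosen to reproduce plausible interquartile
spans, not to claim per-patient fidelity — no patient-level data exist to
fit. Outcomes follow a *stated* generative model:

* 6-month tumor control: Bernoulli with
  $\mathrm{logit}\,p = \mathrm{logit}(0.4) + \log(\mathrm{OR})\cdot
  \mathbb{1}[\mathrm{TNR} > \text{median}]$, default OR 5.9, the median
  taken within sphere type; about 21% of patients lose their 6-month
  status to short follow-up and are excluded listwise from the logistic
  analysis only.
* Overall survival: exponential with baseline median 14 months and hazard
  ratio 14/23 for supramedian post-treatment Dm, censored by an
  independent exponential clock (median 40 months).

All coefficients live in `cohort_params()`; nothing is hard-coded. The
generator records the sub-seeds and the supramedian indicators it actually
used, so recovery tests can compare estimates to truth: the suite checks
that a null OR is not rejected, that the KM median of covariate-free
exponential survival is $\ln 2/\lambda$, that a true OR of 6 is covered by
the 95% CI in ≥ 90% of replicate cohorts (n = 200, 100 replicates), and
that Cox recovers a true HR of 2 within [1.7, 2.35] in ≥ 90% of replicates
at n = 500.

`cohort_images()` optionally realises one phantom per patient from the
sampled volumes/TNR/activity. The statistical calibration runs on the
metric-level cohort — image simulation at those replicate counts would be
pointless cost, since the imaging chain's fidelity is established
separately by the phantom tests.

## Statistics layer

* `agreement_suite()`: Spearman (tie-corrected, asymptotic p), two-sided
  Wilcoxon signed-rank, and Bland–Altman mean difference with a t-based
  95% CI of the mean difference.
* `dichotomize()`: medians computed **within sphere type**, supramedian =
  strictly above. The strict rule puts a value exactly at the median in
  the inframedian group; with continuous metrics the case has probability
  zero, but the convention is documented and tested. Stratified medians
  respect the different tolerated dose ranges of resin and glass spheres
  without halving the sample for the outcome models.
* `logistic_univariate()`: ML fit via `glm` with a tightened convergence
  tolerance so the binary-covariate OR equals the 2×2 cross-product ratio
  $ad/bc$ to $10^{-6}$ relative (asserted exhaustively over all tables
  with cells 1..10). A zero cell is flagged as separation and the Wald CI
  reported as unbounded rather than pretending a finite one.
* `survival_suite()`: product-limit estimation via the survival package;
  the KM median is re-read from the step curve as the **smallest time with
  survival ≤ 0.5** (the common textbook rule; the survival package's
  printed median averages the boundary times when the curve sits exactly
  at 0.5, which is a different convention). Log-rank for two groups; Cox
  with **Breslow** tie handling — the simplest consistent choice, and with
  continuous survival times ties are rare enough that the choice is
  immaterial.
* `multivariate_gate()`: strict p < 0.05 (p = 0.05 excluded), then
  declared-redundant companions dropped, keeping the configured
  representative — mirroring the practice of not entering two near-copies
  of the same information into a small multivariate model.

Wald intervals are used for both OR and HR, matching the reporting
granularity the field uses for univariate predictor tables.

## The pipeline

`run_pipeline(pipeline_config())` chains everything: cohort → per-patient
phantoms → paired SPECT/PET-like counts → Dice QA on a deliberately
shifted liver contour (the configured `qa_shift_voxels` stands in for
registration error; failing patients are excluded from statistics but kept
in the QA report) → both contour families → calibration → LDM dose → the
ten Table-style metrics → agreement, dichotomization, logistic and
survival analyses. Outputs are CSV tables plus a JSON manifest carrying
the config, the derived stage seeds, the package version and the QA tally;
the YAML config round-trips through `read_config()`, and identical
config+seed reproduces every output byte-for-byte. All randomness flows
from one master seed through a single documented splitting scheme
(`sample.int` on the seeded generator), so no stage can silently
desynchronise another.

Default problem sizes — 48³ phantom grids for single-phantom work, 40³ ×
20 patients in the pipeline, 200-patient metric-level cohorts and 100
replicate cohorts for calibration — keep a full run in seconds while
leaving every statistical check comfortably powered; they are package
defaults, not limits, and scale with the config.

## Known limitations

Ellipsoid/sphere geometry cannot probe registration realism or irregular
tumor margins; the PSF is stationary and isotropic, unlike real SPECT
collimator response; Poisson noise on blurred means approximates, not
reproduces, reconstruction noise correlations; the outcome model is a
two-covariate stand-in, so the package recovers *its* truth, and no claim
is made that real dose–response coefficients are reproduced. Absolute
quantification, lung-shunt estimation from planar scans, activity-planning
models and image reconstruction are out of scope by design.
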