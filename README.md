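# dynclamp

An in-silico dynamic-clamp toolkit for phenotyping immature human
cardiomyocytes.

Cardiomyocytes derived from human induced pluripotent stem cells (hiPSC-CM)
are a mixed bag of ventricular-, atrial- and nodal-like cells, and their
weak inward-rectifier potassium current (IK1) leaves them resting at a
depolarized diastolic potential where chamber-specific action-potential (AP)
features cannot be read out. Dynamic clamp (DC) fixes this by computing a
model IK1 from the instantaneous membrane potential and injecting it back
into the cell in real time. `dynclamp` reproduces that whole experiment in
software, for electrophysiologists and modellers who want to study the
method itself — which IK1 formulation to inject, how much conductance is
enough, and how well AP biomarkers separate atrial-like from
ventricular-like cells — without a rig.

The package provides:

* **Four IK1 formulations** (`ik1_config()`, `ik1_current()`, `steady_iv()`,
  `iv_peak()`): the ventricular O'Hara-Rudy form
  `I = G * sqrt(Ko) * xK1 * RK1 * (V - EK)` with its slow gate
  `dx/dt = (x_inf - x)/tau` and rectification factor `RK1(V)`; the
  instantaneous atrial Koivumaki/Nygren form
  `I = G * Ko^0.4457 * (V - EK) / (1 + exp(1.5 (V - EK + 3.6) F/(R T 1000)))`;
  and two hybrid test variants that move the ventricular I/V peak
  (`test1`) or I/V decay (`test2`) onto the atrial ones.
* **A synthetic immature-cardiomyocyte surrogate** (`make_preset()`,
  `generate_cohort()`, `simulate_ap()`): a minimal membrane model with
  atrial/ventricular presets, depolarized unassisted diastolic potential,
  optional ultrarapid delayed rectifier (I_Kur, blockable with
  `apply_ikur_block()`), and seeded log-normal parameter jitter.
* **The virtual DC loop** (`run_dc()`, `switch_formulation()`,
  `ap_clamp()`, `titrate_gk1()`, `find_critical_gk1()`): 5 kHz zero-order
  hold injection with one-sample latency, in-run formulation switching,
  AP-clamp playback, and conductance titration over the published grids
  with plateau-based critical-conductance detection.
* **Biomarkers and variability** (`extract_biomarkers()`, `stv()`,
  `stv_apd_regression()`): the nine per-cell electrical biomarkers
  (capacitance, diastolic potentials with/without DC, APD90/APD50/APD20,
  APD20/APD90 triangulation ratio, maximal upstroke velocity, AP
  amplitude), and short-term variability
  `STV = sum|APD_{n+1} - APD_n| / (n_beats sqrt(2))` with Poincare pairs.
* **Unsupervised phenotype classification** (`classify_cohort()`,
  `standardize_and_pca2()`, `kmeans2()`, `roc_youden()`,
  `classify_by_cutoff()`, `mann_whitney_u()`, `levene_w()`): z-score ->
  PCA to 2-D -> k-means (k = 2), per-biomarker ROC with Youden-index
  cutoffs, and the APD20/APD90 >= 0.44 ventricular-like rule.

## Worked example

Where do the two formulations pass their maximal outward current, and does
a blinded pipeline recover the phenotypes of a synthetic cohort?

```r
library(dynclamp)

str(iv_peak(ik1_config("ventr")))
#> List of 2
#>  $ V_peak: num -82.7
#>  $ I_peak: num 9.51
str(iv_peak(ik1_config("atr")))
#> List of 2
#>  $ V_peak: num -72.8
#>  $ I_peak: num 5.44

cells <- generate_cohort(12, atrial_fraction = 0.5, seed = 7)
tab <- cohort_biomarkers(cells, ik1_config("atr", scaling_DC = 1),
                         stim_protocol(n_beats = 10, discard_beats = 5))
res <- classify_cohort(tab, seed = 11)
print(res)
#> cluster result: 12 cells -> 6 atrial-like, 6 ventricular-like
#>   PC1/PC2 variance explained: 55.6% / 17.5%
#>   agreement with ground truth: ARI 1.000, accuracy 1.000
#>   top discriminating biomarkers (cluster 1 vs 2):
#>     APD90_ms     AUC 1.000, cutoff 168.3
#>     APD50_ms     AUC 1.000, cutoff 157.3
#>     APD20_ms     AUC 1.000, cutoff 70.46
#>     APD20_APD90  AUC 1.000, cutoff 0.4099
```

The I/V peaks land at -82.7 mV (ventricular) and -72.8 mV (atrial): the
atrial formulation keeps delivering outward current at more depolarized
potentials, which is exactly why it repolarizes triangular atrial-like APs
cleanly where the strongly rectified ventricular form cannot. On the
12-cell synthetic cohort, DC recording with the atrial formulation followed
by PCA + k-means recovers the ground-truth phenotypes perfectly, with the
APD-family biomarkers doing the discriminating — the APD20/APD90 cutoff
found here (0.41) sits near the published 0.44 rule used by
`classify_by_cutoff()`.

A command-line interface wrapping the same functions ships in
`inst/cli/dynclamp` (subcommands `ik1-iv`, `ik1-peak`, `cell-simulate`,
`dc-run`, `dc-titrate`, `dc-ap-clamp`, `biomarkers-extract`, `stv-compute`,
`cohort-generate`, `classify-run`).

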