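---
title: "Virtual dynamic clamp with chamber-specific IK1: models and methods"
author: "dynclamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dynamic clamp with chamber-specific IK1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynclamp)
```

## The problem

Cardiomyocytes differentiated from human induced pluripotent stem cells
(hiPSC-CM) are a mixed population of immature ventricular-, atrial- and
nodal-like cells. Because the inward-rectifier potassium current IK1 is
weakly expressed in these cells, their diastolic membrane potential sits
depolarized (around -60 mV) and their action potentials are too immature for
chamber phenotyping. Dynamic clamp (DC) repairs this: a model IK1 is computed
in real time from the recorded membrane potential and injected back into the
cell, hyperpolarizing it to an adult-like diastolic potential so that
discriminative AP biomarkers can be measured.

`dynclamp` is an entirely in-silico rendition of that experiment: the patched
cell is replaced by a synthetic immature-cardiomyocyte surrogate, the DC rig
by a 5 kHz zero-order-hold injection loop, and the downstream analysis (nine
AP biomarkers, beat-to-beat variability, PCA + k-means phenotype clustering,
ROC-derived cutoffs) is implemented exactly as a recording campaign would run
it.

## The IK1 formulations

Four formulations are available through `ik1_config()`; all return current
density in pA/pF, outward positive, and all are exactly zero at the potassium
reversal potential `EK = -94.7 mV` (fixed from the recording solutions, not
recomputed by Nernst).

**Ventricular (ORd).** A slow gate with steady state
$x_{K1,\infty}(V) = \left[1 + e^{-(V + 2.5538\,K_o + 144.59)/(1.5692\,K_o + 3.8115)}\right]^{-1}$
and time constant
$\tau_{x,K1}(V) = 122.2 / \left(e^{-(V+127.2)/20.36} + e^{(V+236.8)/69.33}\right)$ ms,
relaxing as $dx/dt = (x_\infty - x)/\tau$, combined with an instantaneous
rectification factor
$R_{K1}(V) = \left[1 + e^{(V + 105.8 - 2.6\,K_o)/9.493}\right]^{-1}$:
$$I_{K1,Ventr} = G_{K1}\sqrt{K_o}\; x_{K1} R_{K1} (V - E_K), \qquad
G_{K1} = 1.908\,\mathrm{nS/pF} \times \mathrm{scaling_{DC}}.$$
Note that $x_{K1,\infty}$ *increases* with voltage (it deactivates only at
strongly hyperpolarized potentials and is essentially fully open above
-120 mV); the rectification factor $R_{K1}$ is what suppresses outward
current at depolarized potentials.

**Atrial (Koivumaki/Nygren).** Instantaneous, weakly rectifying:
$$I_{K1,Atr} = \frac{G_{K1}\, K_o^{0.4457} (V - E_K)}
{1 + e^{\,1.5 (V - E_K + 3.6)\, F/(R\,T\,1000)}}, \qquad
G_{K1} = 0.7\,\mathrm{nS/pF} \times \mathrm{scaling_{DC}},$$
with `V` in mV (hence the factor 1000 in the exponent) and `T = 308.15 K`
(recordings at 35 C).

**Two hybrid test variants** dissect which property of the ventricular
formulation matters. `test1` moves the I/V peak to the atrial position by
replacing the gate midpoint constant 144.59 with 57.836 (fixed conductance
6.417 nS/pF); `test2` moves the I/V *decay* onto the atrial one by widening
the rectification sigmoid to midpoint 135.8 mV and slope 15.493 mV (fixed
conductance 6.258 nS/pF). The test conductances are printed absolute values
and are deliberately not multiplied by `scaling_DC`.

At the default conditions the steady-state I/V peak (gating at steady state,
0.01 mV grid) falls at -82.7 mV for the ventricular formulation and -72.8 mV
for the atrial one:

```{r iv-peaks}
iv_peak(ik1_config("ventr"))
iv_peak(ik1_config("atr"))
```

## The virtual cell

The published experiment records real hiPSC-CM; no cell model accompanies
it. The surrogate here is therefore this package's own construction: a
minimal Hodgkin-Huxley-style membrane model whose role is to present the
*contracts* that matter for the method — a depolarized unassisted diastolic
potential, phenotype-specific repolarization, and an atrial-specific
ultrarapid delayed rectifier — not to reproduce any published hiPSC-CM
model. The membrane equation (per unit capacitance, so pA/pF = mV/ms) is
$$\frac{dV}{dt} = -(I_{Na} + I_{CaL} + I_{Krep} + I_{Kur} + I_{K1,nat}
+ I_{leak} + I_{inj}) + I_{stim}.$$

| current | form | role |
|---|---|---|
| $I_{Na}$ | $g_{Na} m^3 h (V - 50)$, $\tau_m = 0.25$ ms, $\tau_h = 3$ ms | upstroke |
| $I_{CaL}$ | $g_{CaL}\, d f (V - 60)$, $f$ has a 5% non-inactivating pedestal | plateau/dome |
| $I_{Krep}$ | $g_{Krep}\, n (V + 94.7)$ | delayed repolarization |
| $I_{Kur}$ | $g_{Kur}\, a\, i (V + 94.7)$, fast activation, slow inactivation | atrial phase-1 |
| $I_{K1,nat}$ | $g_{K1}\,(V + 94.7)/(1 + e^{(V+40)/30})$ | weak native rectifier |
| $I_{leak}$ | $g_{leak} (V + 20)$ | depolarizing background |

Preset conductances (nS/pF): atrial `g_Na 2.4, g_CaL 0.18, g_Krep 0.03,
g_Kur 0.06` with faster inactivation/activation clocks (`tau_f` 150 ms,
`tau_n` 60 ms); ventricular `g_Na 2.0, g_CaL 0.38, g_Krep 0.06, g_Kur 0`
with slower clocks (200/150 ms). Both share `Cm = 70 pF` on average — the
recorded clusters in the source experiment did not differ in capacitance, so
capacitance deliberately carries no phenotype information here. The native
inward rectifier scales with a `maturity` parameter in [0, 1]
(`g_K1 = 0.036 + 0.036 * maturity`), placing the unassisted diastolic
potential between roughly -55 and -67 mV.

Cohort heterogeneity is multiplicative log-normal jitter (CV 0.15, chosen as
a typical cell-to-cell conductance spread in patch-clamp cohorts) applied
per conductance; the two background conductances (`g_K1_native`, `g_leak`)
share a single density factor so that their ratio — which pins the
unassisted diastolic potential — is controlled by maturity rather than by
independent noise. Pacing follows the recording protocol: 1 Hz square pulses
(30 pA/pF, 3 ms — suprathreshold by a wide margin), with the first five
beats discarded as the diastolic transient.

What the generator emulates: depolarized diastolic potentials, triangular
short atrial APs versus plateaued long ventricular APs (APD20/APD90 clearly
below vs above ~0.4), I_Kur sensitivity to 4-aminopyridine (50 uM is mapped
to a 0.9 fractional block, configurable), and Std-vs-RA-like differences in
cohort composition through `atrial_fraction`. What it does not emulate:
calcium handling, spontaneous (nodal) activity, beat-to-beat ion
accumulation, electrotonic coupling, or seal-leak artefacts. Passing the
cohort-level tests therefore demonstrates that the *pipeline* discriminates
the constructed phenotypes; it is not evidence about real hiPSC-CM.

## The dynamic-clamp loop

The loop mirrors a 5 kHz real-time rig: once per 0.2 ms sample the injected
IK1 is computed from the most recent membrane potential and held constant for
the interval (zero-order hold, i.e. a one-sample latency); gated formulations
carry their gate state across samples with an exact exponential
(Rush-Larsen) update. A `scaling_DC = 0` run goes through the identical code
path and reproduces the uninjected trace bitwise. `switch_formulation()`
swaps the injected model at the next sampling instant and re-initializes the
gate to its steady state at the instantaneous potential, as a real-time
module swap would. A continuously-coupled integration mode exists purely as
a validation reference: at 5 kHz the hold introduces well under 2% APD90
error on both presets.

Internally the membrane is advanced with fixed substeps (`dt_internal`,
default 0.02 ms, i.e. 10 substeps per sample): gates by exact exponential
updates (all surrogate gate time constants are voltage-independent), voltage
by forward Euler. An adaptive stiff solver was considered and rejected: the
loop must advance sample-by-sample anyway, the fastest time constant
(0.25 ms) is an order of magnitude above the substep, the zero-conductance
identity requires one shared code path, and halving `dt_internal` moves
APD90 by well under 1% (tested). Divergence (non-finite or |V| > 150 mV) is
reported as an explicit simulation failure naming the beat.

## Conductance titration and the critical conductance

`titrate_gk1()` reruns the DC loop over the published scaling grids — 0.2 to
1 in 0.05 steps (atrial), 0.4 to 2 in 0.1 steps (ventricular), 17 points
each — and tabulates E_diast, APD90, APD20/APD90 and APA, each the median of
the analyzed beats. The source experiment reports *that* the biomarkers
stabilize but not a quantitative rule, so the rule here is the package's
own, configurable definition: the critical conductance is the smallest grid
value from which every tracked biomarker changes by less than `rel_tol`
(default 3%) between all consecutive remaining points. Changes are relative
to each biomarker's magnitude except for the triangulation ratio, which is
bounded by 1 and is measured on the unit scale (otherwise a 0.005 absolute
wobble in a ratio of 0.1 would read as 5%). Failed grid points are flagged
and skipped rather than aborting the table; absence of a plateau is an
explicit no-convergence result, not an error. On the default surrogates the
plateau is reached early (scaling 0.25 atrial, 0.4 ventricular, i.e. 0.18
and 0.76 nS/pF); the experimentally reported critical conductances for real
hiPSC-CM are 0.7 nS/pF (atrial formulation) and 1.9 nS/pF (ventricular) —
different cell, different numbers, and no numerical equality is asserted
anywhere.

## Biomarkers and variability

`extract_biomarkers()` measures, per beat and aggregated by the median
(robust to one anomalous beat): diastolic potential (mean over the 10-to-1 ms
pre-stimulus window), AP amplitude (peak minus diastolic), maximal upstroke
velocity (largest forward-difference dV/dt), and APD90/APD50/APD20 — the
time from the AP onset fiducial to the first downward crossing of
`V_peak - (x/100) * APA`, located by linear interpolation. The onset
fiducial is the instant of maximal dV/dt; the source methods do not pin this
choice, so a threshold-crossing alternative is available
(`fiducial = "threshold"`). A beat must overshoot 0 mV to count as an AP,
and a beat whose repolarization never reaches the 90% level is excluded with
a warning. The unassisted diastolic potential comes from a companion
no-injection run of the same cell; when only a DC recording exists it is
reported as missing.

Short-term variability uses the standard Poincare-based definition
$STV = \sum |APD_{n+1} - APD_n| / (n_{beats}\sqrt{2})$
over 30 consecutive differences. The printed formula is ambiguous about
whether "30 APs" yield 29 or 30 differences; this package requires
`n_beats + 1 = 31` values so the divisor matches the number of differences
exactly. The deterministic surrogate produces zero STV by construction;
`simulate_ap(..., noise_sd = )` adds a seeded per-sample held current noise
for variability studies. `stv_apd_regression()` is ordinary least squares
with the standard t-based 95% confidence band.

## Classification pipeline

`classify_cohort()` chains the published processing steps with the
package's own resolutions of its unstated details:

* the nine biomarkers are z-scored before PCA — their raw units differ by
  orders of magnitude, so an unstandardized projection would be dominated by
  APD milliseconds;
* PCA keeps two components; signs are canonicalized (APD90 loading on PC1
  non-negative) since a global flip is an equivalent solution;
* k-means with k = 2 runs on the 2-D scores via `stats::kmeans` with 10
  random restarts under a fixed seed (restart count stands in for k-means++
  seeding; with 46 points in 2-D the best-inertia solution is stable);
* cluster semantics are assigned post hoc by mean APD90 (lower =
  atrial-like), mirroring how the experimenters named their clusters from
  the biomarker pattern;
* per-biomarker ROC curves discriminate the two *clusters*; AUC uses the
  rank (Mann-Whitney) identity, the cutoff maximizes the Youden index
  J = sensitivity + specificity - 1 with ties broken toward the lower
  threshold;
* the rule-based classifier calls a cell ventricular-like when
  APD20/APD90 >= 0.44 (the boundary is ventricular, following the published
  cutoff semantics) and atrial-like below it.

Group comparisons go through the field-standard tests: Mann-Whitney U
(exact for tie-free groups of up to 8, normal approximation otherwise) and
the classic mean-centred Levene statistic (`car::leveneTest`), with
missing-feature columns median-imputed (warning) or dropped when more than
half missing.

## Problem sizes and determinism

The packaged analyses and tests run at deliberately modest sizes chosen to
exercise every code path at interactive speed: 15-beat recordings (5
discarded, medians over 10 analyzed beats), 46-cell cohorts (matching the
published cohort size) at a 50/50 preset mix, the full 17-point titration
grids, and 0.01 mV I/V grids. Every stochastic step (preset jitter, cohort
composition, k-means restarts, noise streams) is seeded; identical seeds
give byte-identical fixture suites (`write_fixture_suite()`).

## Known limitations

* The surrogate is a phenomenological minimal model; its parameters were
  calibrated once against the contracts above and make no claim of ionic
  realism beyond them.
* STV analyses on the surrogate are only meaningful with injected noise;
  the noise model (white, held per sample) is simpler than physiological
  beat-to-beat variability.
* The classification pipeline assumes exactly two phenotypes; nodal-like
  cells are out of scope.
* Published cohort-level numbers (AUC 0.996, cutoff 0.44, 78.9% 4-AP
  accuracy) belong to the authors' recorded cells and cannot be reproduced
  from a synthetic surrogate; the corresponding checks here are
  property-based (separation, ordering, band membership) by design.
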