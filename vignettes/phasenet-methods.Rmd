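---
title: "Methods: phase-lag connectivity and network-based statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-lag connectivity and network-based statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasenet)
```

## The problem

Resting-state MEG studies of paediatric cohorts — for instance children
born at very low birth weight (VLBW, < 1,500 g) compared with full-term
controls — ask whether whole-brain oscillatory networks differ between
groups, and whether network strength relates to cognitive outcomes
(IQ-like and behaviour scores) or to clinical exposures such as early
macronutrient intake. The analysis chain is long: source-space region time
series are cleaned, epoched and quality-controlled; band-limited
instantaneous phase is extracted; phase-lag connectivity is estimated per
region pair; and network-level inference is drawn with permutation-based
family-wise error (FWER) control. Each stage has failure modes that are
invisible without ground truth. phasenet implements the chain as tested,
reusable functions and pairs it with a synthetic-cohort generator that
plants known coupling, so every stage can be validated before being
pointed at real data.

The pipeline deliberately starts at *source-space region time series*
(e.g. the 90 regions of the AAL parcellation). Sensor-level processing —
ICA artefact removal, head modelling, beamforming, MRI co-registration —
requires raw scanner data and is out of scope; users of real data supply
region-by-time matrices or ready-made connectivity matrices.

## Connectivity model

For two analytic signals $z_i(t)$, $z_j(t)$ with cross-spectrum
$X_t = z_i(t)\,\overline{z_j(t)}$, the weighted phase lag index is

$$\mathrm{wPLI}_{ij} \;=\;
  \frac{\bigl|\sum_t \operatorname{Im} X_t\bigr|}
       {\sum_t \bigl|\operatorname{Im} X_t\bigr|} \in [0, 1].$$

Phase differences are weighted by the magnitude of the imaginary part of
the cross-spectrum, so quarter-cycle (90°) lags carry maximal weight and
purely instantaneous (zero-lag) coupling contributes nothing. This makes
the estimator robust to volume conduction / field spread, which mixes
sources into channels with zero lag. Conventions:

* the standard wPLI is used, not the debiased squared variant — the
  debiased estimator can be negative, while this one stays in $[0,1]$
  with 0 meaning no phase locking and 1 full phase locking;
* when the denominator is zero (pure zero-lag or silent input) the value
  is 0 by convention;
* wPLI is computed **within** each epoch over time samples, then averaged
  arithmetically across epochs. Pooling all samples before taking the
  ratio was considered and rejected: it changes the estimator and its
  bias, and epoch-wise estimation matches the way the measure is reported
  in the resting-state literature;
* the diagonal is fixed at 0 and excluded everywhere downstream.

The estimator is biased upward at small sample counts (the ratio of an
absolute sum to a sum of absolute values does not vanish for finite
independent samples); the test suite measures this bias shrinking with
epoch length. Comparisons between subjects are unaffected because every
subject is estimated with the same epoch geometry, but absolute wPLI
values from short epochs should not be over-interpreted.

## Preprocessing rules

* **Broadband cleaning** — 1–150 Hz fourth-order two-pass Butterworth
  band-pass plus notches at 60 and 120 Hz (applied when below Nyquist).
  For working rates that cannot support the 150 Hz edge, the edge clips
  to $0.45 \times$ rate with a warning.
* **Epoching** — non-overlapping 10 s epochs by default; the trailing
  remainder is discarded.
* **QC exclusion** — an epoch is dropped when its head-position deviation
  exceeds 5 mm (*strictly*: exactly 5 mm is retained, the rule is "more
  than") or when any sample exceeds the absolute amplitude limit
  (*strictly*, again "exceeding"). The amplitude limit corresponds to the
  conventional ±2 pT sensor-space rule; since pT is meaningless after
  source reconstruction, the limit is configurable in working units, and
  the simulated pipeline default disables it (simulation amplitudes are
  on an arbitrary scale). Missing motion values are exclusions with their
  own log reason. Every input epoch appears exactly once in the QC log;
  the operation is idempotent.
* **Inclusion rule** — a subject enters group analysis only with ≥ 6
  surviving epochs (1 min of data at 10 s epochs).
* **Band decomposition** — five canonical bands: theta 4–7, alpha 8–14,
  beta 15–29, low gamma 30–55, gamma 65–80 Hz. (Parts of the literature
  call 8–12 Hz "alpha"; the 8–14 Hz convention is adopted and stated
  here so users are not surprised.) Filtering is a windowed-sinc FIR,
  applied as a two-pass (zero-phase) operation, with order at least three
  cycles of the band's low edge at the working rate. The two passes are
  implemented as one symmetric kernel (the filter convolved with its
  reverse) applied by FFT convolution, which is identical to
  forward–backward filtering away from epoch edges and an order of
  magnitude faster in R; the edges are trimmed anyway (next point).
* **Analytic signal** — FFT-based Hilbert transform per region and epoch.
  A configurable number of edge samples (default: the filter order) is
  trimmed from both ends of each epoch so filter and Hilbert edge
  transients never reach the connectivity estimator.

## Network-based statistic

Inference is at the network level. For a stack of per-subject
connectivity matrices (one band at a time):

1. **Edge z-scoring.** Each unique edge is standardised across
   participants (sample SD, $n-1$). The z-scoring axis is per edge
   across participants — the only orientation compatible with an
   edge-wise GLM; zero-variance edges are zeroed and flagged.
2. **Edge-wise GLM.** Ordinary least squares of the z-scored wPLI on an
   intercept, the predictor of interest, and nuisance covariates
   (default: age at scan and sex). The t statistic of the predictor is
   the edge statistic. With a binary predictor and no covariates this is
   exactly the classical pooled-variance two-sample t-test (verified to
   1e-10 in tests). Subjects missing the predictor or a covariate are
   dropped listwise per analysis, with counts reported — different
   analyses may legitimately have different degrees of freedom.
3. **Primary threshold.** A data-driven numeric t threshold retains a
   target fraction of edges (default 1%: for 90 regions, 40 of 4,005
   unique edges). The threshold is the k-th largest direction-signed
   statistic; ties at the cut are all kept and reported. The numeric
   threshold is fixed from the *observed* data and re-applied unchanged
   inside permutations — re-deriving the quantile per permutation would
   guarantee supra-threshold edges in every permutation by construction
   and destroy the test's meaning.
4. **Components.** Connected components of the supra-threshold graph.
   The component statistic is its *extent* (edge count); intensity-style
   statistics are not used, matching how such networks are convention-
   ally reported (edges, nodes).
5. **Permutation null.** For each permutation the maximum component
   extent is recorded. With no covariates and a group contrast, group
   labels are permuted directly. Whenever covariates are present, or the
   predictor is continuous, Freedman–Lane permutation is used: residuals
   of the reduced (covariates-only) model are permuted and added back to
   the reduced fit before re-estimating the full model. Plain label
   permutation is not exchangeable under nuisance covariates; Freedman–
   Lane is the standard fix.
6. **FWER p-values.** Each observed component gets
   $p = (1 + \#\{\text{null} \ge \text{extent}\}) / (1 + N)$, so the
   observed statistic is counted in its own null and $p \ge 1/(1+N)$.

Testing is one-sided per direction; increased and decreased connectivity
are separate analyses, as is conventional for this statistic. Frequency
bands are tested independently without cross-band correction, matching
standard practice in the source literature; users wanting a global
correction can combine the per-band results themselves.

## The synthetic cohort

The generator emulates what arrives *after* source reconstruction:

* Each region carries one independent unit-variance band-limited carrier
  per band — white noise band-pass filtered, **not** a pure sinusoid.
  Pure tones make wPLI trivially 1 and hide estimator bugs;
  stochastic carriers give non-degenerate instantaneous phase.
* A planted edge $(i, j, \text{band})$ replaces region $j$'s carrier in
  that band with
  $\kappa \cdot \text{delay}(x_i) + \sqrt{1-\kappa^2}\, e_j$, where the
  delay realises the requested phase lag (default $\pi/2$, the lag wPLI
  weights most) at the band centre frequency, and $\kappa \in [0,1]$ is
  group-dependent. The delay-based implementation is well defined for
  narrowband signals; a lag that rounds below one sample at the working
  rate is rejected as unrepresentable.
* Optional field spread mixes each region instantaneously with its
  neighbours in atlas order: $(1-s)\cdot\text{own} + s\cdot\text{mean of
  the two ring neighbours}$. Being purely zero-lag, it must not move
  wPLI — the tests verify this, including for pairs that share a mixing
  neighbour (the classic spurious-synchrony configuration).
* Broadband Gaussian noise with configurable SD is added. No
  physiological amplitude scale is asserted — the source literature
  provides none — so SNR is an explicit simulation knob (`noise_sd`,
  default 0.5 against unit-SD carriers).
* Subject metadata: sex and age are drawn independently of group by
  default (configurable per group, e.g. to test covariate adjustment);
  outcome scores follow
  $\beta_0 + \beta_1 \kappa + \text{covariate terms} + \varepsilon$,
  defaulting to an IQ-like scale (100 ± 15) and a BASC-like T-score
  (50 ± 10) with no planted effect; daily nutrient intakes for postnatal
  days 1–29 are drawn per nutrient with defaults matching the reported
  cohort means — protein 3.6 (0.5), lipid 4.9 (1.1), carbohydrate
  11.9 (1.3) g/kg/day, energy 105.6 (14.9) kcal/kg/day — with an
  optional linkage coefficient to $\kappa$. Days 1–8 are generated but
  ignored by the day 9–29 summariser, mirroring the exclusion of the
  parenteral-feeding week.
* Determinism: the full cohort is a pure function of the spec and its
  seed; per-subject series are a pure function of spec seed + subject
  id. Tests assert bit-identical serialisations.

What the generator does **not** emulate: realistic head geometry or
leadfields (mixing is ring-topological, not anatomical), 1/f spectral
shape, non-stationarity, artefact waveforms (motion and amplitude QC are
driven by simulated scalar traces), or the demographic joint
distribution of any real cohort. Passing tests therefore demonstrate
estimator and inference correctness, not robustness to every property of
real MEG.

## Default parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `sampling_rate` | 300 | Hz | keeps the 65–80 Hz band well below Nyquist at desk-scale cost (recordings in this literature are typically 600 Hz) |
| `epoch_length` | 10 | s | the epoch geometry of the emulated studies |
| `n_epochs` | 30 | — | a 5-min recording |
| `phase_lag` | π/2 | rad | the lag wPLI weights maximally; makes planted effects interpretable |
| `noise_sd` | 0.5 | carrier SD | moderate SNR; carriers are unit SD |
| `motion_limit` | 5 | mm | the "more than 5 mm" exclusion rule |
| `amplitude_limit` | 2 | field units | the ±2 pT rule, reinterpreted as a configurable working-unit limit |
| `minimum` epochs | 6 | — | 1 min of 10 s epochs |
| `target_edge_fraction` | 0.01 | — | ~40 of 4,005 edges at 90 regions |
| `n_permutations` | 5000 | — | conventional budget; ≥ 100 enforced |
| `alpha` | 0.05 | — | component significance level |

## Numerical choices and degenerate inputs

* Threshold ties: all edges tied at the cut are retained (count
  reported); an all-tied statistic vector keeps everything, with a
  message.
* A target fraction that rounds to zero edges keeps one edge, with a
  warning.
* Denominator-zero wPLI returns 0 ("no phase locking").
* Zero-variance edges z-score to zero and are flagged; their GLM t is 0,
  so they can never enter a component.
* Rank-deficient designs error, naming the collinear columns; designs
  with fewer than 6 subjects after listwise deletion error rather than
  permute meaninglessly.
* Group factors are coded 0/1 by factor-level order (second level = 1),
  so for groups A/B the positive direction tests B > A; the demo config
  uses `direction = "negative"` to test A > B.
* Percentages in intake summaries round half away from zero to integer
  percent (24/37 → 65%), matching the reporting style of clinical
  tables; base R's round-half-even would give the same here but not in
  general.
* Achievement flags use meets-or-exceeds (≥) against the enteral
  recommendations: protein 3.5, lipid 4.8, carbohydrate 11.6 g/kg/day,
  energy 110 kcal/kg/day.
* The chi-square for categorical demographics is Pearson's without
  continuity correction — with correction, the canonical 2×2 sex table
  (16:21 vs 15:12) does not reproduce its published statistic (0.95).

## Scale of the validation suites

The test-suite simulation sizes are chosen for desk-scale runtime while
keeping the statistical checks meaningful; they are stated here as the
package's own validation conditions:

* FWER calibration: 200 null cohorts of 10+10 subjects, 30 regions,
  5 × 2 s epochs at 100 Hz, alpha band, 500 permutations each; the
  fraction of cohorts with any significant component must not exceed
  0.05 plus two binomial standard errors. (Calibration does not depend
  on epoch length, so short epochs are used.)
* Planted recovery: 20 cohorts of 20+20 subjects, 30 regions, a 6-edge
  alpha star with κ 0.6 vs 0.1, 5 × 6 s epochs, 500 permutations,
  primary threshold at 1.5% of 435 edges (≈ 7 edges, commensurate with
  the 6-edge planted network and the same order as the 1%-of-4,005
  convention); success = a significant component with edge Jaccard ≥ 0.5
  against ground truth, required in ≥ 80% of cohorts. Longer epochs are
  used here because recovery, unlike calibration, depends on estimator
  variance.
* Exhaustive-permutation cross-check at 4+4 subjects (all 70 distinct
  label assignments) against an independent oracle implementing the
  two-sample t formula and breadth-first component search directly.
* Component extraction against a brute-force search oracle on 1,000
  random graphs of up to 20 nodes.
* Zero-lag immunity: 200 paired simulations with and without field
  spread at strength 0.3.

## Worked example

```{r example, eval = FALSE}
library(phasenet)

planted <- tibble::tibble(i = 1L, j = 2:5, band = "alpha")
spec <- cohort_spec(
  n_group_a = 15, n_group_b = 15, n_regions = 30,
  sampling_rate = 100, epoch_length = 6, n_epochs = 5,
  bands = canonical_bands()[1:2, ], planted_edges = planted,
  coupling_a = 0.6, coupling_b = 0.2, noise_sd = 0.5, seed = 42
)
cohort <- generate_cohort(spec)
mats <- lapply(cohort$series, function(es)
  subject_connectivity(band_analytic(es, "alpha")))
stack <- zscore_edges(unname(mats))
res <- nbs_test(stack, cohort$cohort,
                design_spec("group_contrast", "group",
                            direction = "negative",
                            target_edge_fraction = 0.015,
                            n_permutations = 1000, seed = 43))
tidy(res)
autoplot(res)
node_degree(res$components[[1]])
```

Or end to end, with QC, multiple bands and file outputs:

```{r pipeline, eval = FALSE}
res <- run_pipeline(demo_config(seed = 1))
res$summary
```

## Known limitations

* The generator's field spread is topological (ring neighbours), not a
  leadfield; it exercises the zero-lag-immunity property, not realistic
  leakage geometry.
* The packaged AAL-90 atlas table uses the standard region labels but
  synthetic approximate centroid coordinates, suitable for BrainNet-
  format export and layout only; users with real coordinates should
  supply their own file to `load_atlas()`.
* Epoch-level wPLI from short epochs is biased upward; the package
  reports `n_epochs_used` and the vignette's guidance is to compare only
  like-geometry estimates.
* No sensor-space processing, no ICA, no beamforming, no 3-D rendering.
* Permutation p-values are Monte-Carlo estimates; with the default 5,000
  permutations the smallest attainable p is 1/5001.
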