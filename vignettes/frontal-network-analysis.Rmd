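---
title: "Methods: resting-state fNIRS frontal network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state fNIRS frontal network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsnet)
```

This vignette is the package's account of its science: the signal model
and preprocessing chain, the network construction and topological metrics,
the statistical machinery, what the synthetic cohort generator does and
does not emulate, and the numerical and design choices made where the
design was genuinely open.

## 1. Signal model and preprocessing

Continuous-wave fNIRS measures, per channel (one source–detector pair at a
nominal 3 cm separation) and wavelength (690 and 830 nm), a light
intensity time series at 20 Hz. The analysis assumes the usual
differential formulation: slow changes in chromophore concentration
modulate attenuation around an arbitrary baseline, so only *changes* in
optical density and hemoglobin are meaningful.

`run_preprocess()` composes five stages, in a fixed order:

1. **Optical density.** `ΔOD(t) = −ln(I(t)/Ī)` per trace, with `Ī` the
   trace's own temporal mean. A constant trace maps to exactly zero; by
   Jensen's inequality the mean of a fluctuating trace's OD is a small
   positive residual, which is irrelevant downstream because the band-pass
   removes the mean.
2. **Trimming.** The first and last 60 s are dropped (settling and removal
   transients), so a 300 s record keeps 180 s = 3600 samples.
3. **Motion detection and spline correction.** Detection flags windows
   (default 1 s) whose SD exceeds `sd_mult` (default 13.5) times the
   channel's *median* moving-window SD, or whose peak-to-peak amplitude
   exceeds `amp_thresh` (default 0.4 OD), merged and padded by a 0.5 s
   margin. The median-based SD reference makes the rule robust when
   artifacts are frequent. Correction is MARA-style: within each flagged
   interval a near-interpolating smoothing spline
   (`smooth.spline(spar = 0, all.knots = TRUE)`, the analogue of a
   `csaps` smoothing parameter near 0.99) is subtracted — removing nearly
   all within-interval excursion — and the interval is re-levelled to the
   mean of the preceding second of signal. Unflagged samples are never
   modified; a residual step can therefore survive at an interval's
   trailing edge, which the subsequent high-pass largely absorbs.
4. **Band-pass.** Zero-phase 3rd-order Butterworth, 0.01–0.1 Hz, removing
   drift below the band and the physiological confounds above it (Mayer
   waves ~0.1 Hz at the band edge, respiration ~0.4 Hz, cardiac
   1–1.5 Hz). Implementation note: the forward–backward filter is applied
   to an odd-reflection-padded signal *and* to its time reversal, and the
   two outputs averaged. This symmetrized form has the same squared
   Butterworth magnitude response but is exactly time-reversal symmetric
   in floating point, a property the tests assert at 1e-9 (a plain
   `filtfilt` differs at the record edges). Measured response: 0.05 Hz
   passes within 0.2 dB; 0.4 Hz and 1.2 Hz probes are attenuated by more
   than 50 dB.
5. **Modified Beer–Lambert inversion.** Per channel and sample the 2 × 2
   system `ΔOD(λ) = Σ_c ε_c(λ)·Δc·d·DPF(λ)` is solved for
   `(ΔHbO, ΔHbR)` in μM. The acquisition defines only the law and the
   wavelengths, so the constants are package defaults, all overridable in
   `mbll_coefficients()`: extinction coefficients from a standard
   published compilation of hemoglobin spectra (in 1/(mM·cm): 690 nm —
   HbO 0.2764, HbR 2.0520; 830 nm — HbO 0.9740, HbR 0.6930), `DPF = 6.0`
   at both wavelengths, `d = 3` cm. Because the same constants are used by
   the forward simulator, round-trip recovery is exact to numerical
   precision (asserted at 1e-9); with *real* data the constants scale the
   μM values but cancel entirely in correlation-based connectivity, so
   the network results are insensitive to them.

**Subject exclusion.** The study design excludes subjects for head
movement without stating a criterion; the package's rule — exclude when
more than 20 % of samples are masked on more than 30 % of channels — is a
design choice, configurable in `preprocess_config()`. Excluded subjects
carry the reason `"head movement"` into the pipeline log and shrink the
group tables.

Only HbO is analysed downstream (better signal-to-noise than HbR); the
HbR traces are produced and returned but unused.

## 2. Connectivity and thresholded graphs

Connectivity is the full-series Pearson correlation between HbO traces.
The three midline channels (25, 28, 29) belong to neither hemisphere and
are removed, leaving the 50-node lateral matrix. Fisher's
`z = arctanh(r)` normalizes the retained coefficients; negative
correlations are set to zero (analysis confined to positive coupling).
Degenerate cases: off-diagonal `r = 1` (duplicate traces) is clamped to
`arctanh(1 − 1e-7)` with a warning; a zero-variance channel keeps its
row/column (matrix stays 50 × 50) but contributes no edges and is
reported.

Binary graphs retain an edge where the connection strength is *strictly*
greater than the threshold, for each of the eleven thresholds 0.40–0.90 in
steps of 0.05. The threshold is applied on the **r scale** by default: the
sweep's upper values (0.8, 0.9) are reachable for correlations but not
for typical z values, and the sweep is defined on connection strength,
which is the correlation. `threshold_scale = "z"` switches the
scale for toolbox parity. Edge sets are nested across the sweep by
construction (a property test asserts this), and each subject's mean edge
count across the eleven thresholds serves as their total-edge summary.

## 3. Topological metrics and AUC summarization

All metrics operate on binary undirected graphs (the sweep-and-AUC design
implies binarization; weighted variants are out of scope).

* `NCp(i) = 2T(i)/(k_i(k_i−1))` — nodal clustering, triangles over
  possible neighbour pairs; 0 when the degree is below 2.
* `NLe(i)` — nodal local efficiency: the global efficiency of the subgraph
  induced by `i`'s neighbours with `i` removed; 0 when the degree is
  below 2.
* `Cp = mean(NCp)`, `Eloc = mean(NLe)` — by construction, asserted on
  every graph in the tests.
* `Eg` — mean inverse shortest-path distance over distinct pairs, with
  `1/∞ = 0` for unreachable pairs.
* `Lp` — mean shortest-path distance. Three conventions are implemented
  for disconnected graphs (see below).
* `σ = (Cp/⟨Cp_rand⟩)/(Lp/⟨Lp_rand⟩)` — small-worldness against `M = 100`
  Maslov–Sneppen degree-preserving rewirings per graph (10 swap attempts
  per edge), seeded and bit-for-bit reproducible. A graph admitting no
  swap (a star) yields unchanged copies with a warning. Canonical
  behaviour is tested: a Watts–Strogatz ring gives `σ > 1`, an
  Erdős–Rényi graph `σ ≈ 1`, and a graph against itself exactly 1.

These implementations ride on igraph primitives; the test suite verifies
them against independent brute-force oracles (triangle enumeration and
Floyd–Warshall shortest paths) on over 100 random graphs per run, plus
closed forms (`K_n`: Cp = Lp = Eg = 1; `P3`: Lp = 4/3, Eg = 5/6).

**The disconnected-Lp problem.** Thresholded graphs fragment as the sweep
tightens, and the convention for `Lp` then matters more than any other
numerical choice in the package:

* `"reachable"` (the default of `characteristic_path_length()`, matching
  its arithmetic definition): average over reachable pairs only. On a
  fragmenting graph this *collapses* — many small components have short
  internal paths — so a sparser group can show a paradoxically *lower*
  Lp AUC. During development this inverted the expected patient-vs-control
  direction on the synthetic cohort at every seed tried.
* `"harmonic"`: the harmonic mean distance, with unreachable pairs
  contributing `1/d = 0`; identical to `1/Eg`. This grows as a graph
  fragments, matching the behaviour of the toolboxes commonly used for
  such analyses, and is the **pipeline default** for the metric curves.
* `"inf"`: any unreachable pair makes Lp infinite (strictest reading).

Within the threshold sweep the harmonic Lp curve is additionally bounded
at the node count: the harmonic mean distance of any *connected* graph is
below `n`, so values above it only encode how fragmented the graph is
(the raw `1/Eg` of a near-empty 50-node graph is in the hundreds and
would dominate the AUC with noise), and an empty graph contributes the
bound itself — a graph with no edges has the worst possible integration,
not a path length of zero. Other metrics (`Cp`, `Eg`, `Eloc`, `σ`) go to
0 naturally on empty graphs.

Each metric's curve over the eleven thresholds is summarised by the
trapezoidal AUC (`auc_threshold()`; a left-rectangle rule is available
for parity with toolboxes that use it). Nodal AUCs are averaged within
the ten hemisphere × region groups of the channel atlas to give the
region-level values used in group statistics.

## 4. Group statistics

* Normality: Shapiro–Wilk per variable (`normality_check()`), logged.
* Gender: Pearson chi-square on the 2 × 2 table, continuity correction
  off by default (configurable).
* Global metric AUCs: two-sample t-tests, pooled-variance Student form by
  default ("two-sample t-test" without qualification conventionally means
  the equal-variance form; Welch is a switch), two-sided, α = 0.05,
  uncorrected — five planned comparisons.
* Edgewise: a mass-univariate pooled-variance t on the Fisher-z value of
  each of the 1225 node pairs, Benjamini–Hochberg corrected *across
  edges*, significant at adjusted p < 0.01. "FDR correction" without a
  named procedure is read as Benjamini–Hochberg, the standard referent;
  Benjamini–Yekutieli is available where dependence-robust control is
  wanted. Edges with degenerate variance in both groups are excluded and
  counted.
* Region-averaged nodal AUCs: t-tests BH-corrected within each metric
  family (the ten regions of NCp, the ten of NLe), α = 0.05.
* CRS-R correlations: Pearson r with two-sided p between the patients'
  region-averaged nodal AUCs and the six subscales plus total. By default
  only metrics that survived the group comparison are correlated
  (`gate_correlations = TRUE`), mirroring the confirmatory design; the
  raw p-values are reported without further correction. The gate can be disabled for exploratory runs
  (the acceptance script does so, to report the right-DLPFC–auditory
  correlations unconditionally).

The FDR machinery is validated two ways: a hand-computed step-up case,
and a simulation (200 replicates of 1000 uniform null p-values) checking
the empirical false-discovery proportion stays at or below the nominal
level within Monte-Carlo error; a permuted-label edgewise run on
homogeneous groups is checked to produce essentially no survivors.

## 5. The synthetic cohort generator

No real recordings ship with the package, so the generator *is* the
ground truth against which the pipeline is validated. It emulates, per
subject:

* **Structure**: a block correlation matrix over the atlas —
  `r_within = 0.65` inside each hemisphere × region group,
  `r_between = 0.35` elsewhere, unit diagonal. In patients every entry
  touching a designated region (default left FPA and right DLPFC,
  the regions where the group deficits are expected) is multiplied by an
  attenuation factor drawn per subject
  (`Normal(0.6, 0.12)` truncated to `[0.05, 1]`), and the matrix is
  projected to the nearest positive semidefinite correlation matrix by
  eigenvalue clipping (tolerance 1e-10, unit-diagonal rescale). The
  within/between levels are typical of published resting-state fNIRS
  frontal connectivity; the attenuation of 0.6 produces group contrasts
  of roughly the published magnitude at n = 16 vs 15.
* **Neural signal**: band-limited (0.01–0.1 Hz) Gaussian HbO with that
  covariance, at `neural_sd = 0.06` μM. The noise is generated on an
  extended record and the centre taken (no filter edge transients), then
  *empirically whitened* so the record's sample covariance equals the
  target exactly. Without whitening, a 5-minute band-limited record holds
  only ~50 effective samples and the realized correlations would scatter
  around the target with SD ≈ 0.15, leaving the generator without a
  well-defined truth; with it, all residual scatter in recovered
  correlations is attributable to the analysis window (trimming) and the
  nuisance components. HbR is `−0.3 × HbO` plus white noise — downstream
  analysis is HbO-only, so HbR realism is secondary.
* **Nuisance**: sinusoidal Mayer (~0.1 Hz, 0.015 μM), respiratory
  (~0.4 Hz, 0.04 μM) and cardiac (~1.1 Hz, 0.06 μM) components with
  independent per-channel phases; a slow sinusoid (0.002 Hz, 0.15 μM)
  plus a random linear ramp as drift; and Poisson-placed motion spikes
  (0.5 events/min) injected in OD as signed step-and-exponential-decay
  transients (amplitude 0.5 OD, τ = 2 s) — a realistic target for the
  spline corrector. Physiological phases are deliberately *not* coherent
  across channels, so the oscillations add variance without adding
  spurious correlation.
* **Measurement**: forward Beer–Lambert to OD and `I = I₀·exp(−OD)` with
  per-channel baselines, strictly positive by construction.
* **Clinical table**: ages, genders and durations drawn at the published
  group demographics; the auditory subscale derived from a latent equal to
  `coupling × z(attenuation) + noise` (default coupling 0.8), binned to
  the 0–4 range — so better-preserved connectivity maps to higher
  auditory scores and the pipeline's correlation step has a recoverable
  positive target. All randomness flows from one master seed; identical
  configurations give identical cohorts.

**What it does not emulate** — and hence what passing tests do *not*
show about real data: spatially correlated systemic physiology (global
superficial contamination, which in real fNIRS inflates correlations and
is often handled with short-separation regression — out of scope here);
optode-coupling drift and channel-specific noise floors; non-Gaussian,
non-stationary neural dynamics; the true spatial channel → cortex
mapping (the packaged montage and atlas are synthetic stand-ins that
satisfy the acquisition's counting and distance invariants, with files
named `synthetic_*`); and any relationship between etiology, duration and
network structure. Validation on this generator demonstrates the
*pipeline's* correctness and statistical behaviour, not clinical
reproducibility.

## 6. Problem sizes and numerical choices

The test suite and acceptance script run the full design where it is
cheap (the 16-vs-15 cohort at 300 s and 20 Hz, 100 small-world nulls per
threshold) and scaled-down cohorts (3–4 subjects per group, shorter
records, nulls off) where only mechanics are under test. Degenerate-input
policy, in one place: non-positive intensities are rejected at parse
time; records shorter than twice the trim are an error; a window longer
than the record is an error; constant vectors are errors for
Shapiro–Wilk and correlation; zero-variance edges are excluded from the
edgewise test with a count; empty graphs follow the per-metric rules of
Section 3; `tau` must lie in `[0, 1)`; CRS-R subscales outside their
defined ranges are errors, and stored totals that contradict subscale
sums are flagged, never silently corrected (the packaged table contains
exactly one such row, whose subscale sum — not its printed total — is
what reproduces the published cohort mean).

## 7. Known limitations

* SNIRF (HDF5) containers are recognized but not read; the columnar CSV
  dialect is the interchange format of this build.
* Connectivity is full-series Pearson only — no partial correlation,
  coherence, or sliding-window dynamics.
* No short-separation regression or PCA/wavelet motion correction; the
  spline corrector is the only artifact remover.
* Graph analysis is binary and undirected; no betweenness, modularity,
  rich-club or weighted variants.
* No covariate adjustment (age, gender) in the group comparisons.
* The harmonic-Lp bound at the node count is a summarization device for
  the threshold sweep; reported Lp AUCs are comparable within a study
  using this convention but not across conventions.
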