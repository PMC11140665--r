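---
title: "Methods: diurnal hormone rhythms and wavelet-coherence connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal hormone rhythms and wavelet-coherence connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormcoh)
```

## The scientific problem

Steroid hormones — testosterone, 17β-estradiol, cortisol — follow a pronounced
diurnal rhythm, peaking around 7 A.M. and reaching a nadir around 8 P.M.
Dense-sampling ("precision imaging") designs measure one individual
repeatedly — here, 40 resting-state fMRI sessions with concurrent endocrine
sampling over 30 consecutive days (20 morning, 20 evening sessions; serum
assays available on 30 of the 40 sessions because double-session days permit
only one blood draw) — and ask whether day-to-day fluctuations in hormone
concentration are time-synchronously associated with the brain's functional
network architecture.

`hormcoh` implements that analysis as a reusable, fully testable pipeline:

1. **Connectome estimation.** Per session, each of 415 parcellation nodes
   (400 cortical grouped into eight canonical networks, 15 subcortical as a
   ninth) contributes a summary timecourse. Series are band-limited with a
   maximal overlap discrete wavelet transform (MODWT, detail levels 3–6;
   ≈0.01–0.17 Hz at TR 0.72 s), and every node pair's magnitude-squared
   coherence (MSC) is estimated, yielding a symmetric 415 × 415 matrix with
   85,905 unique edges per session.
2. **Edgewise inference.** Edge coherence across sessions is z-scored and
   regressed on the z-scored hormone series; a permutation null (default
   10,000 session relabelings) gives two-tailed empirical p-values; edges
   are reported at p < 0.001 and corrected at FDR q < 0.05 before strength
   estimation.
3. **Network summaries.** Masked, signed edge t statistics define positive
   and negative nodal association strengths (sums of suprathreshold incident
   edges, separately by sign), summarized per network with 95% CIs, and
   compared with two-way hormone × network (and participant × network)
   fixed-effects ANOVAs with Tukey HSD.
4. **Graph topology.** Within-network global efficiency and the weighted
   participation coefficient per session, compared morning vs. evening with
   Welch t tests.

Because the original imaging data are not bundled, the package ships a
synthetic-data generator with *known ground truth*, so every downstream
stage is testable end to end.

## The synthetic study generator

### Hormones

Concentrations are drawn i.i.d. per session from the configured
morning/evening normal distributions (defaults: salivary total testosterone
101.6 ± 10.2 AM / 37.9 ± 11.5 PM pg/ml; serum testosterone 513.4 ± 47 /
286.4 ± 79 ng/dl; free testosterone 3.5 ± 0.4 / 2.6 ± 0.3 %FT; serum
estradiol 23.8 ± 3.6 / 14.5 ± 2.9 pg/ml; salivary cortisol 0.5 ± 0.1 /
0.04 ± 0.02 µg/dl; serum cortisol 15.9 ± 2.1 / 2.6 ± 0.9 µg/dl). Negative
draws are redrawn rather than clipped — clipping would bias upward analytes
whose evening mean sits within two SDs of zero (salivary cortisol). Those
defaults imply morning-to-evening decreases of ≈63% (testosterone), ≈39%
(estradiol) and ≈92% (cortisol). No day-to-day autocorrelation is modeled:
only time-of-day means and SDs are specified by the design being emulated,
so anything richer would be invention. A time-since-waking covariate is
generated at ≈1 h (AM) and ≈14 h (PM).

### BOLD-like regional timeseries

Node series are built from band-limited (0.01–0.17 Hz) unit-variance
Gaussian latents synthesized in the frequency domain:

* a **global latent** shared by all nodes,
* a **network latent** shared within each of the nine networks,
* a **private** component per node, plus broadband white noise
  (`noise_sd`, default 0.1) and a BOLD-like affine scale (mean 1000).

For two nodes mixing a shared unit-variance latent with weight *a* and
independent residuals with weight √(1−a²), the band MSC is *a*⁴. Mixing
weights are therefore chosen as fourth roots so that realized coherence
equals the configured targets: `global_coherence` (default 0.1) between
networks and `baseline_block_coherence` (default 0.3) within them.

**Hormone coupling acts on mixing weights, not on coherence directly.** A
coupled edge (i, j) with slope β shares a pair latent with session-specific
weight `c_s^{1/4}`, where `c_s = clip(c₀ + β·z_s, 0, 0.95)`, `c₀` the
coupled baseline (default 0.4) and `z_s` the session's z-scored coupling
analyte. Realized coherence is then an *emergent* quantity the estimator
must recover, rather than a number injected downstream. Coupled pairs must
be node-disjoint (the pair-latent construction is ill-defined otherwise;
the constructor enforces this). Clipping events are counted and reported in
the ground-truth record.

### Motion and mood

Motion is a six-parameter random walk whose step size targets a configured
mean framewise displacement (defaults 6 µm AM, 10 µm PM — an "exceedingly
minimal" motion regime with an evening excess), with a fixed number of
sessions (default 17) receiving 0.6–0.9 mm spikes so that spike-regressor
code paths are exercised. Mood scores are drawn within plausible scale
ranges and are independent of hormones by construction.

### What the generator does *not* emulate

Hemodynamic response shapes, physiological (cardiac/respiratory) signals,
spatial autocorrelation between neighboring parcels, scanner drift beyond a
linear trend, day-to-day hormone autocorrelation, and any voxel-level
structure. Passing tests on synthetic data therefore demonstrate that the
*estimation machinery* is correct and calibrated under the stated
statistical model — not that real resting-state data satisfy that model.

## Numerical and statistical choices

* **MODWT**: least-asymmetric Daubechies length-8 filter (LA8), the standard
  fMRI choice; reflection boundary (series concatenated with its mirror
  image, periodic transform, first half kept). Detail level j nominally
  covers [fs/2^(j+1), fs/2^j]; levels 3–6 at TR 0.72 s give
  [0.0109, 0.1736] Hz. The transform is implemented in-package (forward,
  inverse, and band reconstruction) and is verified in the tests against
  the perfect-reconstruction identity and FFT energy oracles.
* **MSC estimator**: Welch cross-spectra on the band-limited series — Hann
  window of 128 frames, 50% overlap (18 segments at 1250 frames), per-segment
  demeaning — averaged over in-band frequency bins. With a 128-frame window
  the bin grid lands exactly on the nominal band edges (16 in-band bins).
  Window, overlap and band are recorded as matrix metadata.
* **Per-session matrix thresholding** uses the classical independence null
  of the Welch MSC estimator, P(C > c) = (1 − c)^(L−1) (the estimate is
  Beta(1, L−1) under zero coherence), BH-corrected across the 85,905 edges.
* **Edgewise permutation test**: one random session relabeling per
  iteration applied jointly to all edges (equivalently, permuting the
  hormone vector), which preserves the cross-edge dependence that FDR
  control relies on. p = #{|t_b| ≥ |t_obs|}/B, ties counting as
  exceedances, floored at 1/B (p = 0 is never reported; no +1 smoothing).
  When B reaches the number of distinct permutations (tiny n), the test
  switches to exhaustive enumeration. With covariates, the hormone is
  permuted while covariates stay fixed, and the partial standardized
  coefficient is tested.
* **Regression input**: the edgewise regression uses *unthresholded*
  coherence by default (`threshold_for_regression` flips this). Zeroing
  sub-threshold entries per session would censor exactly the low-coherence
  sessions that carry the lower end of a linear hormone–coherence relation;
  thresholded matrices still drive the graph metrics.
* **ANOVAs**: node-level strengths are treated as observations (as is
  conventional for this analysis; nodes are spatially dependent, so p-values
  are descriptive — the caveat applies equally to the design being
  replicated). Unbalanced network sizes are handled with Type II sums of
  squares for main effects and the interaction F from the full model;
  Tukey HSD runs on the hormone and network margins. Residual df are
  N − (levels_A × levels_B): 3·415 − 27 = 1,218 and 2·415 − 18 = 812 at
  full scale.
* **Graph metrics**: efficiency is computed within each network and
  averaged (it is used as a *within-network* integration marker), with edge
  length 1/weight; the weighted participation coefficient uses the nine
  networks as the module partition and averages over non-isolated nodes.
  Cohen's d uses the pooled SD alongside the Welch t, matching common
  practice.
* **Determinism**: a single master seed derives the generator and
  permutation streams; identical config + seed reproduces every output
  byte-for-byte.

## Design decisions that were genuinely open

* The Bonferroni divisor for the behavioral correlation screen defaults to
  the number of correlations actually computed, and is overridable — the
  printed asterisk thresholds of the emulated analysis do not pin down the
  family size.
* The FWD formula (Power-style, 50 mm head radius) and the
  scale → detrend → residualize order are stated choices, not inferences;
  both are documented in the function help. After residualization the
  scaled baseline (median 1000) is restored so the output remains on a
  BOLD-like scale and a second pass is a near-no-op.
* Physiological noise components are accepted as externally supplied design
  columns; extracting them from tissue masks requires voxel data, which is
  out of scope.
* The nine-network parcellation ships as a synthetic lookup with node
  counts proportional to the reference 415-node scheme
  (61/77/46/47/26/52/77/14/15); at reduced node counts, apportionment uses
  largest remainders with a two-node minimum per network so the ANOVA cells
  stay estimable.
* Nodes with zero strength are included in network means (a drop flag is
  available); singleton networks yield flagged, undefined CIs.

## Problem sizes used by the test-suite and acceptance harness

The packaged checks run the full pipeline at reduced scale, chosen once as
the smallest sizes at which the relevant asymptotics are visible: null
calibration at 46 nodes (1,035 edges), 40 sessions, B = 500; parameter
recovery at 40 nodes, 40 sessions, 10 node-disjoint coupled edges with
|β| = 0.15, B = 2,000, averaged over 20 seeds (B = 2,000 because a single
BH survivor among 780 edges at q = 0.05 requires p ≤ 6.4·10⁻⁴, below the
1/500 permutation floor); estimator bias at L = 8 non-overlapping segments,
where E[MSC] = 1/L exactly under independence. Structural constants
(85,905 edges; residual dfs 1,218 and 812; band edges 0.01/0.17 Hz) are
recomputed at full 415-node scale, where a single session's coherence
matrix takes seconds.

## Known limitations

Single-subject inference: nothing here generalizes across individuals.
The permutation null assumes exchangeability of sessions, which diurnal
designs only approximately satisfy (AM/PM structure travels with the
hormone; the time-since-waking covariate is the provided mitigation).
Node-level ANOVAs ignore spatial dependence. The synthetic generator's
linear coherence–hormone coupling is the simplest model consistent with a
standardized linear edgewise analysis; real coupling may be nonlinear,
lagged, or state-dependent, and recovery rates quoted here do not transfer
to such regimes.
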