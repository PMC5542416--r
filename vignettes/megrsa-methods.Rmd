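---
title: "Time-resolved MEG decoding and RSA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved MEG decoding and RSA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

`megrsa` implements a complete time-resolved multivariate analysis of
sensor-level MEG epochs for a factorial scene-perception experiment. The
design crosses four binary factors — scene **size** (the real-world spatial
extent of the depicted environment), **clutter** (how densely objects fill
it), image **contrast** and image **luminance** — with three exemplar images
per factor-level combination, i.e. 48 conditions. The scientific question is
*when* the brain's visual representations discriminate individual images and
*when* they become organized by abstract scene properties such as size, and
whether computational models of vision (GIST, HMAX, or externally supplied
network activations) carry the same representational structure.

The pipeline has five stages, each exposed as ordinary functions:

1. **Preprocessing** (`reject_trials()`, `baseline_normalize()`,
   `smooth_timecourse()`): trials whose worst channel exceeds 8000 fT
   peak-to-peak are discarded (a single bad channel rejects the trial,
   matching MEG practice); each trial/channel is normalized by its
   pre-stimulus baseline mean and SD over \[-100, 0) ms; time courses are
   smoothed with a 20 ms centered boxcar with truncated windows at the epoch
   edges (no invented pre-baseline data). `rejection_imbalance_test()` checks
   that rejection counts do not differ systematically between factor levels.
2. **Pairwise decoding** (`pairwise_decoding_timecourse()`): at every time
   point, every pair of conditions is classified from sensor patterns with a
   linear soft-margin SVM (C = 1). Raw trials are sub-averaged into
   pseudo-trials in random groups of k = 5 to raise SNR; classification uses
   leave-one-pseudo-trial-out per class, repeated (100 times at full scale)
   with fresh random assignments; accuracies fill a symmetric 48 x 48
   decoding matrix per time point — the MEG representational dissimilarity
   matrix (RDM). Chance is 50%.
3. **RDM statistics** (`factor_average_decoding()`,
   `clustering_timecourse()`): averaging matched-exemplar cells yields the
   single-image decoding time course; the difference of mean between-level
   minus within-level cells yields the representational clustering time
   course for a factor (percent accuracy difference, 0 under the null).
4. **Cross-classification** (`cross_decoding_timecourse()`,
   `identity_cross_decoding()`): the classifier is trained on one level of a
   nuisance factor (or on two of three exemplars) and tested on the other,
   pooling trials across images within each cell (720 raw vectors per class
   at full scale) and sub-averaging with k = 60. Above-chance generalization
   indicates representations tolerant to the nuisance dimension.
5. **Model comparison** (`feature_rdm()`, `rsa_timecourse()`,
   `partial_rsa_timecourse()`): model RDMs are 1 − Spearman correlations of
   per-condition feature vectors (or binary explicit factor models);
   brain-model similarity is the Spearman correlation of the vectorized
   lower RDM triangles, and the partial variant residualizes ranks on
   nuisance model RDMs before correlating.

Inference throughout is nonparametric: the one-sample sign-permutation test
with cluster-size correction over time, bootstrap-over-subjects confidence
intervals for onset and peak latencies, condition-label permutation tests
for model-model correspondences, and Benjamini-Hochberg FDR where families
of model tests are involved.

# The synthetic-data generator

No public MEG recordings accompany this design, so the package ships a
generator that emulates the experiment with known ground truth, making every
downstream stage testable end to end.

* **Design**: `generate_design()` builds the full 2^4 x exemplars crossing.
* **Stimuli**: `generate_images()` draws smooth band-limited random textures
  and rescales each to its condition's RMS statistics. We define RMS
  contrast as sd(I)/mean(I) (relative RMS contrast) and RMS luminance as
  sqrt(mean(I^2)), both in percent of full scale, with targets 34%/50%
  (contrast) and 34%/51% (luminance). These definitions were chosen jointly:
  defining contrast as the raw SD of intensities makes the high-contrast
  (50%) / low-luminance (34%) cell mathematically unattainable on \[0, 1\]
  (an SD of 0.5 forces a binary image with RMS intensity 0.707), whereas the
  relative-contrast definition renders all four cells feasible. Textures are
  clamped at ±1.8 SD before exact restandardization so the affine rescaling
  stays inside \[0, 1\]; if clipping still occurs (very small images) the
  affine map is refit iteratively and a warning reports any residual miss.
* **Epochs**: `generate_epochs()` adds, on top of noise, one spatial pattern
  per factor level (or per condition, for `"identity"` effects) scaled by a
  half-cosine envelope rising from onset to peak and falling to the offset —
  simple, smooth, and with unambiguous latencies for recovery tests.
  Patterns are unit-norm Gaussian vectors shared across subjects, with
  per-subject jitter (default 0.2 of the pattern norm) so subjects are
  heterogeneous. The pre-stimulus window contains noise only.
* **Noise**: Gaussian with a random low-rank-plus-diagonal channel
  covariance (rank 5, 30% shared variance by default) passed through an
  AR(1) filter over time (coefficient 0.8), mimicking correlated MEG sensor
  noise without a forward model; marginal SD 100 fT.
* **Artifacts**: `inject_artifacts()` adds single-channel spikes to a chosen
  fraction of trials to exercise the 8000 fT rejection rule.

What the generator does *not* emulate: realistic head geometry and field
spread, eye/muscle artifacts with structured topographies, non-stationary
noise, or real scene photographs. Passing tests therefore demonstrate the
correctness and calibration of the *analysis machinery* under controlled
conditions, not the neural claims themselves.

# Scale profiles and problem sizes

Two bundled profiles fix the study conditions:

* `full_profile()` mirrors a full experiment: 306 channels, 1 ms sampling
  over −100..900 ms, 60 trials/condition (15 runs x 4 presentations), 15
  subjects, k = 5 with 100 sub-averaging repetitions, k = 60 for
  cross-classification, 1000 permutations and 1000 bootstraps.
* `desk_profile()` is the configuration used by the test suite and the
  acceptance script so that an end-to-end run completes in minutes on one
  core: 30 channels, 5 ms sampling, 20 trials/condition, 8 subjects, 5
  repetitions with decoding evaluated on a 20 ms grid (time decimation
  factor 4), 200 permutations and 200 bootstraps. Some tests reduce further
  (16 conditions, i.e. one exemplar per combination, or 4-6 subjects) where
  the property under test does not depend on the full crossing.

Sub-averaging remainders (M mod k) are discarded within a repetition; a
fresh random assignment every repetition recycles all trials in expectation.

# Numerical and procedural choices

* **Classifier**: the C-SVC dual is solved by an SMO solver (maximal
  violating pair, stopping gap 1e-8) implemented in C++, because the
  pairwise leave-one-out loop fits millions of tiny SVMs per analysis. The
  solver is cross-checked in the test suite against libsvm (via `e1071`) on
  random problems. Prediction ties (decision value exactly 0) go to the
  first class, deterministically. No feature scaling is applied beyond
  baseline normalization.
* **Leave-one-out**: one pseudo-trial per class is held out per fold; with P
  pseudo-trials per class there are P folds, and the two held-out points are
  scored together. When the two classes yield different pseudo-trial counts
  (after rejection), the common minimum is used.
* **Cross-classification**: train/test roles of the two generalization
  levels are swapped and the two directions averaged. Test sets smaller
  than one sub-averaging group fall back to a single whole-set average.
* **RDM conventions**: decoding matrices are written symmetrically with an
  `NA` diagonal; all RDM correlations use the strictly-lower triangle; ranks
  use average ties (standard Spearman). Multi-layer models are correlated
  per layer and averaged across layers.
* **Partial correlation** is computed on ranks (Spearman-partial):
  rank-transform, residualize the target and brain vectors on the nuisance
  ranks by least squares, and correlate the residuals. Collinear nuisance
  columns are dropped with a message. Numerically zero residuals return 0.
* **Sign-permutation cluster test**: per-timepoint two-sided empirical
  p-values are computed from the permutation distribution of the group mean
  at that time point (pooling over permutations only, not over time);
  candidate clusters are maximal runs of p below the cluster-definition
  threshold (0.05) with consistent sign; the cluster statistic is its size
  in time points, referred to the permutation distribution of the maximal
  cluster size. All empirical p-values use the plus-one convention
  (1 + count)/(1 + n), so they are valid and never zero at finite n. When
  2^subjects does not exceed the requested permutation count the full sign
  enumeration is used instead, making small-sample results deterministic.
  The test refuses to run when 1/n_perm already exceeds the
  cluster-definition threshold. A consequence of the size statistic worth
  knowing: it is sensitive to temporally extended effects but insensitive to
  short, strong ones, and for a time course that is constant over the whole
  window the max-size null degenerates (about an alpha fraction of sign
  patterns also span the window), so such effects cannot undercut the
  corrected level — the test suite demonstrates this exactly.
* **Latencies**: onset is the first time point of the earliest significant
  cluster; peak is the argmax of the group-mean time course over the
  post-stimulus window (a `peak_window` argument restricts or widens this).
  The peak is deliberately not constrained to significant clusters; this is
  exposed as a config switch rather than hidden. Bootstraps resample
  subjects only (not trials), rerun the full cluster test per sample, and
  report 2.5/97.5 percentiles; samples without a significant cluster are
  excluded from the onset distribution and counted.
* **Label permutation tests** permute rows and columns of one model RDM
  simultaneously, two-sided, plus-one convention.
* **Seeds**: every source of randomness flows through explicit integer
  seeds; per-subject generator seeds derive from the master seed by a fixed
  offset (1009 x subject index), and each pipeline stage uses a fixed,
  documented offset of the run seed, so whole runs are bit-reproducible.

# Feature models

* **GIST**: the image (resized to 128 x 128 by default) is filtered with a
  bank of 32 complex Gabor kernels (8 orientations x 4 octave-spaced
  frequencies starting at 0.25 cycles/pixel, isotropic Gaussian envelopes,
  mean-corrected so constant images map to zero); response magnitudes are
  averaged on a 4 x 4 grid and concatenated into a 512-dimensional
  descriptor. Filtering is circular via the FFT and is verified against
  direct convolution to 1e-8 in the tests. The exact spatial frequencies are
  configuration-exposed since descriptor variants differ here.
* **HMAX**: a compact 4-layer S1→C1→S2→C2 hierarchy: S1 Gabor magnitudes at
  4 orientations and 4 filter sizes; C1 max-pools over paired scales and
  local neighborhoods; S2 computes Gaussian radial-basis similarity to a
  dictionary of C1 patches sampled from generator images under a fixed seed
  (default 100 patches; no natural-image corpus dependency); C2 is the
  global max per patch. The structural properties (layer order, C2 length =
  dictionary size, greater translation tolerance of C2 than S1) are tested.
* **Activation tables**: `load_activation_features()` reads per-layer
  feature tables (CSV) for externally computed models — e.g. deep-network
  layer activations — aligning rows to the design and validating
  completeness, so any model can be plugged into the RSA stage. Training or
  running networks is out of scope.

# Known limitations

* The generator's spatial patterns are random vectors, not physiologically
  plausible field topographies; effect sizes in fT are therefore only
  meaningful relative to the noise SD.
* Decoding accuracies for a single pattern realization need not average to
  exactly 50% under exemplar-generalization analyses (the realized geometry
  carries a fixed bias); expectations over pattern draws do.
* The cluster-size statistic's insensitivity to brief effects (above) is a
  property of the method, not a bug; threshold-free variants are out of
  scope.
* The pipeline analyses one fixed condition set; temporal generalization
  (train at t, test at t') and sensor-space searchlights are out of scope.
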