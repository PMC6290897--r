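---
title: "Methods: combinational IR signatures, cluster association, and multivariate modelling"
author: "irsigflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinational IR signatures, cluster association, and multivariate modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific setting

Cohort studies of immune aging with and without ART-suppressed HIV measure,
per subject, (i) per-cell fluorescence of lineage markers (CD3, CD4, CD8,
γδTCR, CD127, CD16, CD56) and five inhibitory receptors (PD-1, TIGIT, TIM-3,
CD160, LAG-3) on PBMC; (ii) a plasma panel of inflammation/coagulation
analytes; and (iii) analyte secretion from sorted, briefly cultured γδ T
cells. The analytical questions are: which cell populations' IR expression
separates infected from uninfected subjects; how the abundance of each IR
*combination* on γδ T cells depends on HIV status and age group; and whether
multivariate profiles (combination abundances plus plasma markers) separate
the four subject strata.

## Event preprocessing

Fluorescence is analyzed in arcsinh units, `asinh(x / c)`. The cofactor `c`
defaults to 150 — a conventional choice for fluorescence cytometry — and is
exposed rather than hidden because every downstream statistic is
threshold-relative. The transform is bijective; `inverse_arcsinh()` recovers
raw values to 1e-9 relative, and a double-transform guard refuses to
transform twice. Downsampling (default documented target 10,000
events/subject) is uniform without replacement and seed-deterministic.

CSV (comma-separated, header of channel names, no index column) is the
canonical interchange format. A minimal FCS 3.0 reader/writer (float32,
little-endian, list mode) supports round-tripping event matrices with the
field's binary format; it is deliberately not a general cytometer-file
parser — compensation, spillover and instrument keywords are out of scope
because acquisition software applies compensation before export.

## FM5 gating and combination signatures

IR gates are set per batch from the fluorescence-minus-five control: the
threshold is the empirical `q`-quantile (default `q = 0.995`, i.e. ~0.5%
background positivity) of the FM5 distribution of that channel. A fixed
quantile makes the expert "guided by FM5" practice deterministic and
auditable; `q` is a tunable with a direct operational meaning (tolerated
background rate).

For a chosen IR set of size `k`, `combo_signature()` tallies all `2^k`
positivity patterns among gated γδ cells into a probability vector
(zero-count patterns included). The three bimodal IRs (PD-1, TIGIT, CD160)
form the default combination family of 8 subsets; TIM-3 is added (16
subsets) only for the discriminant-analysis feature block, because TIM-3 and
LAG-3 are expressed unimodally and a positive/negative cut on them is not
reliable — for those markers the ≥k-IR counts still use the same FM5 rule
(the difficulty is handled by exposing the quantile, not by dropping the
markers), and `median_ratio()` (gated median / FM5 median) provides the
gate-free summary. Subjects with zero gated cells propagate missing values,
not zeros: a zero abundance is a biological claim, a missing one is not.

## Cluster association

`pool_and_cluster()` pools (transformed, downsampled) events across samples
and clusters them agglomeratively with Ward linkage on Euclidean distance
over the 7 lineage channels. Nodes holding at least `min_cluster_frac`
(default 5%) of pooled events qualify for characterization; the qualifying
set is closed under ancestors by construction. `cluster_features()` then
yields one feature per (qualifying node × IR channel): the per-sample median
intensity, with sample-empty cells imputed by the node's pooled median and
flagged in a mask.

`stats::hclust` needs the full O(n²) distance matrix, so the tree is built
on a seeded uniform subsample capped at `max_pooled_events` (default
10,000); every pooled event is then assigned down the qualifying subtree by
nearest-child-centroid descent, so the per-sample medians use all events.
The cap is a memory/time trade-off of the clustering step only — feature
medians and everything downstream see the full pool. Tests run with a few
thousand pooled events; the package's documented full-scale default remains
10,000 events/subject.

Two association models act on the feature matrix:

* **Nearest shrunken centroids** (`pamr_fit_cv`): per-feature, per-class
  statistics `d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s0))` with
  `m_k = sqrt(1/n_k − 1/n)`, pooled within-class SD `s_i`, and
  `s0 = median(s_i)`; soft-thresholding by Δ shrinks class centroids toward
  the overall centroid, performing embedded feature selection; classification
  minimizes the standardized distance to the shrunken centroid minus
  `2 log π_k`. Stratified n-fold CV gives an error curve over the Δ grid and
  the selected Δ is the *largest* value attaining the minimum error — the
  model with the fewest surviving features among the best performers.
* **Moderated-statistic selection** (`sam_select`): two-class
  `d_i = (x̄_i1 − x̄_i0)/(s_i + s0)` with a permutation null; per cutoff, the
  estimated FDR is the mean permuted exceedance count over the observed
  count, and the significant set is the largest cutoff-defined set with
  estimated FDR at or below the target (default 1%). The mean, rather than
  the median, permuted exceedance is the default estimator: with stringent
  cutoffs the exceedance counts are mostly zero and their median collapses
  to an estimated FDR of exactly zero, admitting isolated null features;
  the mean keeps the estimate strictly positive and calibrated. The median
  variant remains available.

## Beta regression with a permutation minP threshold

Each subset abundance is modelled as `y ~ Beta(μφ, (1−μ)φ)` with
`logit(μ) = β0 + β_HIV·hiv + β_age·old`, fit by maximum likelihood (BFGS on
`(β, log φ)` with the analytic gradient; Wald tests from the observed
information). Exact 0/1 values trigger the standard interior transform
`y' = (y(n−1) + 0.5)/n` applied to the whole vector and flagged. The fitter
is authored in the package because the permutation layer refits it tens of
thousands of times; an independent beta-family ML implementation (glmmTMB)
serves as a cross-check oracle in the test suite, not as the implementation.

Multiplicity over the 8 subsets is controlled per model term by a
permutation minP threshold: each permuted dataset permutes, independently
within each subject, that subject's 8 abundances across the subset labels —
the only permutation scheme under which the subject's abundance
inter-dependency (they sum to 1) is literally maintained, and an exact null
when subsets are exchangeable. Per permuted dataset the regressions are
refit and the minimum Wald p across subsets is recorded per term; the
threshold is the `ceiling(0.05 · n_perm)`-th smallest minimum (5th smallest
at 100 permutations; no interpolation, a reproducible and conservative
convention at small `n_perm`). Observed subsets are significant iff their p
is *strictly* below the threshold. Implementation detail: the within-subject
draw permutes the subject's sorted abundance multiset, which makes the
threshold exactly invariant to the order of the input columns under a fixed
seed. Non-convergent permutation fits score p = 1, conservative for a
minimum. The alternative reading of the scheme (resampling each subset
across subjects) is exposed as `scheme = "across_subjects"` but breaks the
within-subject dependence and is not the default.

The acceptance script estimates the procedure's family-wise error under a
global null in which each subject's abundances are symmetric-Dirichlet
(exchangeable, so the permutation null is exact): 100 replicate cohorts of
90 subjects, 100 permutations each. The weak-control guarantee is nominal
0.05 up to Monte-Carlo error; the 100-permutation discreteness of the
plug-in threshold adds a small upward wobble.

## PLS regression and discriminant analysis

Both X and Y blocks are z-scored column-wise (sample SD). The NIPALS
algorithm (tolerance 1e-10, ≤500 inner iterations, deflation of both
blocks) extracts latent variables; discriminant mode encodes classes as one
indicator column each and decodes by argmax, ties to class order. The number
of latent variables is selected by 3-fold cross-validation — each fold one
third of the samples, stratified by class in discriminant mode, so every
sample receives exactly one held-out prediction and the error is cumulated
over all of them (RMSEP in regression mode, misclassification fraction in
discriminant mode); ties go to the smaller A. On data whose predictive rank
is exhausted, the CV curve beyond the true rank is nearly flat and the
strict minimum can land one component high — a known property of
minimum-PRESS selection worth remembering when reading `cv_error` curves.

`vip_scores()` computes
`VIP_j = sqrt(p · Σ_a w_ja² SSY_a / Σ_a SSY_a)` with `SSY_a = |t_a|²|q_a|²`
the Y-variance captured by LV a; mean VIP² = 1 identically, so VIP > 1 marks
above-average contribution. `orthogonal_rotate()` finds the orthogonal
rotation of the score space whose first axis maximizes the between-class
variance fraction (discriminant; a generalized Rayleigh quotient solved in
closed form) or the squared covariance with Y (regression; leading left
singular vector of TᵀY), completes an orthonormal basis, and rotates T, P,
W, Q together — predictions are invariant. Model significance permutes the
Y rows `n_perm` times (A re-selected per permutation by default —
conservative — with `freeze_A` to pin it), and compares the true model's
per-held-out-sample errors against the pooled permuted per-sample errors
with a one-sided Mann–Whitney U test; this is the minimal reading that makes
a rank test on "a distribution of error" well-formed. Score-cloud 95%
ellipses use the 2×2 score covariance scaled by the χ²(2) quantile.

## The synthetic cohort generator

The generator emulates the study's data structure with known ground truth;
its defaults are the study conditions, not tuning dials:

* Four groups sized 21/21/22/28 (uninfected/HIV × young/old), 10,000
  events/subject, 11 staining batches (tests use smaller cohorts; the
  defaults document the full-scale shape).
* Five cell subsets (γδ T at 8%, CD4 T, CD8 T, NK, other) with Gaussian
  lineage components in arcsinh space; events are generated directly in
  arcsinh units and the raw export applies the inverse transform, avoiding a
  commitment to instrument-specific raw scales.
* Bimodal IRs (PD-1, TIGIT, CD160): per-cell positivity from a logistic
  model `base + β_HIV·hiv + β_age·old + b_subject + λ·z` with subject
  intercepts `b ~ N(0, 0.3²)` and a standard-normal per-cell activation
  scalar `z` shared across IRs (loading λ ≈ 0.6–0.8). The shared scalar
  induces positive IR co-expression, without which multi-IR fractions and
  combination trajectories would be degenerate products of marginals.
  Positive/negative intensities are Gaussians at 2.5/0.3 arcsinh units.
  Default effects: TIGIT +1.5 logits with HIV and +0.8 with age, smaller
  HIV shifts on TIM-3 and CD160, a mild negative PD-1 shift.
* Smooth IRs (TIM-3, LAG-3): a single Gaussian whose mean shifts
  continuously with the same logistic drive — unimodal expression for which
  positive/negative gating is intrinsically unreliable.
* FM5 controls per batch: lineage from the pooled mixture, IR channels pure
  background — the same negative distribution as IR-negative cells in the
  main samples (a tested invariant).
* Plasma: log-normal analytes with HIV and age shifts on the markers
  classically reported to move (sCD14, A2M, fibrinogen, SAP, adipsin, vWF;
  D-dimer, CRP with age) and a positive coupling of selected cytokines to
  the subject's true TIGIT⁺ fraction.
* Supernatant: per-cell secretion `intercept_g + slope_g · TIGIT⁺ fraction +
  noise`, truncated at zero, times a cultured-cell count drawn uniformly
  from 2,000–26,000; the slope is positive in the HIV groups and zero in the
  uninfected groups, mirroring the stratified regression picture the
  pipeline is meant to recover.

What the generator does *not* emulate: spillover/compensation artifacts,
doublets and debris (excluded upstream by manual gating in practice), batch
drift of channel gains, heavy-tailed or zero-inflated analyte noise, and any
correlation structure among plasma analytes beyond their shared TIGIT
coupling. Passing tests therefore certify the statistical machinery under a
clean generative model, not robustness to instrument artifacts.

No distributional description of the real cytometry data is available to
copy; all generative choices are explicit stand-ins chosen once, at values a
cytometrist would call realistic, and are labelled as synthetic throughout.

## Numerical choices and degenerate inputs

* Beta MLE: starting values from OLS on the empirical logit plus
  method-of-moments φ; up to 3 jittered restarts; non-convergence is an
  error for observed fits and p = 1 inside permutations.
* PAMR Δ-grid: 30 points from 0 to max|d_ik|; Δ selection tie-break toward
  the sparser model; fold redraw (new sub-seed, logged) if a fold loses a
  class.
* Zero-variance columns are an error naming the column (z-scoring), a
  missing value with a warning (correlations, FM5 median ratio at zero
  median), or an NA row (regressions on constant x).
* Empty gates warn and flag rather than error; downstream tables carry NA.
* Seeds: one master seed per run; `derive_seed(seed, label)` hashes stage
  labels into independent 32-bit sub-seeds so stages re-run independently
  yet reproducibly.

## Problem sizes used by the test and acceptance runs

Unit tests use cohorts of 16–48 subjects at 100–2,000 events/subject and
pooled clustering of ≤6,000 events; the family-wise-error study uses 100
replicate null cohorts of 90 subjects at 100 permutations; the end-to-end
recovery study uses 40 subjects at 1,000 events/subject. These sizes were
chosen so the full suite exercises every stage at full statistical strength
on a single CPU in minutes; the package's documented defaults (10,000
events/subject, 11 batches, 92 subjects) describe the full-scale study
shape.

## Known limitations

* The FWER guarantee is weak control (global null); under partial
  alternatives the minP plug-in can be mildly anti-conservative, and 100
  permutations quantize the threshold to the 5th smallest minimum.
* Multi-response PLS may need more latent variables than the rank of the
  planted structure (the NIPALS Y-weighting compromise); the CV curve's flat
  tail makes strict-minimum selection wander by one component on some draws.
* The FCS support is interchange-grade (float32 list mode only).
* Cluster features for very small nodes rest on few cells per sample; the
  imputation mask should be consulted before interpreting such features.
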