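# irsigflow

Multivariate analysis of combinational **inhibitory-receptor (IR) signatures**
on gated immune-cell subsets from flow cytometry cohorts, built for studies
that ask how a binary clinical condition (here, ART-suppressed HIV infection)
and an age stratum jointly reshape the IR landscape of a cell population such
as γδ T cells.

The package covers the whole analysis chain:

1. **Events** — per-sample event matrices with channel roles, the arcsinh
   transform `asinh(x / c)`, seeded downsampling, CSV and minimal FCS 3.0
   interchange.
2. **Gating & signatures** — IR gates set at an empirical quantile (default
   0.995) of per-batch fluorescence-minus-five (FM5) background controls;
   boolean combination gating over k IRs giving the `2^k` pattern abundances
   (a probability vector per subject); ≥2/≥3/≥4-IR fractions; median
   intensities and FM5 median ratios.
3. **Cluster association (CITRUS-style)** — pooled Ward clustering on the
   7 lineage channels, per-sample cluster-median IR features for every node
   holding ≥5% of pooled events, then (a) a cross-validated **nearest
   shrunken centroid** (PAMR) model with embedded feature selection and (b) a
   permutation-FDR **moderated-statistic** (SAM-style) selector.
4. **Abundance modelling** — per-subset **beta regression**
   `y ~ Beta(μφ, (1−μ)φ)`, `logit(μ) = β0 + β_HIV·hiv + β_age·old`, with a
   **permutation minP family-wise threshold**: each subject's 8 subset
   abundances are permuted across the subset labels, the regressions are
   refit, the minimum p per model term is recorded over 100 permutations, and
   the 5th percentile of those minima is the per-term significance cutoff.
5. **PLSR / PLS-DA** — NIPALS partial least squares with z-scored blocks,
   latent-variable selection by one-third cross-validation, VIP scores
   (mean VIP² = 1), orthogonal score rotation for maximal axis-1 separation,
   and permutation model significance via a one-sided Mann–Whitney U test on
   held-out per-sample errors.
6. **Univariate layer** — Welch t-tests with Bonferroni correction (6
   pairwise four-group comparisons → displayed threshold p < 0.008), Pearson
   correlation heatmaps of combination abundances per stratum, per-cell
   analyte normalization with a 45% responder cutoff, per-analyte OLS on the
   TIGIT⁺ fraction.
7. **Synthetic cohort generator** — a fully parameterized study emulator
   (bimodal and smooth IR expression, subject-level intercepts, a latent
   per-cell activation scalar driving IR co-expression, FM5 controls, plasma
   panels with group shifts, supernatant secretion coupled to the TIGIT⁺
   fraction) so every stage is testable against known ground truth.

## Worked example

```r
library(irsigflow)

cfg <- synthetic_config(
  group_sizes = c(uninfected_young = 12, uninfected_old = 12,
                  hiv_young = 12, hiv_old = 12),
  events_per_subject = 2000, n_batches = 3, seed = 20)
cohort <- generate_cohort(cfg)

sig <- signature_table(cohort$events, cohort$fm5, cohort$design)
ab  <- combo_abundances(sig)   # 48 subjects x 8 patterns (PD-1, TIGIT, CD160)

round(colMeans(ab[cohort$design$hiv == 0, ]), 3)
#>   ---   --+   -+-   -++   +--   +-+   ++-   +++
#> 0.362 0.135 0.157 0.080 0.101 0.050 0.067 0.049
round(colMeans(ab[cohort$design$hiv == 1, ]), 3)
#>   ---   --+   -+-   -++   +--   +-+   ++-   +++
#> 0.164 0.110 0.269 0.262 0.027 0.023 0.063 0.082

summary(fit_beta_regression(ab[, "-+-"], cohort$design))  # TIGIT-only subset
#>              Estimate Std. Error  z value  Pr(>|z|)
#> (Intercept) -1.807742   0.084369 -21.4265 < 2.2e-16 ***
#> hiv          0.644268   0.089323   7.2128 5.481e-13 ***
#> age_old      0.285146   0.088118   3.2360  0.001212 **
#> precision phi = 63.702, logLik = 76.423, n = 48

thr <- minp_threshold(ab, cohort$design, n_perm = 100, seed = 1)
thr
#> minP permutation thresholds (100 permutations, within_subject scheme):
#>   HIV term: 0.003255
#>   age term: 0.002412

apply_thresholds(fit_subset_regressions(ab, cohort$design), thr)$hiv
#> [1] "---" "-+-" "-++" "+--" "+-+" "+++"
```

Read: the pattern string orders PD-1, TIGIT, CD160, so `-+-` is the
TIGIT-only subset. The generator's default condition raises TIGIT positivity
with HIV (+1.5 logits) and age (+0.8 logits); the fitted HIV coefficient
(0.64 on the logit-mean scale of the *abundance*, attenuated relative to the
per-cell effect) is declared significant because its Wald p falls below the
permutation-derived HIV threshold (0.0033), which controls the family-wise
error over the eight subsets.

The same cohort feeds the cluster-association stage
(`pool_and_cluster` → `cluster_features` → `pamr_fit_cv` / `sam_select`), the
PLS layer (`fit_pls`, `select_n_lv`, `vip_scores`, `orthogonal_rotate`,
`permutation_significance`), and the end-to-end runner:

```r
pipeline_run("all", run_config(list(out_dir = "run1", seed = 5)))
```

which writes TSV/JSON artifacts for every stage plus a consolidated
`report.json` (a thin CLI over the same functions is installed at
`inst/exec/irsigflow`).

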