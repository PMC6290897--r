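test_that("configuration invariants are enforced with field names", {
  expect_error(synthetic_config(group_sizes = c(1, 2, 3)), "group_sizes")
  w <- matrix(0.25, 4, 5, dimnames = list(c("uninfected_young", "uninfected_old",
                                            "hiv_young", "hiv_old"),
                                          c("gdT", "CD4T", "CD8T", "NK", "other")))
  expect_error(synthetic_config(subset_weights = w), "subset_weights")
  expect_error(synthetic_config(events_per_subject = 0), "events_per_subject")
  expect_error(synthetic_config(neg_intensity = c(mean = 0.3, sd = 0)),
               "neg_intensity")
})

test_that("cohort generation is seed-deterministic and honors group sizes", {
  cfg <- synthetic_config(group_sizes = c(uninfected_young = 2, uninfected_old = 2,
                                          hiv_young = 2, hiv_old = 2),
                          events_per_subject = 100, n_batches = 2, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$events[["S001"]]$values, c2$events[["S001"]]$values)
  expect_identical(c1$plasma$concentrations, c2$plasma$concentrations)
  expect_identical(nrow(c1$design), 8L)
  expect_identical(as.vector(table(c1$design$group)), rep(2L, 4))
  expect_true(all(c1$design$batch %in% 1:2))
  expect_false(anyDuplicated(c1$design$subject_id) > 0)
})

test_that("a configured TIGIT HIV effect is recovered on the logit scale", {
  # 40 subjects per group, subject_sd 0.3; the marginal positivity gap on the
  # logit scale recovers the configured 1.5 within the Monte-Carlo band
  cfg <- synthetic_config(
    group_sizes = c(uninfected_young = 40, uninfected_old = 0,
                    hiv_young = 40, hiv_old = 0),
    events_per_subject = 2000, n_batches = 2, seed = 31,
    ir_hiv_effect = c("PD-1" = 0, "TIGIT" = 1.5, "TIM-3" = 0,
                      "CD160" = 0, "LAG-3" = 0),
    ir_age_effect = c("PD-1" = 0, "TIGIT" = 0, "TIM-3" = 0,
                      "CD160" = 0, "LAG-3" = 0),
    subject_sd = 0.3)
  coh <- generate_cohort(cfg)
  frac <- coh$truth$frac_TIGIT
  hiv <- coh$design$hiv
  gap <- qlogis(mean(frac[hiv == 1])) - qlogis(mean(frac[hiv == 0]))
  expect_gt(mean(frac[hiv == 1]), mean(frac[hiv == 0]))

  # independent Monte-Carlo oracle: marginal positivity averages the inverse
  # logit over the subject intercept and the per-cell activation scalar, so
  # the marginal logit gap is slightly attenuated below the configured 1.5
  set.seed(99)
  eps <- rnorm(4e5, 0, sqrt(cfg$subject_sd^2 + cfg$coexpression_loading[["TIGIT"]]^2))
  oracle_gap <- qlogis(mean(plogis(cfg$ir_base_logit[["TIGIT"]] + 1.5 + eps))) -
    qlogis(mean(plogis(cfg$ir_base_logit[["TIGIT"]] + eps)))
  expect_lt(abs(oracle_gap - 1.5), 0.25)   # the band the generator targets

  # empirical gap agrees with the oracle within 3 Monte-Carlo SE
  se_group <- function(f) {
    p <- mean(f)
    sd(f) / (p * (1 - p)) / sqrt(length(f))   # delta method on qlogis(mean)
  }
  se_gap <- sqrt(se_group(frac[hiv == 1])^2 + se_group(frac[hiv == 0])^2)
  expect_lt(abs(gap - oracle_gap), 3 * se_gap)
})

test_that("FM5 IR channels match the main samples' IR-negative distribution", {
  sc <- small_cohort()
  coh <- sc$cohort
  fm5_tigit <- coh$fm5[[1]]$values[, "TIGIT"]
  # pool IR-negative cells (generator truth) across a few samples
  neg <- unlist(lapply(coh$events[1:6], function(m) {
    tr <- attr(m, "truth")
    m$values[!tr$ir_pos[, "TIGIT"], "TIGIT"]
  }))
  set.seed(1)
  neg <- sample(neg, min(length(neg), 5000))
  ks <- suppressWarnings(ks.test(neg, fm5_tigit))
  expect_gt(ks$p.value, 0.01)
})

test_that("supernatant secretion follows the group-specific linear model", {
  design <- make_design(3)
  cfg <- synthetic_config(seed = 5, secretion_noise_sd = 1e-9)
  tf <- setNames(runif(nrow(design), 0.1, 0.6), design$subject_id)

  # zero slope and (near) zero noise: identical per-cell values within a group
  cfg0 <- cfg
  cfg0$secretion_slope[] <- 0
  sup <- generate_supernatant(design, tf, cfg0)
  per_cell <- normalize_per_cell(sup)
  young_u <- design$subject_id[design$group == "uninfected_young"]
  vals <- per_cell$concentrations[young_u, "sCD137"]
  expect_lt(diff(range(vals)), 1e-6)

  # well total is per-cell rate times cell count
  expect_equal(sup$concentrations, per_cell$concentrations *
                 per_cell$cells_per_well[rownames(per_cell$concentrations)],
               tolerance = 1e-12)
  expect_true(all(sup$cells_per_well >= 2000 & sup$cells_per_well <= 26000))

  # subject mismatch errors
  expect_error(generate_supernatant(design, tf[-1], cfg), "subject")

  # positive slope only in HIV groups is recovered by downstream regression
  sup2 <- normalize_per_cell(generate_supernatant(design, tf,
                                                  synthetic_config(seed = 6)))
  reg_h <- analyte_regressions(tf, sup2, design, "hiv")
  reg_u <- analyte_regressions(tf, sup2, design, "uninfected")
  expect_true(all(reg_h$slope > 0))
  expect_true(mean(abs(reg_u$slope)) < mean(reg_h$slope))
})

test_that("null abundances are exchangeable Dirichlet compositions", {
  ab <- generate_null_abundances(1000, 8, seed = 4)
  expect_identical(dim(ab), c(1000L, 8L))
  expect_true(all(abs(rowSums(ab) - 1) < 1e-9))
  # marginal mean ~ 1/8 within 3 SE (Dirichlet moments: var = p(1-p)/(K*conc+1))
  se <- sqrt((1 / 8) * (7 / 8) / (8 * 2 + 1)) / sqrt(1000)
  expect_true(all(abs(colMeans(ab) - 1 / 8) < 3 * se))
  expect_error(generate_null_abundances(3, 8), "n_subjects")
  expect_error(generate_null_abundances(10, 1), "n_subsets")
  expect_identical(ab, generate_null_abundances(1000, 8, seed = 4))
})
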