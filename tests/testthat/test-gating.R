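test_that("FM5 quantile gates behave like empirical quantiles", {
  vals <- matrix(2, 100, 13, dimnames = list(NULL, names(synthetic_channel_roles())))
  fm5 <- make_event_matrix(vals)
  g <- derive_gates(fm5, markers = "TIGIT", quantile = 0.995)
  expect_equal(g$threshold, 2)          # degenerate distribution

  set.seed(4)
  vals[, "TIGIT"] <- rnorm(100)
  fm5 <- make_event_matrix(vals)
  g1 <- derive_gates(fm5, "TIGIT", quantile = 0.9)
  g2 <- derive_gates(fm5, "TIGIT", quantile = 0.995)
  expect_lte(g1$threshold, g2$threshold)   # monotone in the quantile
  expect_error(derive_gates(fm5, "NotAChannel"), "NotAChannel")

  # ~0.5% of FM5 events exceed their own 0.995 gate
  big <- make_event_matrix(matrix(rnorm(13 * 10000), ncol = 13,
                                  dimnames = list(NULL, names(synthetic_channel_roles()))))
  thr <- derive_gates(big, "PD-1", quantile = 0.995)$threshold
  expect_equal(sum(big$values[, "PD-1"] > thr), 50, tolerance = 0.3)
})

test_that("gate_subset is a pure order-independent conjunction", {
  sc <- small_cohort()
  m <- sc$cohort$events[["S001"]]
  all_pass <- list(list("CD3", ">", -Inf))
  expect_identical(gate_subset(m, all_pass)$values, m$values)

  strat <- gd_gate_strategy()
  g1 <- gate_subset(m, strat)
  g2 <- gate_subset(m, rev(strat))
  expect_identical(g1$values, g2$values)
  expect_identical(attr(g1, "n_gated"), nrow(g1$values))

  # against generator truth: gated cells are overwhelmingly gamma-delta
  expect_gte(mean(attr(g1, "truth")$subset == "gdT"), 0.95)

  # empty gate warns and flags instead of erroring
  expect_warning(e <- gate_subset(m, list(list("CD3", ">", 1e6))), "no cells")
  expect_true(attr(e, "empty"))
  expect_identical(attr(e, "n_gated"), 0L)
})

test_that("combination signatures enumerate and tally exactly", {
  vals <- matrix(0.1, 4, 13, dimnames = list(NULL, names(synthetic_channel_roles())))
  # patterns over (PD-1, TIGIT, CD160): +--, +--, -+-, ---
  vals[1:2, "PD-1"] <- 3
  vals[3, "TIGIT"] <- 3
  m <- make_event_matrix(vals)
  gates <- data.frame(marker = c("PD-1", "TIGIT", "CD160"), threshold = 1,
                      source_batch = 1L, quantile = 0.995)
  cs <- combo_signature(m, gates)
  expect_length(cs, 8)                        # 2^3 patterns, zeros included
  expect_equal(unname(cs[["+--"]]), 0.5)
  expect_equal(unname(cs[["-+-"]]), 0.25)
  expect_equal(unname(cs[["---"]]), 0.25)
  expect_equal(sum(cs), 1, tolerance = 1e-12)

  # zero-cell input propagates missing values with a flag
  empty <- make_event_matrix(vals[0, , drop = FALSE])
  cs0 <- combo_signature(empty, gates)
  expect_true(all(is.na(cs0)))
  expect_true(attr(cs0, "undefined"))
})

test_that("combo_signature equals a brute-force per-cell pattern tally", {
  sc <- small_cohort()
  coh <- sc$cohort
  gates <- derive_gates(coh$fm5[[1]])
  m <- coh$events[["S013"]]   # an HIV subject, ungated: 800 cells
  ir_set <- c("PD-1", "TIGIT", "CD160")
  cs <- combo_signature(m, gates, ir_set)
  # independent oracle: loop over cells, build the pattern string directly
  oracle <- setNames(numeric(8), names(cs))
  for (i in seq_len(nrow(m$values))) {
    pat <- paste(ifelse(m$values[i, ir_set] >
                          gates$threshold[match(ir_set, gates$marker)],
                        "+", "-"), collapse = "")
    oracle[pat] <- oracle[pat] + 1
  }
  expect_equal(as.numeric(cs), as.numeric(oracle / nrow(m$values)),
               tolerance = 1e-12)
})

test_that("multi-IR fractions count and nest correctly", {
  vals <- matrix(0.1, 4, 13, dimnames = list(NULL, names(synthetic_channel_roles())))
  irs <- c("CD160", "TIGIT", "TIM-3", "LAG-3", "PD-1")
  vals[1, c("CD160", "TIGIT")] <- 3                    # 2 IRs
  vals[3, c("CD160", "TIGIT", "PD-1")] <- 3            # 3 IRs
  vals[4, "PD-1"] <- 3                                 # 1 IR
  m <- make_event_matrix(vals)
  gates <- data.frame(marker = irs, threshold = 1, source_batch = 1L,
                      quantile = 0.995)
  f <- multi_ir_fractions(m, gates)
  expect_equal(unname(f), c(0.5, 0.25, 0))
  expect_true(f[["ge2"]] >= f[["ge3"]] && f[["ge3"]] >= f[["ge4"]])
})

test_that("raising an IR gate never increases its marginal positive fraction", {
  sc <- small_cohort()
  m <- sc$cohort$events[["S002"]]
  for (thr in seq(0.5, 3, by = 0.5)) {
    lo <- mean(m$values[, "TIGIT"] > thr)
    hi <- mean(m$values[, "TIGIT"] > thr + 0.25)
    expect_lte(hi, lo)
  }
})

test_that("median ratios compare gated cells to the FM5 background", {
  vals <- matrix(1, 50, 13, dimnames = list(NULL, names(synthetic_channel_roles())))
  vals[, "TIM-3"] <- seq(0.5, 2, length.out = 50)
  a <- make_event_matrix(vals)
  expect_equal(median_ratio(a, a, "TIM-3"), 1)
  b <- a
  b$values[, "TIM-3"] <- 2 * b$values[, "TIM-3"]
  expect_equal(median_ratio(b, a, "TIM-3"), 2)
  z <- a
  z$values[, "TIM-3"] <- 0
  expect_warning(r <- median_ratio(a, z, "TIM-3"), "undefined")
  expect_true(is.na(r))
})

test_that("the signature table satisfies the partition property", {
  sc <- small_cohort()
  coh <- sc$cohort
  sig <- signature_table(coh$events, coh$fm5, coh$design)
  ab <- combo_abundances(sig)
  expect_true(all(abs(rowSums(ab) - 1) < 1e-9))
  expect_true(all(ab >= 0))
  # marginal positive = sum of combos with that IR positive (combo set order
  # PD-1, TIGIT, CD160)
  for (i in seq_len(nrow(sig))) {
    tigit_pos <- sum(ab[i, substr(colnames(ab), 2, 2) == "+"])
    expect_equal(unname(tigit_pos), sig$`pos_TIGIT`[i], tolerance = 1e-9)
  }
  # multi-IR nesting holds subject-wise
  expect_true(all(sig$ge2 >= sig$ge3 & sig$ge3 >= sig$ge4))
  # the configured HIV effects raise the >=3-IR fraction in the HIV groups
  expect_gt(mean(sig$ge3[coh$design$hiv == 1]),
            mean(sig$ge3[coh$design$hiv == 0]))
})
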