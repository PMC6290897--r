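test_that("z-scoring uses the sample SD and round-trips", {
  z <- zscore_fit_apply(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z$z), c(-1, 0, 1))
  tab <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  zz <- zscore_fit_apply(tab)
  expect_equal(unname(colMeans(zz$z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(zz$z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  back <- irsigflow:::.invert_zscore(zz$z, zz$center, zz$scale)
  expect_equal(unname(back), unname(tab), tolerance = 1e-9)
  bad <- cbind(ok = rnorm(5), flat = rep(2, 5))
  expect_error(zscore_fit_apply(bad), "flat")
})

test_that("PLSR reduces to OLS with one predictor and recovers exact structure", {
  set.seed(21)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x"))
  y <- 1.7 * x[, 1] + rnorm(40, 0, 0.4)
  m <- fit_pls(x, y, 1)
  expect_equal(unname(pls_fitted(m)[, 1]), unname(fitted(lm(y ~ x))),
               tolerance = 1e-8)
  # noiseless Y = X b with rank r: perfect fit at A = r
  X <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- X %*% c(1, -2, 0.5, 3)
  mr <- fit_pls(X, Y, 4)
  expect_equal(unname(pls_fitted(mr)[, 1]), unname(Y[, 1]), tolerance = 1e-8)
  # score columns orthogonal
  G <- crossprod(mr$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
})

test_that("VIP scores obey their normalization identity and rank signal", {
  set.seed(22)
  x1 <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "only"))
  m1 <- fit_pls(x1, rnorm(30) + x1[, 1], 1)
  expect_equal(as.numeric(vip_scores(m1)), 1, tolerance = 1e-12)

  X <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, paste0("v", 1:10)))
  y <- 3 * X[, 1] + rnorm(60, 0, 0.2)
  m <- fit_pls(X, y, 3)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-9)
  expect_gt(v[["v1"]], 1)
  expect_gt(v[["v1"]], median(v[-1]))
  expect_lt(median(v[-1]), 1)
})

test_that("latent-variable selection minimizes held-out error", {
  set.seed(23)
  # planted 2-LV structure: the response depends on two orthogonal latent X
  # directions expressed through unequal column blocks, so one LV underfits
  # (it favors the dominant block) and a third LV fits only noise
  recovered <- replicate(100, {
    n <- 42
    t1 <- rnorm(n); t2 <- rnorm(n)
    X <- cbind(sapply(1:5, function(i) t1 + rnorm(n, 0, 0.3)),
               sapply(1:3, function(i) t2 + rnorm(n, 0, 0.3)))
    colnames(X) <- paste0("x", 1:8)
    y <- t1 + t2 + rnorm(n, 0, 0.3)
    sel <- select_n_lv(X, y, 1:4, seed = sample.int(1e6, 1))
    expect_length(sel$cv_error, 4)
    sel$A_star
  })
  expect_gte(mean(recovered == 2), 0.8)

  # pure noise: the smallest model wins most of the time
  noise_A <- replicate(50, {
    X <- matrix(rnorm(36 * 8), 36)
    colnames(X) <- paste0("x", 1:8)
    select_n_lv(X, rnorm(36), 1:4, seed = sample.int(1e6, 1))$A_star
  })
  expect_gte(mean(noise_A == 1), 0.5)
  expect_error(select_n_lv(matrix(rnorm(10), 5), rnorm(5)), "6 samples")
})

test_that("the NIPALS fit agrees with an independent PLS implementation", {
  suppressMessages(suppressWarnings(library(mixOmics)))
  set.seed(27)
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- cbind(y1 = X[, 1] + rnorm(30, 0, 0.3),
             y2 = X[, 2] - X[, 3] + rnorm(30, 0, 0.3))
  m <- fit_pls(X, Y, 2)
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  pr <- predict(mo, X)
  expect_lt(max(abs(pls_fitted(m) - pr$predict[, , 2])), 1e-8)
  # scores agree up to the usual sign indeterminacy
  expect_equal(abs(diag(cor(m$T, mo$variates$X))), c(1, 1), tolerance = 1e-8)
})

test_that("orthogonal rotation maximizes axis-1 separation without changing fit", {
  set.seed(24)
  cls <- factor(rep(c("a", "b"), each = 25))
  # separation deliberately placed so it loads on LV2, not LV1: a high-variance
  # noise direction dominates X variance, a weaker direction carries the classes
  X <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("x", 1:6)))
  X[, 1] <- rnorm(50, 0, 6)                         # dominant variance, no class info
  X[cls == "b", 2] <- X[cls == "b", 2] + 2.5        # class signal
  m <- fit_pls(X, cls, 2)
  pred0 <- predict(m, X)
  rot <- orthogonal_rotate(m, "class_separation")
  expect_lt(max(abs(predict(rot, X) - pred0)), 1e-9)
  expect_lt(max(abs(crossprod(rot$R) - diag(2))), 1e-9)

  sep_frac <- function(t1) {
    mu <- mean(t1)
    between <- sum(sapply(levels(cls), function(k)
      sum(cls == k) * (mean(t1[cls == k]) - mu)^2))
    between / sum((t1 - mu)^2)
  }
  expect_gte(sep_frac(rot$T[, 1]), sep_frac(rot$T[, 2]))

  # dense angle-grid oracle: no rotation angle beats the closed-form solution
  angles <- seq(0, pi, length.out = 721)
  grid_best <- max(vapply(angles, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sep_frac((m$T %*% R)[, 1])
  }, numeric(1)))
  expect_gte(sep_frac(rot$T[, 1]) + 1e-9, grid_best)
})

test_that("permutation significance is powered, calibrated and reproducible", {
  set.seed(25)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * X[, 1] + X[, 2] + rnorm(30, 0, 0.4)
  p1 <- permutation_significance(X, y, 1:3, n_perm = 30, seed = 6)
  p2 <- permutation_significance(X, y, 1:3, n_perm = 30, seed = 6)
  expect_identical(p1$p_value, p2$p_value)
  expect_lt(p1$p_value, 0.05)
  expect_error(permutation_significance(X, y, 1:3, n_perm = 10), "n_perm")

  # strong planted signal rejects in nearly every replicate
  rejections <- replicate(20, {
    Xs <- matrix(rnorm(24 * 4), 24, dimnames = list(NULL, paste0("x", 1:4)))
    ys <- 3 * Xs[, 1] + rnorm(24, 0, 0.3)
    permutation_significance(Xs, ys, 1:2, n_perm = 25,
                             seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("confidence ellipses match the chi-square geometry", {
  set.seed(26)
  ce <- confidence_ellipse(matrix(rnorm(2e4), ncol = 2))
  expect_equal(unname(ce$axes), rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
  # level -> 0 collapses onto the centroid
  ce0 <- confidence_ellipse(matrix(rnorm(100), ncol = 2), level = 1e-12)
  expect_lt(max(ce0$axes), 1e-5)
  # large-sample containment near the nominal level
  S <- matrix(c(2, 0.7, 0.7, 1), 2)
  pts <- matrix(rnorm(2e4), ncol = 2) %*% chol(S)
  ce2 <- confidence_ellipse(pts)
  centered <- sweep(pts, 2, ce2$center)
  inside <- rowSums((centered %*% solve(ce2$cov)) * centered) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "singular")
})
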