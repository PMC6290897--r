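# Beta regression of subset abundances: y ~ Beta(mu*phi, (1-mu)*phi) with
# logit(mu) = X beta. Maximum likelihood via BFGS on (beta, log phi) with
# analytic gradient; Wald tests from the observed information. Written as a
# compact fitter because the permutation layer refits the model tens of
# thousands of times.

# negative log-likelihood and gradient; ly = log(y), l1y = log(1-y) precomputed
.br_nll <- function(theta, X, ly, l1y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[1:k])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * ly + (b - 1) * l1y)
}

.br_grad <- function(theta, X, ly, l1y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[1:k])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  ystar <- ly - l1y
  mustar <- digamma(a) - digamma(b)
  # d nll / d beta
  gb <- -drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  # d nll / d log phi
  gp <- -phi * sum(digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
                     mu * ly + (1 - mu) * l1y)
  c(gb, gp)
}

# Core MLE on a model matrix. Returns NULL only on hard failure.
.betareg_mle <- function(y, X, max_restarts = 3) {
  n <- length(y)
  boundary <- any(y <= 0 | y >= 1)
  if (boundary) y <- (y * (n - 1) + 0.5) / n   # interior transform, whole vector
  ly <- log(y); l1y <- log1p(-y)
  # starting values: OLS on the empirical logit, method-of-moments phi
  yl <- logit(y)
  beta0 <- tryCatch(qr.coef(qr(X), yl), error = function(e) rep(0, ncol(X)))
  beta0[is.na(beta0)] <- 0
  mu0 <- stats::plogis(drop(X %*% beta0))
  s2 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(s2, 1e-8) - 1, 1)
  theta <- c(beta0, log(phi0))
  fit <- NULL
  for (r in 0:max_restarts) {
    start <- if (r == 0) theta else theta + stats::rnorm(length(theta), 0, 0.5 * r)
    res <- tryCatch(
      stats::optim(start, .br_nll, .br_grad, X = X, ly = ly, l1y = l1y,
                   method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0 && is.finite(res$value)) {
      fit <- res
      break
    }
    if (!is.null(res) && is.null(fit)) fit <- res  # keep last iterate
  }
  if (is.null(fit)) return(NULL)
  H <- tryCatch(
    stats::optimHess(fit$par, .br_nll, .br_grad, X = X, ly = ly, l1y = l1y),
    error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  list(par = fit$par, loglik = -fit$value, vcov = vc,
       converged = fit$convergence == 0, boundary = boundary, n = n)
}

#' Beta regression of an abundance on HIV status and age group
#'
#' Fits `y ~ Beta(mu*phi, (1-mu)*phi)` with
#' `logit(mu) = beta0 + beta_hiv * hiv + beta_age * old` by maximum
#' likelihood. Boundary values (0 or 1) are handled by the interior transform
#' `y' = (y*(n-1) + 0.5)/n` applied to the whole vector (and flagged). Wald
#' z-statistics and two-sided p-values come from the observed information.
#'
#' @param y abundance vector in `[0, 1]`, length >= 4.
#' @param design cohort design data.frame with columns `hiv` (0/1) and
#'   `age_group` (`young`/`old`); both levels of each term must be present.
#' @return an object of class `beta_reg` with components `coefficients`
#'   (intercept, hiv, age_old), `phi`, `se`, `z`, `p`, `loglik`, `vcov`,
#'   `converged`, `boundary_adjusted`, `n`.
#' @export
fit_beta_regression <- function(y, design) {
  if (any(is.na(y)) || any(y < 0 | y > 1))
    stop_field("y", "abundances must lie in [0, 1] with no missing values")
  if (length(y) < 4) stop("need at least 4 observations", call. = FALSE)
  if (length(y) != nrow(design))
    stop("length(y) must match nrow(design)", call. = FALSE)
  if (length(unique(design$hiv)) < 2 || length(unique(design$age_group)) < 2)
    stop("both HIV and age levels must be represented", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, hiv = design$hiv,
             age_old = as.integer(design$age_group == "old"))
  fit <- .betareg_mle(y, X)
  if (is.null(fit) || !fit$converged)
    stop(structure(class = c("betareg_nonconvergence", "error", "condition"),
                   list(message = "beta regression failed to converge after restarts",
                        call = sys.call(-1), last = fit)))
  k <- ncol(X)
  coefs <- stats::setNames(fit$par[1:k], colnames(X))
  phi <- unname(exp(fit$par[k + 1]))
  if (!is.null(fit$vcov)) {
    se <- sqrt(pmax(diag(fit$vcov)[1:k], 0))
  } else {
    se <- rep(NA_real_, k)
  }
  z <- coefs / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = coefs, phi = phi,
                 se = stats::setNames(se, colnames(X)),
                 z = stats::setNames(z, colnames(X)),
                 p = stats::setNames(p, colnames(X)),
                 loglik = fit$loglik, vcov = fit$vcov,
                 converged = fit$converged,
                 boundary_adjusted = fit$boundary, n = fit$n),
            class = "beta_reg")
}

#' @export
coef.beta_reg <- function(object, ...) object$coefficients

#' @export
logLik.beta_reg <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
vcov.beta_reg <- function(object, ...) object$vcov

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit link), ML fit\n")
  cat(sprintf("  n = %d, phi = %.3f, logLik = %.3f%s\n", x$n, x$phi, x$loglik,
              if (x$boundary_adjusted) " (boundary-adjusted y)" else ""))
  print(round(rbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p), 4))
  invisible(x)
}

#' @export
summary.beta_reg <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(coefficients = tab, phi = object$phi, loglik = object$loglik,
                 n = object$n, boundary_adjusted = object$boundary_adjusted),
            class = "summary.beta_reg")
}

#' @export
print.summary.beta_reg <- function(x, ...) {
  cat("Beta regression of abundance on HIV status and age group\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nprecision phi = %.3f, logLik = %.3f, n = %d\n",
              x$phi, x$loglik, x$n))
  invisible(x)
}

# Wald p-values of the hiv and age terms for one abundance column; used by
# the permutation layer. Non-convergent fits score p = 1 (conservative for a
# minimum).
.term_pvalues <- function(y, X) {
  fit <- .betareg_mle(y, X)
  if (is.null(fit) || !fit$converged || is.null(fit$vcov))
    return(c(hiv = 1, age = 1))
  se <- sqrt(pmax(diag(fit$vcov)[2:3], 0))
  z <- fit$par[2:3] / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  c(hiv = p[1], age = p[2])
}

#' Permutation-derived minimum-p significance threshold
#'
#' Implements family-wise error control for the per-subset beta regressions:
#' `n_perm` permuted datasets are created by permuting, independently within
#' each subject, that subject's vector of subset abundances across the subset
#' labels (so the inter-dependency of a subject's abundances is maintained);
#' for each permuted dataset the beta regression is refit per subset and the
#' minimum Wald p across subsets is recorded per model term; the threshold is
#' the 5th percentile of those minima, computed as the
#' `ceiling(0.05 * n_perm)`-th smallest value (the 5th smallest at
#' `n_perm = 100`), with no interpolation.
#'
#' The alternative reading of the permutation scheme — resampling each
#' subset's abundances across subjects — is available as
#' `scheme = "across_subjects"` but is not the default because it breaks the
#' within-subject dependence the default scheme preserves.
#'
#' @param abundances subjects x subsets matrix (e.g. the 8 combination
#'   columns from [combo_abundances()]).
#' @param design cohort design data.frame (`hiv`, `age_group`).
#' @param n_perm number of permutations (>= 20; default 100).
#' @param seed integer seed; the threshold is seed-deterministic.
#' @param scheme `"within_subject"` (default) or `"across_subjects"`.
#' @return object of class `perm_threshold`: per-term thresholds and minimum-p
#'   distributions, plus `n_perm` and `seed`.
#' @export
minp_threshold <- function(abundances, design, n_perm = 100, seed = 1,
                           scheme = c("within_subject", "across_subjects")) {
  scheme <- match.arg(scheme)
  abundances <- as.matrix(abundances)
  if (n_perm < 20) stop_field("n_perm", "must be >= 20")
  if (nrow(abundances) != nrow(design))
    stop("abundances and design must cover the same subjects", call. = FALSE)
  n <- nrow(abundances); k <- ncol(abundances)
  X <- cbind(`(Intercept)` = 1, hiv = design$hiv,
             age_old = as.integer(design$age_group == "old"))
  set.seed(seed)
  minp <- matrix(NA_real_, n_perm, 2, dimnames = list(NULL, c("hiv", "age")))
  for (b in seq_len(n_perm)) {
    perm <- if (scheme == "within_subject") {
      # permute each subject's multiset of abundances across the subset
      # labels; acting on the sorted values makes the draw (hence the
      # threshold) invariant to the input column order under a fixed seed
      t(apply(abundances, 1, function(r) sort(r)[sample.int(length(r))]))
    } else {
      apply(abundances, 2, sample)
    }
    ps <- vapply(seq_len(k), function(j) .term_pvalues(perm[, j], X),
                 c(hiv = 0, age = 0))
    minp[b, "hiv"] <- min(ps["hiv", ])
    minp[b, "age"] <- min(ps["age", ])
  }
  r <- as.integer(ceiling(0.05 * n_perm))
  thr <- apply(minp, 2, function(v) sort(v)[r])
  structure(list(thresholds = thr, minp_distribution = minp,
                 n_perm = n_perm, seed = seed, scheme = scheme,
                 rank_used = r),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("minP permutation thresholds (%d permutations, %s scheme):\n",
              x$n_perm, x$scheme))
  cat(sprintf("  HIV term: %.6f\n  age term: %.6f\n",
              x$thresholds[["hiv"]], x$thresholds[["age"]]))
  invisible(x)
}

#' Apply per-term minP thresholds to per-subset fits
#'
#' A subset is significant for a term iff its Wald p is strictly below that
#' term's permutation threshold.
#'
#' @param fits named list of [fit_beta_regression()] results (one per subset).
#' @param thresholds a [minp_threshold()] result.
#' @return list with elements `hiv` and `age`: character vectors of
#'   significant subset names.
#' @export
apply_thresholds <- function(fits, thresholds) {
  stopifnot(inherits(thresholds, "perm_threshold"))
  if (length(fits) == 0) return(list(hiv = character(0), age = character(0)))
  p_hiv <- vapply(fits, function(f) f$p[["hiv"]], numeric(1))
  p_age <- vapply(fits, function(f) f$p[["age_old"]], numeric(1))
  list(hiv = names(fits)[p_hiv < thresholds$thresholds[["hiv"]]],
       age = names(fits)[p_age < thresholds$thresholds[["age"]]])
}

#' Fit the per-subset beta regressions of a combination-abundance matrix
#'
#' @param abundances subjects x subsets matrix.
#' @param design cohort design data.frame.
#' @return named list of `beta_reg` fits (non-convergent subsets are dropped
#'   with a warning).
#' @export
fit_subset_regressions <- function(abundances, design) {
  abundances <- as.matrix(abundances)
  out <- list()
  for (j in colnames(abundances)) {
    f <- tryCatch(fit_beta_regression(abundances[, j], design),
                  error = function(e) NULL)
    if (is.null(f)) warning(sprintf("subset '%s' did not converge; dropped", j),
                            call. = FALSE)
    else out[[j]] <- f
  }
  out
}
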