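# Partial least squares regression / discriminant analysis: z-scoring,
# NIPALS decomposition, one-third cross-validation for latent-variable
# selection, VIP scores, orthogonal score rotation, and permutation-based
# model significance.

#' Z-score a table and keep the parameters
#'
#' Columns are centered and scaled to unit sample standard deviation; the
#' centers and scales are stored so new samples can be mapped into the same
#' space and predictions mapped back.
#'
#' @param table samples x variables numeric matrix.
#' @return list `z` (standardized matrix), `center`, `scale`.
#' @export
zscore_fit_apply <- function(table) {
  table <- as.matrix(table)
  s <- apply(table, 2, stats::sd)
  zero <- which(s == 0 | is.na(s))
  if (length(zero))
    stop(paste("zero-variance column(s):",
               paste(colnames(table)[zero], collapse = ", ")), call. = FALSE)
  ctr <- colMeans(table)
  list(z = scale(table, center = ctr, scale = s), center = ctr, scale = s)
}

.apply_zscore <- function(table, ctr, s) scale(as.matrix(table), ctr, s)
.invert_zscore <- function(z, ctr, s) {
  out <- sweep(sweep(as.matrix(z), 2, s, "*"), 2, ctr, "+")
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# Raw NIPALS on standardized X, Y. Deflates both blocks.
.nipals <- function(X, Y, A, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, q, A); TT <- matrix(0, n, A)
  ssy <- numeric(A)
  Xd <- X; Yd <- Y
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    if (sum(u^2) < 1e-300) stop("Y block exhausted before component ", a,
                                call. = FALSE)
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xd %*% w)
      qv <- drop(crossprod(Yd, tt)) / sum(tt^2)
      u <- drop(Yd %*% qv) / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- drop(crossprod(Xd, tt)) / sum(tt^2)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; TT[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(qv^2)   # Y-variance captured by this LV
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, qv)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- colnames(Y)
  list(W = W, P = P, Q = Q, T = TT, ssy = ssy)
}

#' Fit a partial least squares model
#'
#' NIPALS decomposition with deflation of both blocks. In regression mode Y
#' is one or more continuous responses; in discriminant mode `Y` is a factor
#' that is encoded as one indicator column per class, and predictions decode
#' by argmax (ties broken by class order). Both blocks are z-scored
#' internally and the parameters are stored on the model.
#'
#' @param X samples x predictors matrix.
#' @param Y response matrix/vector (regression) or factor (discriminant).
#' @param A number of latent variables; at most `min(samples - 1,
#'   predictors)`.
#' @param mode `"regression"` or `"discriminant"` (inferred when `Y` is a
#'   factor).
#' @return object of class `pls_model`: weights `W`, loadings `P` and `Q`,
#'   scores `T`, per-LV captured Y-variance `ssy`, rotation `R` (identity
#'   until [orthogonal_rotate()]), z-score parameters, explained-variance
#'   fractions, mode and class map.
#' @export
fit_pls <- function(X, Y, A, mode = NULL) {
  X <- as.matrix(X)
  if (is.factor(Y) || is.character(Y)) {
    if (is.null(mode)) mode <- "discriminant"
  } else if (is.null(mode)) mode <- "regression"
  mode <- match.arg(mode, c("regression", "discriminant"))
  if (mode == "discriminant") {
    cls <- droplevels(as.factor(Y))
    class_map <- levels(cls)
    Ymat <- sapply(class_map, function(k) as.numeric(cls == k))
    colnames(Ymat) <- class_map
  } else {
    class_map <- NULL
    Ymat <- as.matrix(Y)
    if (is.null(colnames(Ymat)))
      colnames(Ymat) <- paste0("Y", seq_len(ncol(Ymat)))
  }
  if (anyNA(X) || anyNA(Ymat)) stop("NaN/NA in inputs", call. = FALSE)
  if (A > min(nrow(X) - 1, ncol(X)))
    stop("A exceeds min(samples - 1, predictors)", call. = FALSE)
  zx <- zscore_fit_apply(X)
  zy <- zscore_fit_apply(Ymat)
  dec <- .nipals(zx$z, zy$z, A)
  tot_x <- sum(zx$z^2); tot_y <- sum(zy$z^2)
  # X-variance per LV: ||t_a p_a'||^2 = |t_a|^2 |p_a|^2
  xvar <- vapply(seq_len(A), function(a)
    sum(dec$T[, a]^2) * sum(dec$P[, a]^2) / tot_x, numeric(1))
  yvar <- dec$ssy / tot_y
  structure(list(W = dec$W, P = dec$P, Q = dec$Q, T = dec$T, ssy = dec$ssy,
                 A = A, R = diag(A), mode = mode, class_map = class_map,
                 classes = if (mode == "discriminant") cls else NULL,
                 x_center = zx$center, x_scale = zx$scale,
                 y_center = zy$center, y_scale = zy$scale,
                 tot_x = tot_x, tot_y = tot_y,
                 x_variance = xvar, y_variance = yvar,
                 y_names = colnames(Ymat)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS %s model: %d predictors, %d response column(s), %d LV(s)\n",
              x$mode, nrow(x$W), nrow(x$Q), x$A))
  cat(sprintf("  variance captured per LV: X %s; Y %s\n",
              paste(sprintf("%.1f%%", 100 * x$x_variance), collapse = ", "),
              paste(sprintf("%.1f%%", 100 * x$y_variance), collapse = ", ")))
  if (!identical(x$R, diag(x$A))) cat("  (scores orthogonally rotated)\n")
  invisible(x)
}

# regression coefficients on the standardized scale
.pls_beta <- function(model) {
  model$W %*% solve(crossprod(model$P, model$W), t(model$Q))
}

#' Predict from a PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata samples x predictors matrix (original scale).
#' @param type `"response"` (back-transformed Y, or class indicator scores in
#'   discriminant mode), `"class"` (discriminant mode: argmax-decoded
#'   labels), or `"scores"` (latent-variable coordinates, rotated if the
#'   model was rotated).
#' @param ... unused.
#' @return matrix of predictions, or character vector of classes.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class",
                                                        "scores"), ...) {
  type <- match.arg(type)
  Z <- .apply_zscore(newdata, object$x_center, object$x_scale)
  if (type == "scores") {
    Tn <- Z %*% object$W %*% solve(crossprod(object$P, object$W))
    return(Tn %*% object$R)
  }
  Yz <- Z %*% .pls_beta(object)
  Yhat <- .invert_zscore(Yz, object$y_center, object$y_scale)
  colnames(Yhat) <- object$y_names
  if (type == "class") {
    if (object$mode != "discriminant")
      stop("type = 'class' needs a discriminant model", call. = FALSE)
    return(object$class_map[max.col(Yhat, ties.method = "first")])
  }
  Yhat
}

#' Fitted responses of a PLS model on its training data
#'
#' @param model a [fit_pls()] model.
#' @return back-transformed fitted Y matrix.
#' @export
pls_fitted <- function(model) {
  Yz <- model$T %*% t(model$Q)
  Yhat <- .invert_zscore(Yz, model$y_center, model$y_scale)
  colnames(Yhat) <- model$y_names
  Yhat
}

.pls_folds <- function(n, y_class, n_folds, seed) {
  if (!is.null(y_class)) return(.stratified_folds(y_class, n_folds, seed))
  set.seed(seed)
  fold <- rep_len(seq_len(n_folds), n)
  sample(fold)
}

# held-out per-sample errors at each candidate A; returns matrix n x |grid|
.cv_sample_errors <- function(X, Y, A_grid, mode, n_folds, seed) {
  n <- nrow(X)
  y_class <- if (mode == "discriminant") droplevels(as.factor(Y)) else NULL
  fold <- .pls_folds(n, y_class, n_folds, seed)
  if (!is.null(y_class)) {
    for (redraw in 1:10) {
      ok <- all(vapply(seq_len(n_folds), function(f)
        nlevels(droplevels(y_class[fold != f])) == nlevels(y_class),
        logical(1)))
      if (ok) break
      fold <- .stratified_folds(y_class, n_folds, seed + 1000 * redraw)
    }
  }
  err <- matrix(NA_real_, n, length(A_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (g in seq_along(A_grid)) {
      m <- fit_pls(X[tr, , drop = FALSE],
                   if (is.null(y_class)) as.matrix(Y)[tr, , drop = FALSE]
                   else y_class[tr],
                   A = min(A_grid[g], sum(tr) - 1, ncol(X)), mode = mode)
      if (mode == "discriminant") {
        pred <- predict(m, X[!tr, , drop = FALSE], type = "class")
        err[!tr, g] <- as.numeric(pred != as.character(y_class[!tr]))
      } else {
        pred <- predict(m, X[!tr, , drop = FALSE])
        err[!tr, g] <- rowSums((as.matrix(Y)[!tr, , drop = FALSE] - pred)^2)
      }
    }
  }
  err
}

#' Select the number of latent variables by one-third cross-validation
#'
#' Three folds, each one-third of the samples (stratified by class in
#' discriminant mode); every sample is held out exactly once and the error is
#' cumulated over all held-out predictions — root-mean-squared prediction
#' error in regression mode, misclassification fraction in discriminant
#' mode. The selected A minimizes the curve; ties go to the smaller A.
#'
#' @param X predictors, `Y` responses or class factor.
#' @param Y response.
#' @param A_grid candidate LV counts (default 1 up to
#'   `min(samples - 2, predictors, 6)`).
#' @param mode `"regression"` or `"discriminant"`.
#' @param n_folds folds (default 3: one-third holdouts).
#' @param seed fold seed.
#' @return list `A_star`, `cv_error` (named by grid value).
#' @export
select_n_lv <- function(X, Y, A_grid = NULL, mode = NULL, n_folds = 3,
                        seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 6) stop("need at least 6 samples", call. = FALSE)
  if (is.null(mode))
    mode <- if (is.factor(Y) || is.character(Y)) "discriminant" else "regression"
  if (is.null(A_grid))
    A_grid <- seq_len(max(1, min(nrow(X) - 2, ncol(X), 6)))
  err <- .cv_sample_errors(X, Y, A_grid, mode, n_folds, seed)
  cv_error <- if (mode == "discriminant") colMeans(err)
              else sqrt(colMeans(err))
  names(cv_error) <- A_grid
  list(A_star = A_grid[which.min(cv_error)], cv_error = cv_error)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a(w_ja^2 * SSY_a) / sum_a SSY_a )` with `SSY_a` the
#' Y-variance captured by LV a and p the number of predictors; the mean
#' squared VIP is 1 by construction, so scores above 1 mark above-average
#' contribution.
#'
#' @param model a [fit_pls()] model.
#' @return named numeric VIP vector with attribute `important` (names of
#'   entries > 1).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  w2 <- model$W^2   # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- rownames(model$W)
  attr(vip, "important") <- names(vip)[vip > 1]
  vip
}

#' Orthogonally rotate a PLS model for maximal axis-1 structure
#'
#' Finds an orthogonal `A x A` rotation of the score space that maximizes,
#' on rotated axis 1, the between-class variance fraction of the scores
#' (`criterion = "class_separation"`) or the squared covariance with the
#' standardized responses (`criterion = "y_covariance"`). Scores, loadings
#' and weights rotate together (`T -> TR`, `P -> PR`, `W -> WR`, `Q -> QR`),
#' so fitted predictions are unchanged. The first axis solves a generalized
#' Rayleigh-quotient problem in the A-dimensional score space; the remaining
#' axes complete an orthonormal basis.
#'
#' @param model a [fit_pls()] model with `A >= 2` (at `A = 1` the identity
#'   rotation is returned with a message).
#' @param criterion rotation criterion; default `"class_separation"` for
#'   discriminant models, `"y_covariance"` for regression models.
#' @param classes class labels for `"class_separation"`; defaults to the
#'   training classes of a discriminant model.
#' @param y standardized-response matrix for `"y_covariance"`; defaults to
#'   the fitted `T Q'` reconstruction target.
#' @return the rotated `pls_model` (field `R` holds the rotation).
#' @export
orthogonal_rotate <- function(model,
                              criterion = c("class_separation", "y_covariance"),
                              classes = NULL, y = NULL) {
  stopifnot(inherits(model, "pls_model"))
  criterion <- match.arg(criterion)
  A <- model$A
  if (A < 2) {
    message("A = 1: identity rotation")
    return(model)
  }
  TT <- model$T
  if (criterion == "class_separation") {
    if (is.null(classes)) classes <- model$classes
    if (is.null(classes))
      stop("class_separation needs class labels", call. = FALSE)
    cls <- droplevels(as.factor(classes))
    mu <- colMeans(TT)
    B <- matrix(0, A, A)
    for (k in levels(cls)) {
      nk <- sum(cls == k)
      mk <- colMeans(TT[cls == k, , drop = FALSE]) - mu
      B <- B + nk * tcrossprod(mk)
    }
    Tot <- crossprod(sweep(TT, 2, mu))   # total scatter
    M <- solve(Tot, B)
  } else {
    if (is.null(y)) y <- TT %*% t(model$Q)
    C <- crossprod(TT, as.matrix(y))
    M <- tcrossprod(C)
  }
  e <- eigen(M)
  a1 <- Re(e$vectors[, 1])
  a1 <- a1 / sqrt(sum(a1^2))
  # complete an orthonormal basis with a1 as the first axis
  R <- qr.Q(qr(cbind(a1, diag(A)[, -1, drop = FALSE])))
  if (sum(R[, 1] * a1) < 0) R[, 1] <- -R[, 1]
  model$T <- TT %*% R
  model$P <- model$P %*% R
  model$W <- model$W %*% R
  model$Q <- model$Q %*% R
  model$R <- model$R %*% R
  model$x_variance <- vapply(seq_len(A), function(a)
    sum(model$T[, a]^2) * sum(model$P[, a]^2) / model$tot_x, numeric(1))
  model$y_variance <- vapply(seq_len(A), function(a)
    sum(model$T[, a]^2) * sum(model$Q[, a]^2), numeric(1)) / model$tot_y
  model
}

#' Permutation significance of a PLS model
#'
#' The fitted model's per-held-out-sample cross-validation errors are
#' compared against the pooled per-sample errors of `n_perm` models refit on
#' row-permuted Y (re-selecting A per permutation unless `freeze_A`), with a
#' one-sided Mann-Whitney U test (true errors smaller than permuted).
#'
#' @param X predictors; `Y` responses or class factor.
#' @param Y response.
#' @param A_grid candidate LV grid.
#' @param mode `"regression"` or `"discriminant"`.
#' @param n_perm permutations (>= 20; refuse below, the rank test is
#'   underpowered).
#' @param n_folds CV folds (default 3).
#' @param seed seed.
#' @param freeze_A if TRUE, reuse the true model's A* in every permutation.
#' @return list `p_value`, `A_star`, `cv_error`, `true_errors`,
#'   `perm_errors`.
#' @export
permutation_significance <- function(X, Y, A_grid = NULL, mode = NULL,
                                     n_perm = 100, n_folds = 3, seed = 1,
                                     freeze_A = FALSE) {
  if (n_perm < 20) stop_field("n_perm", "must be >= 20")
  X <- as.matrix(X)
  if (is.null(mode))
    mode <- if (is.factor(Y) || is.character(Y)) "discriminant" else "regression"
  if (is.null(A_grid))
    A_grid <- seq_len(max(1, min(nrow(X) - 2, ncol(X), 6)))
  err <- .cv_sample_errors(X, Y, A_grid, mode, n_folds, seed)
  agg <- if (mode == "discriminant") colMeans(err) else sqrt(colMeans(err))
  sel <- which.min(agg)
  true_err <- err[, sel]
  perm_err <- numeric(0)
  set.seed(derive_seed(seed, "pls-perm"))
  for (b in seq_len(n_perm)) {
    idx <- sample(nrow(X))
    Yp <- if (is.factor(Y) || is.character(Y)) Y[idx]
          else as.matrix(Y)[idx, , drop = FALSE]
    errp <- .cv_sample_errors(X, Yp,
                              if (freeze_A) A_grid[sel] else A_grid,
                              mode, n_folds, seed + b)
    aggp <- if (mode == "discriminant") colMeans(errp) else sqrt(colMeans(errp))
    perm_err <- c(perm_err, errp[, which.min(aggp)])
  }
  p <- stats::wilcox.test(true_err, perm_err, alternative = "less",
                          exact = FALSE)$p.value
  list(p_value = p, A_star = A_grid[sel],
       cv_error = stats::setNames(agg, A_grid),
       true_errors = true_err, perm_errors = perm_err)
}

#' 95% confidence ellipse of a two-dimensional score cloud
#'
#' Ellipse of the bivariate normal fitted to the scores: the score
#' covariance scaled by the chi-square(2) quantile at the stated level.
#'
#' @param scores samples x 2 matrix.
#' @param level coverage level (default 0.95).
#' @return list `center`, `axes` (semi-axis lengths), `angle` (radians of the
#'   major axis), `cov`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns", call. = FALSE)
  if (nrow(scores) < 3) stop("need at least 3 samples", call. = FALSE)
  S <- stats::cov(scores)
  if (abs(det(S)) < 1e-300) stop("singular score covariance", call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  list(center = colMeans(scores),
       axes = sqrt(pmax(e$values, 0) * r2),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S)
}
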