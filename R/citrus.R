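# Cluster identification, characterization and regression: pooled Ward
# clustering on lineage channels, per-sample cluster-median functional
# features, and two association models (cross-validated nearest shrunken
# centroids; permutation-FDR moderated-statistic selection).

#' Pool samples and build the hierarchical cluster tree
#'
#' Events from all samples are pooled and clustered agglomeratively (Ward
#' linkage on Euclidean distance over the lineage channels). Qualifying nodes
#' are those whose member count is at least `min_cluster_frac` of the pooled
#' total; since a parent contains its children's members, the qualifying set
#' is closed under taking ancestors. `stats::hclust` needs the full distance
#' matrix, so when the pool exceeds `max_pooled_events` a seeded uniform
#' subsample of the pooled events is clustered instead (sample provenance is
#' kept either way).
#'
#' @param samples list of [event_matrix()] sharing channels and transform
#'   state (transformed, downsampled).
#' @param lineage_channels channels to cluster on; default the channels with
#'   role `lineage` in the first sample.
#' @param min_cluster_frac minimum node size fraction in (0, 1] (default
#'   0.05).
#' @param max_pooled_events cap on the pooled matrix actually clustered.
#' @param seed seed for the pooled-level subsample.
#' @return object of class `cluster_tree`: `hclust` fit, per-node member
#'   index lists, node size fractions, qualifying node ids, the pooled value
#'   matrix, per-event `sample_id`, and per-event hidden truth labels when
#'   the inputs carry them.
#' @export
pool_and_cluster <- function(samples, lineage_channels = NULL,
                             min_cluster_frac = 0.05,
                             max_pooled_events = 10000, seed = 1) {
  if (min_cluster_frac <= 0 || min_cluster_frac > 1)
    stop_field("min_cluster_frac", "must be in (0, 1]")
  states <- unique(vapply(samples, function(m) m$transform_state, character(1)))
  if (length(states) != 1)
    stop("all samples must share a transform state", call. = FALSE)
  if (is.null(lineage_channels))
    lineage_channels <- channels_by_role(samples[[1]], "lineage")
  pooled <- do.call(rbind, lapply(samples, function(m) m$values))
  sample_id <- rep(vapply(samples, function(m) m$sample_id, character(1)),
                   vapply(samples, function(m) nrow(m$values), integer(1)))
  truth <- unlist(lapply(samples, function(m) {
    tr <- attr(m, "truth")
    if (is.null(tr)) rep(NA_character_, nrow(m$values))
    else as.character(tr$subset)
  }), use.names = FALSE)
  if (nrow(pooled) < 2) stop("need at least 2 pooled events", call. = FALSE)
  full <- NULL
  if (nrow(pooled) > max_pooled_events) {
    full <- list(values = pooled, sample_id = sample_id, truth = truth)
    keep <- local({
      set.seed(seed)
      sort(sample.int(nrow(pooled), max_pooled_events))
    })
    pooled <- pooled[keep, , drop = FALSE]
    sample_id <- sample_id[keep]
    truth <- truth[keep]
  }
  hc <- stats::hclust(stats::dist(pooled[, lineage_channels, drop = FALSE]),
                      method = "ward.D2")
  n <- nrow(pooled)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    members[[i]] <- c(if (left < 0) -left else members[[left]],
                      if (right < 0) -right else members[[right]])
  }
  size_frac <- vapply(members, length, integer(1)) / n
  qualifying <- which(size_frac >= min_cluster_frac)
  tree <- structure(list(hclust = hc, members = members, size_frac = size_frac,
                         qualifying = qualifying, values = pooled,
                         sample_id = sample_id, truth = truth,
                         lineage_channels = lineage_channels,
                         min_cluster_frac = min_cluster_frac,
                         assigned = NULL),
                    class = "cluster_tree")
  if (!is.null(full)) {
    # assign every pooled event (not only the clustered subsample) down the
    # qualifying subtree by nearest-child-centroid descent, so per-sample
    # medians downstream use all events
    tree <- .assign_all_events(tree, full)
  }
  tree
}

# Descend each event of `full` through the qualifying subtree; events join
# every qualifying node along their path. Child centroids come from the
# clustered subsample (singletons use the event itself).
.assign_all_events <- function(tree, full) {
  merge <- tree$hclust$merge
  lin <- tree$lineage_channels
  centroid <- function(child) {
    if (child < 0) tree$values[-child, lin, drop = FALSE]
    else matrix(colMeans(tree$values[tree$members[[child]], lin, drop = FALSE]),
                nrow = 1)
  }
  root <- length(tree$members)
  X <- full$values[, lin, drop = FALSE]
  n_full <- nrow(X)
  node_of <- matrix(FALSE, n_full, length(tree$qualifying),
                    dimnames = list(NULL, tree$qualifying))
  recurse <- function(nd, idx) {
    if (length(idx) == 0) return()
    node_of[idx, as.character(nd)] <<- TRUE
    kids <- merge[nd, ]
    c1 <- centroid(kids[1]); c2 <- centroid(kids[2])
    d1 <- rowSums(sweep(X[idx, , drop = FALSE], 2, as.numeric(c1))^2)
    d2 <- rowSums(sweep(X[idx, , drop = FALSE], 2, as.numeric(c2))^2)
    go1 <- d1 <= d2
    if (kids[1] > 0 && kids[1] %in% tree$qualifying)
      recurse(kids[1], idx[go1])
    if (kids[2] > 0 && kids[2] %in% tree$qualifying)
      recurse(kids[2], idx[!go1])
  }
  recurse(root, seq_len(n_full))
  tree$assigned <- lapply(tree$qualifying, function(nd)
    which(node_of[, as.character(nd)]))
  names(tree$assigned) <- tree$qualifying
  tree$values <- full$values
  tree$sample_id <- full$sample_id
  tree$truth <- full$truth
  tree
}

# events of a qualifying node: full-pool assignment when available, else the
# clustered subsample membership
.node_events <- function(tree, nd) {
  if (!is.null(tree$assigned)) tree$assigned[[as.character(nd)]]
  else tree$members[[nd]]
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d pooled events, %d samples, %d qualifying nodes (>= %.1f%%)\n",
              nrow(x$values), length(unique(x$sample_id)),
              length(x$qualifying), 100 * x$min_cluster_frac))
  invisible(x)
}

#' Dominant hidden-truth label of each qualifying node
#'
#' Available only for trees built from synthetic samples that carry
#' ground-truth subset labels; used to audit feature selection.
#'
#' @param tree a [pool_and_cluster()] result.
#' @return data.frame: node id, dominant label, purity.
#' @export
node_truth_composition <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  rows <- lapply(tree$qualifying, function(nd) {
    lab <- tree$truth[.node_events(tree, nd)]
    tab <- sort(table(lab), decreasing = TRUE)
    data.frame(node = nd,
               dominant = if (length(tab)) names(tab)[1] else NA_character_,
               purity = if (length(tab)) as.numeric(tab[1]) / sum(tab) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample cluster-median functional features
#'
#' Entry (sample, node, channel) is the median intensity of the functional
#' channel over the node's members that came from that sample. Sample-empty
#' cells are imputed with the node's pooled median and flagged in the mask so
#' the association models need no missing-data machinery.
#'
#' @param tree a [pool_and_cluster()] result.
#' @param functional_channels channels to summarize (default the IR set
#'   TIGIT, TIM-3, PD-1, CD160, LAG-3 when present).
#' @return object of class `cluster_features`: `features` matrix samples x
#'   (qualifying node x channel), columns named `node<id>_<channel>`;
#'   `imputed` logical mask of the same shape.
#' @export
cluster_features <- function(tree, functional_channels = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (is.null(functional_channels)) {
    default_irs <- c("TIGIT", "TIM-3", "PD-1", "CD160", "LAG-3")
    functional_channels <- intersect(default_irs, colnames(tree$values))
  }
  samples <- unique(tree$sample_id)
  cols <- as.vector(outer(tree$qualifying, functional_channels,
                          function(nd, ch) paste0("node", nd, "_", ch)))
  feat <- matrix(NA_real_, length(samples), length(cols),
                 dimnames = list(samples, cols))
  mask <- matrix(FALSE, length(samples), length(cols),
                 dimnames = list(samples, cols))
  for (qi in seq_along(tree$qualifying)) {
    nd <- tree$qualifying[qi]
    mem <- .node_events(tree, nd)
    vals <- tree$values[mem, functional_channels, drop = FALSE]
    sid <- tree$sample_id[mem]
    pooled_med <- apply(vals, 2, stats::median)
    for (ci in seq_along(functional_channels)) {
      col <- paste0("node", nd, "_", functional_channels[ci])
      med_by_sample <- tapply(vals[, ci], factor(sid, levels = samples),
                              stats::median)
      empty <- is.na(med_by_sample)
      med_by_sample[empty] <- pooled_med[ci]
      feat[, col] <- med_by_sample
      mask[empty, col] <- TRUE
    }
  }
  structure(list(features = feat, imputed = mask,
                 functional_channels = functional_channels,
                 qualifying = tree$qualifying),
            class = "cluster_features")
}

# ---- nearest shrunken centroid (PAMR) ----------------------------------

# Train on X (samples x features), y factor. Returns centroid statistics.
.nsc_train <- function(X, y) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  n <- nrow(X); K <- length(classes)
  nk <- table(y)
  xbar <- colMeans(X)
  cent <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                   numeric(ncol(X))))   # K x p
  ss <- matrix(0, 1, ncol(X))
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    ss <- ss + colSums((Xi - matrix(cent[k, ], nrow(Xi), ncol(X), byrow = TRUE))^2)
  }
  s <- sqrt(as.numeric(ss) / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)   # class standardizer
  d <- sweep(sweep(cent, 2, xbar, "-"), 2, s + s0, "/") / mk   # K x p
  list(classes = classes, nk = as.numeric(nk), prior = as.numeric(nk) / n,
       xbar = xbar, s = s, s0 = s0, mk = mk, d = d)
}

.soft <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

# Predict classes for X given trained stats and shrinkage delta
.nsc_predict <- function(tr, X, delta) {
  dshr <- .soft(tr$d, delta)                                # K x p
  cent_shr <- sweep(dshr * tr$mk, 2, tr$s + tr$s0, "*")     # K x p offsets
  cent_shr <- sweep(cent_shr, 2, tr$xbar, "+")
  denom <- (tr$s + tr$s0)^2
  scores <- vapply(seq_along(tr$classes), function(k) {
    rowSums(sweep(X, 2, cent_shr[k, ], "-")^2 / matrix(denom, nrow(X),
                                                       ncol(X), byrow = TRUE)) -
      2 * log(tr$prior[k])
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X))
  tr$classes[max.col(-scores, ties.method = "first")]
}

.stratified_folds <- function(y, n_folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated nearest shrunken centroid association model
#'
#' For each shrinkage value delta, per-feature per-class statistics
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` are soft-thresholded and
#' classification uses the shrunken-centroid discriminant with class priors
#' proportional to class sizes. Stratified n-fold cross-validation yields an
#' error curve; the selected delta is the **largest** delta attaining the
#' minimum CV error (the model with the fewest surviving features), and the
#' selected features are those with any nonzero shrunken statistic at that
#' delta in the full-data fit.
#'
#' @param features a [cluster_features()] object or a plain samples x
#'   features matrix.
#' @param labels per-sample class labels (two or more classes, >= 2 samples
#'   per class).
#' @param n_folds folds (default 10).
#' @param delta_grid shrinkage grid; default 30 values from 0 to the largest
#'   absolute unshrunken statistic.
#' @param seed fold-assignment seed.
#' @return object of class `assoc_result` (`model = "pamr"`): grid, CV error
#'   and SE per delta, selected delta, selected features, CV accuracy, the
#'   full-data centroid statistics.
#' @export
pamr_fit_cv <- function(features, labels, n_folds = 10, delta_grid = NULL,
                        seed = 1) {
  X <- if (inherits(features, "cluster_features")) features$features else features
  y <- droplevels(as.factor(labels))
  if (nrow(X) != length(y)) stop("labels must match sample rows", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 samples per class", call. = FALSE)
  tr_full <- .nsc_train(X, y)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(tr_full$d)), length.out = 30)
  n_folds <- min(n_folds, min(table(y)))
  # stratified folds; re-draw with a new sub-seed if a fold loses a class
  fold <- .stratified_folds(y, n_folds, seed)
  for (redraw in 1:10) {
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold != f])) == nlevels(y), logical(1)))
    if (ok) break
    fold <- .stratified_folds(y, n_folds, seed + 1000 * redraw)
  }
  err_mat <- matrix(NA_real_, n_folds, length(delta_grid))
  for (f in seq_len(n_folds)) {
    tr <- .nsc_train(X[fold != f, , drop = FALSE], y[fold != f])
    for (g in seq_along(delta_grid)) {
      pred <- .nsc_predict(tr, X[fold == f, , drop = FALSE], delta_grid[g])
      err_mat[f, g] <- mean(pred != as.character(y[fold == f]))
    }
  }
  fold_sizes <- as.numeric(table(factor(fold, levels = seq_len(n_folds))))
  cv_error <- colSums(err_mat * fold_sizes) / sum(fold_sizes)
  cv_se <- apply(err_mat, 2, stats::sd) / sqrt(n_folds)
  best <- min(cv_error)
  sel_idx <- max(which(cv_error <= best + 1e-12))  # largest delta at min error
  delta_star <- delta_grid[sel_idx]
  nonzero <- colSums(abs(.soft(tr_full$d, delta_star)) > 0) > 0
  structure(list(model = "pamr", delta_grid = delta_grid, cv_error = cv_error,
                 cv_se = cv_se, selected_delta = delta_star,
                 selected_features = colnames(X)[nonzero],
                 cv_accuracy = 1 - cv_error[sel_idx],
                 train = tr_full, n_folds = n_folds, seed = seed,
                 feature_names = colnames(X)),
            class = "assoc_result")
}

#' Predict classes with a fitted nearest-shrunken-centroid model
#'
#' @param object an `assoc_result` with `model = "pamr"`.
#' @param newdata samples x features matrix with the training columns.
#' @param delta shrinkage (default the selected delta).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.assoc_result <- function(object, newdata, delta = object$selected_delta,
                                 ...) {
  stopifnot(object$model == "pamr")
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  .nsc_predict(object$train, X, delta)
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$model == "pamr") {
    cat(sprintf("Nearest shrunken centroid fit: %d features, %d-fold CV\n",
                length(x$feature_names), x$n_folds))
    cat(sprintf("  selected delta = %.3f, CV accuracy = %.3f, %d features retained\n",
                x$selected_delta, x$cv_accuracy, length(x$selected_features)))
  } else {
    cat(sprintf("Moderated-statistic selection: %d features, %d permutations\n",
                length(x$d), x$n_perm))
    cat(sprintf("  %d significant at FDR <= %g\n",
                length(x$significant), x$fdr_target))
  }
  invisible(x)
}

# ---- SAM-style moderated-statistic selection ---------------------------

#' Permutation-FDR selection with a moderated difference statistic
#'
#' Per-feature `d_i = (xbar_{i,1} - xbar_{i,0}) / (s_i + s0)` with `s0` the
#' median of the pooled within-class standard deviations. The null
#' distribution comes from label permutations; for each candidate cutoff the
#' estimated FDR is the permuted exceedance count (averaged over
#' permutations) divided by the observed exceedance count, and the
#' significant set is the largest cutoff-defined set whose estimated FDR is
#' at or below the target (these sets are nested across FDR levels). The
#' mean exceedance is the default estimator because the median's integer
#' granularity returns an estimated FDR of exactly zero at stringent
#' cutoffs, letting isolated null features into the set; the median variant
#' remains available.
#'
#' @param features a [cluster_features()] object or samples x features
#'   matrix.
#' @param labels binary per-sample labels.
#' @param fdr_target target FDR (default 0.01, the 1% constraint).
#' @param n_perm label permutations (>= 100).
#' @param seed permutation seed.
#' @param estimator `"mean"` (default) or `"median"` permuted exceedance.
#' @return object of class `assoc_result` (`model = "sam"`): statistics `d`,
#'   per-cutoff FDR table, significant feature set.
#' @export
sam_select <- function(features, labels, fdr_target = 0.01, n_perm = 200,
                       seed = 1, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  X <- if (inherits(features, "cluster_features")) features$features else features
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (n_perm < 100) stop_field("n_perm", "must be >= 100")
  dstat <- function(yy) {
    g1 <- X[yy == levels(y)[2], , drop = FALSE]
    g0 <- X[yy == levels(y)[1], , drop = FALSE]
    n1 <- nrow(g1); n0 <- nrow(g0)
    sp <- sqrt((colSums(sweep(g1, 2, colMeans(g1))^2) +
                  colSums(sweep(g0, 2, colMeans(g0))^2)) / (n1 + n0 - 2))
    s0 <- stats::median(sp)
    (colMeans(g1) - colMeans(g0)) / (sp + s0)
  }
  d_obs <- dstat(y)
  set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(b) abs(dstat(sample(y))),
                   numeric(ncol(X)))
  cuts <- sort(unique(abs(d_obs)))
  fdr <- vapply(cuts, function(cc) {
    obs <- sum(abs(d_obs) >= cc)
    exceed <- colSums(d_perm >= cc)
    null_count <- if (estimator == "mean") mean(exceed)
                  else stats::median(exceed)
    min(null_count / max(obs, 1), 1)
  }, numeric(1))
  ok <- which(fdr <= fdr_target)
  significant <- if (length(ok)) {
    names(d_obs)[abs(d_obs) >= cuts[min(ok)]]
  } else character(0)
  structure(list(model = "sam", d = d_obs, cutoffs = cuts, fdr = fdr,
                 fdr_target = fdr_target, significant = significant,
                 n_perm = n_perm, seed = seed,
                 feature_names = colnames(X)),
            class = "assoc_result")
}
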