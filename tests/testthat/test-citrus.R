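channel_names <- names(synthetic_channel_roles())

# two synthetic samples whose lineage space is two well-separated blobs
make_blob_samples <- function(n_per_sample = 300, sep = 6, seed = 1) {
  set.seed(seed)
  lapply(1:4, function(s) {
    n1 <- n_per_sample / 2
    blob <- rep(c("A", "B"), each = n1)
    vals <- matrix(rnorm(n_per_sample * 13, 0, 1), ncol = 13,
                   dimnames = list(NULL, channel_names))
    vals[blob == "B", 1:7] <- vals[blob == "B", 1:7] + sep
    m <- event_matrix(vals, sprintf("B%d", s), synthetic_channel_roles(),
                      transform_state = "arcsinh")
    attr(m, "truth") <- list(subset = factor(blob))
    m
  })
}

test_that("well-separated blobs are recovered as the qualifying nodes", {
  samples <- make_blob_samples()
  tree <- pool_and_cluster(samples, min_cluster_frac = 0.3)
  root <- length(tree$members)
  expect_true(root %in% tree$qualifying)
  expect_equal(tree$size_frac[root], 1)
  # the root's two children are the two blobs, each about half the pool and
  # >99% pure against the generating assignment (the nearest-center oracle)
  kids <- tree$hclust$merge[root, ]
  expect_true(all(kids > 0))
  expect_true(all(kids %in% tree$qualifying))
  comp <- node_truth_composition(tree)
  expect_true(all(comp$purity[comp$node %in% kids] > 0.99))
  expect_setequal(comp$dominant[comp$node %in% kids], c("A", "B"))
  expect_equal(unname(tree$size_frac[kids]), c(0.5, 0.5), tolerance = 0.05)
  # every other qualifying node (besides the mixed root) is a within-blob
  # fragment, still blob-pure
  expect_true(all(comp$purity[comp$node != root] > 0.99))
})

test_that("the dendrogram is a nested partition closed under ancestors", {
  samples <- make_blob_samples(n_per_sample = 100, seed = 2)
  tree <- pool_and_cluster(samples, min_cluster_frac = 0.05)
  merge <- tree$hclust$merge
  n_nodes <- length(tree$members)
  for (i in seq_len(n_nodes)) {
    for (child in merge[i, ]) {
      if (child > 0)
        expect_true(all(tree$members[[child]] %in% tree$members[[i]]))
    }
  }
  # qualifying set closed under taking ancestors
  parent_of <- integer(n_nodes)
  for (i in seq_len(n_nodes)) for (child in merge[i, ])
    if (child > 0) parent_of[child] <- i
  for (q in setdiff(tree$qualifying, n_nodes))
    expect_true(parent_of[q] %in% tree$qualifying)
  expect_error(pool_and_cluster(samples, min_cluster_frac = 0), "min_cluster_frac")
})

test_that("clustering is invariant to sample file ordering", {
  samples <- make_blob_samples(n_per_sample = 80, seed = 3)
  key <- function(tree) {
    # identify events by (sample, within-sample index), independent of pooling
    ord <- order(tree$sample_id)
    within <- ave(seq_along(tree$sample_id), tree$sample_id, FUN = seq_along)
    sets <- lapply(tree$members[tree$qualifying], function(mem)
      sort(paste(tree$sample_id[mem], within[mem])))
    sort(vapply(sets, paste, character(1), collapse = "|"))
  }
  t1 <- pool_and_cluster(samples, min_cluster_frac = 0.1)
  t2 <- pool_and_cluster(rev(samples), min_cluster_frac = 0.1)
  expect_identical(key(t1), key(t2))
})

test_that("cluster features are per-sample medians with masked imputation", {
  samples <- make_blob_samples(n_per_sample = 60, seed = 4)
  single <- samples[1]
  tree1 <- pool_and_cluster(single, min_cluster_frac = 0.3)
  f1 <- cluster_features(tree1)
  # single sample: features equal pooled node medians, nothing imputed
  expect_false(any(f1$imputed))
  for (nd in tree1$qualifying) {
    col <- paste0("node", nd, "_TIGIT")
    expect_equal(unname(f1$features[1, col]),
                 median(tree1$values[tree1$members[[nd]], "TIGIT"]))
  }
  # hand-built check: three events from one sample, median of {1,2,3} is 2
  vals <- matrix(0.5, 6, 13, dimnames = list(NULL, channel_names))
  vals[, "TIGIT"] <- c(1, 2, 3, 1, 2, 3)
  m <- event_matrix(vals, "only", synthetic_channel_roles(),
                    transform_state = "arcsinh")
  tr <- pool_and_cluster(list(m), min_cluster_frac = 1)
  fx <- cluster_features(tr)
  expect_equal(unname(fx$features[1, paste0("node", tr$qualifying[1], "_TIGIT")]), 2)
})

test_that("nearest shrunken centroids select the planted feature", {
  set.seed(16)
  n <- 40
  X <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", 7] <- X[y == "b", 7] + 4   # 4 pooled-SD gap on one feature
  fit <- pamr_fit_cv(X, y, n_folds = 5, seed = 3)
  expect_equal(fit$cv_error[match(fit$selected_delta, fit$delta_grid)], 0)
  expect_identical(fit$selected_features, "f7")
  expect_gte(fit$cv_accuracy, 0.999)
  # delta = 0 keeps every feature
  fit0 <- pamr_fit_cv(X, y, n_folds = 5, delta_grid = 0, seed = 3)
  expect_length(fit0$selected_features, 15)
  # delta beyond max |d|: all centroids collapse, prediction = majority class
  y2 <- factor(rep(c("a", "b"), times = c(25, 15)))
  fit_big <- pamr_fit_cv(X, y2, n_folds = 5,
                         delta_grid = c(0, 1e6), seed = 3)
  expect_equal(unname(fit_big$cv_error[2]), 15 / 40)
})

test_that("PAMR at delta = 0 equals an unshrunk nearest-centroid oracle", {
  set.seed(17)
  n <- 30
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", 2] <- X[y == "b", 2] + 1.5
  fit <- pamr_fit_cv(X, y, n_folds = 5, delta_grid = 0, seed = 5)
  pred <- predict(fit, X, delta = 0)
  # independent oracle: standardized distance to each class centroid with the
  # same pooled-SD metric and log-prior term, written from the definition
  cent_a <- colMeans(X[y == "a", ]); cent_b <- colMeans(X[y == "b", ])
  ss <- colSums(sweep(X[y == "a", ], 2, cent_a)^2) +
    colSums(sweep(X[y == "b", ], 2, cent_b)^2)
  s <- sqrt(ss / (n - 2)); s0 <- median(s)
  delta_k <- function(x, cent, prior)
    sum((x - cent)^2 / (s + s0)^2) - 2 * log(prior)
  oracle <- apply(X, 1, function(x)
    if (delta_k(x, cent_a, 0.5) <= delta_k(x, cent_b, 0.5)) "a" else "b")
  expect_identical(pred, unname(oracle))
})

test_that("CV error is invariant to feature column permutation", {
  set.seed(18)
  X <- matrix(rnorm(40 * 10), 40, dimnames = list(NULL, paste0("f", 1:10)))
  y <- factor(rep(c("a", "b"), each = 20))
  X[y == "b", 4] <- X[y == "b", 4] + 2
  f1 <- pamr_fit_cv(X, y, n_folds = 5, seed = 9)
  f2 <- pamr_fit_cv(X[, 10:1], y, n_folds = 5, seed = 9)
  expect_equal(f1$cv_error, f2$cv_error, tolerance = 1e-12)
})

test_that("moderated-statistic selection controls the null and finds effects", {
  set.seed(19)
  n <- 40; p <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  # global null: mean significant-set size stays near zero at 1% FDR
  sizes <- replicate(50, {
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    length(sam_select(X, y, fdr_target = 0.01, n_perm = 100,
                      seed = sample.int(1e6, 1))$significant)
  })
  expect_lte(mean(sizes), 0.6)

  # planted 3-feature effect at 2.5 SD among 60: recovered with <= 1 extra
  hits <- replicate(50, {
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    X[y == "b", 1:3] <- X[y == "b", 1:3] + 2.5
    sig <- sam_select(X, y, fdr_target = 0.01, n_perm = 100,
                      seed = sample.int(1e6, 1))$significant
    all(c("f1", "f2", "f3") %in% sig) && length(setdiff(sig, c("f1", "f2", "f3"))) <= 1
  })
  expect_gte(mean(hits), 0.9)

  # significant sets nest across FDR targets
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  X[y == "b", 1:5] <- X[y == "b", 1:5] + 1.5
  s1 <- sam_select(X, y, fdr_target = 0.01, n_perm = 100, seed = 1)$significant
  s5 <- sam_select(X, y, fdr_target = 0.05, n_perm = 100, seed = 1)$significant
  expect_true(all(s1 %in% s5))
  expect_error(sam_select(X, y, n_perm = 50), "n_perm")
  expect_error(sam_select(X, factor(rep("a", n)), n_perm = 100), "two classes")
})
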