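# End-to-end orchestration: a validated run configuration, stage
# subcommands with stable on-disk artifact names, and a machine-readable
# run report. One global seed derives per-stage sub-seeds so stages re-run
# independently yet reproducibly.

.TOP_KEYS <- c("out_dir", "seed", "cofactor", "gate_quantile", "downsample_n",
               "ir_combo_set", "plsda_combo_set", "citrus", "betaperm", "pls",
               "synthetic", "log_level")
.CITRUS_KEYS <- c("min_cluster_frac", "n_folds", "max_pooled_events",
                  "fdr_target", "sam_n_perm", "delta_grid_len")
.BETAPERM_KEYS <- c("n_perm")
.PLS_KEYS <- c("n_perm", "a_grid_max", "n_folds", "rotation_criterion")

#' Build and validate a pipeline run configuration
#'
#' Defaults give a small, fully synthetic run. Unknown keys anywhere in the
#' configuration are rejected before any stage runs.
#'
#' @param config named list (e.g. from [read_run_config()]) overriding the
#'   defaults.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    out_dir = file.path(tempdir(), "irsigflow_run"),
    seed = 1,
    cofactor = 150,
    gate_quantile = 0.995,
    downsample_n = 1000,
    ir_combo_set = c("PD-1", "TIGIT", "CD160"),
    plsda_combo_set = c("PD-1", "TIGIT", "CD160", "TIM-3"),
    citrus = list(min_cluster_frac = 0.05, n_folds = 5,
                  max_pooled_events = 4000, fdr_target = 0.01,
                  sam_n_perm = 100, delta_grid_len = 30),
    betaperm = list(n_perm = 100),
    pls = list(n_perm = 30, a_grid_max = 4, n_folds = 3,
               rotation_criterion = "class_separation"),
    synthetic = list(events_per_subject = 600,
                     group_sizes = c(uninfected_young = 10, uninfected_old = 10,
                                     hiv_young = 10, hiv_old = 10),
                     n_batches = 4),
    log_level = "info")
  unknown <- setdiff(names(config), .TOP_KEYS)
  if (length(unknown))
    stop(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (blk in c("citrus", "betaperm", "pls")) {
    keys <- get(paste0(".", toupper(blk), "_KEYS"))
    unknown <- setdiff(names(config[[blk]]), keys)
    if (length(unknown))
      stop(paste0("unknown config key(s) in ", blk, ": ",
                  paste(unknown, collapse = ", ")), call. = FALSE)
    defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    config[[blk]] <- NULL
  }
  if (!is.null(config$synthetic)) {
    syn_ok <- names(formals(synthetic_config))
    unknown <- setdiff(names(config$synthetic), syn_ok)
    if (length(unknown))
      stop(paste("unknown config key(s) in synthetic:",
                 paste(unknown, collapse = ", ")), call. = FALSE)
    defaults$synthetic[names(config$synthetic)] <- config$synthetic
    config$synthetic <- NULL
  }
  defaults[names(config)] <- config
  cfg <- defaults
  if (cfg$gate_quantile <= 0 || cfg$gate_quantile >= 1)
    stop_field("gate_quantile", "must be in (0, 1)")
  if (cfg$downsample_n < 1) stop_field("downsample_n", "must be positive")
  if (cfg$citrus$min_cluster_frac <= 0 || cfg$citrus$min_cluster_frac > 1)
    stop_field("citrus$min_cluster_frac", "must be in (0, 1]")
  if (cfg$betaperm$n_perm < 20) stop_field("betaperm$n_perm", "must be >= 20")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

.config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 0xFFFFFFFB
  sprintf("%08x", as.integer(h %% 2147483647))
}

.log <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message(sprintf("[%s] %s", level, sprintf(...)))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.need_artifact <- function(cfg, name, stage) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run stage '%s' first", name, stage),
         call. = FALSE)
  p
}

.update_run_report <- function(cfg, stage, summary) {
  path <- .artifact(cfg, "run_report.json")
  rep <- if (file.exists(path)) jsonlite::read_json(path) else
    list(package_version = as.character(utils::packageVersion("irsigflow")),
         config_hash = .config_hash(cfg), seed = cfg$seed, stages = list())
  rep$stages[[stage]] <- summary
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.read_design <- function(cfg) {
  d <- utils::read.table(.need_artifact(cfg, "design.tsv", "simulate"),
                         sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = .GROUPS)
  d
}

.read_cohort_events <- function(cfg, design) {
  roles <- .default_roles()
  events <- lapply(design$subject_id, function(sid)
    read_events(.artifact(cfg, file.path("events", paste0(sid, ".csv"))),
                "csv", roles, sample_id = sid, transform_state = "arcsinh",
                cofactor = cfg$cofactor))
  names(events) <- design$subject_id
  batches <- sort(unique(design$batch))
  fm5 <- lapply(batches, function(b) {
    m <- read_events(.artifact(cfg, file.path("fm5", sprintf("fm5_batch%02d.csv", b))),
                     "csv", roles, transform_state = "arcsinh",
                     cofactor = cfg$cofactor)
    attr(m, "batch") <- b
    m
  })
  list(events = events, fm5 = fm5)
}

.read_panel <- function(path, cells_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cells <- NULL
  if (!is.null(cells_path) && file.exists(cells_path)) {
    cd <- utils::read.table(cells_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cells <- stats::setNames(cd$cells_per_well, cd$subject_id)
  }
  analyte_panel(m, cells_per_well = cells)
}

.stage_simulate <- function(cfg) {
  syn <- do.call(synthetic_config,
                 c(cfg$synthetic[setdiff(names(cfg$synthetic), "seed")],
                   list(seed = derive_seed(cfg$seed, "simulate"))))
  cohort <- generate_cohort(syn)
  dir.create(.artifact(cfg, "events"), showWarnings = FALSE, recursive = TRUE)
  dir.create(.artifact(cfg, "fm5"), showWarnings = FALSE)
  .write_tsv(cohort$design, .artifact(cfg, "design.tsv"))
  for (sid in names(cohort$events))
    write_events(cohort$events[[sid]],
                 .artifact(cfg, file.path("events", paste0(sid, ".csv"))), "csv")
  for (b in seq_along(cohort$fm5))
    write_events(cohort$fm5[[b]],
                 .artifact(cfg, file.path("fm5", sprintf("fm5_batch%02d.csv", b))),
                 "csv")
  .write_tsv(cbind(subject_id = rownames(cohort$plasma$concentrations),
                   as.data.frame(cohort$plasma$concentrations,
                                 check.names = FALSE)),
             .artifact(cfg, "plasma.tsv"))
  tf <- stats::setNames(cohort$truth$frac_TIGIT, cohort$truth$subject_id)
  sup <- generate_supernatant(cohort$design, tf, syn,
                              seed = derive_seed(cfg$seed, "supernatant"))
  .write_tsv(cbind(subject_id = rownames(sup$concentrations),
                   as.data.frame(sup$concentrations, check.names = FALSE)),
             .artifact(cfg, "supernatant.tsv"))
  .write_tsv(data.frame(subject_id = names(sup$cells_per_well),
                        cells_per_well = sup$cells_per_well),
             .artifact(cfg, "cells_per_well.tsv"))
  .write_tsv(cohort$truth, .artifact(cfg, "truth.tsv"))
  list(subjects = nrow(cohort$design), batches = length(cohort$fm5),
       events_per_subject = syn$events_per_subject)
}

.stage_gate <- function(cfg) {
  design <- .read_design(cfg)
  dat <- .read_cohort_events(cfg, design)
  gates <- do.call(rbind, lapply(dat$fm5, derive_gates,
                                 quantile = cfg$gate_quantile))
  .write_tsv(gates, .artifact(cfg, "gates.tsv"))
  list(n_gates = nrow(gates), quantile = cfg$gate_quantile)
}

.stage_signatures <- function(cfg) {
  design <- .read_design(cfg)
  dat <- .read_cohort_events(cfg, design)
  sig <- signature_table(dat$events, dat$fm5, design,
                         ir_set = cfg$ir_combo_set,
                         quantile = cfg$gate_quantile)
  .write_tsv(sig, .artifact(cfg, "signatures.tsv"))
  sig4 <- signature_table(dat$events, dat$fm5, design,
                          ir_set = cfg$plsda_combo_set,
                          quantile = cfg$gate_quantile)
  .write_tsv(sig4, .artifact(cfg, "signatures_plsda.tsv"))
  list(subjects = nrow(sig), combo_columns = sum(grepl("^combo_", names(sig))))
}

.stage_citrus <- function(cfg) {
  design <- .read_design(cfg)
  dat <- .read_cohort_events(cfg, design)
  seed <- derive_seed(cfg$seed, "citrus")
  samples <- lapply(dat$events, downsample_events, n = cfg$downsample_n,
                    seed = seed)
  tree <- pool_and_cluster(samples,
                           min_cluster_frac = cfg$citrus$min_cluster_frac,
                           max_pooled_events = cfg$citrus$max_pooled_events,
                           seed = seed)
  feats <- cluster_features(tree)
  .write_tsv(cbind(sample_id = rownames(feats$features),
                   as.data.frame(feats$features, check.names = FALSE)),
             .artifact(cfg, "citrus_features.tsv"))
  labels <- factor(ifelse(design[match(rownames(feats$features),
                                       design$subject_id), "hiv"] == 1,
                          "hiv", "uninfected"))
  pam <- pamr_fit_cv(feats, labels, n_folds = cfg$citrus$n_folds, seed = seed)
  sam <- sam_select(feats, labels, fdr_target = cfg$citrus$fdr_target,
                    n_perm = cfg$citrus$sam_n_perm, seed = seed)
  jsonlite::write_json(
    list(pamr = list(delta_grid = pam$delta_grid, cv_error = pam$cv_error,
                     selected_delta = pam$selected_delta,
                     selected_features = pam$selected_features,
                     cv_accuracy = pam$cv_accuracy),
         sam = list(fdr_target = sam$fdr_target,
                    significant = sam$significant),
         seed = seed),
    .artifact(cfg, "citrus_assoc.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .write_tsv(data.frame(feature = names(sam$d), d = sam$d),
             .artifact(cfg, "citrus_sam_stats.tsv"))
  list(qualifying_nodes = length(tree$qualifying),
       pamr_cv_accuracy = pam$cv_accuracy,
       pamr_selected = length(pam$selected_features),
       sam_significant = length(sam$significant))
}

.stage_betaperm <- function(cfg) {
  sig <- utils::read.table(.need_artifact(cfg, "signatures.tsv", "signatures"),
                           sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  design <- .read_design(cfg)
  class(sig) <- c("signature_table", "data.frame")
  ab <- combo_abundances(sig)
  ok <- stats::complete.cases(ab)
  ab <- ab[ok, , drop = FALSE]
  des <- design[ok, , drop = FALSE]
  seed <- derive_seed(cfg$seed, "betaperm")
  fits <- fit_subset_regressions(ab, des)
  thr <- minp_threshold(ab, des, n_perm = cfg$betaperm$n_perm, seed = seed)
  sig_sets <- apply_thresholds(fits, thr)
  coef_tab <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    data.frame(subset = s, term = names(f$coefficients),
               estimate = unname(f$coefficients), se = unname(f$se),
               p = unname(f$p), phi = f$phi, stringsAsFactors = FALSE)
  }))
  .write_tsv(coef_tab, .artifact(cfg, "betaperm_coefficients.tsv"))
  jsonlite::write_json(
    list(thresholds = as.list(thr$thresholds), n_perm = thr$n_perm,
         seed = seed, significant = sig_sets,
         minp_hiv = thr$minp_distribution[, "hiv"],
         minp_age = thr$minp_distribution[, "age"]),
    .artifact(cfg, "betaperm.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(threshold_hiv = unname(thr$thresholds[["hiv"]]),
       threshold_age = unname(thr$thresholds[["age"]]),
       significant_hiv = length(sig_sets$hiv),
       significant_age = length(sig_sets$age))
}

.stage_pls <- function(cfg) {
  design <- .read_design(cfg)
  sig <- utils::read.table(.need_artifact(cfg, "signatures.tsv", "signatures"),
                           sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  plasma <- .read_panel(.need_artifact(cfg, "plasma.tsv", "simulate"))
  seed <- derive_seed(cfg$seed, "pls")
  out <- list(seed = seed)
  vip_rows <- list()
  for (stratum in c("uninfected", "hiv")) {
    ids <- design$subject_id[if (stratum == "hiv") design$hiv == 1 else design$hiv == 0]
    ids <- intersect(ids, sig$subject_id[!is.na(sig$pos_TIGIT)])
    X <- plasma$concentrations[ids, , drop = FALSE]
    y <- sig$pos_TIGIT[match(ids, sig$subject_id)]
    A_grid <- seq_len(min(cfg$pls$a_grid_max, nrow(X) - 2, ncol(X)))
    sel <- select_n_lv(X, y, A_grid, mode = "regression",
                       n_folds = cfg$pls$n_folds, seed = seed)
    model <- fit_pls(X, y, sel$A_star, mode = "regression")
    perm <- permutation_significance(X, y, A_grid, mode = "regression",
                                     n_perm = cfg$pls$n_perm,
                                     n_folds = cfg$pls$n_folds, seed = seed)
    vip <- vip_scores(model)
    vip_rows[[stratum]] <- data.frame(stratum = stratum, variable = names(vip),
                                      vip = as.numeric(vip),
                                      stringsAsFactors = FALSE)
    out[[stratum]] <- list(A_star = sel$A_star, cv_error = sel$cv_error,
                           permutation_p = perm$p_value,
                           vip_gt1 = names(vip)[vip > 1])
  }
  .write_tsv(do.call(rbind, vip_rows), .artifact(cfg, "pls_vip.tsv"))
  jsonlite::write_json(out, .artifact(cfg, "pls.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(p_uninfected = out$uninfected$permutation_p,
       p_hiv = out$hiv$permutation_p)
}

.stage_plsda <- function(cfg) {
  design <- .read_design(cfg)
  sig4 <- utils::read.table(.need_artifact(cfg, "signatures_plsda.tsv", "signatures"),
                            sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  class(sig4) <- c("signature_table", "data.frame")
  plasma <- .read_panel(.need_artifact(cfg, "plasma.tsv", "simulate"))
  ab <- combo_abundances(sig4)
  ok <- stats::complete.cases(ab)
  ids <- sig4$subject_id[ok]
  X <- cbind(ab[ok, , drop = FALSE], plasma$concentrations[ids, , drop = FALSE])
  groups <- design$group[match(ids, design$subject_id)]
  seed <- derive_seed(cfg$seed, "plsda")
  A_grid <- seq_len(min(cfg$pls$a_grid_max, nrow(X) - 2, ncol(X)))
  sel <- select_n_lv(X, groups, A_grid, mode = "discriminant",
                     n_folds = cfg$pls$n_folds, seed = seed)
  model <- fit_pls(X, groups, max(sel$A_star, 2), mode = "discriminant")
  rot <- orthogonal_rotate(model, cfg$pls$rotation_criterion)
  perm <- permutation_significance(X, groups, A_grid, mode = "discriminant",
                                   n_perm = cfg$pls$n_perm,
                                   n_folds = cfg$pls$n_folds, seed = seed)
  vip <- vip_scores(rot)
  .write_tsv(cbind(subject_id = ids, group = as.character(groups),
                   as.data.frame(rot$T[, 1:2, drop = FALSE])),
             .artifact(cfg, "plsda_scores.tsv"))
  jsonlite::write_json(
    list(A_star = sel$A_star, cv_error = sel$cv_error,
         permutation_p = perm$p_value, vip_gt1 = names(vip)[vip > 1],
         x_variance = rot$x_variance, y_variance = rot$y_variance,
         seed = seed),
    .artifact(cfg, "plsda.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(permutation_p = perm$p_value, A_star = sel$A_star)
}

.stage_report <- function(cfg) {
  path <- .artifact(cfg, "run_report.json")
  if (!file.exists(path))
    stop("no run_report.json: run the analysis stages first", call. = FALSE)
  rep <- jsonlite::read_json(path)
  gaps <- setdiff(c("simulate", "gate", "signatures", "citrus", "betaperm",
                    "pls", "plsda"), names(rep$stages))
  consolidated <- list(
    config_hash = rep$config_hash, seed = rep$seed,
    stages = rep$stages, gaps = gaps)
  for (f in c("citrus_assoc.json", "betaperm.json", "pls.json", "plsda.json")) {
    p <- .artifact(cfg, f)
    if (file.exists(p))
      consolidated[[sub("\\.json$", "", f)]] <- jsonlite::read_json(p)
  }
  jsonlite::write_json(consolidated, .artifact(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(gaps = length(gaps))
}

#' Run a pipeline stage (or all of them)
#'
#' Stage outputs are written under `config$out_dir` with stable filenames and
#' each stage appends its summary to `run_report.json` (software version,
#' configuration hash, seeds, per-stage summaries). `all` runs
#' simulate, gate, signatures, citrus, betaperm, pls, plsda, then report.
#' Stages that need upstream artifacts fail naming the stage to run first.
#'
#' @param subcommand one of `simulate`, `gate`, `signatures`, `citrus`,
#'   `betaperm`, `pls`, `plsda`, `report`, `all`.
#' @param config a [run_config()] (or plain list passed through it).
#' @return invisibly, the stage summary (or list of summaries for `all`).
#' @export
pipeline_run <- function(subcommand = c("all", "simulate", "gate", "signatures",
                                        "citrus", "betaperm", "pls", "plsda",
                                        "report"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("simulate", "gate", "signatures", "citrus", "betaperm", "pls", "plsda",
      "report")
  else subcommand
  out <- list()
  for (st in stages) {
    .log(config, "info", "stage %s ...", st)
    fun <- switch(st, simulate = .stage_simulate, gate = .stage_gate,
                  signatures = .stage_signatures, citrus = .stage_citrus,
                  betaperm = .stage_betaperm, pls = .stage_pls,
                  plsda = .stage_plsda, report = .stage_report)
    res <- fun(config)
    if (st != "report") .update_run_report(config, st, res)
    out[[st]] <- res
    .log(config, "info", "stage %s done", st)
  }
  invisible(if (length(out) == 1) out[[1]] else out)
}

#' Consolidated pipeline report
#'
#' Collates the per-stage artifacts (selected clusters, significant subsets
#' per term, PLS permutation p-values and VIP>1 lists) into `report.json`.
#'
#' @param config a [run_config()].
#' @return the consolidated report list, invisibly.
#' @export
pipeline_report <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  pipeline_run("report", config)
  invisible(jsonlite::read_json(file.path(config$out_dir, "report.json")))
}
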