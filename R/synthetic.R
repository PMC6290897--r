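# Synthetic study generator: cohort design, per-subject event matrices, FM5
# background controls, plasma and supernatant analyte panels, all with known
# ground-truth effects so every downstream stage is testable without data
# downloads.

.LINEAGE <- c("CD3", "CD4", "CD8", "gdTCR", "CD127", "CD16", "CD56")
.IRS <- c("PD-1", "TIGIT", "TIM-3", "CD160", "LAG-3")
.SUBSETS <- c("gdT", "CD4T", "CD8T", "NK", "other")
.GROUPS <- c("uninfected_young", "uninfected_old", "hiv_young", "hiv_old")

.PLASMA_ANALYTES <- c("sCD14", "D-dimer", "CRP", "Fibrinogen", "SAP", "Adipsin",
                      "vWF", "A2M", "Haptoglobin", "L-selectin", "CXCL4",
                      "PAI-1", "sVCAM-1", "TNF-a", "IL-6", "IL-1b")
.SUP_ANALYTES <- c("sCD137", "GranzymeA", "GranzymeB", "Perforin", "MIP-1b",
                   "CCL20", "TNF-a", "IFN-g", "IL-17A", "sFasL", "IL-8")

.default_lineage_means <- function() {
  m <- matrix(0.4, nrow = 5, ncol = 7, dimnames = list(.SUBSETS, .LINEAGE))
  m["gdT", ]  <- c(3.5, 0.5, 1.2, 3.0, 0.5, 1.5, 1.8)
  m["CD4T", ] <- c(3.5, 3.0, 0.4, 0.4, 2.5, 0.4, 0.4)
  m["CD8T", ] <- c(3.5, 0.4, 3.2, 0.4, 1.8, 0.5, 0.6)
  m["NK", ]   <- c(0.4, 0.4, 0.8, 0.4, 0.4, 3.0, 3.0)
  m["other", ] <- c(0.4, 0.5, 0.4, 0.4, 0.6, 0.8, 0.5)
  m
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults define the study conditions the generator emulates: four
#' subject groups (uninfected/HIV x young/old, default sizes 21/21/22/28),
#' seven lineage channels over five cell subsets, five inhibitory receptors
#' of which PD-1, TIGIT and CD160 are bimodally expressed and TIM-3 and LAG-3
#' are smooth unimodal shifts, a per-cell latent activation scalar that
#' induces positive IR co-expression, per-subject random intercepts on IR
#' log-odds, per-batch FM5 background controls, a 16-analyte plasma panel with
#' group shifts and TIGIT coupling, and a supernatant panel whose per-cell
#' secretion depends linearly on the subject's TIGIT-positive fraction with
#' group-specific slopes.
#'
#' All event intensities are generated directly in arcsinh units; the raw
#' export applies the inverse transform.
#'
#' @param group_sizes four non-negative integers named
#'   `uninfected_young`, `uninfected_old`, `hiv_young`, `hiv_old`.
#' @param events_per_subject positive integer.
#' @param n_batches positive integer number of staining batches.
#' @param seed integer master seed.
#' @param subset_weights 4 x 5 matrix (groups x subsets) of mixture weights,
#'   each row summing to 1.
#' @param lineage_mean,lineage_sd 5 x 7 matrices (subsets x lineage channels)
#'   of component means and spreads, arcsinh units.
#' @param ir_base_logit named length-5 baseline log-odds of IR positivity on
#'   gamma-delta T cells.
#' @param ir_hiv_effect,ir_age_effect named length-5 log-odds shifts.
#' @param ir_other_logit log-odds of IR positivity on non-gamma-delta subsets
#'   (no group effects).
#' @param subject_sd SD of the per-subject random intercept on IR logits.
#' @param coexpression_loading named length-5 loading of each IR's logit on a
#'   per-cell standard-normal activation scalar (drives multi-IR combos).
#' @param smooth_ir_set IRs generated as unimodal continuous shifts rather
#'   than bimodal mixtures.
#' @param pos_intensity,neg_intensity length-2 `c(mean, sd)` of positive and
#'   negative IR fluorescence, arcsinh units.
#' @param viability_mean,viability_sd live-cell viability-channel parameters.
#' @param plasma_base,plasma_hiv_effect,plasma_age_effect,plasma_tigit_coupling
#'   named length-16 log-scale parameters of the plasma panel.
#' @param plasma_noise_sd log-scale plasma noise SD.
#' @param secretion_intercept,secretion_slope 4 x 11 matrices (groups x
#'   supernatant analytes): per-cell secretion linear model, pg per cell.
#' @param secretion_noise_sd per-cell secretion noise SD.
#' @param cells_per_well_range integer range the cultured cell count per well
#'   is drawn from.
#' @param supernatant_detection_limit pg per well below which an entry is
#'   flagged undetected.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(group_sizes = c(uninfected_young = 21, uninfected_old = 21,
                                             hiv_young = 22, hiv_old = 28),
                             events_per_subject = 10000,
                             n_batches = 11,
                             seed = 1,
                             subset_weights = NULL,
                             lineage_mean = .default_lineage_means(),
                             lineage_sd = NULL,
                             ir_base_logit = c("PD-1" = -1.2, "TIGIT" = -1.0,
                                               "TIM-3" = -0.8, "CD160" = -0.7,
                                               "LAG-3" = -1.8),
                             ir_hiv_effect = c("PD-1" = -0.4, "TIGIT" = 1.5,
                                               "TIM-3" = 0.6, "CD160" = 0.6,
                                               "LAG-3" = 0),
                             ir_age_effect = c("PD-1" = 0, "TIGIT" = 0.8,
                                               "TIM-3" = 0, "CD160" = 0,
                                               "LAG-3" = 0),
                             ir_other_logit = -2.5,
                             subject_sd = 0.3,
                             coexpression_loading = c("PD-1" = 0.8, "TIGIT" = 0.8,
                                                      "TIM-3" = 0.6, "CD160" = 0.6,
                                                      "LAG-3" = 0.6),
                             smooth_ir_set = c("TIM-3", "LAG-3"),
                             pos_intensity = c(mean = 2.5, sd = 0.4),
                             neg_intensity = c(mean = 0.3, sd = 0.3),
                             viability_mean = 0.5, viability_sd = 0.2,
                             plasma_base = NULL,
                             plasma_hiv_effect = NULL,
                             plasma_age_effect = NULL,
                             plasma_tigit_coupling = NULL,
                             plasma_noise_sd = 0.4,
                             secretion_intercept = NULL,
                             secretion_slope = NULL,
                             secretion_noise_sd = 5e-4,
                             cells_per_well_range = c(2000, 26000),
                             supernatant_detection_limit = 5) {
  if (is.null(subset_weights)) {
    w <- c(gdT = 0.08, CD4T = 0.35, CD8T = 0.25, NK = 0.15, other = 0.17)
    subset_weights <- matrix(rep(w, each = 4), nrow = 4,
                             dimnames = list(.GROUPS, .SUBSETS))
  }
  if (is.null(lineage_sd))
    lineage_sd <- matrix(0.35, nrow = 5, ncol = 7,
                         dimnames = dimnames(.default_lineage_means()))
  if (is.null(plasma_base))
    plasma_base <- stats::setNames(
      log(c(1500, 300, 2, 2500, 25, 2.5, 10, 1800, 1200, 1100, 8, 20, 900, 5, 2, 0.5)),
      .PLASMA_ANALYTES)
  if (is.null(plasma_hiv_effect))
    plasma_hiv_effect <- stats::setNames(
      ifelse(.PLASMA_ANALYTES %in% c("sCD14", "A2M", "Fibrinogen", "SAP",
                                     "Adipsin", "vWF"), 0.5, 0),
      .PLASMA_ANALYTES)
  if (is.null(plasma_age_effect))
    plasma_age_effect <- stats::setNames(
      ifelse(.PLASMA_ANALYTES %in% c("D-dimer", "CRP", "Fibrinogen", "SAP",
                                     "Adipsin", "vWF"), 0.4, 0),
      .PLASMA_ANALYTES)
  if (is.null(plasma_tigit_coupling))
    plasma_tigit_coupling <- stats::setNames(
      ifelse(.PLASMA_ANALYTES %in% c("IL-6", "TNF-a", "CXCL4", "L-selectin"),
             1.5, 0),
      .PLASMA_ANALYTES)
  if (is.null(secretion_intercept))
    secretion_intercept <- matrix(2e-3, nrow = 4, ncol = length(.SUP_ANALYTES),
                                  dimnames = list(.GROUPS, .SUP_ANALYTES))
  if (is.null(secretion_slope)) {
    # secretion tracks the TIGIT+ fraction only in the HIV groups
    secretion_slope <- matrix(0, nrow = 4, ncol = length(.SUP_ANALYTES),
                              dimnames = list(.GROUPS, .SUP_ANALYTES))
    secretion_slope[c("hiv_young", "hiv_old"), ] <- 8e-3
  }
  cfg <- structure(list(
    group_sizes = group_sizes, events_per_subject = events_per_subject,
    n_batches = n_batches, seed = seed, subset_weights = subset_weights,
    lineage_mean = lineage_mean, lineage_sd = lineage_sd,
    ir_base_logit = ir_base_logit, ir_hiv_effect = ir_hiv_effect,
    ir_age_effect = ir_age_effect, ir_other_logit = ir_other_logit,
    subject_sd = subject_sd, coexpression_loading = coexpression_loading,
    smooth_ir_set = smooth_ir_set, pos_intensity = pos_intensity,
    neg_intensity = neg_intensity, viability_mean = viability_mean,
    viability_sd = viability_sd, plasma_base = plasma_base,
    plasma_hiv_effect = plasma_hiv_effect, plasma_age_effect = plasma_age_effect,
    plasma_tigit_coupling = plasma_tigit_coupling,
    plasma_noise_sd = plasma_noise_sd,
    secretion_intercept = secretion_intercept,
    secretion_slope = secretion_slope, secretion_noise_sd = secretion_noise_sd,
    cells_per_well_range = cells_per_well_range,
    supernatant_detection_limit = supernatant_detection_limit),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic configuration
#'
#' Checks the structural invariants: four non-negative group sizes, mixture
#' weights summing to one within 1e-9 per group, strictly positive spread
#' parameters. Errors name the offending field.
#'
#' @param cfg a [synthetic_config()].
#' @return `cfg`, invisibly.
#' @export
validate_synthetic_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (length(gs) != 4 || any(gs < 0) || any(gs != floor(gs)))
    stop_field("group_sizes", "must be four non-negative integers")
  if (cfg$events_per_subject < 1)
    stop_field("events_per_subject", "must be a positive integer")
  if (cfg$n_batches < 1) stop_field("n_batches", "must be a positive integer")
  w <- cfg$subset_weights
  if (!is.matrix(w) || nrow(w) != 4 || ncol(w) != 5)
    stop_field("subset_weights", "must be a 4 x 5 matrix (groups x subsets)")
  if (any(abs(rowSums(w) - 1) > 1e-9))
    stop_field("subset_weights", "each group's weights must sum to 1 within 1e-9")
  if (any(w < 0)) stop_field("subset_weights", "weights must be non-negative")
  for (f in c("lineage_sd")) if (any(cfg[[f]] <= 0))
    stop_field(f, "spread parameters must be > 0")
  if (cfg$subject_sd < 0) stop_field("subject_sd", "must be >= 0")
  if (cfg$pos_intensity[["sd"]] <= 0) stop_field("pos_intensity", "sd must be > 0")
  if (cfg$neg_intensity[["sd"]] <= 0) stop_field("neg_intensity", "sd must be > 0")
  for (f in c("ir_base_logit", "ir_hiv_effect", "ir_age_effect",
              "coexpression_loading"))
    if (!all(.IRS %in% names(cfg[[f]])))
      stop_field(f, "must name all five inhibitory receptors")
  if (cfg$cells_per_well_range[1] < 1 ||
      cfg$cells_per_well_range[2] < cfg$cells_per_well_range[1])
    stop_field("cells_per_well_range", "must be an increasing positive range")
  invisible(cfg)
}

#' Subject-level analyte panel
#'
#' @param concentrations subjects x analytes numeric matrix (row names =
#'   subject ids), non-negative.
#' @param cells_per_well per-subject positive integer (supernatant panels).
#' @param per_cell_normalized logical flag; requires `cells_per_well`.
#' @param detection_mask logical matrix, same shape as `concentrations`.
#' @return an object of class `analyte_panel`.
#' @export
analyte_panel <- function(concentrations, cells_per_well = NULL,
                          per_cell_normalized = FALSE, detection_mask = NULL) {
  if (!is.matrix(concentrations) || any(concentrations < 0))
    stop_field("concentrations", "must be a non-negative matrix")
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    stop_field("concentrations", "must carry subject and analyte names")
  if (per_cell_normalized && is.null(cells_per_well))
    stop_field("cells_per_well", "required when per_cell_normalized")
  if (!is.null(cells_per_well) && any(cells_per_well <= 0))
    stop_field("cells_per_well", "must be positive")
  if (is.null(detection_mask))
    detection_mask <- matrix(TRUE, nrow(concentrations), ncol(concentrations),
                             dimnames = dimnames(concentrations))
  structure(list(concentrations = concentrations,
                 cells_per_well = cells_per_well,
                 per_cell_normalized = per_cell_normalized,
                 detection_mask = detection_mask),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel> %d subjects x %d analytes (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              if (x$per_cell_normalized) "per-cell normalized" else "well totals"))
  invisible(x)
}

.design_groups <- function(design) {
  factor(ifelse(design$hiv == 1,
                ifelse(design$age_group == "old", "hiv_old", "hiv_young"),
                ifelse(design$age_group == "old", "uninfected_old",
                       "uninfected_young")),
         levels = .GROUPS)
}

.default_roles <- function() {
  stats::setNames(c(rep("lineage", 7), rep("ir", 5), "viability"),
                  c(.LINEAGE, .IRS, "Viability"))
}

#' Default channel-role map of the synthetic panel
#'
#' @return named character vector: 7 lineage channels, 5 IR channels, one
#'   viability channel.
#' @export
synthetic_channel_roles <- .default_roles

# Simulate one sample's events. eta_gd: named per-IR logit offset applying to
# gamma-delta cells (base + group effects + subject intercept).
.simulate_events <- function(n, weights, cfg, eta_gd, sample_id) {
  subset <- factor(sample(.SUBSETS, n, replace = TRUE, prob = weights),
                   levels = .SUBSETS)
  idx <- as.integer(subset)
  lin <- matrix(stats::rnorm(n * 7, mean = cfg$lineage_mean[idx, ],
                             sd = cfg$lineage_sd[idx, ]),
                nrow = n, ncol = 7, dimnames = list(NULL, .LINEAGE))
  z <- stats::rnorm(n)   # latent activation: shared across IRs -> co-expression
  is_gd <- subset == "gdT"
  posm <- cfg$pos_intensity[["mean"]]; poss <- cfg$pos_intensity[["sd"]]
  negm <- cfg$neg_intensity[["mean"]]; negs <- cfg$neg_intensity[["sd"]]
  ir_vals <- matrix(0, n, 5, dimnames = list(NULL, .IRS))
  ir_pos <- matrix(NA, n, 5, dimnames = list(NULL, .IRS))
  for (j in .IRS) {
    eta <- ifelse(is_gd, eta_gd[[j]], cfg$ir_other_logit) +
      cfg$coexpression_loading[[j]] * z
    if (j %in% cfg$smooth_ir_set) {
      mu <- negm + (posm - negm) * inv_logit(eta)
      ir_vals[, j] <- stats::rnorm(n, mu, negs)
    } else {
      pos <- stats::runif(n) < inv_logit(eta)
      ir_pos[, j] <- pos
      ir_vals[, j] <- stats::rnorm(n, ifelse(pos, posm, negm),
                                   ifelse(pos, poss, negs))
    }
  }
  viab <- stats::rnorm(n, cfg$viability_mean, cfg$viability_sd)
  vals <- cbind(lin, ir_vals, Viability = viab)
  m <- event_matrix(vals, sample_id = sample_id,
                    channel_roles = .default_roles(),
                    transform_state = "arcsinh", cofactor = 150)
  attr(m, "truth") <- list(subset = subset, ir_pos = ir_pos)
  m
}

#' Generate a full synthetic cohort
#'
#' Produces the cohort design table, one arcsinh-space event matrix per
#' subject (with hidden ground-truth subset labels and IR positivity retained
#' as a `truth` attribute), one FM5 background event matrix per batch whose IR
#' channels are drawn from the negative intensity distribution only, and the
#' plasma analyte panel. Identical seeds give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `design` (data.frame: subject_id, hiv,
#'   age_group, batch, group), `events` (named list of [event_matrix()]),
#'   `fm5` (list of per-batch FM5 [event_matrix()]), `plasma`
#'   ([analyte_panel()]), and `truth` (per-subject data.frame with the
#'   realized gamma-delta counts and true IR-positive fractions).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, "cohort"))
  gs <- cfg$group_sizes
  n <- sum(gs)
  group <- factor(rep(.GROUPS, times = gs), levels = .GROUPS)
  design <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    hiv = as.integer(group %in% c("hiv_young", "hiv_old")),
    age_group = ifelse(group %in% c("uninfected_old", "hiv_old"), "old", "young"),
    batch = rep_len(seq_len(cfg$n_batches), n),
    group = group,
    stringsAsFactors = FALSE)

  b_subj <- matrix(stats::rnorm(n * 5, sd = cfg$subject_sd), n, 5,
                   dimnames = list(design$subject_id, .IRS))
  events <- vector("list", n)
  names(events) <- design$subject_id
  truth <- data.frame(subject_id = design$subject_id, n_gd = 0L,
                      stringsAsFactors = FALSE)
  for (j in .IRS) truth[[paste0("frac_", j)]] <- NA_real_
  for (i in seq_len(n)) {
    eta_gd <- cfg$ir_base_logit[.IRS] +
      design$hiv[i] * cfg$ir_hiv_effect[.IRS] +
      (design$age_group[i] == "old") * cfg$ir_age_effect[.IRS] +
      b_subj[i, .IRS]
    m <- .simulate_events(cfg$events_per_subject, cfg$subset_weights[group[i], ],
                          cfg, as.list(eta_gd), design$subject_id[i])
    tr <- attr(m, "truth")
    gd <- tr$subset == "gdT"
    truth$n_gd[i] <- sum(gd)
    for (j in .IRS)
      truth[[paste0("frac_", j)]][i] <-
        if (any(gd) && !all(is.na(tr$ir_pos[, j])))
          mean(tr$ir_pos[gd, j]) else NA_real_
    events[[i]] <- m
  }

  # FM5: pooled 5% mixture stained without the five IR antibodies -> IR
  # channels show pure background regardless of subset
  pooled_w <- colMeans(cfg$subset_weights)
  pooled_w <- pooled_w / sum(pooled_w)
  fm5 <- lapply(seq_len(cfg$n_batches), function(b) {
    m <- .simulate_events(cfg$events_per_subject, pooled_w, cfg,
                          as.list(stats::setNames(rep(-Inf, 5), .IRS)),
                          sprintf("FM5_batch%02d", b))
    negm <- cfg$neg_intensity[["mean"]]; negs <- cfg$neg_intensity[["sd"]]
    nr <- nrow(m$values)
    m$values[, .IRS] <- stats::rnorm(nr * 5, negm, negs)
    attr(m, "truth")$ir_pos[] <- FALSE
    attr(m, "batch") <- b
    m
  })

  tigit_frac <- truth[["frac_TIGIT"]]
  conc <- sapply(.PLASMA_ANALYTES, function(a) {
    exp(cfg$plasma_base[[a]] +
          design$hiv * cfg$plasma_hiv_effect[[a]] +
          (design$age_group == "old") * cfg$plasma_age_effect[[a]] +
          cfg$plasma_tigit_coupling[[a]] * ifelse(is.na(tigit_frac), 0, tigit_frac) +
          stats::rnorm(n, 0, cfg$plasma_noise_sd))
  })
  rownames(conc) <- design$subject_id
  plasma <- analyte_panel(conc)

  list(design = design, events = events, fm5 = fm5, plasma = plasma,
       truth = truth)
}

#' Generate the supernatant analyte panel
#'
#' Per-cell secretion of each analyte follows the group-specific linear model
#' `intercept_g + slope_g * tigit_fraction` plus Gaussian noise, truncated at
#' zero; well totals multiply by the cultured cell count, which is drawn
#' uniformly from `cells_per_well_range`.
#'
#' @param design cohort design data.frame as produced by [generate_cohort()].
#' @param tigit_fraction named per-subject TIGIT-positive fraction in `[0, 1]`
#'   (names = subject ids).
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to a sub-seed of the config seed).
#' @return an [analyte_panel()] of well totals with `cells_per_well` and a
#'   detection mask at the configured detection limit.
#' @export
generate_supernatant <- function(design, tigit_fraction, config,
                                 seed = derive_seed(config$seed, "supernatant")) {
  validate_synthetic_config(config)
  if (is.null(names(tigit_fraction)) ||
      !setequal(names(tigit_fraction), design$subject_id) ||
      length(tigit_fraction) != nrow(design))
    stop("tigit_fraction must be named by exactly the design's subject ids",
         call. = FALSE)
  tf <- tigit_fraction[design$subject_id]
  if (any(is.na(tf)) || any(tf < 0 | tf > 1))
    stop_field("tigit_fraction", "must lie in [0, 1]")
  set.seed(seed)
  g <- as.integer(.design_groups(design))
  n <- nrow(design)
  analytes <- colnames(config$secretion_intercept)
  rate <- sapply(analytes, function(a) {
    r <- config$secretion_intercept[g, a] + config$secretion_slope[g, a] * tf +
      stats::rnorm(n, 0, config$secretion_noise_sd)
    pmax(r, 0)
  })
  cells <- sample(seq(config$cells_per_well_range[1],
                      config$cells_per_well_range[2]), n, replace = TRUE)
  conc <- rate * cells
  rownames(conc) <- design$subject_id
  names(cells) <- design$subject_id
  analyte_panel(conc, cells_per_well = cells,
                detection_mask = conc > config$supernatant_detection_limit)
}

#' Generate exchangeable null subset abundances
#'
#' Each subject's abundance vector is drawn from a symmetric Dirichlet, so the
#' subset labels are exchangeable within subject and the within-subject
#' permutation null of the minP procedure holds exactly, with no dependence on
#' any covariate.
#'
#' @param n_subjects number of subjects (at least 4, the minimum for the
#'   two-term abundance model).
#' @param n_subsets number of subsets (at least 2; 8 for the three-IR
#'   combination family).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration parameter (default 2).
#' @return matrix subjects x subsets, rows summing to 1.
#' @export
generate_null_abundances <- function(n_subjects, n_subsets = 8, seed = 1,
                                     concentration = 2) {
  if (n_subjects < 4)
    stop("n_subjects must be >= 4 to support the two-term model", call. = FALSE)
  if (n_subsets < 2) stop_field("n_subsets", "must be >= 2")
  if (concentration <= 0) stop_field("concentration", "must be > 0")
  set.seed(seed)
  g <- matrix(stats::rgamma(n_subjects * n_subsets, shape = concentration),
              n_subjects, n_subsets)
  ab <- g / rowSums(g)
  dimnames(ab) <- list(sprintf("S%03d", seq_len(n_subjects)),
                       sprintf("subset_%d", seq_len(n_subsets)))
  ab
}
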