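# Expert-gating analytics: FM5-quantile IR gates, subset extraction by
# ordered boolean predicates, combination-signature abundances, multi-IR
# fractions, and median-intensity summaries.

#' Derive IR gate thresholds from an FM5 background control
#'
#' The gate for each marker is the stated empirical quantile of the FM5
#' (fluorescence-minus-five) distribution of that channel: cells of the main
#' samples above the threshold are called positive. The default quantile
#' 0.995 leaves about 0.5% background positivity.
#'
#' @param fm5 an arcsinh-transformed [event_matrix()] of the batch's FM5
#'   control.
#' @param markers IR channel names to gate; default all channels with role
#'   `ir`.
#' @param quantile gate quantile in (0, 1).
#' @param batch integer batch label recorded on each gate (default from the
#'   FM5 matrix's `batch` attribute, else 1).
#' @return data.frame of class `gate_spec`: marker, threshold (arcsinh
#'   units), source_batch, quantile.
#' @export
derive_gates <- function(fm5, markers = channels_by_role(fm5, "ir"),
                         quantile = 0.995,
                         batch = if (!is.null(attr(fm5, "batch"))) attr(fm5, "batch") else 1L) {
  stopifnot(inherits(fm5, "event_matrix"))
  if (fm5$transform_state != "arcsinh")
    stop("FM5 matrix must be arcsinh-transformed before gating", call. = FALSE)
  if (quantile <= 0 || quantile >= 1) stop_field("quantile", "must be in (0, 1)")
  missing_mk <- setdiff(markers, colnames(fm5$values))
  if (length(missing_mk))
    stop(paste("markers absent from FM5 sample:",
               paste(missing_mk, collapse = ", ")), call. = FALSE)
  thr <- vapply(markers, function(mk)
    stats::quantile(fm5$values[, mk], probs = quantile, names = FALSE,
                    type = 7),
    numeric(1))
  structure(data.frame(marker = markers, threshold = thr,
                       source_batch = as.integer(batch), quantile = quantile,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gate_spec", "data.frame"))
}

#' Extract a cell subset with an ordered predicate list
#'
#' Each predicate is a list `list(channel, op, value)` with `op` one of
#' `">"`, `"<"`, `">="`, `"<="`; a cell is kept iff it satisfies every
#' predicate. The conjunction makes the order immaterial to the result; it is
#' kept for auditability of gating strategies. An empty result is returned
#' with a warning flag (`attr(, "empty")`), not an error.
#'
#' @param m an [event_matrix()].
#' @param strategy list of predicates.
#' @return the gated [event_matrix()], row order preserved, with attribute
#'   `n_gated`.
#' @export
gate_subset <- function(m, strategy) {
  stopifnot(inherits(m, "event_matrix"))
  keep <- rep(TRUE, nrow(m$values))
  for (p in strategy) {
    ch <- p[[1]]; op <- p[[2]]; v <- p[[3]]
    if (!ch %in% colnames(m$values))
      stop(sprintf("gating channel '%s' not present", ch), call. = FALSE)
    keep <- keep & switch(op,
                          ">"  = m$values[, ch] >  v,
                          "<"  = m$values[, ch] <  v,
                          ">=" = m$values[, ch] >= v,
                          "<=" = m$values[, ch] <= v,
                          stop(sprintf("unknown gate operator '%s'", op),
                               call. = FALSE))
  }
  idx <- which(keep)
  truth <- attr(m, "truth")
  m$values <- m$values[idx, , drop = FALSE]
  if (!is.null(truth)) {
    truth$subset <- truth$subset[idx]
    if (!is.null(truth$ir_pos)) truth$ir_pos <- truth$ir_pos[idx, , drop = FALSE]
    attr(m, "truth") <- truth
  }
  attr(m, "n_gated") <- length(idx)
  if (length(idx) == 0) {
    warning(sprintf("gate_subset: no cells pass for sample '%s'", m$sample_id),
            call. = FALSE)
    attr(m, "empty") <- TRUE
  }
  m
}

#' Default gamma-delta T cell gating strategy for the synthetic panel
#'
#' Viable CD3+ gdTCR+ events: the manual-gating analog of the sorter gate
#' (live, dump-negative, CD3-positive, gamma-delta-TCR-positive).
#'
#' @param cd3_min,gdtcr_min,viability_max arcsinh-unit thresholds.
#' @return a predicate list for [gate_subset()].
#' @export
gd_gate_strategy <- function(cd3_min = 2.0, gdtcr_min = 1.8, viability_max = 1.5) {
  list(list("Viability", "<", viability_max),
       list("CD3", ">", cd3_min),
       list("gdTCR", ">", gdtcr_min))
}

.gate_threshold <- function(gates, marker) {
  i <- match(marker, gates$marker)
  if (is.na(i))
    stop(sprintf("no gate for marker '%s'", marker), call. = FALSE)
  gates$threshold[i]
}

# Per-cell positivity matrix for a set of markers under FM5 gates
.positivity <- function(m, gates, markers) {
  sapply(markers, function(mk) m$values[, mk] > .gate_threshold(gates, mk))
}

#' Combination-signature abundances of a gated sample
#'
#' Tallies every one of the `2^k` positivity patterns over the chosen IR set;
#' zero-count patterns are present with abundance 0 and the abundances sum to
#' 1. Pattern names are `+`/`-` strings in the order of `ir_set`. With zero
#' gated cells all abundances are `NA` and the result carries
#' `attr(, "undefined") = TRUE`.
#'
#' @param gated a gated [event_matrix()].
#' @param gates a `gate_spec` data.frame covering `ir_set`.
#' @param ir_set character vector of k markers (default the three bimodal IRs
#'   PD-1, TIGIT, CD160).
#' @return named numeric vector of length `2^k` with attribute `n_gated`.
#' @export
combo_signature <- function(gated, gates, ir_set = c("PD-1", "TIGIT", "CD160")) {
  stopifnot(inherits(gated, "event_matrix"), length(ir_set) >= 1)
  if (!all(ir_set %in% gates$marker))
    stop("gates must cover every marker in ir_set", call. = FALSE)
  k <- length(ir_set)
  patterns <- apply(as.matrix(expand.grid(rep(list(c("-", "+")), k))[, k:1, drop = FALSE]),
                    1, paste, collapse = "")
  n <- nrow(gated$values)
  out <- stats::setNames(rep(0, 2^k), patterns)
  if (n == 0) {
    out[] <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "n_gated") <- 0L
    return(out)
  }
  pos <- .positivity(gated, gates, ir_set)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = n)
  lab <- apply(pos, 1, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  tab <- table(factor(lab, levels = patterns))
  out[] <- as.numeric(tab) / n
  attr(out, "n_gated") <- n
  out
}

#' Fractions of cells positive for at least k inhibitory receptors
#'
#' Counts positivity over all five IRs (the non-bimodal ones gated by the
#' same FM5 quantile rule) and reports the fractions of cells with >= 2,
#' >= 3 and >= 4 positive IRs.
#'
#' @param gated a gated [event_matrix()].
#' @param gates a `gate_spec` covering all five IRs.
#' @param markers the IR set to count over.
#' @return named numeric `c(ge2, ge3, ge4)`; all `NA` (flagged) if no cells.
#' @export
multi_ir_fractions <- function(gated, gates,
                               markers = c("CD160", "TIGIT", "TIM-3", "LAG-3", "PD-1")) {
  stopifnot(inherits(gated, "event_matrix"))
  if (!all(markers %in% gates$marker))
    stop("gates must cover all five IRs", call. = FALSE)
  n <- nrow(gated$values)
  if (n == 0) {
    out <- c(ge2 = NA_real_, ge3 = NA_real_, ge4 = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  pos <- .positivity(gated, gates, markers)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = n)
  cnt <- rowSums(pos)
  c(ge2 = mean(cnt >= 2), ge3 = mean(cnt >= 3), ge4 = mean(cnt >= 4))
}

#' Median intensity ratio of a marker against the FM5 control
#'
#' `median(marker | gated) / median(marker | fm5)`, both on the same arcsinh
#' scale; the summary used for non-bimodal markers whose positive fraction
#' cannot be gated reliably.
#'
#' @param gated gated [event_matrix()].
#' @param fm5 FM5 [event_matrix()] with equal transform state and cofactor.
#' @param marker channel name.
#' @return the ratio, or `NA` with a warning when the FM5 median is 0.
#' @export
median_ratio <- function(gated, fm5, marker) {
  stopifnot(inherits(gated, "event_matrix"), inherits(fm5, "event_matrix"))
  if (gated$transform_state != fm5$transform_state ||
      !isTRUE(all.equal(gated$cofactor, fm5$cofactor)))
    stop("gated and FM5 matrices must share transform state and cofactor",
         call. = FALSE)
  if (!marker %in% colnames(gated$values) || !marker %in% colnames(fm5$values))
    stop(sprintf("marker '%s' absent", marker), call. = FALSE)
  denom <- stats::median(fm5$values[, marker])
  if (denom == 0) {
    warning(sprintf("FM5 median for '%s' is 0; ratio undefined", marker),
            call. = FALSE)
    return(NA_real_)
  }
  stats::median(gated$values[, marker]) / denom
}

#' Build the per-subject signature table of a cohort
#'
#' For every subject: gates the gamma-delta subset, then computes the
#' combination abundances over `ir_set` (columns `combo_<pattern>`), the
#' marginal IR-positive fractions (`pos_<marker>`), the multi-IR fractions
#' (`ge2`, `ge3`, `ge4`), the median arcsinh intensities (`med_<marker>`),
#' the FM5 median ratios (`medratio_<marker>`) and the gated cell count
#' (`n_gated_cells`). Gates come from the subject's batch FM5 control.
#' Zero-cell subjects propagate missing values rather than zeros.
#'
#' @param events named list of [event_matrix()] (names = subject ids).
#' @param fm5 list of per-batch FM5 matrices (index = batch).
#' @param design cohort design data.frame (subject_id, batch).
#' @param strategy gating predicate list (default [gd_gate_strategy()]).
#' @param ir_set combination IR set (default PD-1, TIGIT, CD160).
#' @param quantile FM5 gate quantile.
#' @return data.frame of class `signature_table`, one row per subject.
#' @export
signature_table <- function(events, fm5, design,
                            strategy = gd_gate_strategy(),
                            ir_set = c("PD-1", "TIGIT", "CD160"),
                            quantile = 0.995) {
  all_ir <- channels_by_role(events[[1]], "ir")
  gates_by_batch <- lapply(fm5, derive_gates, markers = all_ir,
                           quantile = quantile)
  k <- length(ir_set)
  rows <- lapply(design$subject_id, function(sid) {
    m <- events[[sid]]
    b <- design$batch[design$subject_id == sid]
    gates <- gates_by_batch[[b]]
    gated <- suppressWarnings(gate_subset(m, strategy))
    combos <- combo_signature(gated, gates, ir_set)
    multi <- suppressWarnings(multi_ir_fractions(gated, gates))
    n <- attr(combos, "n_gated")
    pos <- if (n > 0) {
      p <- .positivity(gated, gates, all_ir)
      if (is.null(dim(p))) p <- matrix(p, nrow = n, dimnames = list(NULL, all_ir))
      colMeans(p)
    } else stats::setNames(rep(NA_real_, length(all_ir)), all_ir)
    med <- if (n > 0) apply(gated$values[, all_ir, drop = FALSE], 2, stats::median)
           else stats::setNames(rep(NA_real_, length(all_ir)), all_ir)
    mrat <- vapply(all_ir, function(mk)
      if (n > 0) suppressWarnings(median_ratio(gated, fm5[[b]], mk)) else NA_real_,
      numeric(1))
    row <- c(stats::setNames(as.numeric(combos), paste0("combo_", names(combos))),
             stats::setNames(as.numeric(pos), paste0("pos_", all_ir)),
             multi,
             stats::setNames(as.numeric(med), paste0("med_", all_ir)),
             stats::setNames(as.numeric(mrat), paste0("medratio_", all_ir)),
             n_gated_cells = n)
    row
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(data.frame(subject_id = design$subject_id,
                          stringsAsFactors = FALSE), out)
  class(out) <- c("signature_table", "data.frame")
  attr(out, "ir_set") <- ir_set
  out
}

#' Extract the combination-abundance block of a signature table
#'
#' @param signatures a `signature_table`.
#' @return numeric matrix subjects x patterns (row names = subject ids).
#' @export
combo_abundances <- function(signatures) {
  cols <- grep("^combo_", names(signatures), value = TRUE)
  m <- as.matrix(signatures[, cols])
  rownames(m) <- signatures$subject_id
  colnames(m) <- sub("^combo_", "", cols)
  m
}
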