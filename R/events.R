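#' Per-sample cytometry event matrix
#'
#' The basic container of the pipeline: one sample's events (rows) by
#' fluorescence channels (columns), together with the role of each channel
#' (`lineage`, `ir`, `viability`, `dump`, `other`), the transform state
#' (`raw` fluorescence or dimensionless `arcsinh` units) and the arcsinh
#' cofactor.
#'
#' @param values numeric matrix, events x channels, with unique column names
#'   and no missing values.
#' @param sample_id character scalar.
#' @param channel_roles named character vector mapping every channel to one of
#'   `lineage`, `ir`, `viability`, `dump`, `other`.
#' @param transform_state `"raw"` or `"arcsinh"`.
#' @param cofactor positive arcsinh scale `c`; values transform as
#'   `asinh(x / c)`.
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(values, sample_id, channel_roles,
                         transform_state = c("raw", "arcsinh"),
                         cofactor = 150) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_field("values", "channel names must be present and unique")
  if (anyNA(values)) stop_field("values", "missing values are not allowed")
  if (!is.character(sample_id) || length(sample_id) != 1)
    stop_field("sample_id", "must be a single string")
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop_field("cofactor", "must be a single positive number")
  roles <- c("lineage", "ir", "viability", "dump", "other")
  unmapped <- setdiff(colnames(values), names(channel_roles))
  if (length(unmapped))
    stop_field("channel_roles",
               paste("unmapped channels:", paste(unmapped, collapse = ", ")))
  bad <- !channel_roles[colnames(values)] %in% roles
  if (any(bad))
    stop_field("channel_roles",
               paste("unknown role for:",
                     paste(colnames(values)[bad], collapse = ", ")))
  structure(list(sample_id = sample_id,
                 values = values,
                 channel_roles = channel_roles[colnames(values)],
                 transform_state = transform_state,
                 cofactor = cofactor),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> sample '%s': %d events x %d channels (%s",
              x$sample_id, nrow(x$values), ncol(x$values), x$transform_state))
  cat(sprintf(", cofactor %g)\n", x$cofactor))
  tab <- table(x$channel_roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

#' Channels of an event matrix holding a given role
#'
#' @param m an [event_matrix()].
#' @param role one of `lineage`, `ir`, `viability`, `dump`, `other`.
#' @return character vector of channel names.
#' @export
channels_by_role <- function(m, role) {
  names(m$channel_roles)[m$channel_roles == role]
}

#' Arcsinh-transform an event matrix
#'
#' Applies `x -> asinh(x / cofactor)` to every value, the standard
#' variance-stabilizing transform for fluorescence cytometry. Transforming an
#' already-transformed matrix is an error (double-transform guard).
#'
#' @param m an [event_matrix()] in `raw` state.
#' @param cofactor positive scale; defaults to the matrix's stored cofactor.
#' @return the transformed `event_matrix` with `transform_state = "arcsinh"`.
#' @export
arcsinh_transform <- function(m, cofactor = m$cofactor) {
  stopifnot(inherits(m, "event_matrix"))
  if (m$transform_state != "raw")
    stop("event matrix is already arcsinh-transformed", call. = FALSE)
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop_field("cofactor", "must be a single positive number")
  m$values <- asinh(m$values / cofactor)
  m$transform_state <- "arcsinh"
  m$cofactor <- cofactor
  m
}

#' Invert the arcsinh transform
#'
#' @param m an [event_matrix()] in `arcsinh` state.
#' @return the `event_matrix` back on the raw fluorescence scale.
#' @export
inverse_arcsinh <- function(m) {
  stopifnot(inherits(m, "event_matrix"))
  if (m$transform_state != "arcsinh")
    stop("event matrix is not arcsinh-transformed", call. = FALSE)
  m$values <- sinh(m$values) * m$cofactor
  m$transform_state <- "raw"
  m
}

#' Downsample events uniformly without replacement
#'
#' @param m an [event_matrix()].
#' @param n target number of events; if `n` is at least the number of events
#'   the matrix is returned unchanged (with a message).
#' @param seed integer seed; the draw is seed-deterministic.
#' @return an `event_matrix` with `min(n, events)` rows.
#' @export
downsample_events <- function(m, n, seed = 1) {
  stopifnot(inherits(m, "event_matrix"))
  if (!is.numeric(n) || length(n) != 1 || n < 0)
    stop_field("n", "must be a single non-negative integer")
  total <- nrow(m$values)
  if (n >= total) {
    message(sprintf("downsample: requested %d >= %d events; returning all", n, total))
    return(m)
  }
  keep <- local({
    set.seed(seed)
    sort(sample.int(total, n))
  })
  truth <- attr(m, "truth")
  m$values <- m$values[keep, , drop = FALSE]
  if (!is.null(truth)) {
    truth$subset <- truth$subset[keep]
    if (!is.null(truth$ir_pos)) truth$ir_pos <- truth$ir_pos[keep, , drop = FALSE]
    attr(m, "truth") <- truth
  }
  m
}

#' Read an event matrix from CSV or FCS 3.0
#'
#' CSV is the canonical interchange dialect: comma-separated, header row of
#' channel names, UTF-8, no index column.
#'
#' @param path file path.
#' @param format `"csv"` or `"fcs"`.
#' @param channel_roles named character role map covering every channel in the
#'   file; unknown channels are an error listing the unmapped names.
#' @param sample_id sample identifier; defaults to the file stem.
#' @param transform_state state to record on the result (files do not carry
#'   it); defaults to `"raw"`.
#' @param cofactor arcsinh cofactor to record.
#' @return an [event_matrix()].
#' @export
read_events <- function(path, format = c("csv", "fcs"), channel_roles,
                        sample_id = sub("\\.[^.]+$", "", basename(path)),
                        transform_state = "raw", cofactor = 150) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  values <- if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    as.matrix(df)
  } else {
    read_fcs(path)
  }
  event_matrix(values, sample_id = sample_id, channel_roles = channel_roles,
               transform_state = transform_state, cofactor = cofactor)
}

#' Write an event matrix to CSV or FCS 3.0
#'
#' @param m an [event_matrix()].
#' @param path output path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(m, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "event_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(m$values), path, row.names = FALSE)
  } else {
    write_fcs(m$values, path)
  }
  invisible(path)
}
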