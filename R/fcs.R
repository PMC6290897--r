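# Minimal FCS 3.0 list-mode support: single data set, float32 ($DATATYPE/F),
# little-endian ($BYTEORD/1,2,3,4), $MODE/L. Covers interchange of the event
# matrices this package produces; it is not a general cytometer-file parser.

#' Write a numeric matrix as an FCS 3.0 file
#'
#' Events are stored row-major as IEEE float32, little-endian, with one
#' `$PnN` keyword per channel. Round-tripping through [read_fcs()] preserves
#' values to float32 precision (~1e-7 relative).
#'
#' @param values numeric matrix, events x channels, with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  n_par <- ncol(values)
  n_tot <- nrow(values)
  d <- "/"
  kw <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kw <- c(kw,
            sprintf("$P%dN", i), colnames(values)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(max(1, ceiling(max(abs(values[, i]), 1))),
                                        scientific = FALSE))
  }
  data_n <- 4L * n_par * n_tot
  # iterate because BEGIN/END offsets appear inside the TEXT segment itself
  begin_text <- 58L
  text_len <- 0L
  for (iter in 1:5) {
    begin_data <- begin_text + text_len
    end_data <- begin_data + data_n - 1L
    full <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
              "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
              "$BEGINDATA", as.character(begin_data),
              "$ENDDATA", as.character(end_data), kw)
    text <- paste0(d, paste(full, collapse = d), d)
    new_len <- nchar(text, type = "bytes")
    if (new_len == text_len) break
    text_len <- new_len
  }
  end_text <- begin_text + text_len - 1L
  fmt8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", fmt8(begin_text), fmt8(end_text),
                   if (end_data <= 99999999) fmt8(begin_data) else fmt8(0),
                   if (end_data <= 99999999) fmt8(end_data) else fmt8(0),
                   fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0 file written in float32 list mode
#'
#' @param path file path.
#' @return numeric matrix, events x channels, column names from `$PnN`.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 58 || rawToChar(raw[1:6]) != "FCS3.0")
    stop("not an FCS 3.0 file (bad header)", call. = FALSE)
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  begin_text <- off(11, 18); end_text <- off(19, 26)   # 0-based offsets
  if (is.na(begin_text) || is.na(end_text) || end_text + 1L > length(raw))
    stop("truncated FCS file (TEXT segment out of range)", call. = FALSE)
  text <- rawToChar(raw[(begin_text + 1L):(end_text + 1L)])
  d <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), d, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kv <- stats::setNames(vals, toupper(keys))
  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD", "$BEGINDATA", "$ENDDATA")
  if (any(!need %in% names(kv)))
    stop(paste("FCS file missing keywords:",
               paste(setdiff(need, names(kv)), collapse = ", ")), call. = FALSE)
  if (kv[["$DATATYPE"]] != "F")
    stop("only $DATATYPE/F (float32) FCS data are supported", call. = FALSE)
  if (kv[["$BYTEORD"]] != "1,2,3,4")
    stop("only little-endian FCS data are supported", call. = FALSE)
  n_par <- as.integer(kv[["$PAR"]])
  n_tot <- as.integer(kv[["$TOT"]])
  begin_data <- as.integer(kv[["$BEGINDATA"]])
  end_data <- as.integer(kv[["$ENDDATA"]])
  if (end_data + 1L > length(raw) ||
      end_data - begin_data + 1L < 4L * n_par * n_tot)
    stop("truncated FCS file (DATA segment shorter than $PAR x $TOT)", call. = FALSE)
  vec <- readBin(raw[(begin_data + 1L):(end_data + 1L)], "numeric",
                 n = n_par * n_tot, size = 4, endian = "little")
  m <- matrix(vec, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par), function(i) {
    k <- sprintf("$P%dN", i)
    if (k %in% names(kv)) kv[[k]] else sprintf("P%d", i)
  }, character(1))
  m
}
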