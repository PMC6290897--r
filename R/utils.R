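#' @keywords internal
"_PACKAGE"

# Stop with a message naming the offending field; used by all validators.
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' A single global seed deterministically spawns per-stage seeds so pipeline
#' stages can be re-run independently yet reproducibly. The label is hashed
#' with a small polynomial rolling hash; the result stays inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483629)
}

# logit / inverse logit used across the generators and models
logit <- function(p) log(p) - log1p(-p)
inv_logit <- stats::plogis
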