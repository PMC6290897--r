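# Shared fixtures, built in code at test time.

# A balanced two-factor design without any cohort generation.
make_design <- function(n_per_group = 5) {
  g <- rep(c("uninfected_young", "uninfected_old", "hiv_young", "hiv_old"),
           each = n_per_group)
  data.frame(subject_id = sprintf("S%03d", seq_along(g)),
             hiv = as.integer(grepl("^hiv", g)),
             age_group = ifelse(grepl("old$", g), "old", "young"),
             batch = rep_len(1:2, length(g)),
             group = factor(g, levels = c("uninfected_young", "uninfected_old",
                                          "hiv_young", "hiv_old")),
             stringsAsFactors = FALSE)
}

# Tiny event matrix with explicit values on the synthetic 13-channel panel.
make_event_matrix <- function(values, sample_id = "T1",
                              transform_state = "arcsinh") {
  event_matrix(values, sample_id = sample_id,
               channel_roles = synthetic_channel_roles(),
               transform_state = transform_state)
}

# Small standard cohort used by several suites (cached per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        group_sizes = c(uninfected_young = 6, uninfected_old = 6,
                        hiv_young = 6, hiv_old = 6),
        events_per_subject = 800, n_batches = 2, seed = 42)
      cache <<- list(config = cfg, cohort = generate_cohort(cfg))
    }
    cache
  }
})

# Closed-form Welch t statistic and two-sided p, independent of stats::t.test.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
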