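# Small programmatic fixtures shared across test files.

tiny_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 4L, 0L,
                1L, 1L, 8L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a1", "a2", "a3")))
  feature_table(m)
}

tiny_meta_df <- function() {
  data.frame(
    sample_id = c("P1_baseline", "P1_d15", "P1_m1", "P1_m3", "P1_m6",
                  "P2_baseline", "P2_d15", "P2_m3",
                  "D1_donor"),
    subject_id = c(rep("P1", 5), rep("P2", 3), "D1"),
    role = c(rep("patient", 8), "donor"),
    arm = c(rep("FMT", 5), rep("placebo", 3), "not-applicable"),
    timepoint = c("baseline", "d15", "m1", "m3", "m6",
                  "baseline", "d15", "m3", "donor"),
    ibs_sss = c(370, 350, 330, 310, 300, 250, 240, 230, NA),
    stringsAsFactors = FALSE)
}

# a small but fully featured simulated cohort, cached per session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_fmt_patients = 6, n_placebo_patients = 6,
                               n_asvs = 300, n_planted_gains = 12,
                               n_planted_losses = 8,
                               n_planted_transients = 10,
                               dropout_rate = 0, rng_seed = 42)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
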