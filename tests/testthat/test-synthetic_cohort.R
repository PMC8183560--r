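test_that("identical configurations give bit-identical cohorts", {
  cfg <- simulation_config(n_fmt_patients = 3, n_placebo_patients = 3,
                           n_asvs = 120, n_planted_gains = 5,
                           n_planted_losses = 4, n_planted_transients = 4,
                           rng_seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$meta$ibs_sss, b$meta$ibs_sss)
})

test_that("cohort structure matches the configuration", {
  sim <- small_cohort()
  cfg <- sim$truth$config
  n_expected <- (cfg$n_fmt_patients + cfg$n_placebo_patients) * 5 +
    cfg$n_donors
  expect_equal(nrow(sim$table), n_expected)
  expect_equal(ncol(sim$table), cfg$n_asvs)
  cov <- coverage(sim$table)
  expect_true(all(cov >= cfg$depth_range[1] & cov <= cfg$depth_range[2]))
  expect_equal(sum(sim$meta$role == "donor"), cfg$n_donors)
})

test_that("planted truth is internally consistent", {
  sim <- small_cohort()
  ev <- sim$truth$events
  for (s in unique(ev$subject_id)) {
    g <- ev$asv[ev$subject_id == s & ev$event == "gain"]
    l <- ev$asv[ev$subject_id == s & ev$event == "loss"]
    expect_length(intersect(g, l), 0)
    tr <- ev[ev$subject_id == s & ev$event == "transient", ]
    n_tps <- lengths(strsplit(tr$followups, ","))
    expect_true(all(n_tps <= 2))
  }
  # gains and transients come from the donor-enriched pool,
  # hence are absent from every patient baseline
  m <- unclass(sim$table)
  base_samples <- sim$meta$sample_id[sim$meta$timepoint == "baseline"]
  gains <- unique(ev$asv[ev$event != "loss"])
  expect_true(all(gains %in% sim$truth$donor_pool))
  expect_true(all(m[base_samples, gains] == 0))
})

test_that("planted gains are observed at depth (Poisson detection)", {
  # proportion 0.01 at depths >= 10,000 means lambda >= 100 per
  # follow-up: absence probability ~ exp(-100), so every planted gain
  # should be seen in every follow-up
  cfg <- simulation_config(n_fmt_patients = 4, n_placebo_patients = 0,
                           n_asvs = 200, n_planted_gains = 10,
                           n_planted_losses = 0, n_planted_transients = 0,
                           planted_post_proportion = 0.01,
                           depth_range = c(10000, 50000),
                           dropout_rate = 0, rng_seed = 5)
  sim <- simulate_cohort(cfg)
  m <- unclass(sim$table)
  ev <- sim$truth$events[sim$truth$events$event == "gain", ]
  fu <- c("d15", "m1", "m3", "m6")
  for (i in seq_len(nrow(ev))) {
    samples <- paste(ev$subject_id[i], fu, sep = "_")
    expect_true(all(m[samples, ev$asv[i]] > 0))
  }
})

test_that("zero fluctuation leaves placebo follow-ups inside the baseline repertoire", {
  cfg <- simulation_config(n_fmt_patients = 0, n_placebo_patients = 4,
                           n_asvs = 150, n_planted_gains = 0,
                           n_planted_losses = 0, n_planted_transients = 0,
                           placebo_fluctuation_rate = 0,
                           dropout_rate = 0, rng_seed = 9)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth$events), 0)
  m <- unclass(sim$table)
  for (s in unique(sim$meta$subject_id[sim$meta$role == "patient"])) {
    # latent support never grows without fluctuation, so no donor-pool
    # ASV can appear in any placebo sample
    rows <- sim$meta$sample_id[sim$meta$subject_id == s]
    seen <- colnames(m)[colSums(m[rows, , drop = FALSE]) > 0]
    expect_length(intersect(seen, sim$truth$donor_pool), 0)
  }
})

test_that("IBS-SSS respects the response rule and score bounds", {
  sim <- small_cohort()
  cl <- sim$truth$clinical
  expect_true(all(cl$baseline_sss - cl$m3_sss >= 50 |
                    !cl$responder))
  expect_true(all(cl$baseline_sss - cl$m3_sss < 50 | cl$responder))
  scores <- unlist(cl[, c("baseline_sss", "d15_sss", "m1_sss",
                          "m3_sss", "m6_sss")])
  expect_true(all(scores >= 0 & scores <= 500))
  # metadata carries the same scores
  p <- sim$meta[sim$meta$role == "patient" & sim$meta$timepoint == "m3", ]
  expect_equal(p$ibs_sss[match(cl$subject_id, p$subject_id)], cl$m3_sss)
})

test_that("impossible planting configurations are rejected", {
  expect_error(simulation_config(n_asvs = 100, n_planted_gains = 20,
                                 n_planted_transients = 20),
               "exceed the donor-enriched")
  expect_error(simulation_config(n_asvs = 100, n_planted_gains = 2,
                                 n_planted_transients = 2,
                                 n_planted_losses = 50),
               "exceed low-diversity")
  expect_error(simulation_config(depth_range = c(100, 50)), "depth_range")
  expect_error(simulation_config(planted_post_proportion = 1.2),
               "planted_post_proportion")
})
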