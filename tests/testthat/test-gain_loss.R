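test_that("absence probability score is the Poisson survival at zero", {
  expect_equal(absence_probability_score(0), 0)
  expect_equal(absence_probability_score(1), 1 - exp(-1))
  expect_equal(absence_probability_score(100), 1, tolerance = 1e-12)
  expect_error(absence_probability_score(-0.5), "expected_count")
  expect_error(absence_probability_score(Inf), "expected_count")
})

hand_cases <- list(
  # counts (T0 first), coverages, expected score, type
  list(c(0, 100, 100, 100, 100), rep(1e4, 5),
       (1 - exp(-100)) * 1, "gain"),
  list(c(0, 0, 0, 0, 0), c(1e4, 1e4, 1e4, 1e3, 1e3), 0, "gain"),
  list(c(0, 20, 20, 0, 0), c(1e4, 1e4, 1e4, 1e3, 1e3),
       (1 - exp(-10)) * mean(c(exp(-2), 0)), "gain"),
  list(c(100, 0, 0, 0, 0), rep(1e4, 5),
       mean(rep((1 - exp(-100))^2, 3)), "loss"),
  list(c(100, 5, 3, 7, 2), rep(1e4, 5), 0, "loss"),
  list(c(1, 0, 0, 0, 0), c(1e4, rep(5e3, 4)),
       (1 - exp(-0.5))^2, "loss"))

test_that("gain and loss scores reproduce hand-worked cases to 4 decimals", {
  for (case in hand_cases) {
    fn <- if (case[[4]] == "gain") gain_score else loss_score
    oracle <- if (case[[4]] == "gain") oracle_gain else oracle_loss
    got <- fn(case[[1]], case[[2]])
    expect_equal(round(got, 4), round(case[[3]], 4))
    expect_equal(got, oracle(case[[1]], case[[2]]), tolerance = 1e-12)
  }
})

test_that("vectorized scoring agrees with the scalar oracle on random series", {
  set.seed(77)
  for (rep in 1:50) {
    m <- sample(2:4, 1)                      # follow-ups
    cov <- round(exp(runif(m + 1, log(6000), log(120000))))
    counts <- rpois(m + 1, lambda = sample(c(0, 1, 5, 50), m + 1,
                                           replace = TRUE))
    mat <- matrix(counts, ncol = 1, dimnames = list(NULL, "a"))
    res <- patient_gain_loss_scores(mat, cov)
    if (counts[1] == 0) {
      expect_equal(unname(res$gain), oracle_gain(counts, cov),
                   tolerance = 1e-12)
      expect_equal(unname(res$loss), 0)
    } else {
      expect_equal(unname(res$loss), oracle_loss(counts, cov),
                   tolerance = 1e-12)
      expect_equal(unname(res$gain), 0)
    }
    expect_true(res$gain >= 0 && res$gain <= 1)
    expect_true(res$loss >= 0 && res$loss <= 1)
  }
})

test_that("contract violations and eligibility are enforced", {
  expect_error(gain_score(c(1, 0, 0), c(10, 10, 10)), "zero count")
  expect_error(loss_score(c(0, 1, 1), c(10, 10, 10)), "positive count")
  expect_error(patient_gain_loss_scores(
    matrix(c(0, 5), 2, 1), c(10, 10)), "2 follow-up")
})

test_that("gain score grows with follow-up proportions when consistently present", {
  cov <- rep(2e4, 5)
  props <- c(1e-4, 5e-4, 2e-3, 1e-2)
  scores <- vapply(props, function(p) {
    gain_score(c(0, rep(p * 2e4, 4)), cov)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("loss score grows with follow-up coverage when absent", {
  covs <- c(2e3, 1e4, 5e4, 1e5)
  scores <- vapply(covs, function(cv) {
    loss_score(c(5, 0, 0, 0, 0), c(1e4, rep(cv, 4)))
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("one shallow absence cannot sink an otherwise saturated gain call", {
  # ASV at proportion 0.01, all follow-ups deep except one very shallow
  # sample (lambda = 0.1) where it goes unseen
  counts <- c(0, 100, 100, 0, 100)
  cov <- c(1e4, 1e4, 1e4, 10, 1e4)
  expect_gte(gain_score(counts, cov), 0.85)
  # the same pattern with a deep absent sample is a real inconsistency
  counts2 <- c(0, 100, 100, 0, 100)
  cov2 <- c(1e4, 1e4, 1e4, 1e4, 1e4)
  expect_lt(gain_score(counts2, cov2), 0.85)
})

test_that("ternary calls use an inclusive cutoff and structural zeros", {
  scores <- list(
    gain = matrix(c(0.9, 0.2, 0, 0.85), 2, 2,
                  dimnames = list(c("P1", "P2"), c("a", "b"))),
    loss = matrix(c(0, 0, 0.85, 0), 2, 2,
                  dimnames = list(c("P1", "P2"), c("a", "b"))))
  calls <- call_gains_losses(scores, cutoff = 0.85)
  expect_equal(calls["P1", "a"], 2L)   # gain 0.9
  expect_equal(calls["P2", "a"], 1L)   # gain 0.2
  expect_equal(calls["P1", "b"], 0L)   # loss 0.85 exactly: inclusive
  expect_equal(calls["P2", "b"], 2L)   # gain 0.85 exactly
  expect_error(call_gains_losses(scores, cutoff = 0), "cutoff")
  expect_error(call_gains_losses(scores, cutoff = 1.2), "cutoff")
})

test_that("ternary profile distances follow closed forms", {
  k <- 6
  p_same <- matrix(1L, 3, k, dimnames = list(paste0("P", 1:3), NULL))
  res <- ternary_distance_pcoa(p_same)
  expect_true(all(res$dm == 0))
  p <- p_same
  p[2, 1] <- 2L                        # one gained vs unchanged
  expect_equal(as.matrix(dist(p))["P1", "P2"], 1)
  all_gain <- matrix(2L, 1, k)
  all_loss <- matrix(0L, 1, k)
  expect_equal(as.numeric(dist(rbind(all_gain, all_loss))), 2 * sqrt(k))
  expect_error(ternary_distance_pcoa(p[1:2, ]), "3 profiles")
})

test_that("group trend test separates planted clusters and not identical ones", {
  set.seed(12)
  k <- 40
  g1 <- matrix(1L, 6, k) ; g1[, 1:15] <- 2L
  g2 <- matrix(1L, 6, k) ; g2[, 26:40] <- 0L
  noise <- function(g) (g + matrix(rbinom(6 * k, 1, 0.05), 6)) %% 3L
  profiles <- rbind(noise(g1), noise(g2))
  labels <- rep(c("FMT", "placebo"), each = 6)
  res <- group_trend_test(profiles, labels, n_permutations = 999, seed = 4)
  # maximal separation saturates the permutation floor (the identity and
  # whole-group-swap relabelings reproduce F_obs, so the floor is a few
  # permutations, not exactly one)
  expect_lte(res$p_value, 5 / (1 + 999))
  ident <- matrix(1L, 8, k)
  res0 <- group_trend_test(ident, rep(c("A", "B"), each = 4),
                           n_permutations = 999)
  expect_equal(res0$p_value, 1)
  expect_error(group_trend_test(profiles, labels, n_permutations = 50),
               "99")
})

test_that("summaries encode the genus triple layout and group medians", {
  profiles <- matrix(1L, 5, 4,
                     dimnames = list(paste0("P", 1:5),
                                     c("a1", "a2", "b1", "b2")))
  profiles["P1", c("a1", "a2", "b1")] <- 2L     # 3 gains
  profiles["P1", "b2"] <- 0L                    # 1 loss
  profiles["P2", "a1"] <- 2L
  profiles["P3", "a1"] <- 2L                    # a1 gained by 3 patients
  profiles["P4", "a2"] <- 2L                    # a2 gained by 2 patients
  meta <- cohort_metadata(data.frame(
    sample_id = paste0("P", 1:5, "_baseline"),
    subject_id = paste0("P", 1:5), role = "patient", arm = "FMT",
    timepoint = "baseline", ibs_sss = NA))
  taxonomy <- tibble::tibble(asv = c("a1", "a2", "b1", "b2"),
                             genus = c("gA", "gA", "gB", "gB"))
  s <- summarize_gains_losses(profiles, meta, taxonomy)
  gA <- s$per_genus[s$per_genus$genus == "gA", ]
  expect_equal(gA$gained_asvs, 2)       # (i) ASVs gained
  expect_equal(gA$gain_events, 5)       # (ii) total gains
  expect_equal(gA$gain_max_patients, 3) # (iii) max patients for one ASV
  expect_equal(s$per_patient$n_gained[s$per_patient$subject_id == "P1"], 3)
  expect_equal(s$per_patient$n_lost[s$per_patient$subject_id == "P1"], 1)
})

test_that("planted events are recovered from a simulated cohort", {
  sim <- small_cohort()
  sc <- score_cohort_gain_loss(sim$table, sim$meta)
  calls <- call_gains_losses(sc)
  ev <- sim$truth$events
  hits <- function(event, code) {
    e <- ev[ev$event == event, ]
    mean(mapply(function(s, a) calls[s, a] == code, e$subject_id, e$asv))
  }
  expect_gte(hits("gain", 2L), 0.95)
  expect_gte(hits("loss", 0L), 0.95)
  expect_lte(hits("transient", 2L), 0.05)
  s <- summarize_gains_losses(calls, sim$meta)
  med <- s$group_summary
  expect_gt(med$median_gains[med$arm == "FMT"],
            med$median_gains[med$arm == "placebo"])
  expect_lt(s$group_tests$p_value[s$group_tests$metric == "gains"], 0.05)
})
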