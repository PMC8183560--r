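#' Poisson absence-confidence score
#'
#' Given the expected read count `lambda` an ASV would have produced if
#' it were truly present, returns the probability that at least one read
#' would have been observed, `P(X >= 1) = 1 - exp(-lambda)` for
#' `X ~ Poisson(lambda)`.  A value near 1 means the sample was deep
#' enough that a true presence could not have been missed, so an
#' observed absence is real rather than a detection-limit artifact.
#'
#' @param expected_count expected read count(s), finite and >= 0.
#' @return Score(s) in [0, 1].
#' @export
absence_probability_score <- function(expected_count) {
  if (anyNA(expected_count) || any(expected_count < 0) ||
      any(!is.finite(expected_count))) {
    stop("expected_count must be finite and >= 0")
  }
  stats::ppois(0, expected_count, lower.tail = FALSE)
}

# P(X = 0): the probability an absence is a pure depth artifact, i.e.
# the ASV is plausibly present despite yielding zero reads.
depth_artifact_probability <- function(expected_count) {
  stats::dpois(0, expected_count)
}

#' Gain and loss scores for every ASV of one patient
#'
#' Vectorized core of the depth-aware gain/loss calculation.  The first
#' row of `counts` is the baseline (T0) sample; subsequent rows are the
#' chronologically ordered follow-ups (missing visits are simply absent
#' from the matrix, never zero-filled).
#'
#' For an ASV absent at T0 a gain score is assessed: the confidence that
#' the baseline absence is real (`absence_probability_score` of baseline
#' coverage times the mean follow-up proportion), multiplied by a
#' consistency term built from chronologically adjacent follow-up
#' pairs - 1 when both present, 0 when both absent, and the Poisson
#' probability `exp(-lambda)` that the single absence is a depth
#' artifact otherwise (`lambda` = absent sample's coverage times the
#' proportion in the present sample).  Adjacent pair scores are
#' multiplied pairwise along the series and the products averaged (a
#' lone pair score is used directly), so an isolated dropout is
#' forgiven when its depth made detection unlikely, while a genuine
#' transient collapses the score.
#'
#' For an ASV present at T0 a loss score is assessed: each follow-up
#' contributes 0 if the ASV is observed, otherwise
#' `absence_probability_score` of that sample's coverage times the T0
#' relative abundance; adjacent scores are multiplied pairwise and the
#' products averaged.
#'
#' @param counts matrix (1 + n_followups) x ASVs of read counts,
#'   baseline first.
#' @param coverages per-row sample coverages; defaults to row sums of
#'   `counts` (pass explicitly when `counts` is a subset of the full
#'   table).
#' @return List of two named numeric vectors in [0, 1]: `gain` and
#'   `loss`.  Structural zeros: `loss` is 0 wherever the T0 count is 0,
#'   `gain` is 0 wherever it is positive.
#' @export
patient_gain_loss_scores <- function(counts, coverages = rowSums(counts)) {
  counts <- as.matrix(counts)
  m <- nrow(counts) - 1
  if (m < 2) stop("at least 2 follow-up samples required")
  cnt0 <- counts[1, ]
  cov0 <- coverages[1]
  fu <- counts[-1, , drop = FALSE]
  cov_fu <- coverages[-1]
  present <- fu > 0
  prop <- sweep(fu, 1, cov_fu, `/`)
  n <- ncol(counts)

  # --- gain: T0 absent ---
  lambda0 <- cov0 * colMeans(prop)
  s0 <- absence_probability_score(lambda0)
  pair <- matrix(0, m - 1, n)
  for (k in seq_len(m - 1)) {
    a <- present[k, ]
    b <- present[k + 1, ]
    lam_ab <- cov_fu[k + 1] * prop[k, ]   # k present, k+1 absent
    lam_ba <- cov_fu[k] * prop[k + 1, ]   # k absent, k+1 present
    pair[k, ] <- ifelse(a & b, 1,
                        ifelse(!a & !b, 0,
                               depth_artifact_probability(
                                 ifelse(a, lam_ab, lam_ba))))
  }
  consistency <- if (m - 1 == 1) {
    pair[1, ]
  } else {
    prods <- pair[-nrow(pair), , drop = FALSE] * pair[-1, , drop = FALSE]
    colMeans(prods)
  }
  gain <- s0 * consistency
  gain[cnt0 > 0] <- 0

  # --- loss: T0 present ---
  p0 <- cnt0 / cov0
  lscore <- matrix(0, m, n)
  for (k in seq_len(m)) {
    lscore[k, ] <- ifelse(present[k, ], 0,
                          absence_probability_score(cov_fu[k] * p0))
  }
  loss <- if (m == 2) {
    lscore[1, ] * lscore[2, ]
  } else {
    prods <- lscore[-m, , drop = FALSE] * lscore[-1, , drop = FALSE]
    colMeans(prods)
  }
  loss[cnt0 == 0] <- 0

  list(gain = stats::setNames(pmin(1, gain), colnames(counts)),
       loss = stats::setNames(pmin(1, loss), colnames(counts)))
}

#' Gain score for one ASV time series
#'
#' Scalar interface to the gain branch of [patient_gain_loss_scores()];
#' the T0 count must be zero.
#'
#' @param asv_counts counts at (T0, follow-ups...), chronological.
#' @param coverages sample coverages, same length and order.
#' @return Gain score in [0, 1].
#' @export
gain_score <- function(asv_counts, coverages) {
  if (asv_counts[1] != 0) {
    stop("gain score requires a zero count at the initial time-point")
  }
  series_scores(asv_counts, coverages)$gain
}

#' Loss score for one ASV time series
#'
#' Scalar interface to the loss branch of [patient_gain_loss_scores()];
#' the T0 count must be positive.
#'
#' @inheritParams gain_score
#' @return Loss score in [0, 1].
#' @export
loss_score <- function(asv_counts, coverages) {
  if (asv_counts[1] <= 0) {
    stop("loss score requires a positive count at the initial time-point")
  }
  series_scores(asv_counts, coverages)$loss
}

series_scores <- function(asv_counts, coverages) {
  if (length(asv_counts) != length(coverages)) {
    stop("counts and coverages must align")
  }
  m <- matrix(asv_counts, ncol = 1, dimnames = list(NULL, "asv"))
  res <- patient_gain_loss_scores(m, coverages)
  list(gain = unname(res$gain), loss = unname(res$loss))
}

#' Score gains and losses across a cohort
#'
#' Applies [patient_gain_loss_scores()] to every eligible patient: one
#' with a baseline sample and at least `min_followups` follow-up
#' samples.  Ineligible patients are reported, not scored.
#'
#' @param table a [feature_table()].
#' @param meta a [cohort_metadata()] tibble.
#' @param min_followups minimum follow-up samples required (default 2).
#' @return List: `gain` and `loss` (eligible patients x ASVs score
#'   matrices), `patients` (tibble subject_id/arm/eligible/n_followups),
#'   `min_followups`.
#' @export
score_cohort_gain_loss <- function(table, meta, min_followups = 2) {
  if (min_followups < 2) stop("min_followups must be >= 2")
  tc <- build_timecourses(table, meta)
  m <- unclass(table)
  tc$eligible <- tc$has_baseline & tc$n_followups >= min_followups
  elig <- tc[tc$eligible, , drop = FALSE]
  gain <- loss <- matrix(NA_real_, nrow(elig), ncol(m),
                         dimnames = list(elig$subject_id, colnames(m)))
  for (i in seq_len(nrow(elig))) {
    samples <- c(elig$baseline_sample[i], unname(elig$followups[[i]]))
    sub <- m[samples, , drop = FALSE]
    res <- patient_gain_loss_scores(sub, rowSums(sub))
    gain[i, ] <- res$gain
    loss[i, ] <- res$loss
  }
  if (any(!tc$eligible)) {
    message(sum(!tc$eligible), " patient(s) ineligible for gain/loss ",
            "scoring (no baseline or < ", min_followups, " follow-ups)")
  }
  list(gain = gain, loss = loss,
       patients = tc[, c("subject_id", "arm", "eligible", "has_baseline",
                         "n_followups")],
       min_followups = min_followups)
}

#' Threshold gain/loss scores into ternary calls
#'
#' Lost ASVs are coded 0, unchanged 1, gained 2.  The cutoff comparison
#' is inclusive (score >= cutoff), so the printed cutoff itself makes a
#' call.
#'
#' @param scores result of [score_cohort_gain_loss()].
#' @param cutoff call threshold in (0, 1]; default 0.85.
#' @return Integer matrix patients x ASVs with values in \{0, 1, 2\}.
#' @export
call_gains_losses <- function(scores, cutoff = 0.85) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  codes <- matrix(1L, nrow(scores$gain), ncol(scores$gain),
                  dimnames = dimnames(scores$gain))
  codes[scores$gain >= cutoff] <- 2L
  codes[scores$loss >= cutoff] <- 0L
  codes
}

#' Euclidean distances and PCoA of ternary gain/loss profiles
#'
#' @param profiles ternary matrix from [call_gains_losses()] (>= 3
#'   patients).
#' @param n_axes ordination axes to retain.
#' @return List: `dm` (Euclidean distance matrix) and `ordination`
#'   ([pcoa()] result).
#' @export
ternary_distance_pcoa <- function(profiles, n_axes = 2) {
  if (nrow(profiles) < 3) stop("need at least 3 profiles")
  dm <- as.matrix(stats::dist(profiles))
  list(dm = dm, ordination = pcoa(dm, n_axes))
}

#' Permutation test for group differences in gain/loss profiles
#'
#' PERMANOVA-style pseudo-F on the Euclidean distances between ternary
#' profiles, with group labels permuted; the p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.  Delegates the
#' permutation machinery to `vegan::adonis2`.
#'
#' @param profiles ternary matrix (patients x ASVs), >= 3 per group.
#' @param group_labels factor/character of group membership (2 groups).
#' @param n_permutations at least 99; default 999.
#' @param seed optional seed fixing the permutation stream.
#' @return List: `p_value`, `pseudo_F`.
#' @export
group_trend_test <- function(profiles, group_labels, n_permutations = 999,
                             seed = NULL) {
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  if (length(unique(group_labels)) != 2) stop("exactly two groups required")
  if (min(table(group_labels)) < 3) stop("each group needs >= 3 profiles")
  d <- stats::dist(profiles)
  if (sum(d) == 0) {
    return(list(p_value = 1, pseudo_F = NA_real_))
  }
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(group = factor(group_labels))
  fit <- vegan::adonis2(d ~ group, data = df,
                        permutations = n_permutations)
  list(p_value = fit$`Pr(>F)`[1], pseudo_F = fit$F[1])
}

#' Cohort summaries of gain/loss calls
#'
#' Per-patient gain and loss counts with arm medians and Mann-Whitney
#' comparisons, per-ASV patient tallies, and (when a taxonomy is
#' supplied) per-genus summaries in the three-number layout: number of
#' ASVs changed, total events in parentheses, and the maximum number of
#' patients for any single ASV in brackets.
#'
#' @param profiles ternary matrix from [call_gains_losses()].
#' @param meta a [cohort_metadata()] tibble (for arm membership).
#' @param taxonomy optional tibble `asv`, `genus`.
#' @return List: `per_patient`, `group_summary`, `per_asv`, `per_genus`
#'   (NULL without taxonomy).
#' @export
summarize_gains_losses <- function(profiles, meta, taxonomy = NULL) {
  arms <- unique(meta[meta$role == "patient", c("subject_id", "arm")])
  per_patient <- tibble::tibble(
    subject_id = rownames(profiles),
    n_gained = unname(rowSums(profiles == 2L)),
    n_lost = unname(rowSums(profiles == 0L)))
  per_patient <- dplyr::left_join(per_patient, arms, by = "subject_id")

  group_summary <- dplyr::summarise(
    dplyr::group_by(per_patient, .data$arm),
    n_patients = dplyr::n(),
    median_gains = stats::median(.data$n_gained),
    median_losses = stats::median(.data$n_lost), .groups = "drop")
  mw <- function(metric) {
    a <- per_patient[[metric]][per_patient$arm == "FMT"]
    b <- per_patient[[metric]][per_patient$arm == "placebo"]
    if (!length(a) || !length(b)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  tests <- tibble::tibble(metric = c("gains", "losses"),
                          p_value = c(mw("n_gained"), mw("n_lost")))

  per_asv <- tibble::tibble(
    asv = colnames(profiles),
    n_patients_gaining = colSums(profiles == 2L),
    n_patients_losing = colSums(profiles == 0L))

  per_genus <- NULL
  if (!is.null(taxonomy)) {
    pa <- dplyr::inner_join(per_asv, taxonomy, by = "asv")
    triple <- function(v) {
      changed <- sum(v > 0)
      total <- sum(v)
      top <- if (length(v)) max(v) else 0
      c(changed, total, top)
    }
    per_genus <- dplyr::summarise(
      dplyr::group_by(pa, .data$genus),
      n_asvs = dplyr::n(),
      gained_asvs = triple(.data$n_patients_gaining)[1],
      gain_events = triple(.data$n_patients_gaining)[2],
      gain_max_patients = triple(.data$n_patients_gaining)[3],
      lost_asvs = triple(.data$n_patients_losing)[1],
      loss_events = triple(.data$n_patients_losing)[2],
      loss_max_patients = triple(.data$n_patients_losing)[3],
      .groups = "drop")
  }
  list(per_patient = per_patient, group_summary = group_summary,
       group_tests = tests, per_asv = per_asv, per_genus = per_genus)
}
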