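#' Chao1 richness estimator
#'
#' Adds the classical singleton/doubleton correction to observed
#' richness: `S_obs + F1^2 / (2 F2)`, where F1 and F2 are the numbers of
#' ASVs seen exactly once and twice.  When no doubletons are present the
#' bias-corrected branch `S_obs + F1 (F1 - 1) / 2` is used.  Operates on
#' raw counts; no rarefaction is applied.
#'
#' @param counts non-negative integer vector with at least one positive
#'   entry.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  counts <- check_count_vector(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

check_count_vector <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

#' Shannon and Simpson diversity with effective numbers
#'
#' Shannon entropy uses the natural log so that the effective Shannon
#' number is exactly `exp(H)`; Simpson is reported in the dominance form
#' `sum(p^2)` so that the effective Simpson number is exactly its
#' reciprocal (the Hill numbers of order 1 and 2).
#'
#' @param counts non-negative integer vector with at least one positive
#'   entry.
#' @return Named list: `shannon`, `effective_shannon`, `simpson`,
#'   `effective_simpson`.
#' @export
shannon_family <- function(counts) {
  counts <- check_count_vector(counts)
  p <- counts[counts > 0] / sum(counts)
  shannon <- -sum(p * log(p))
  simpson <- sum(p^2)
  list(shannon = shannon,
       effective_shannon = exp(shannon),
       simpson = simpson,
       effective_simpson = 1 / simpson)
}

#' Per-sample alpha-diversity table
#'
#' @param table a [feature_table()].
#' @return Tibble with one row per sample: `sample_id`, `chao1`,
#'   `shannon`, `effective_shannon`, `simpson`, `effective_simpson`.
#' @export
diversity_table <- function(table) {
  m <- unclass(table)
  rows <- lapply(rownames(m), function(s) {
    v <- m[s, ]
    fam <- shannon_family(v)
    tibble::tibble(sample_id = s, chao1 = chao1(v),
                   shannon = fam$shannon,
                   effective_shannon = fam$effective_shannon,
                   simpson = fam$simpson,
                   effective_simpson = fam$effective_simpson)
  })
  dplyr::bind_rows(rows)
}

#' Classify a patient's initial diversity against the donors'
#'
#' Normal initial diversity: baseline Chao1 at or above the donors' mean
#' minus one standard deviation.  Low: below the mean minus three
#' standard deviations.  The band in between is deliberately left as a
#' grey zone (unclassified) so that patients with near-identical
#' baseline diversity cannot land in opposite groups.  The standard
#' deviation is the sample (n-1) SD over the individual donor values.
#'
#' @param baseline_chao1 the patient's baseline Chao1 richness.
#' @param donor_chao1s Chao1 values of the donor samples (>= 2).
#' @return List: `class` ("low", "normal" or "unclassified"),
#'   `threshold_normal` (mean - 1 SD), `threshold_low` (mean - 3 SD).
#' @export
classify_initial_diversity <- function(baseline_chao1, donor_chao1s) {
  if (length(donor_chao1s) < 2) {
    stop("at least 2 donor diversity values required")
  }
  m <- mean(donor_chao1s)
  s <- stats::sd(donor_chao1s)
  thr_normal <- m - s
  thr_low <- m - 3 * s
  cls <- if (baseline_chao1 >= thr_normal) {
    "normal"
  } else if (baseline_chao1 < thr_low) {
    "low"
  } else {
    "unclassified"
  }
  list(class = cls, threshold_normal = thr_normal, threshold_low = thr_low)
}

#' Classify every patient's initial diversity
#'
#' @param table a [feature_table()].
#' @param meta a [cohort_metadata()] tibble.
#' @return Tibble: `subject_id`, `arm`, `baseline_chao1`, `class`, plus
#'   the thresholds used.
#' @export
initial_diversity_classes <- function(table, meta) {
  m <- unclass(table)
  donors <- meta$sample_id[meta$role == "donor"]
  donors <- intersect(donors, rownames(m))
  donor_vals <- vapply(donors, function(s) chao1(m[s, ]), numeric(1))
  base <- meta[meta$role == "patient" & meta$timepoint == "baseline", ]
  base <- base[base$sample_id %in% rownames(m), ]
  rows <- lapply(seq_len(nrow(base)), function(i) {
    bc <- chao1(m[base$sample_id[i], ])
    cl <- classify_initial_diversity(bc, donor_vals)
    tibble::tibble(subject_id = base$subject_id[i], arm = base$arm[i],
                   baseline_chao1 = bc, class = cl$class,
                   threshold_normal = cl$threshold_normal,
                   threshold_low = cl$threshold_low)
  })
  dplyr::bind_rows(rows)
}

#' Per-patient diversity change from baseline, with group tests
#'
#' For each patient with a baseline sample, computes the change in a
#' diversity metric at every available follow-up relative to baseline.
#' Within each arm and time-point the changes are tested against zero
#' with a paired t-test (equivalently a one-sample t-test on the
#' deltas), and FMT is compared with placebo by a two-sample t-test on
#' the deltas.  Degenerate cases (all deltas identical, or fewer than
#' two patients) are reported as "no difference" with p = 1.
#'
#' @param records per-sample diversity tibble from [diversity_table()].
#' @param meta a [cohort_metadata()] tibble.
#' @param metric which column of `records` to track (default `"chao1"`).
#' @return List of two tibbles: `deltas` (subject_id, arm, timepoint,
#'   baseline_value, value, delta) and `tests` (arm/timepoint paired
#'   t-test plus the FMT-vs-placebo two-sample test per timepoint).
#' @export
diversity_change_table <- function(records, meta, metric = "chao1") {
  if (!metric %in% names(records)) stop("unknown metric: ", metric)
  pat <- meta[meta$role == "patient", ]
  rec <- dplyr::inner_join(records, pat, by = "sample_id")
  base <- rec[rec$timepoint == "baseline",
              c("subject_id", metric)]
  names(base)[2] <- "baseline_value"
  no_base <- setdiff(unique(pat$subject_id), base$subject_id)
  if (length(no_base)) {
    message("excluding patients without baseline: ",
            paste(no_base, collapse = ", "))
  }
  fu <- rec[rec$timepoint != "baseline", ]
  deltas <- dplyr::inner_join(fu, base, by = "subject_id")
  deltas$value <- deltas[[metric]]
  deltas$delta <- deltas$value - deltas$baseline_value
  deltas <- deltas[, c("subject_id", "arm", "timepoint", "baseline_value",
                       "value", "delta")]
  deltas <- tibble::as_tibble(deltas)

  safe_p <- function(expr) {
    tryCatch(expr, error = function(e) 1)
  }
  one_sample <- function(d) {
    if (length(d) < 2 || stats::sd(d) == 0) {
      return(if (length(d) && mean(d) == 0) 1 else 1)
    }
    safe_p(stats::t.test(d)$p.value)
  }
  two_sample <- function(a, b) {
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0)) {
      return(1)
    }
    safe_p(stats::t.test(a, b)$p.value)
  }

  tps <- intersect(patient_timepoints(), unique(deltas$timepoint))
  tests <- lapply(tps, function(tp) {
    d_tp <- deltas[deltas$timepoint == tp, ]
    arms_here <- unique(d_tp$arm)
    within <- lapply(arms_here, function(a) {
      d <- d_tp$delta[d_tp$arm == a]
      tibble::tibble(timepoint = tp, comparison = "baseline-vs-followup",
                     arm = a, n = length(d), mean_delta = mean(d),
                     p_value = one_sample(d))
    })
    between <- NULL
    if (all(c("FMT", "placebo") %in% arms_here)) {
      a <- d_tp$delta[d_tp$arm == "FMT"]
      b <- d_tp$delta[d_tp$arm == "placebo"]
      between <- tibble::tibble(timepoint = tp, comparison = "FMT-vs-placebo",
                                arm = NA_character_, n = length(a) + length(b),
                                mean_delta = mean(a) - mean(b),
                                p_value = two_sample(a, b))
    }
    dplyr::bind_rows(c(within, list(between)))
  })
  list(deltas = deltas, tests = dplyr::bind_rows(tests))
}
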