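#' Clinical response from IBS-SSS change
#'
#' A patient responds when the IBS Symptom Severity Score decreases by
#' at least 50 points at 3 months relative to baseline (boundary
#' inclusive).
#'
#' @param baseline_sss,m3_sss scores in [0, 500]; `m3_sss` may be NA
#'   (returns NA so the subject can be excluded and logged).
#' @return Logical (vectorized).
#' @export
classify_response <- function(baseline_sss, m3_sss) {
  check_sss(baseline_sss, allow_na = TRUE)
  check_sss(m3_sss, allow_na = TRUE)
  ifelse(is.na(baseline_sss) | is.na(m3_sss), NA,
         baseline_sss - m3_sss >= 50)
}

check_sss <- function(x, allow_na = FALSE) {
  if (!allow_na && anyNA(x)) stop("missing IBS-SSS value")
  bad <- !is.na(x) & (x < 0 | x > 500)
  if (any(bad)) stop("IBS-SSS outside [0, 500]")
  invisible(x)
}

#' IBS severity category from IBS-SSS
#'
#' Bands: below 75 remission, 75 to under 175 mild, 175 to 300 moderate,
#' above 300 severe.  The shared boundary at 175 goes to moderate (the
#' bands are half-open below) and 300 itself is moderate.
#'
#' @param sss score(s) in [0, 500].
#' @return Character vector of categories.
#' @export
severity_category <- function(sss) {
  check_sss(sss)
  cut_points <- cut(sss, breaks = c(-Inf, 75, 175, 300, Inf),
                    labels = c("remission", "mild", "moderate", "severe"),
                    right = FALSE)
  out <- as.character(cut_points)
  out[sss == 300] <- "moderate"  # "more than 300" reads strictly greater
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param p_values numeric vector in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential ASV abundance between two groups at one time-point
#'
#' Two-sided Mann-Whitney U test on relative abundances per ASV, with
#' Benjamini-Hochberg adjustment across all tested ASVs.  ASVs absent
#' from every sample of both groups are skipped.  R's `wilcox.test`
#' supplies the machinery: exact when the combined sample size is small
#' and tie-free, otherwise the normal approximation with tie
#' correction.
#'
#' @param table a [feature_table()].
#' @param meta a [cohort_metadata()] tibble.
#' @param group_a,group_b arm labels to compare (matched against `arm`).
#' @param timepoint time-point at which to compare.
#' @param alpha significance level on the adjusted p-values.
#' @return Tibble per tested ASV: `asv`, `p_value`, `p_adjusted`,
#'   `direction` (sign of mean difference, group_a minus group_b),
#'   `significant`.
#' @export
differential_abundance <- function(table, meta, group_a = "FMT",
                                   group_b = "placebo", timepoint = "m3",
                                   alpha = 0.05) {
  sel <- function(arm) {
    ids <- meta$sample_id[meta$role == "patient" & meta$arm == arm &
                            meta$timepoint == timepoint]
    intersect(ids, rownames(table))
  }
  ids_a <- sel(group_a)
  ids_b <- sel(group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("both groups need >= 2 samples at ", timepoint)
  }
  m <- unclass(table)
  ra <- m[c(ids_a, ids_b), , drop = FALSE] /
    rowSums(m[c(ids_a, ids_b), , drop = FALSE])
  in_a <- seq_along(ids_a)
  keep <- colSums(ra) > 0
  tested <- colnames(ra)[keep]
  p <- vapply(tested, function(asv) {
    x <- ra[in_a, asv]
    y <- ra[-in_a, asv]
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  direction <- vapply(tested, function(asv) {
    sign(mean(ra[in_a, asv]) - mean(ra[-in_a, asv]))
  }, numeric(1))
  adj <- bh_adjust(p)
  tibble::tibble(asv = tested, p_value = unname(p),
                 p_adjusted = unname(adj), direction = unname(direction),
                 significant = unname(adj) <= alpha)
}

#' Spearman correlation screen
#'
#' Spearman rank correlation with the joint pass criterion used for
#' diversity-symptom screens: p <= `p_max` and rho^2 >= `r2_min`.
#' Constant series leave rho undefined; the screen fails with a reason.
#'
#' @param x,y paired numeric vectors (n >= 4 after removing missing
#'   pairs).
#' @param p_max,r2_min pass criteria (defaults 0.05 and 0.15).
#' @return Tibble row: `n`, `rho`, `r_squared`, `p_value`, `pass`,
#'   `reason`.
#' @export
spearman_screen <- function(x, y, p_max = 0.05, r2_min = 0.15) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(n = length(x), rho = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          pass = FALSE, reason = "constant series"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  r2 <- rho^2
  pass <- ct$p.value <= p_max && r2 >= r2_min
  reason <- if (pass) {
    "meets both criteria"
  } else if (ct$p.value > p_max && r2 < r2_min) {
    "fails p and R2 criteria"
  } else if (ct$p.value > p_max) {
    "fails p criterion"
  } else {
    "fails R2 criterion"
  }
  tibble::tibble(n = length(x), rho = rho, r_squared = r2,
                 p_value = ct$p.value, pass = pass, reason = reason)
}

#' Clinical status table for a cohort
#'
#' Derives responder status and per-time-point severity categories from
#' the IBS-SSS values carried in the metadata.
#'
#' @param meta a [cohort_metadata()] tibble with `ibs_sss` populated for
#'   patient samples.
#' @return Tibble per patient: `subject_id`, `arm`, `baseline_sss`,
#'   `m3_sss`, `responder`, and `severity_<timepoint>` columns.
#' @export
clinical_status <- function(meta) {
  pat <- meta[meta$role == "patient" & !is.na(meta$ibs_sss), ]
  wide <- tidyr::pivot_wider(pat[, c("subject_id", "arm", "timepoint",
                                     "ibs_sss")],
                             names_from = "timepoint",
                             values_from = "ibs_sss")
  for (tp in patient_timepoints()) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  missing_m3 <- wide$subject_id[is.na(wide$m3) | is.na(wide$baseline)]
  if (length(missing_m3)) {
    message("subjects without baseline or 3-month IBS-SSS left ",
            "unclassified: ", paste(missing_m3, collapse = ", "))
  }
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    arm = wide$arm,
    baseline_sss = wide$baseline,
    m3_sss = wide$m3,
    responder = ifelse(is.na(wide$baseline) | is.na(wide$m3), NA,
                       classify_response(wide$baseline, wide$m3)))
  for (tp in patient_timepoints()) {
    out[[paste0("severity_", tp)]] <-
      ifelse(is.na(wide[[tp]]), NA_character_,
             severity_category(tidyr::replace_na(wide[[tp]], 0)))
  }
  out
}
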