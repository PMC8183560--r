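#' Configuration for a synthetic FMT trial cohort
#'
#' Defaults emulate a capsule-FMT trial in IBS: ~52 patients randomized
#' 1:1 to FMT or placebo, sampled at baseline and four follow-ups (2
#' weeks, 1, 3 and 6 months), 4 stool donors, ~2,000 ASVs, and per-sample
#' sequencing depth spanning 6,483-113,847 reads.  Latent communities
#' are log-normal (sigma ~ 2), giving the long tail of rare ASVs where
#' depth-aware presence calling matters.  Donors draw from a pool of
#' donor-enriched ASVs absent from all patient baselines, so engraftment
#' has an unambiguous planted truth.
#'
#' @param n_fmt_patients,n_placebo_patients patients per arm.
#' @param n_donors number of stool donors (one sample each).
#' @param n_asvs total ASVs in the simulated universe.
#' @param depth_range min/max reads per sample; realized depths are drawn
#'   log-uniformly between them.
#' @param n_planted_gains,n_planted_losses,n_planted_transients planted
#'   events per FMT patient.
#' @param planted_post_proportion latent relative abundance given to
#'   planted gains (and transient appearances) in follow-up profiles.
#' @param placebo_fluctuation_rate per-ASV per-follow-up probability of a
#'   spontaneous appearance or disappearance (both arms).
#' @param donor_pool_frac fraction of ASVs reserved for the
#'   donor-enriched pool.
#' @param donor_richness_frac per-donor richness within the
#'   donor-enriched pool, as a fraction of that pool.
#' @param donor_common_frac additional per-donor richness drawn from the
#'   shared (patient-accessible) pool, as a fraction of `n_asvs`; real
#'   donors carry plenty of taxa their recipients also have, and this
#'   keeps donor diversity at or above patient diversity.
#' @param donor_richness_spread relative spread of per-donor richness
#'   (uniform in 1 +/- spread); donors are individuals, not replicates,
#'   and the spread keeps the donor-anchored classification thresholds
#'   honestly wide.
#' @param normal_richness_frac,low_richness_frac baseline richness of
#'   normal- and low-diversity patients as fractions of `n_asvs`.
#' @param low_diversity_frac fraction of patients (per arm) constructed
#'   with low baseline richness.
#' @param donor_mix_low,donor_mix_normal donor-community mixing
#'   proportion in FMT follow-up profiles for low-/normal-diversity
#'   recipients; engraftment is stronger where baseline diversity (and
#'   hence colonization resistance) is low.
#' @param baseline_sigma log-normal sigma of latent baseline abundances.
#' @param followup_noise_sd sd of multiplicative log-normal noise applied
#'   to the baseline component of every follow-up profile.
#' @param dropout_rate probability that any given follow-up visit is
#'   missing (baselines are always retained).
#' @param response_rate_fmt,response_rate_placebo fraction of patients
#'   per arm designated clinical responders (IBS-SSS decrease >= 50 at 3
#'   months).
#' @param min_loss_proportion minimum latent baseline proportion an ASV
#'   must have to be eligible as a planted loss (so the loss is
#'   detectable at the shallowest depths).
#' @param rng_seed integer seed; identical configurations give
#'   bit-identical cohorts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_fmt_patients = 26,
                              n_placebo_patients = 26,
                              n_donors = 4,
                              n_asvs = 2000,
                              depth_range = c(6483, 113847),
                              n_planted_gains = 50,
                              n_planted_losses = 30,
                              n_planted_transients = 50,
                              planted_post_proportion = 0.002,
                              placebo_fluctuation_rate = 0.005,
                              donor_pool_frac = 0.25,
                              donor_richness_frac = 0.9,
                              donor_common_frac = 0.3,
                              donor_richness_spread = 0.15,
                              normal_richness_frac = 0.6,
                              low_richness_frac = 0.08,
                              low_diversity_frac = 0.3,
                              donor_mix_low = 0.45,
                              donor_mix_normal = 0.25,
                              baseline_sigma = 2,
                              followup_noise_sd = 0.4,
                              dropout_rate = 0.2,
                              response_rate_fmt = 8 / 21,
                              response_rate_placebo = 19 / 24,
                              min_loss_proportion = 1e-3,
                              rng_seed = 1) {
  cfg <- list(n_fmt_patients = n_fmt_patients,
              n_placebo_patients = n_placebo_patients,
              n_donors = n_donors, n_asvs = n_asvs,
              depth_range = depth_range,
              n_planted_gains = n_planted_gains,
              n_planted_losses = n_planted_losses,
              n_planted_transients = n_planted_transients,
              planted_post_proportion = planted_post_proportion,
              placebo_fluctuation_rate = placebo_fluctuation_rate,
              donor_pool_frac = donor_pool_frac,
              donor_richness_frac = donor_richness_frac,
              donor_common_frac = donor_common_frac,
              donor_richness_spread = donor_richness_spread,
              normal_richness_frac = normal_richness_frac,
              low_richness_frac = low_richness_frac,
              low_diversity_frac = low_diversity_frac,
              donor_mix_low = donor_mix_low,
              donor_mix_normal = donor_mix_normal,
              baseline_sigma = baseline_sigma,
              followup_noise_sd = followup_noise_sd,
              dropout_rate = dropout_rate,
              response_rate_fmt = response_rate_fmt,
              response_rate_placebo = response_rate_placebo,
              min_loss_proportion = min_loss_proportion,
              rng_seed = rng_seed)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_fmt_patients >= 0, cfg$n_placebo_patients >= 0,
            cfg$n_donors >= 1, cfg$n_asvs >= 10)
  if (cfg$depth_range[1] > cfg$depth_range[2] || cfg$depth_range[1] < 1) {
    stop("invalid depth_range")
  }
  counts <- c(cfg$n_planted_gains, cfg$n_planted_losses,
              cfg$n_planted_transients)
  if (any(counts < 0)) stop("planted event counts must be >= 0")
  props <- c(cfg$planted_post_proportion, cfg$placebo_fluctuation_rate)
  if (cfg$planted_post_proportion <= 0 || cfg$planted_post_proportion >= 1) {
    stop("planted_post_proportion must lie in (0, 1)")
  }
  if (cfg$placebo_fluctuation_rate < 0 || cfg$placebo_fluctuation_rate >= 1) {
    stop("placebo_fluctuation_rate must lie in [0, 1)")
  }
  donor_pool <- round(cfg$donor_pool_frac * cfg$n_asvs)
  if (cfg$n_planted_gains + cfg$n_planted_transients > donor_pool) {
    stop("planted gains + transients exceed the donor-enriched ASV pool")
  }
  low_rich <- round(cfg$low_richness_frac * cfg$n_asvs)
  if (cfg$n_planted_losses > low_rich) {
    stop("planted losses exceed low-diversity baseline richness")
  }
  patient_pool <- cfg$n_asvs - donor_pool
  if (round(cfg$normal_richness_frac * cfg$n_asvs) > patient_pool) {
    stop("normal baseline richness exceeds the patient ASV pool")
  }
  spread <- cfg$donor_richness_spread %||% 0
  if (round((1 + spread) * cfg$donor_common_frac * cfg$n_asvs) >
        patient_pool) {
    stop("donor_common_frac exceeds the shared ASV pool")
  }
  invisible(cfg)
}

draw_depth <- function(n, depth_range) {
  lo <- log(depth_range[1])
  hi <- log(depth_range[2])
  pmin(depth_range[2], pmax(depth_range[1], round(exp(stats::runif(n, lo, hi)))))
}

draw_counts <- function(depth, prob) {
  x <- stats::rmultinom(1, depth, prob)[, 1]
  names(x) <- names(prob)
  x
}

#' Simulate a synthetic FMT trial cohort with planted ground truth
#'
#' Builds latent relative-abundance profiles per subject and time-point,
#' draws observed counts multinomially at a log-uniform sequencing
#' depth, and records which ASVs were truly gained, lost, or transiently
#' present in each FMT patient.  Placebo follow-ups perturb the baseline
#' by multiplicative log-normal noise plus rare spontaneous
#' appearance/disappearance; FMT follow-ups additionally mix in the
#' pooled donor community and apply the planted-event overrides.  One
#' RNG stream is split per subject, so adding a patient does not perturb
#' the other patients' draws.
#'
#' @param config a [simulation_config()].
#' @return List with elements `table` (a [feature_table()]), `meta`
#'   (a [cohort_metadata()] tibble), `tree` (random `phylo` over the
#'   ASVs with exponential branch lengths), `truth` (planted-event
#'   ledger; see Details), and `taxonomy` (tibble `asv`, `genus`).
#'
#' @details `truth` is a list: `events` (tibble subject_id/asv/event in
#'   gain, loss, transient, with the follow-up indices at which a
#'   transient appears), `diversity_class` (intended low/normal per
#'   patient), `clinical` (responder flag and IBS-SSS per time-point),
#'   and `donor_pool` (the donor-enriched ASV ids).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$rng_seed)
  n_asvs <- cfg$n_asvs
  asv_ids <- sprintf("asv%05d", seq_len(n_asvs))
  fu_tps <- c("d15", "m1", "m3", "m6")

  donor_pool_size <- round(cfg$donor_pool_frac * n_asvs)
  donor_pool <- sort(sample(asv_ids, donor_pool_size))
  patient_pool <- setdiff(asv_ids, donor_pool)

  tree <- ape::rtree(n_asvs, tip.label = sample(asv_ids), br = stats::rexp)

  # donor communities: shared enriched pool, individual log-normal profiles
  donor_rich <- round(cfg$donor_richness_frac * donor_pool_size)
  donor_common <- round(cfg$donor_common_frac * n_asvs)
  donor_prof <- matrix(0, cfg$n_donors, n_asvs,
                       dimnames = list(NULL, asv_ids))
  for (d in seq_len(cfg$n_donors)) {
    scale_d <- stats::runif(1, 1 - cfg$donor_richness_spread,
                            1 + cfg$donor_richness_spread)
    rep_d <- c(sample(donor_pool, min(donor_pool_size,
                                      round(scale_d * donor_rich))),
               sample(patient_pool, round(scale_d * donor_common)))
    ab <- stats::rlnorm(length(rep_d), 0, cfg$baseline_sigma)
    donor_prof[d, rep_d] <- ab / sum(ab)
  }
  donor_mix <- colMeans(donor_prof)
  # planted gains must be identifiable: donor-enriched taxa only
  enriched_mix <- donor_mix[donor_pool]
  gain_candidates <- names(sort(enriched_mix, decreasing = TRUE))[
    seq_len(min(2 * max(cfg$n_planted_gains, 1), sum(enriched_mix > 0)))]

  n_pat <- cfg$n_fmt_patients + cfg$n_placebo_patients
  subject_ids <- c(sprintf("F%02d", seq_len(cfg$n_fmt_patients)),
                   sprintf("C%02d", seq_len(cfg$n_placebo_patients)))
  arms <- rep(c("FMT", "placebo"),
              c(cfg$n_fmt_patients, cfg$n_placebo_patients))
  # deterministic low-diversity assignment: first k patients of each arm
  n_low_fmt <- round(cfg$low_diversity_frac * cfg$n_fmt_patients)
  n_low_pla <- round(cfg$low_diversity_frac * cfg$n_placebo_patients)
  low_flag <- c(seq_len(cfg$n_fmt_patients) <= n_low_fmt,
                seq_len(cfg$n_placebo_patients) <= n_low_pla)

  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_pat + 1L)

  rows <- list()       # count vectors, named by sample id
  meta_rows <- list()
  event_rows <- list()

  # donor samples (global stream)
  for (d in seq_len(cfg$n_donors)) {
    sid <- sprintf("D%d", d)
    samp <- sprintf("%s_donor", sid)
    depth <- draw_depth(1, cfg$depth_range)
    rows[[samp]] <- draw_counts(depth, donor_prof[d, ])
    meta_rows[[samp]] <- tibble::tibble(sample_id = samp, subject_id = sid,
                                        role = "donor",
                                        arm = "not-applicable",
                                        timepoint = "donor",
                                        ibs_sss = NA_real_)
  }

  normal_rich <- round(cfg$normal_richness_frac * n_asvs)
  low_rich <- round(cfg$low_richness_frac * n_asvs)

  for (i in seq_len(n_pat)) {
    set.seed(subject_seeds[i])
    sid <- subject_ids[i]
    is_fmt <- arms[i] == "FMT"
    rich <- if (low_flag[i]) low_rich else normal_rich
    repertoire <- sample(patient_pool, rich)
    base <- stats::setNames(numeric(n_asvs), asv_ids)
    base[repertoire] <- stats::rlnorm(rich, 0, cfg$baseline_sigma)
    base <- base / sum(base)

    gains <- losses <- transients <- character(0)
    transient_tps <- list()
    if (is_fmt) {
      if (cfg$n_planted_gains > 0) {
        gains <- sample(gain_candidates, cfg$n_planted_gains)
      }
      if (cfg$n_planted_losses > 0) {
        eligible <- names(base)[base >= cfg$min_loss_proportion]
        if (length(eligible) >= cfg$n_planted_losses) {
          losses <- sample(eligible, cfg$n_planted_losses)
        } else {
          losses <- names(sort(base, decreasing = TRUE))[
            seq_len(cfg$n_planted_losses)]
        }
      }
      if (cfg$n_planted_transients > 0) {
        transients <- sample(setdiff(donor_pool, gains),
                             cfg$n_planted_transients)
        transient_tps <- lapply(transients, function(a) {
          sort(sample(seq_along(fu_tps), sample(1:2, 1)))
        })
        names(transient_tps) <- transients
      }
    }
    planted <- c(gains, losses, transients)
    mix_p <- if (!is_fmt) 0 else {
      if (low_flag[i]) cfg$donor_mix_low else cfg$donor_mix_normal
    }

    # baseline observation
    samp0 <- sprintf("%s_baseline", sid)
    depth0 <- draw_depth(1, cfg$depth_range)
    rows[[samp0]] <- draw_counts(depth0, base)
    meta_rows[[samp0]] <- tibble::tibble(sample_id = samp0, subject_id = sid,
                                         role = "patient", arm = arms[i],
                                         timepoint = "baseline",
                                         ibs_sss = NA_real_)

    keep_fu <- stats::runif(length(fu_tps)) >= cfg$dropout_rate
    for (j in seq_along(fu_tps)) {
      noise <- exp(stats::rnorm(n_asvs, 0, cfg$followup_noise_sd))
      prof <- base * noise
      prof <- prof / sum(prof)
      if (mix_p > 0) prof <- (1 - mix_p) * prof + mix_p * donor_mix
      if (cfg$placebo_fluctuation_rate > 0) {
        open <- !(asv_ids %in% planted)
        absent <- open & prof == 0
        appear <- absent & stats::runif(n_asvs) < cfg$placebo_fluctuation_rate
        prof[appear] <- cfg$planted_post_proportion
        present <- open & prof > 0
        vanish <- present & stats::runif(n_asvs) < cfg$placebo_fluctuation_rate
        prof[vanish] <- 0
      }
      if (length(gains)) prof[gains] <- cfg$planted_post_proportion
      if (length(losses)) prof[losses] <- 0
      for (a in transients) {
        prof[a] <- if (j %in% transient_tps[[a]]) {
          cfg$planted_post_proportion
        } else {
          0
        }
      }
      prof <- prof / sum(prof)
      if (!keep_fu[j]) next
      samp <- sprintf("%s_%s", sid, fu_tps[j])
      depth <- draw_depth(1, cfg$depth_range)
      rows[[samp]] <- draw_counts(depth, prof)
      meta_rows[[samp]] <- tibble::tibble(sample_id = samp, subject_id = sid,
                                          role = "patient", arm = arms[i],
                                          timepoint = fu_tps[j],
                                          ibs_sss = NA_real_)
    }

    if (length(planted)) {
      event_rows[[sid]] <- tibble::tibble(
        subject_id = sid,
        asv = c(gains, losses, transients),
        event = rep(c("gain", "loss", "transient"),
                    c(length(gains), length(losses), length(transients))),
        followups = c(rep(NA_character_, length(gains) + length(losses)),
                      vapply(transient_tps, paste, "", collapse = ",")))
    }
  }

  counts <- do.call(rbind, rows)
  table <- feature_table(counts)

  truth <- list(
    events = if (length(event_rows)) dplyr::bind_rows(event_rows) else
      tibble::tibble(subject_id = character(), asv = character(),
                     event = character(), followups = character()),
    diversity_class = tibble::tibble(
      subject_id = subject_ids, arm = arms,
      intended_class = ifelse(low_flag, "low", "normal")),
    clinical = NULL,
    donor_pool = donor_pool,
    config = cfg)
  class(truth) <- "synthetic_truth"

  truth <- simulate_ibs_sss(cfg, truth, seed = subject_seeds[n_pat + 1L])

  meta <- dplyr::bind_rows(meta_rows)
  sss_long <- tidyr::pivot_longer(truth$clinical,
                                  cols = dplyr::ends_with("_sss"),
                                  names_to = "timepoint",
                                  values_to = "sss_value")
  sss_long$timepoint <- sub("_sss$", "", sss_long$timepoint)
  meta <- dplyr::left_join(meta,
                           sss_long[, c("subject_id", "timepoint",
                                        "sss_value")],
                           by = c("subject_id", "timepoint"))
  meta$ibs_sss <- ifelse(meta$role == "patient", meta$sss_value, NA_real_)
  meta$sss_value <- NULL
  meta <- cohort_metadata(as.data.frame(meta))

  taxonomy <- tibble::tibble(
    asv = asv_ids,
    genus = sprintf("genus%03d", ceiling(seq_len(n_asvs) / 20)))

  list(table = table, meta = meta, tree = tree, truth = truth,
       taxonomy = taxonomy)
}

#' Simulate IBS symptom severity time-courses
#'
#' Baseline IBS-SSS is drawn uniformly in 171-485 (the span seen in
#' moderate-to-severe IBS trial populations).  Designated responders
#' receive a 3-month decrease of at least 50 points; non-responders a
#' change below that threshold.  Intermediate and 6-month scores follow
#' a noisy linear trend toward the 3-month value.  All scores are
#' clipped to [0, 500].
#'
#' @param config a [simulation_config()].
#' @param truth a partial truth object holding `diversity_class` (one
#'   row per patient with `subject_id` and `arm`).
#' @param seed optional integer seed for the clinical draws.
#' @return `truth` with a populated `clinical` tibble.
#' @export
simulate_ibs_sss <- function(config, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- truth$diversity_class
  n <- nrow(subj)
  n_resp_fmt <- round(config$response_rate_fmt * sum(subj$arm == "FMT"))
  n_resp_pla <- round(config$response_rate_placebo *
                        sum(subj$arm == "placebo"))
  responder <- logical(n)
  responder[sample(which(subj$arm == "FMT"),
                   min(n_resp_fmt, sum(subj$arm == "FMT")))] <- TRUE
  responder[sample(which(subj$arm == "placebo"),
                   min(n_resp_pla, sum(subj$arm == "placebo")))] <- TRUE

  baseline <- round(stats::runif(n, 171, 485))
  decrease <- ifelse(responder,
                     50 + round(stats::rexp(n, 1 / 40)),
                     round(stats::runif(n, -60, 49)))
  clip <- function(x) pmin(500, pmax(0, round(x)))
  m3 <- clip(baseline - decrease)
  wiggle <- function(frac) {
    clip(baseline + frac * (m3 - baseline) + stats::rnorm(n, 0, 25))
  }
  truth$clinical <- tibble::tibble(
    subject_id = subj$subject_id,
    arm = subj$arm,
    responder = responder,
    baseline_sss = baseline,
    d15_sss = wiggle(0.5),
    m1_sss = wiggle(0.8),
    m3_sss = m3,
    m6_sss = wiggle(1.0))
  truth
}

#' Write the planted-event ledger to TSV
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_events <- function(truth, path) {
  utils::write.table(as.data.frame(truth$events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
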