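#' Run the full engraftment analysis
#'
#' Orchestrates the stages — input (or simulation), alpha diversity and
#' initial-diversity classes, beta diversity relative to donors,
#' gain/loss scoring and calling, source-attribution engraftment
#' scores, and the clinical/statistical screens — writing one TSV per
#' product plus a JSON manifest echoing every threshold actually used.
#' Identical configuration and seed give identical outputs.
#'
#' @param config list with either `simulation` (a [simulation_config()])
#'   or `paths` (list `table`, `meta`, `tree`, and optional
#'   `orientation`), plus optional `cutoff` (default 0.85),
#'   `min_followups` (2), `gunifrac_alpha` (0.5), `n_permutations`
#'   (999), `rng_seed` (1), and `out_dir`.
#' @return Invisibly, a list of the in-memory stage results; files are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cutoff <- config$cutoff %||% 0.85
  min_followups <- config$min_followups %||% 2
  g_alpha <- config$gunifrac_alpha %||% 0.5
  n_perm <- config$n_permutations %||% 999
  seed <- config$rng_seed %||% 1
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  if (!is.null(config$simulation) && !is.null(config$paths)) {
    stop("supply exactly one of simulation or paths")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(cutoff = cutoff, min_followups = min_followups,
                   gunifrac_alpha = g_alpha, n_permutations = n_perm,
                   rng_seed = seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] done")
  }

  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    table <- sim$table; meta <- sim$meta; tree <- sim$tree
    taxonomy <- sim$taxonomy
    write_feature_table(table, file.path(out_dir, "feature_table.tsv"))
    write_metadata(meta, file.path(out_dir, "metadata.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_truth_events(sim$truth, file.path(out_dir, "truth_events.tsv"))
    log_stage("simulate", n_samples = nrow(table), n_asvs = ncol(table))
  } else {
    p <- config$paths
    table <- read_feature_table(p$table,
                                orientation = p$orientation %||%
                                  "samples-as-rows")
    meta <- read_metadata(p$meta)
    tree <- if (!is.null(p$tree)) read_tree(p$tree) else NULL
    taxonomy <- if (!is.null(p$taxonomy)) {
      tibble::as_tibble(utils::read.delim(p$taxonomy,
                                          stringsAsFactors = FALSE))
    } else {
      NULL
    }
    sim <- NULL
    log_stage("input", n_samples = nrow(table), n_asvs = ncol(table))
  }

  div <- diversity_table(table)
  classes <- initial_diversity_classes(table, meta)
  change <- diversity_change_table(div, meta, metric = "chao1")
  tsv(div, "diversity.tsv")
  tsv(classes, "diversity_classes.tsv")
  tsv(change$tests, "diversity_change_tests.tsv")
  log_stage("alpha", n_samples = nrow(div),
            n_low = sum(classes$class == "low"))

  beta <- NULL
  if (!is.null(tree)) {
    beta <- donor_distance_course(table, meta, tree, alpha = g_alpha)
    tsv(beta$distances, "donor_distances.tsv")
    tsv(beta$tests, "donor_distance_tests.tsv")
    log_stage("beta", n_patient_samples = nrow(beta$distances))
  } else {
    message("[beta] skipped: no tree supplied")
  }

  scores <- score_cohort_gain_loss(table, meta,
                                   min_followups = min_followups)
  calls <- call_gains_losses(scores, cutoff = cutoff)
  summ <- summarize_gains_losses(calls, meta, taxonomy)
  trend <- NULL
  arms <- summ$per_patient$arm
  if (sum(arms == "FMT") >= 3 && sum(arms == "placebo") >= 3) {
    trend <- group_trend_test(calls, arms, n_permutations = n_perm,
                              seed = seed)
  }
  tsv(tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(scores$gain),
                  subject_id = rownames(scores$gain)),
    -dplyr::all_of("subject_id"), names_to = "asv",
    values_to = "gain_score"), "gain_scores.tsv")
  tsv(tibble::as_tibble(calls, rownames = "subject_id"),
      "gainloss_calls.tsv")
  tsv(summ$per_patient, "gainloss_per_patient.tsv")
  tsv(summ$group_summary, "gainloss_group_summary.tsv")
  if (!is.null(summ$per_genus)) tsv(summ$per_genus, "gainloss_per_genus.tsv")
  log_stage("gainloss", n_scored = nrow(calls),
            trend_p = if (is.null(trend)) NA else trend$p_value)

  engraft <- NULL
  fmt_present <- any(meta$arm == "FMT")
  if (fmt_present && any(meta$arm == "placebo") &&
      any(meta$role == "donor")) {
    engraft <- pipeline_engraftment(table, meta, taxonomy)
    if (!is.null(engraft)) {
      tsv(engraft, "engraftment_scores.tsv")
      log_stage("engraft", n_nodes = nrow(engraft))
    }
  } else {
    message("[engraft] skipped: needs both arms and donor samples")
  }

  clinical <- clinical_status(meta)
  tsv(clinical, "clinical.tsv")
  screens <- tryCatch(
    differential_abundance(table, meta, timepoint = "m3"),
    error = function(e) NULL)
  if (!is.null(screens)) tsv(screens, "differential_abundance_m3.tsv")
  log_stage("stats", n_responders = sum(clinical$responder, na.rm = TRUE))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(table = table, meta = meta, tree = tree, truth = sim$truth,
                 diversity = div, classes = classes, change = change,
                 beta = beta, scores = scores, calls = calls,
                 summary = summ, trend = trend, engraftment = engraft,
                 clinical = clinical, screens = screens))
}

# naive attribution of every m3 sink against donors + own baseline,
# then genus-level scores with the placebo floor
pipeline_engraftment <- function(table, meta, taxonomy) {
  m <- unclass(table)
  donors <- meta$sample_id[meta$role == "donor"]
  donors <- intersect(donors, rownames(m))
  donor_sources <- stats::setNames(lapply(donors, function(d) m[d, ]), donors)
  sinks <- meta[meta$role == "patient" & meta$timepoint == "m3" &
                  meta$sample_id %in% rownames(m), ]
  base <- meta[meta$role == "patient" & meta$timepoint == "baseline", ]
  attr_arm <- function(arm) {
    rows <- sinks[sinks$arm == arm, ]
    out <- list()
    for (i in seq_len(nrow(rows))) {
      b <- base$sample_id[base$subject_id == rows$subject_id[i]]
      if (!length(b) || !b %in% rownames(m)) next
      sources <- c(donor_sources,
                   stats::setNames(list(m[b, ]), "pretreatment"))
      out[[rows$sample_id[i]]] <- naive_attribution(
        m[rows$sample_id[i], ], sources, sink_id = rows$sample_id[i])
    }
    if (!length(out)) return(NULL)
    dplyr::bind_rows(out)
  }
  attr_fmt <- attr_arm("FMT")
  attr_pla <- attr_arm("placebo")
  if (is.null(attr_fmt) || is.null(attr_pla) || is.null(taxonomy)) {
    return(NULL)
  }
  node_map <- tibble::tibble(asv = taxonomy$asv, node = taxonomy$genus)
  taxon_engraftment_scores(attr_fmt, attr_pla, node_map, donors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
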