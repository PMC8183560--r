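#' Construct a feature table
#'
#' A feature table holds non-negative integer read counts for amplicon
#' sequence variants (ASVs) across samples, oriented samples x ASVs.
#' Per-sample coverage (sequencing depth) is the row sum and is the
#' quantity that sets the detection limit for rare ASVs downstream.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns, with
#'   row and column names giving sample and ASV identifiers.
#' @return A `feature_table` object (a validated integer matrix with
#'   class attribute).
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample row names and ASV column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV identifiers")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop("non-numeric counts in feature table")
  if (any(storage < 0)) stop("negative counts in feature table")
  if (any(storage != round(storage))) stop("counts must be integers")
  mode(counts) <- "numeric"
  rs <- rowSums(counts)
  if (any(rs < 1)) {
    stop("samples with zero coverage: ",
         paste(rownames(counts)[rs < 1], collapse = ", "))
  }
  structure(counts, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d ASVs; coverage %s-%s\n",
              nrow(x), ncol(x), format(min(rowSums(x))),
              format(max(rowSums(x)))))
  invisible(x)
}

#' Per-sample coverage (sequencing depth)
#'
#' @param table a `feature_table`.
#' @return Named numeric vector of row sums.
#' @export
coverage <- function(table) rowSums(unclass(table))

#' Read a feature table from TSV
#'
#' Accepts both of the common dialects: samples as rows or ASVs as rows
#' (the QIIME-style `#ASV_ID<TAB>sample1...` layout).  The orientation is
#' never guessed; silent transposition is a classic source of corrupted
#' analyses, so the caller must state it.
#'
#' @param path path to a tab-separated file with a header row and
#'   identifiers in the first column.
#' @param orientation `"samples-as-rows"` or `"asvs-as-rows"`.
#' @return A `feature_table` oriented samples x ASVs.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples-as-rows",
                                               "asvs-as-rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate identifiers in first column of ", path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1]], colnames(m)[bad[2]], path))
  }
  dimnames(num) <- list(ids, colnames(m))
  if (orientation == "asvs-as-rows") num <- t(num)
  feature_table(num)
}

#' Write a feature table to TSV
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param orientation layout to write; see [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                orientation = c("samples-as-rows",
                                                "asvs-as-rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  first <- "#Sample_ID"
  if (orientation == "asvs-as-rows") {
    m <- t(m)
    first <- "#ASV_ID"
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- first
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

timepoint_levels <- function() c("baseline", "d15", "m1", "m3", "m6", "donor")
patient_timepoints <- function() c("baseline", "d15", "m1", "m3", "m6")

#' Read cohort sample metadata
#'
#' Metadata records tie each sequenced sample to a subject, a role
#' (patient or donor), a treatment arm, a visit time-point on the fixed
#' chronology baseline < d15 < m1 < m3 < m6, and optionally an IBS
#' Symptom Severity Score (IBS-SSS, 0-500).
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `role`,
#'   `arm`, `timepoint`, `ibs_sss` (empty/NA allowed for `ibs_sss`).
#' @return A tibble of validated sample records (class
#'   `cohort_metadata`).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  cohort_metadata(df)
}

#' Validate cohort metadata
#'
#' @param df data frame with the six metadata columns (see
#'   [read_metadata()]).
#' @return A validated `cohort_metadata` tibble.
#' @export
cohort_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "role", "arm", "timepoint", "ibs_sss")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df[need])
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$role %in% c("patient", "donor"))) {
    stop("role must be 'patient' or 'donor'")
  }
  if (!all(df$arm %in% c("FMT", "placebo", "not-applicable"))) {
    stop("unknown arm token: ",
         paste(setdiff(df$arm, c("FMT", "placebo", "not-applicable")),
               collapse = ", "))
  }
  if (!all(df$timepoint %in% timepoint_levels())) {
    stop("unknown timepoint token: ",
         paste(setdiff(df$timepoint, timepoint_levels()), collapse = ", "))
  }
  if (any(df$role == "donor" & df$arm != "not-applicable")) {
    stop("donor samples must have arm 'not-applicable'")
  }
  if (any(df$role == "patient" & df$timepoint == "donor")) {
    stop("patient samples cannot carry the 'donor' timepoint")
  }
  dup <- duplicated(df[, c("subject_id", "timepoint")])
  if (any(dup)) {
    stop("duplicate (subject_id, timepoint): ",
         paste(unique(df$subject_id[dup]), collapse = ", "))
  }
  if (any(df$role == "donor" & !is.na(df$ibs_sss))) {
    warning("IBS-SSS present for donor samples; values ignored")
    df$ibs_sss[df$role == "donor"] <- NA
  }
  sss <- df$ibs_sss[!is.na(df$ibs_sss)]
  if (length(sss) && (any(sss < 0) || any(sss > 500))) {
    stop("ibs_sss outside [0, 500]")
  }
  class(df) <- c("cohort_metadata", class(df))
  df
}

#' Write cohort metadata to TSV
#'
#' @param meta a `cohort_metadata` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree of ASVs
#'
#' @param path newick file; branch lengths expected.  Missing branch
#'   lengths are set to 0 with a warning; negative lengths are rejected.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparseable newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  tree
}

#' Assemble per-patient time-courses
#'
#' One time-course per patient subject: the baseline sample (if any) plus
#' chronologically ordered follow-up samples.  Donors are excluded.
#' Patients lacking a baseline are flagged ineligible for gain/loss
#' scoring rather than dropped, so the caller can report them.  Missing
#' visits are represented by absence, never by zero-filled samples.
#'
#' @param table a `feature_table` (used only to check sample coverage of
#'   the metadata; may be `NULL`).
#' @param meta a `cohort_metadata` tibble.
#' @return Tibble with one row per patient: `subject_id`, `arm`,
#'   `baseline_sample` (NA when missing), `followups` (list column of
#'   named character vectors, names = time-points), `n_followups`,
#'   `has_baseline`.
#' @export
build_timecourses <- function(table, meta) {
  if (!is.null(table)) {
    extra <- setdiff(rownames(table), meta$sample_id)
    if (length(extra)) {
      stop("feature table samples missing from metadata: ",
           paste(extra, collapse = ", "))
    }
  }
  pat <- meta[meta$role == "patient", , drop = FALSE]
  chron <- patient_timepoints()
  split_rows <- split(seq_len(nrow(pat)), pat$subject_id)
  out <- lapply(names(split_rows), function(sid) {
    rows <- pat[split_rows[[sid]], , drop = FALSE]
    base <- rows$sample_id[rows$timepoint == "baseline"]
    fu <- rows[rows$timepoint != "baseline", , drop = FALSE]
    ord <- order(match(fu$timepoint, chron))
    fu_samples <- stats::setNames(fu$sample_id[ord], fu$timepoint[ord])
    tibble::tibble(
      subject_id = sid,
      arm = rows$arm[1],
      baseline_sample = if (length(base)) base else NA_character_,
      followups = list(fu_samples),
      n_followups = length(fu_samples),
      has_baseline = length(base) > 0
    )
  })
  dplyr::bind_rows(out)
}

#' Relative abundances of one sample
#'
#' Proportions are always derived on the fly as count/coverage and never
#' stored, so counts remain the single source of truth.
#'
#' @param table a `feature_table`.
#' @param sample_id sample to extract.
#' @return Named numeric vector of proportions summing to 1.
#' @export
relative_abundance <- function(table, sample_id) {
  if (!sample_id %in% rownames(table)) stop("unknown sample: ", sample_id)
  v <- unclass(table)[sample_id, ]
  v / sum(v)
}
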