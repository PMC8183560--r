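#' Read a per-sink per-ASV source-attribution table
#'
#' Long-format TSV with columns `sink`, `source`, `asv`, `proportion`:
#' for every ASV in a sink (post-treatment) sample, the proportion of it
#' attributed to each source (the individual donors, the patient's
#' pre-treatment community, and "unknown").  Proportions over sources
#' must sum to 1 per (sink, ASV); when the "unknown" row is missing the
#' remainder is assigned to it with a warning.
#'
#' @param path TSV path.
#' @param tol simplex tolerance (default 1e-6).
#' @return Validated attribution tibble.
#' @export
read_attribution <- function(path, tol = 1e-6) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_attribution(tibble::as_tibble(df), tol = tol)
}

validate_attribution <- function(attr, tol = 1e-6) {
  need <- c("sink", "source", "asv", "proportion")
  if (!all(need %in% names(attr))) {
    stop("attribution table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(attr$proportion < -tol | attr$proportion > 1 + tol)) {
    stop("attribution proportions outside [0, 1]")
  }
  sums <- dplyr::summarise(dplyr::group_by(attr, .data$sink, .data$asv),
                           total = sum(.data$proportion),
                           has_unknown = any(.data$source == "unknown"),
                           .groups = "drop")
  if (any(sums$total > 1 + tol)) {
    stop("attribution proportions sum to > 1 for some (sink, ASV)")
  }
  short <- sums[!sums$has_unknown & sums$total < 1 - tol, ]
  if (nrow(short)) {
    warning(nrow(short), " (sink, ASV) pair(s) missing an 'unknown' row; ",
            "remainder assigned to unknown")
    fill <- tibble::tibble(sink = short$sink, source = "unknown",
                           asv = short$asv,
                           proportion = 1 - short$total)
    attr <- dplyr::bind_rows(attr, fill)
  }
  attr
}

#' Naive per-ASV source attribution
#'
#' A deliberately simple stand-in for Bayesian source-tracking: the
#' proportion of a sink ASV attributed to source s is proportional to
#' that source's relative abundance of the ASV plus a pseudo-mass, with
#' one additional pseudo-mass share reserved for "unknown".  As the
#' pseudo-mass tends to 0, an ASV unique to one source is attributed
#' entirely to it.  The unknown source carries its own small fixed mass
#' (`unknown_mass`), larger than the per-source pseudo-mass, so an ASV
#' absent from every source is attributed to unknown rather than split
#' uniformly.  The engraftment post-processing is defined over the
#' attribution-table contract, so any upstream attribution tool can be
#' substituted.
#'
#' @param sink named count vector of the sink sample.
#' @param sources named list of count vectors (names become source
#'   labels).
#' @param sink_id label for the sink column.
#' @param pseudo per-source pseudo-mass (default 1e-9).
#' @param unknown_mass weight of the unknown source (default 1e-5).
#' @return Attribution tibble (`sink`, `source`, `asv`, `proportion`)
#'   covering the ASVs present in the sink.
#' @export
naive_attribution <- function(sink, sources, sink_id = "sink",
                              pseudo = 1e-9, unknown_mass = 1e-5) {
  if (!length(sources)) stop("at least one source required")
  if (sum(sink) == 0) stop("empty sink sample")
  if (is.null(names(sources))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  asvs <- names(sink)[sink > 0]
  src_prop <- vapply(sources, function(s) {
    (s / sum(s))[asvs]
  }, numeric(length(asvs)))
  if (length(asvs) == 1) src_prop <- matrix(src_prop, nrow = 1)
  src_prop[is.na(src_prop)] <- 0
  w <- src_prop + pseudo
  w <- cbind(w, unknown = rep(unknown_mass, length(asvs)))
  w <- w / rowSums(w)
  colnames(w) <- c(names(sources), "unknown")
  out <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(w), asv = asvs),
    cols = -dplyr::all_of("asv"), names_to = "source",
    values_to = "proportion")
  out$sink <- sink_id
  out[, c("sink", "source", "asv", "proportion")]
}

#' Placebo-floored rescaling of a donor-attribution proportion
#'
#' The apparent donor attribution seen in the placebo arm measures the
#' background noise of the source-attribution procedure.  If the placebo
#' background meets or exceeds the FMT proportion the engraftment score
#' is 0; otherwise the score is `(p_fmt - p_placebo) / (1 - p_placebo)`,
#' the fraction of the head-room above background that the FMT arm
#' realizes.
#'
#' @param p_fmt,p_placebo proportions in [0, 1] (vectorized).
#' @return Rescaled score(s) in [0, 1].
#' @export
rescale_engraftment <- function(p_fmt, p_placebo) {
  if (any(p_fmt < 0 | p_fmt > 1 | p_placebo < 0 | p_placebo > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  out <- ifelse(p_placebo >= p_fmt, 0,
                (p_fmt - p_placebo) / (1 - p_placebo))
  out[p_placebo >= 1] <- 0
  pmin(1, pmax(0, out))
}

donor_share_by_sink_asv <- function(attr, donor_sources) {
  donor <- attr[attr$source %in% donor_sources, , drop = FALSE]
  dplyr::summarise(dplyr::group_by(donor, .data$sink, .data$asv),
                   donor_share = sum(.data$proportion), .groups = "drop")
}

#' Per-node engraftment scores with a placebo floor
#'
#' For each node (taxon, clade, or any grouping of ASVs): the raw FMT
#' proportion is the mean over FMT sinks and member ASVs of the
#' donor-attributed share, averaging leaf-level means; an ASV absent
#' from a sink contributes 0 (none of it came from the donors, since
#' none of it is there).  The placebo floor is computed identically over
#' the placebo sinks, and the node is rescaled once via
#' [rescale_engraftment()] (average, then floor, then rescale).  Nodes
#' none of whose member ASVs are observed in any FMT sink are omitted.
#'
#' @param attr_fmt,attr_placebo attribution tibbles for the two arms'
#'   sink samples at one time-point.
#' @param node_map tibble `asv`, `node` assigning member ASVs to nodes
#'   (an ASV may appear under several nested nodes).
#' @param donor_sources character vector naming the donor source labels
#'   (summed into a single donor share per sink ASV).
#' @return Tibble: `node`, `raw_fmt`, `floor_placebo`, `score`.
#' @export
taxon_engraftment_scores <- function(attr_fmt, attr_placebo, node_map,
                                     donor_sources) {
  arm_node_means <- function(attr) {
    share <- donor_share_by_sink_asv(attr, donor_sources)
    sinks <- unique(attr$sink)
    # leaf-level mean over sinks, absent ASVs contributing 0
    full <- tidyr::expand_grid(sink = sinks,
                               asv = unique(node_map$asv))
    full <- dplyr::left_join(full, share, by = c("sink", "asv"))
    full$donor_share[is.na(full$donor_share)] <- 0
    leaf <- dplyr::summarise(dplyr::group_by(full, .data$asv),
                             leaf_mean = mean(.data$donor_share),
                             observed = any(.data$donor_share > 0) ||
                               .data$asv[1] %in% share$asv,
                             .groups = "drop")
    nodes <- dplyr::inner_join(node_map, leaf, by = "asv")
    dplyr::summarise(dplyr::group_by(nodes, .data$node),
                     node_mean = mean(.data$leaf_mean),
                     any_observed = any(.data$observed),
                     .groups = "drop")
  }
  fmt <- arm_node_means(attr_fmt)
  pla <- arm_node_means(attr_placebo)
  out <- dplyr::left_join(
    fmt[fmt$any_observed, c("node", "node_mean")],
    pla[, c("node", "node_mean")],
    by = "node", suffix = c("_fmt", "_placebo"))
  out$node_mean_placebo[is.na(out$node_mean_placebo)] <- 0
  tibble::tibble(node = out$node,
                 raw_fmt = out$node_mean_fmt,
                 floor_placebo = out$node_mean_placebo,
                 score = rescale_engraftment(out$node_mean_fmt,
                                             out$node_mean_placebo))
}

#' Export node engraftment scores for tree rendering
#'
#' Resolves node labels against the tree's tips and internal node
#' labels, emitting one row per resolvable node with the score doubling
#' as a color value in [0, 1].  Unresolvable nodes are skipped with a
#' warning; rendering itself is out of scope.
#'
#' @param scores tibble from [taxon_engraftment_scores()].
#' @param tree a `phylo` tree.
#' @return Tibble: `node`, `score`, `color_value`.
#' @export
annotate_tree <- function(scores, tree) {
  known <- c(tree$tip.label, tree$node.label)
  ok <- scores$node %in% known
  if (any(!ok)) {
    warning("skipping node(s) not in tree: ",
            paste(scores$node[!ok], collapse = ", "))
  }
  kept <- scores[ok, , drop = FALSE]
  tibble::tibble(node = kept$node,
                 score = kept$score,
                 color_value = pmin(1, pmax(0, kept$score)))
}
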