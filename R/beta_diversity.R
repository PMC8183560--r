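#' Per-branch descendant-leaf proportions
#'
#' For each edge of a rooted tree, the fraction of a sample's reads
#' assigned to leaves descending from that edge.  This is the per-branch
#' aggregation all UniFrac variants are built from; computing it once as
#' an edges x samples matrix makes whole-cohort distance matrices cheap.
#'
#' @param tree a `phylo` tree whose leaves cover all ASVs with nonzero
#'   counts.
#' @param counts matrix samples x ASVs (or a [feature_table()]).
#' @return List: `P` (edges x samples matrix of proportions),
#'   `lengths` (edge lengths).
#' @keywords internal
branch_proportions <- function(tree, counts) {
  counts <- as.matrix(unclass(counts))
  missing <- setdiff(colnames(counts)[colSums(counts) > 0], tree$tip.label)
  if (length(missing)) {
    stop("ASV(s) missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  props <- counts / rowSums(counts)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_p <- matrix(0, n_node, nrow(counts))
  present <- intersect(tree$tip.label, colnames(props))
  node_p[match(present, tree$tip.label), ] <- t(props[, present, drop = FALSE])
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    node_p[parent, ] <- node_p[parent, ] + node_p[child, ]
  }
  P <- node_p[tree$edge[, 2], , drop = FALSE]
  colnames(P) <- rownames(counts)
  list(P = P, lengths = tree$edge.length)
}

unifrac_from_branches <- function(pa, pb, b, variant, alpha) {
  tot <- pa + pb
  keep <- tot > 0
  pa <- pa[keep]; pb <- pb[keep]; b <- b[keep]; tot <- tot[keep]
  if (!length(b) || sum(b) == 0) return(0)
  if (variant == "unweighted") {
    in_a <- pa > 0
    in_b <- pb > 0
    denom <- sum(b)
    if (denom == 0) return(0)
    return(sum(b[xor(in_a, in_b)]) / denom)
  }
  if (variant == "weighted") {
    return(sum(b * abs(pa - pb)) / sum(b * tot))
  }
  # generalized: branch weights (pa+pb)^alpha, difference |pa-pb|/(pa+pb)
  w <- b * tot^alpha
  sum(w * abs(pa - pb) / tot) / sum(w)
}

#' UniFrac distance between two samples
#'
#' Phylogenetic community distance.  `unweighted` is the fraction of
#' observed branch length unique to one of the two samples;
#' `generalized` weights each branch by `(p_A + p_B)^alpha` times the
#' normalized abundance difference `|p_A - p_B| / (p_A + p_B)`;
#' `weighted` is the normalized abundance-weighted form, algebraically
#' the generalized distance at `alpha = 1`.  All variants lie in [0, 1].
#'
#' @param a,b count vectors named by ASV.
#' @param tree rooted `phylo` tree covering all ASVs with nonzero
#'   counts.
#' @param variant `"unweighted"`, `"weighted"` or `"generalized"`.
#' @param alpha generalized-UniFrac exponent in [0, 1]; default 0.5.
#' @return Distance in [0, 1].
#' @export
unifrac <- function(a, b, tree,
                    variant = c("generalized", "weighted", "unweighted"),
                    alpha = 0.5) {
  variant <- match.arg(variant)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  counts <- rbind(a = a, b = b)
  br <- branch_proportions(tree, counts)
  unifrac_from_branches(br$P[, 1], br$P[, 2], br$lengths, variant, alpha)
}

#' All-pairs UniFrac distance matrix
#'
#' @param table a [feature_table()].
#' @param tree rooted `phylo` tree.
#' @inheritParams unifrac
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
unifrac_matrix <- function(table, tree,
                           variant = c("generalized", "weighted",
                                       "unweighted"),
                           alpha = 0.5) {
  variant <- match.arg(variant)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  br <- branch_proportions(tree, table)
  ids <- colnames(br$P)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- unifrac_from_branches(br$P[, i], br$P[, j],
                                                  br$lengths, variant, alpha)
    }
  }
  d
}

#' Distance-to-donors time-course
#'
#' For each patient sample, the arithmetic mean of the generalized
#' UniFrac distances to the individual donor samples (donors are kept
#' separate, not pooled).  Group-level change from baseline at each
#' follow-up is tested with the two-sided Mann-Whitney U test.
#'
#' @param table a [feature_table()].
#' @param meta a [cohort_metadata()] tibble with >= 1 donor sample.
#' @param tree rooted `phylo` tree.
#' @param alpha generalized-UniFrac exponent.
#' @return List: `distances` (subject_id, arm, timepoint, dist_to_donors)
#'   and `tests` (arm, timepoint, baseline-vs-timepoint Mann-Whitney p).
#' @export
donor_distance_course <- function(table, meta, tree, alpha = 0.5) {
  donors <- meta$sample_id[meta$role == "donor"]
  donors <- intersect(donors, rownames(table))
  if (!length(donors)) stop("no donor samples available")
  br <- branch_proportions(tree, table)
  pat <- meta[meta$role == "patient" & meta$sample_id %in% rownames(table), ]
  rows <- lapply(seq_len(nrow(pat)), function(i) {
    s <- pat$sample_id[i]
    dd <- vapply(donors, function(d) {
      unifrac_from_branches(br$P[, s], br$P[, d], br$lengths,
                            "generalized", alpha)
    }, numeric(1))
    tibble::tibble(subject_id = pat$subject_id[i], arm = pat$arm[i],
                   timepoint = pat$timepoint[i], sample_id = s,
                   dist_to_donors = mean(dd))
  })
  distances <- dplyr::bind_rows(rows)

  tests <- list()
  for (a in intersect(c("FMT", "placebo"), unique(distances$arm))) {
    base <- distances$dist_to_donors[distances$arm == a &
                                       distances$timepoint == "baseline"]
    for (tp in setdiff(patient_timepoints(), "baseline")) {
      cur <- distances$dist_to_donors[distances$arm == a &
                                        distances$timepoint == tp]
      if (!length(cur) || !length(base)) next
      p <- if (all(c(base, cur) == base[1])) 1 else {
        suppressWarnings(stats::wilcox.test(base, cur)$p.value)
      }
      tests[[paste(a, tp)]] <- tibble::tibble(
        arm = a, timepoint = tp, n_baseline = length(base),
        n_followup = length(cur),
        mean_change = mean(cur) - mean(base), p_value = p)
    }
  }
  list(distances = distances, tests = dplyr::bind_rows(tests))
}

#' Principal coordinates analysis
#'
#' Classical metric ordination: Gower double-centering of the squared
#' distances followed by eigendecomposition.  Axes with negative
#' eigenvalues are dropped (their total magnitude is reported via the
#' `negative_eigenvalue_mass` attribute rather than corrected), and
#' coordinates are scaled by the square root of the eigenvalues.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to retain (capped at the number of
#'   positive eigenvalues).
#' @return List: `ids`, `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, positive), `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dm)))
  n <- nrow(dm)
  gower <- -0.5 * dm^2
  centered <- gower - rowMeans(gower)[row(gower)] -
    colMeans(gower)[col(gower)] + mean(gower)
  eig <- eigen(centered, symmetric = TRUE)
  pos <- eig$values > max(eig$values[1], 0) * 1e-12
  values <- eig$values[pos]
  vectors <- eig$vectors[, pos, drop = FALSE]
  neg_mass <- sum(abs(eig$values[eig$values < 0]))
  k <- min(n_axes, length(values))
  coords <- if (k > 0) {
    sweep(vectors[, seq_len(k), drop = FALSE], 2, sqrt(values[seq_len(k)]),
          `*`)
  } else {
    # degenerate (e.g. all-zero distances): every sample sits at the origin
    matrix(0, n, min(n_axes, n))
  }
  rownames(coords) <- ids
  if (ncol(coords)) colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(
    list(ids = ids, coordinates = coords,
         eigenvalues = values[seq_len(k)],
         proportion_explained = if (length(values)) {
           values[seq_len(k)] / sum(values)
         } else {
           numeric(0)
         }),
    negative_eigenvalue_mass = neg_mass,
    class = "pcoa_ordination")
}
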