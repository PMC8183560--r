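# Independent step-by-step re-implementations used as oracles.  These
# are deliberately scalar, loop-based, and share no code with the
# vectorized implementations they check.

oracle_gain <- function(counts, coverages) {
  stopifnot(counts[1] == 0)
  fu <- counts[-1]
  cf <- coverages[-1]
  m <- length(fu)
  props <- fu / cf
  s0 <- 1 - exp(-(coverages[1] * mean(props)))
  pair <- numeric(m - 1)
  for (k in seq_len(m - 1)) {
    a <- fu[k] > 0
    b <- fu[k + 1] > 0
    pair[k] <- if (a && b) {
      1
    } else if (!a && !b) {
      0
    } else {
      lam <- if (a) cf[k + 1] * props[k] else cf[k] * props[k + 1]
      exp(-lam)
    }
  }
  consistency <- if (length(pair) == 1) {
    pair
  } else {
    prods <- numeric(length(pair) - 1)
    for (i in seq_along(prods)) prods[i] <- pair[i] * pair[i + 1]
    mean(prods)
  }
  s0 * consistency
}

oracle_loss <- function(counts, coverages) {
  stopifnot(counts[1] > 0)
  p0 <- counts[1] / coverages[1]
  fu <- counts[-1]
  cf <- coverages[-1]
  m <- length(fu)
  sc <- numeric(m)
  for (k in seq_len(m)) {
    sc[k] <- if (fu[k] > 0) 0 else 1 - exp(-(cf[k] * p0))
  }
  prods <- numeric(m - 1)
  for (i in seq_along(prods)) prods[i] <- sc[i] * sc[i + 1]
  mean(prods)
}

# Brute-force UniFrac via explicit clade enumeration (phangorn
# Descendants), independent of the postorder accumulation in the package.
oracle_unifrac <- function(a, b, tree, variant, alpha = 0.5) {
  pa_tip <- a / sum(a)
  pb_tip <- b / sum(b)
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), "tips")
  num <- den <- 0
  uw_num <- uw_den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    pa <- sum(pa_tip[tips], na.rm = TRUE)
    pb <- sum(pb_tip[tips], na.rm = TRUE)
    bl <- tree$edge.length[e]
    if (pa + pb == 0) next
    if (variant == "unweighted") {
      uw_den <- uw_den + bl
      if (xor(pa > 0, pb > 0)) uw_num <- uw_num + bl
    } else if (variant == "weighted") {
      num <- num + bl * abs(pa - pb)
      den <- den + bl * (pa + pb)
    } else {
      w <- bl * (pa + pb)^alpha
      num <- num + w * abs(pa - pb) / (pa + pb)
      den <- den + w
    }
  }
  if (variant == "unweighted") uw_num / uw_den else num / den
}
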