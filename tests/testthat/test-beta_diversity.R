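random_instance <- function(n_tips = 10, zero_frac = 0.3) {
  tree <- ape::rtree(n_tips, br = stats::rexp)
  cnt <- matrix(rpois(2 * n_tips, 10), 2, n_tips,
                dimnames = list(c("x", "y"), tree$tip.label))
  cnt[matrix(runif(2 * n_tips) < zero_frac, 2)] <- 0L
  if (sum(cnt[1, ]) == 0) cnt[1, 1] <- 5L
  if (sum(cnt[2, ]) == 0) cnt[2, 2] <- 5L
  list(tree = tree, counts = cnt)
}

test_that("unifrac identities: zero on identical, one on disjoint", {
  tree <- ape::read.tree(text = "((A:1):1,(B:1):1);")
  a <- c(A = 5, B = 0)
  b <- c(A = 0, B = 7)
  for (v in c("unweighted", "weighted", "generalized")) {
    expect_equal(unifrac(a, a, tree, v), 0)
    expect_equal(unifrac(a, b, tree, v), 1)
  }
})

test_that("unifrac agrees with a clade-enumeration oracle and phyloseq", {
  skip_if_not_installed("phyloseq")
  set.seed(31)
  for (i in 1:8) {
    inst <- random_instance()
    x <- inst$counts[1, ]; y <- inst$counts[2, ]
    for (v in c("unweighted", "weighted", "generalized")) {
      expect_equal(unifrac(x, y, inst$tree, v, alpha = 0.5),
                   oracle_unifrac(x, y, inst$tree, v, alpha = 0.5),
                   tolerance = 1e-12)
    }
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(inst$counts, taxa_are_rows = FALSE),
      phyloseq::phy_tree(inst$tree))
    expect_equal(unifrac(x, y, inst$tree, "unweighted"),
                 as.numeric(phyloseq::UniFrac(ps, weighted = FALSE)),
                 tolerance = 1e-10)
    expect_equal(unifrac(x, y, inst$tree, "weighted"),
                 as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                              normalized = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("generalized unifrac at alpha = 1 equals the weighted form", {
  set.seed(17)
  for (i in 1:25) {
    inst <- random_instance()
    g1 <- unifrac(inst$counts[1, ], inst$counts[2, ], inst$tree,
                  "generalized", alpha = 1)
    w <- unifrac(inst$counts[1, ], inst$counts[2, ], inst$tree, "weighted")
    expect_equal(g1, w, tolerance = 1e-12)
  }
})

test_that("unweighted unifrac depends only on presence/absence", {
  set.seed(23)
  inst <- random_instance()
  d1 <- unifrac(inst$counts[1, ], inst$counts[2, ], inst$tree, "unweighted")
  d2 <- unifrac(inst$counts[1, ] * 7L, inst$counts[2, ] * 3L, inst$tree,
                "unweighted")
  expect_equal(d1, d2)
})

test_that("missing leaves are reported by name", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 2, Z = 3)
  y <- c(A = 1, B = 2, Z = 0)
  expect_error(unifrac(x, y, tree), "Z")
})

test_that("unifrac matrix is symmetric, zero-diagonal and matches pairwise calls", {
  set.seed(5)
  tree <- ape::rtree(8, br = stats::rexp)
  cnt <- matrix(rpois(4 * 8, 6), 4, 8,
                dimnames = list(paste0("s", 1:4), tree$tip.label))
  cnt[cnt < 2] <- 0
  cnt[rowSums(cnt) == 0, 1] <- 3
  dm <- unifrac_matrix(feature_table(cnt), tree, "generalized")
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_equal(dm["s1", "s3"],
               unifrac(cnt["s1", ], cnt["s3", ], tree, "generalized"))
})

test_that("pcoa exactly recovers a Euclidean configuration", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(which.max(ord$proportion_explained), 1L)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  zero <- matrix(0, 3, 3)
  expect_true(all(pcoa(zero, 2)$coordinates == 0))
})

test_that("donor distances fall for FMT patients, not placebo", {
  sim <- small_cohort()
  dd <- donor_distance_course(sim$table, sim$meta, sim$tree)
  fmt <- dd$tests[dd$tests$arm == "FMT", ]
  expect_true(all(fmt$mean_change < 0))
  expect_true(all(fmt$p_value < 0.05))
  pla <- dd$tests[dd$tests$arm == "placebo", ]
  expect_true(all(abs(pla$mean_change) < 0.05))
  # a patient identical to the sole donor sits at distance zero
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cnt <- rbind(P1_baseline = c(A = 5L, B = 3L, C = 2L),
               P1_d15 = c(A = 5L, B = 3L, C = 2L),
               D1_donor = c(A = 5L, B = 3L, C = 2L))
  meta <- cohort_metadata(data.frame(
    sample_id = rownames(cnt),
    subject_id = c("P1", "P1", "D1"),
    role = c("patient", "patient", "donor"),
    arm = c("FMT", "FMT", "not-applicable"),
    timepoint = c("baseline", "d15", "donor"),
    ibs_sss = NA))
  dd2 <- donor_distance_course(feature_table(cnt), meta, tree)
  expect_true(all(dd2$distances$dist_to_donors == 0))
})
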