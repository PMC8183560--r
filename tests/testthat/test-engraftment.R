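test_that("placebo-floored rescaling matches the closed form", {
  expect_equal(rescale_engraftment(0.5, 0.2), 0.375)
  expect_equal(rescale_engraftment(0.2, 0.5), 0)
  expect_equal(rescale_engraftment(0.3, 0.3), 0)
  for (x in seq(0, 1, by = 0.25)) {
    expect_equal(rescale_engraftment(x, 0), x)
  }
  expect_equal(rescale_engraftment(1, 1), 0)
  expect_error(rescale_engraftment(1.2, 0), "\\[0, 1\\]")
  expect_error(rescale_engraftment(0.5, -0.1), "\\[0, 1\\]")
  # monotone in p_fmt, anti-monotone in p_placebo
  grid <- seq(0, 1, by = 0.1)
  expect_true(all(diff(rescale_engraftment(grid, 0.3)) >= 0))
  expect_true(all(diff(rescale_engraftment(0.7, grid)) <= 0))
})

test_that("attribution tables are validated and completed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sink\tsource\tasv\tproportion",
               "s1\tdonor1\ta1\t0.6",
               "s1\tself\ta1\t0.3",
               "s1\tunknown\ta1\t0.1"), path)
  attr <- read_attribution(path)
  expect_equal(sum(attr$proportion), 1)

  writeLines(c("sink\tsource\tasv\tproportion",
               "s1\tdonor1\ta1\t0.9",
               "s1\tself\ta1\t0.6"), path)
  expect_error(read_attribution(path), "sum to > 1")

  writeLines(c("sink\tsource\tasv\tproportion",
               "s1\tdonor1\ta1\t0.6",
               "s1\tself\ta1\t0.3"), path)
  expect_warning(attr2 <- read_attribution(path), "unknown")
  unk <- attr2[attr2$source == "unknown", ]
  expect_equal(unk$proportion, 0.1)
})

test_that("naive attribution honours source-uniqueness, symmetry and absence", {
  sink <- c(a1 = 50, a2 = 30, a3 = 20)
  d1 <- c(a1 = 0, a2 = 100, a3 = 0)
  d2 <- c(a1 = 80, a2 = 0, a3 = 0)
  attr <- naive_attribution(sink, list(donor1 = d1, donor2 = d2),
                            pseudo = 1e-9)
  get <- function(asv, src) {
    attr$proportion[attr$asv == asv & attr$source == src]
  }
  expect_gt(get("a1", "donor2"), 0.999)      # unique to donor2
  expect_gt(get("a2", "donor1"), 0.999)
  expect_gt(get("a3", "unknown"), 0.999)     # absent from all sources
  twin <- naive_attribution(sink, list(s1 = d1, s2 = d1), pseudo = 1e-9)
  expect_equal(twin$proportion[twin$asv == "a2" & twin$source == "s1"],
               twin$proportion[twin$asv == "a2" & twin$source == "s2"],
               tolerance = 1e-9)
  expect_error(naive_attribution(c(a1 = 0), list(d1)), "empty sink")
})

test_that("node scores average leaves first, then rescale once", {
  attr_fmt <- tibble::tibble(
    sink = "f1", source = "donor1", asv = c("L1", "L2"),
    proportion = c(0.5, 0.9))
  attr_fmt <- dplyr::bind_rows(attr_fmt, tibble::tibble(
    sink = "f1", source = "unknown", asv = c("L1", "L2"),
    proportion = c(0.5, 0.1)))
  attr_pla <- tibble::tibble(
    sink = "p1", source = "donor1", asv = c("L1", "L2"),
    proportion = c(0.2, 0.1))
  attr_pla <- dplyr::bind_rows(attr_pla, tibble::tibble(
    sink = "p1", source = "unknown", asv = c("L1", "L2"),
    proportion = c(0.8, 0.9)))
  node_map <- tibble::tibble(asv = c("L1", "L2"), node = "clade")
  sc <- taxon_engraftment_scores(attr_fmt, attr_pla, node_map, "donor1")
  expect_equal(sc$raw_fmt, 0.7)
  expect_equal(sc$floor_placebo, 0.15)
  expect_equal(sc$score, 0.55 / 0.85)
  # identical arms: exact zero everywhere
  sc0 <- taxon_engraftment_scores(attr_fmt, attr_fmt, node_map, "donor1")
  expect_true(all(sc0$score == 0))
})

test_that("donor-unique planted ASVs earn high donor shares and clade scores", {
  sim <- small_cohort()
  m <- unclass(sim$table)
  donors <- sim$meta$sample_id[sim$meta$role == "donor"]
  donor_src <- setNames(lapply(donors, function(d) m[d, ]), donors)
  ev <- sim$truth$events
  attr_arm <- function(subjects) {
    dplyr::bind_rows(lapply(subjects, function(s) {
      naive_attribution(m[paste0(s, "_m3"), ],
                        c(donor_src,
                          list(pretreatment = m[paste0(s, "_baseline"), ])),
                        sink_id = paste0(s, "_m3"))
    }))
  }
  fmt_subj <- unique(sim$meta$subject_id[sim$meta$arm == "FMT"])
  pla_subj <- unique(sim$meta$subject_id[sim$meta$arm == "placebo"])
  attr_fmt <- attr_arm(fmt_subj)
  attr_pla <- attr_arm(pla_subj)

  gains <- ev[ev$event == "gain", ]
  share <- attr_fmt[attr_fmt$source %in% donors, ]
  share <- dplyr::summarise(dplyr::group_by(share, sink, asv),
                            donor_share = sum(proportion),
                            .groups = "drop")
  key <- paste(paste0(gains$subject_id, "_m3"), gains$asv)
  got <- share$donor_share[match(key, paste(share$sink, share$asv))]
  got <- got[!is.na(got)]   # planted gain unseen at m3 in rare cases
  expect_gt(length(got), 0.8 * nrow(gains))
  expect_true(all(got >= 0.9))

  node_map <- tibble::tibble(asv = unique(gains$asv), node = "planted")
  sc <- taxon_engraftment_scores(attr_fmt, attr_pla, node_map, donors)
  expect_gte(sc$score[sc$node == "planted"], 0.8)
})

test_that("tree annotation keeps resolvable nodes and clamps colors", {
  tree <- ape::read.tree(text = "((A:1,B:1)n1:1,C:2)root;")
  scores <- tibble::tibble(node = c("A", "n1", "ghost"),
                           score = c(0, 0.5, 0.9))
  expect_warning(out <- annotate_tree(scores, tree), "ghost")
  expect_equal(nrow(out), 2)
  expect_equal(out$color_value, c(0, 0.5))
})
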