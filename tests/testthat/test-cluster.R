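test_that("pairwise clustering distances follow the f95 rules", {
  f95 <- 466
  # two left-side reads 400 apart: one cluster
  r <- cluster_supporting_reads(supp_table(
    supp_row(anchor_pos = 1000, side = "left"),
    supp_row(anchor_pos = 1400, side = "left")), f95)
  expect_identical(length(unique(r$cluster_id)), 1L)
  # two left-side reads 500 apart: two clusters
  r <- cluster_supporting_reads(supp_table(
    supp_row(anchor_pos = 1000, side = "left"),
    supp_row(anchor_pos = 1500, side = "left")), f95)
  expect_identical(length(unique(r$cluster_id)), 2L)
  # convergent left + right 900 apart: one cluster (900 < 2 * 466)
  r <- cluster_supporting_reads(supp_table(
    supp_row(anchor_pos = 1000, side = "left"),
    supp_row(anchor_pos = 1900, side = "right")), f95)
  expect_identical(length(unique(r$cluster_id)), 1L)
  # divergent right-then-left at the same distance: two clusters
  r <- cluster_supporting_reads(supp_table(
    supp_row(anchor_pos = 1000, side = "right"),
    supp_row(anchor_pos = 1900, side = "left")), f95)
  expect_identical(length(unique(r$cluster_id)), 2L)
  # single-linkage chain a-b-c with 400-bp steps: one cluster of three
  r <- cluster_supporting_reads(supp_table(
    supp_row(anchor_pos = 1000, side = "left"),
    supp_row(anchor_pos = 1400, side = "left"),
    supp_row(anchor_pos = 1800, side = "left")), f95)
  expect_identical(length(unique(r$cluster_id)), 1L)
})

test_that("union-find clustering equals the brute-force closure oracle", {
  f95 <- 466
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    reads <- supp_table(
      data.table::rbindlist(lapply(seq_len(n), function(i) {
        supp_row(anchor_pos = sample(0:20000, 1),
                 side = sample(c("left", "right"), 1),
                 qname = paste0("q", i))
      })))
    got <- cluster_supporting_reads(reads, f95)
    data.table::setorder(got, anchor_pos, side, qname)
    want <- oracle_clusters(got$anchor_pos, got$side, f95)
    # compare partitions: same groups regardless of labels
    expect_identical(
      as.integer(factor(got$cluster_id, levels = unique(got$cluster_id))),
      as.integer(factor(want, levels = unique(want))))
  }
})

test_that("every read lands in exactly one cluster", {
  set.seed(12)
  reads <- data.table::rbindlist(lapply(1:80, function(i) {
    supp_row(anchor_pos = sample(0:50000, 1),
             side = sample(c("left", "right"), 1),
             chrom = sample(c("chr1", "chr2"), 1),
             transposon = sample(c("alpha", "beta"), 1),
             qname = paste0("q", i))
  }))
  reads[, family := transposon]
  got <- cluster_supporting_reads(reads, 466)
  expect_identical(nrow(got), 80L)
  expect_identical(anyDuplicated(got$qname), 0L)
  # clusters never span chromosomes or families
  per <- got[, .(n = data.table::uniqueN(paste(chrom, family))),
             by = cluster_id]
  expect_true(all(per$n == 1L))
})

test_that("breakpoints use modal split site, else rounded mean of 3' ends", {
  cl <- supp_table(
    supp_row(anchor_pos = 10000, side = "left", is_split = TRUE, qname = "a"),
    supp_row(anchor_pos = 10000, side = "left", is_split = TRUE, qname = "b"),
    supp_row(anchor_pos = 10000, side = "right", is_split = TRUE, qname = "c"),
    supp_row(anchor_pos = 10002, side = "right", is_split = TRUE, qname = "d"),
    supp_row(anchor_pos = 9800, side = "left", qname = "e"))
  expect_identical(call_breakpoint(cl), 10000L)
  # tie in split sites: smallest coordinate wins
  tie <- supp_table(
    supp_row(anchor_pos = 10002, side = "left", is_split = TRUE, qname = "a"),
    supp_row(anchor_pos = 10000, side = "right", is_split = TRUE, qname = "b"))
  expect_identical(call_breakpoint(tie), 10000L)
  # no split reads: mean of anchor 3' ends, rounded half-up
  nospl <- supp_table(
    supp_row(anchor_pos = 9990, side = "left"),
    supp_row(anchor_pos = 10010, side = "right"))
  expect_identical(call_breakpoint(nospl), 10000L)
  expect_identical(call_breakpoint(supp_row(anchor_pos = 5000,
                                            side = "left")), 5000L)
  # half-up rounding
  half <- supp_table(supp_row(anchor_pos = 10, side = "left", qname = "x"),
                     supp_row(anchor_pos = 11, side = "left", qname = "y"))
  expect_identical(call_breakpoint(half), 11L)
})

test_that("cluster classes follow side structure and read count", {
  both <- supp_table(
    supp_row(anchor_pos = 1:3 * 10, side = "left",
             qname = paste0("l", 1:3)),
    supp_row(anchor_pos = 4:5 * 10, side = "right",
             qname = paste0("r", 1:2)))
  expect_identical(classify_cluster(both), "1p1")
  one_side <- supp_table(
    supp_row(anchor_pos = 1:4 * 10, side = "left", qname = paste0("l", 1:4)))
  expect_identical(classify_cluster(one_side), "2p")
  expect_identical(classify_cluster(supp_row(anchor_pos = 5, side = "left")),
                   "singleton")
})

test_that("insertion frequency formula and monotonicity", {
  expect_equal(estimate_insertion_frequency(10, 10), 1 / 3)
  expect_equal(estimate_insertion_frequency(5, 0), 1)
  expect_equal(estimate_insertion_frequency(1, 49), 1 / 99, tolerance = 1e-4)
  # monotone in S, antitone in R
  S <- 1:50
  expect_true(all(diff(estimate_insertion_frequency(S, 10)) > 0))
  R <- 0:50
  expect_true(all(diff(estimate_insertion_frequency(10, R)) < 0))
})

test_that("reference reads are proper unsplit pairs whose fragment crosses", {
  bp <- 10000L
  calls <- data.table::data.table(chrom = "chr1", breakpoint = bp)
  mk <- function(qname, s, e, ...) {
    pair_row(qname = qname, pos1 = s, end1 = s + 100L, pos2 = e - 100L,
             end2 = e, ...)
  }
  pairs <- data.table::rbindlist(list(
    mk("spans_wide", bp - 250L, bp + 250L),         # counts
    mk("read_crosses", bp - 80L, bp + 350L),        # read1 covers bp+-21
    mk("gap_crosses", bp - 200L, bp + 220L),        # junction in gap: counts
    mk("exact20", bp - 20L, bp + 400L),             # only 20 bases left: no
    mk("left_of", bp - 900L, bp - 450L),            # does not cross
    mk("clipped", bp - 250L, bp + 250L, clip5_2 = 30L),  # split pair: no
    mk("improper", bp - 250L, bp + 250L, proper = FALSE),
    mk("multimapped", bp - 250L, bp + 250L, mapq1 = 0L)
  ))
  expect_identical(count_reference_reads(calls, pairs), 3L)
})

test_that("te end prediction is the envelope of consensus hits", {
  cl <- supp_table(
    supp_row(anchor_pos = 1, side = "left", hit_start = 0, hit_end = 95,
             qname = "a"),
    supp_row(anchor_pos = 2, side = "right", hit_start = 4900,
             hit_end = 4980, qname = "b", hit_strand = "+"))
  expect_identical(predict_te_ends(cl), c(0L, 4980L))
  single <- supp_row(anchor_pos = 3, side = "left", hit_start = 200,
                     hit_end = 290)
  expect_identical(predict_te_ends(single), c(200L, 290L))
})
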