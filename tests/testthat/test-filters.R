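mk_call <- function(chrom = "chr1", breakpoint, transposon,
                    family = transposon, n_support = 10L,
                    n_support_5p = 5L, n_support_3p = 5L,
                    n_reference = 10L, class = "1p1", strand = "+",
                    te_start = 0L, te_end = 500L, cluster_id = 1L) {
  data.table::data.table(
    chrom = chrom, breakpoint = as.integer(breakpoint),
    transposon = transposon, family = family, strand = strand,
    class = class, n_support = as.integer(n_support),
    n_support_5p = as.integer(n_support_5p),
    n_support_3p = as.integer(n_support_3p),
    n_reference = as.integer(n_reference),
    frequency = estimate_insertion_frequency(n_support, n_reference),
    te_start = te_start, te_end = te_end,
    cluster_id = as.integer(cluster_id))
}

roo_ann <- repeat_annotation(data.frame(
  chrom = "chr1", start = 900L, end = 6000L, transposon = "roo",
  strand = "+"))

test_that("same-transposon filter removes, blacklists, and spares others", {
  calls <- data.table::rbindlist(list(
    mk_call(breakpoint = 1000, transposon = "roo", cluster_id = 1),
    mk_call(breakpoint = 1000, transposon = "blood", cluster_id = 2),
    mk_call(breakpoint = 3000, transposon = "copia", cluster_id = 3),
    mk_call(breakpoint = 9000, transposon = "roo", cluster_id = 4)))
  r <- filter_same_transposon(calls, roo_ann)
  # roo inside its own annotated copy: removed and blacklisted
  expect_true(1000 %in% r$blacklist$breakpoint)
  # blood at the blacklisted position: removed although a different family
  expect_false(any(r$kept$transposon == "blood"))
  # copia inside the roo copy: different family, kept
  expect_true("copia" %in% r$kept$transposon)
  # roo outside the copy: kept
  expect_true(9000 %in% r$kept$breakpoint)
  expect_identical(nrow(r$kept) + nrow(r$removed), nrow(calls))
})

test_that("annotation pad extends the same-transposon interval", {
  calls <- mk_call(breakpoint = 6200, transposon = "roo")
  expect_identical(nrow(filter_same_transposon(calls, roo_ann,
                                               pad = 0L)$removed), 0L)
  expect_identical(nrow(filter_same_transposon(calls, roo_ann,
                                               pad = 400L)$removed), 1L)
})

test_that("library family map drives the same-family rule", {
  lib <- te_library(c(roo = random_dna(60, seed = 2), roo2 = random_dna(60)),
                    family = c(roo = "roo", roo2 = "roo"))
  calls <- mk_call(breakpoint = 1000, transposon = "roo2", family = "roo")
  r <- filter_same_transposon(calls, roo_ann, library = lib)
  expect_identical(nrow(r$removed), 1L)
})

test_that("high-coverage filter removes calls in >= ratio x mean windows", {
  # 40 windows of background (one read start each) + one pileup window
  set.seed(4)
  bg <- data.table::rbindlist(lapply(0:39, function(w) {
    pair_row(qname = paste0("bg", w), pos1 = w * 1000L + 100L,
             end1 = w * 1000L + 200L, pos2 = w * 1000L + 400L,
             end2 = w * 1000L + 500L)
  }))
  hot <- data.table::rbindlist(lapply(1:50, function(i) {
    pair_row(qname = paste0("hot", i), pos1 = 5000L + i, end1 = 5100L + i,
             pos2 = 5200L + i, end2 = 5300L + i)
  }))
  pairs <- data.table::rbindlist(list(bg, hot))
  calls <- data.table::rbindlist(list(
    mk_call(breakpoint = 5500, transposon = "roo"),    # in the hot window
    mk_call(breakpoint = 20500, transposon = "roo")))  # background
  r <- filter_high_coverage(calls, pairs, window = 1000L, ratio = 5)
  expect_identical(r$removed$breakpoint, 5500L)
  expect_identical(r$kept$breakpoint, 20500L)
  expect_error(coverage_profile(pair_row(mapped1 = FALSE, mapped2 = FALSE)),
               "depth")
})

test_that("uniform simulated coverage removes nothing", {
  fix <- small_sim()
  res <- detect_insertions(fix$pairs, fix$lib,
                           annotation = fix$emb$annotation)
  expect_identical(nrow(res$removed_coverage), 0L)
})

test_that("same-position merge pools reads onto the dominant transposon", {
  calls <- data.table::rbindlist(list(
    mk_call(breakpoint = 5000, chrom = "chr2", transposon = "TE_A",
            n_support = 7, n_support_5p = 4, n_support_3p = 3,
            cluster_id = 1),
    mk_call(breakpoint = 5000, chrom = "chr2", transposon = "TE_B",
            n_support = 3, n_support_5p = 3, n_support_3p = 0,
            cluster_id = 2)))
  m <- merge_same_position(calls)
  expect_identical(nrow(m), 1L)
  expect_identical(m$transposon, "TE_A")
  expect_identical(m$n_support, 10L)
  expect_equal(m$frequency, 10 / 30)
  # read conservation
  expect_identical(sum(m$n_support), sum(calls$n_support))
  # tie: lexicographically first transposon
  tie <- data.table::rbindlist(list(
    mk_call(breakpoint = 5000, transposon = "TE_B", n_support = 5,
            cluster_id = 1),
    mk_call(breakpoint = 5000, transposon = "TE_A", n_support = 5,
            cluster_id = 2)))
  mt <- merge_same_position(tie)
  expect_identical(mt$transposon, "TE_A")
  expect_identical(mt$n_support, 10L)
  # single call untouched
  single <- mk_call(breakpoint = 7777, transposon = "solo")
  expect_identical(merge_same_position(single)$breakpoint, 7777L)
})

test_that("filters are idempotent", {
  calls <- data.table::rbindlist(list(
    mk_call(breakpoint = 1000, transposon = "roo", cluster_id = 1),
    mk_call(breakpoint = 9000, transposon = "roo", cluster_id = 2),
    mk_call(breakpoint = 9000, transposon = "blood", cluster_id = 3,
            n_support = 2)))
  r1 <- filter_same_transposon(calls, roo_ann)
  r2 <- filter_same_transposon(r1$kept, roo_ann, blacklist = r1$blacklist)
  expect_identical(r2$kept, r1$kept)

  m1 <- merge_same_position(calls)
  m2 <- merge_same_position(m1)
  expect_equal(m2, m1)

  pairs <- data.table::rbindlist(lapply(0:19, function(w) {
    pair_row(qname = paste0("p", w), pos1 = w * 1000L + 10L,
             end1 = w * 1000L + 110L)
  }))
  h1 <- filter_high_coverage(calls, pairs, window = 1000L, ratio = 5)
  h2 <- filter_high_coverage(h1$kept, pairs, window = 1000L, ratio = 5)
  expect_identical(h2$kept, h1$kept)
})
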