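long_record <- function(qname, chrom, pos, cigar, seq, flag = 0L) {
  data.table::data.table(qname = qname, flag = flag, chrom = chrom,
                         pos = as.integer(pos), mapq = 60L, cigar = cigar,
                         mchrom = NA_character_, mpos = NA_integer_,
                         seq = seq, tlen = 0L)
}

test_that("CIGAR insertion operations become events at the right spot", {
  seq <- paste0(random_dna(1000, seed = 141), strrep("G", 400),
                random_dna(1000))
  rec <- long_record("r1", "chr1", 5000, "1000M400I1000M", seq)
  ev <- extract_long_insertions(rec, min_len = 300L)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$pos, 6000L)
  expect_identical(ev$len, 400L)
  expect_identical(ev$seq, strrep("G", 400))
  # shorter insertions are ignored
  rec2 <- long_record("r2", "chr1", 5000, "1000M250I1000M",
                      random_dna(2250))
  expect_identical(nrow(extract_long_insertions(rec2)), 0L)
  # two large insertions in one read give two events
  seq3 <- paste0(random_dna(500), strrep("A", 300), random_dna(500),
                 strrep("C", 350), random_dna(500))
  rec3 <- long_record("r3", "chr1", 0, "500M300I500M350I500M", seq3)
  ev3 <- extract_long_insertions(rec3)
  expect_identical(ev3$pos, c(500L, 1000L))
  expect_identical(ev3$len, c(300L, 350L))
})

test_that("validation enforces aligned length and end windows", {
  cons <- random_dna(4000, seed = 142)
  lib <- te_library(c(TEq = cons))
  # nearly full-length insert: valid
  good <- validate_te_insertion(substr(cons, 101, 4000), lib)
  expect_identical(good$transposon, "TEq")
  # only ~1900 of 4000 aligned: below half, invalid
  bad_half <- paste0(substr(cons, 1, 1900), random_dna(2100))
  # the random tail keeps the insert length at 4000 but only 1900 align
  expect_null(validate_te_insertion(bad_half, lib))
  # alignment starts 600 nt into the insert: outside the 500-nt window
  bad_start <- paste0(random_dna(600), substr(cons, 1, 3000))
  expect_null(validate_te_insertion(bad_start, lib))
})

test_that("merging pools events within 50 bp and drops loners", {
  ev <- data.table::data.table(
    qname = paste0("r", 1:5),
    chrom = "chr1",
    pos = c(10000L, 10000L, 10000L, 10020L, 20000L),
    transposon = "TEq",
    hit_start = c(0L, 5L, 0L, 2L, 0L),
    hit_end = c(4000L, 3990L, 4000L, 3995L, 4000L))
  cur <- merge_and_filter(ev)
  expect_identical(nrow(cur), 1L)            # loner at 20000 dropped
  expect_identical(cur$breakpoint, 10000L)   # modal position
  expect_identical(cur$n_supporting, 4L)
  expect_identical(cur$te_start, 0L)
  expect_identical(cur$te_end, 4000L)
  # events 60 bp apart stay separate insertions
  ev2 <- data.table::data.table(qname = paste0("s", 1:4), chrom = "chr1",
                                pos = c(1000L, 1000L, 1060L, 1060L),
                                transposon = "TEq")
  expect_identical(nrow(merge_and_filter(ev2)), 2L)
})

test_that("long-read frequency counts both-end traversals twice", {
  bp <- 5000L
  # 4 supporting (2 insertion-carrying reads, each counted twice),
  # 4 reference reads crossing by >= 50
  recs <- data.table::rbindlist(c(
    lapply(1:2, function(i) long_record(paste0("ins", i), "chr1", 4000,
                                        "1000M400I1000M", random_dna(2400))),
    lapply(1:4, function(i) long_record(paste0("ref", i), "chr1", 4500,
                                        "1000M", random_dna(1000))),
    # crosses the breakpoint by only 30 bp: neither reference nor support
    list(long_record("short", "chr1", 4030, "1000M", random_dna(1000)))
  ))
  ev <- extract_long_insertions(recs)
  f <- longread_frequency(bp, "chr1", recs, ev)
  expect_identical(f$S, 4L)
  expect_identical(f$R, 4L)
  expect_equal(f$frequency, 4 / 12)
  # clipped alignment near the breakpoint counts as one supporting read
  recs2 <- data.table::rbindlist(list(
    long_record("clip", "chr1", 4000, "1000M500S", random_dna(1500)),
    long_record("ref", "chr1", 4000, "2000M", random_dna(2000))))
  f2 <- longread_frequency(bp, "chr1", recs2, NULL)
  expect_identical(f2$S, 1L)
  expect_identical(f2$R, 1L)
})

test_that("a half-frequency insertion lands inside its binomial interval", {
  set.seed(143)
  n <- 40
  carrier <- rbinom(n, 1, 0.5) == 1
  recs <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    if (carrier[i]) {
      long_record(paste0("c", i), "chr1", 4000, "1000M400I1000M",
                  random_dna(2400))
    } else {
      long_record(paste0("n", i), "chr1", 4000, "2000M", random_dna(2000))
    }
  }))
  ev <- extract_long_insertions(recs)
  f <- longread_frequency(5000L, "chr1", recs, ev)
  k <- sum(carrier)
  ci <- stats::binom.test(k, n)$conf.int
  expect_equal(f$frequency, k / n)   # both-end double counting cancels
  expect_gte(f$frequency, ci[1])
  expect_lte(f$frequency, ci[2])
})

test_that("end-to-end curation recovers a constructed insertion", {
  set.seed(144)
  genome <- c(chr1 = random_dna(20000))
  cons <- random_dna(2000)
  lib <- te_library(c(TEz = cons))
  mk_read <- function(qname, start, ins_at, with_ins) {
    # 7-kb read; insertion (if any) at reference position ins_at
    left <- substr(genome[["chr1"]], start + 1, ins_at)
    right <- substr(genome[["chr1"]], ins_at + 1, start + 7000)
    if (with_ins) {
      long_record(qname, "chr1", start,
                  sprintf("%dM2000I%dM", nchar(left), nchar(right)),
                  paste0(left, cons, right))
    } else {
      long_record(qname, "chr1", start,
                  sprintf("%dM", nchar(left) + nchar(right)),
                  paste0(left, right))
    }
  }
  recs <- data.table::rbindlist(list(
    mk_read("a", 2000, 8000, TRUE),
    mk_read("b", 2010, 8000, TRUE),
    mk_read("c", 2050, 8000, TRUE),
    mk_read("d", 2100, 8000, FALSE),
    mk_read("lone", 12000, 14000, TRUE)))
  path <- write_test_sam(recs, c(chr1 = 30000L))
  cur <- curate_longread_insertions(path, lib)
  expect_identical(nrow(cur), 1L)
  expect_identical(cur$breakpoint, 8000L)
  expect_identical(cur$transposon, "TEz")
  expect_gte(cur$n_supporting, 2L)
  expect_true(cur$frequency > 0.5)  # 3 of 4 haplotypes carry it
})
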