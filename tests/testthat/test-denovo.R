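test_that("end regions follow f95 - 25 with center-undefined flagging", {
  lib <- te_library(c(big = random_dna(5000, seed = 61),
                      small = random_dna(800),
                      mid = random_dna(900)))
  spec <- define_end_regions(lib, f95 = 466)
  big <- spec[transposon == "big"]
  expect_identical(big$l_end, 441L)
  expect_identical(big$end5_hi, 441L)
  expect_identical(big$end3_lo, 4559L)
  expect_true(big$center_defined)
  expect_false(spec[transposon == "small"]$center_defined)
  # degenerate but valid tiny f95
  spec2 <- define_end_regions(lib, f95 = 26)
  expect_identical(spec2$l_end[1], 1L)
})

mk_hit <- function(transposon, mid, strand = "-", family = transposon,
                   side = "left", qname = NULL, width = 100L) {
  supp_row(anchor_pos = sample.int(1e6, 1), side = side,
           transposon = transposon, family = family,
           hit_start = as.integer(mid - width / 2),
           hit_end = as.integer(mid + width / 2), hit_strand = strand,
           qname = if (is.null(qname)) paste0("h", mid, strand) else qname)
}

test_that("singleton tallies split end versus center with orientation", {
  lib <- te_library(c(TEx = random_dna(5000, seed = 62)))
  spec <- define_end_regions(lib, 466)
  singles <- data.table::rbindlist(list(
    mk_hit("TEx", 150, "-"),          # 5' end, correct orientation
    mk_hit("TEx", 4800, "+"),         # 3' end, correct orientation
    mk_hit("TEx", 150, "+"),          # 5' end, wrong orientation -> center
    mk_hit("TEx", 2050, "-"),         # true center
    mk_hit("TEx", 2100, "+")))
  raw <- data.table::rbindlist(lapply(seq(100, 4900, by = 100), function(m)
    mk_hit("TEx", m, qname = paste0("raw", m))))
  tal <- tally_end_center(singles, raw, spec, orientation_check = TRUE)
  expect_identical(tal$SE, 2L)
  expect_identical(tal$SC, 3L)
  expect_identical(tal$AE + tal$AC, nrow(raw))
  # without the orientation check the wrongly oriented end read counts
  tal2 <- tally_end_center(singles, raw, spec, orientation_check = FALSE)
  expect_identical(tal2$SE, 3L)
})

test_that("the four side x strand geometries imply the expected terminus", {
  # enumeration oracle: a minus-strand consensus hit means the mate reads
  # out of the 5' terminus; plus-strand out of the 3' terminus -- on either
  # anchor side (the side fixes the insertion orientation instead)
  lib <- te_library(c(TEo = random_dna(4000, seed = 63)))
  spec <- define_end_regions(lib, 466)
  combos <- data.table::CJ(side = c("left", "right"), strand = c("+", "-"))
  for (i in seq_len(nrow(combos))) {
    near5 <- mk_hit("TEo", 100, combos$strand[i], side = combos$side[i])
    near3 <- mk_hit("TEo", 3900, combos$strand[i], side = combos$side[i])
    t5 <- tally_end_center(near5, NULL, spec)$SE
    t3 <- tally_end_center(near3, NULL, spec)$SE
    if (combos$strand[i] == "-") {
      expect_identical(c(t5, t3), c(1L, 0L))
    } else {
      expect_identical(c(t5, t3), c(0L, 1L))
    }
  }
})

test_that("chimera correction reproduces the printed arithmetic", {
  tal <- data.table::data.table(family = "TEx", SE = 10L, SC = 2L,
                                AE = 50L, AC = 50L)
  est <- estimate_de_novo(tal, total_depth = 20, read_length = 100,
                          frag_mean = 450, f95 = 466)
  expect_equal(est$corrected_reads, 8)
  expect_equal(est$confidence, 0.8)
  # SE below the expected chimera level floors at zero
  tal2 <- data.table::data.table(family = "roo", SE = 5L, SC = 20L,
                                 AE = 30L, AC = 30L)
  est2 <- estimate_de_novo(tal2, 20, 100, 450, 466)
  expect_equal(est2$corrected_reads, 0)
  expect_equal(est2$confidence, 0)
})

test_that("pure chimera reads give a corrected count centred on zero", {
  # uniform singleton and raw positions on one consensus, no insertions:
  # across replicates the uncorrected difference SE - SC * AE/AC has mean
  # within 3 standard errors of zero
  lib <- te_library(c(TEc = random_dna(5000, seed = 64)))
  spec <- define_end_regions(lib, 466)
  set.seed(65)
  diffs <- replicate(150, {
    mids <- runif(60, 50, 4950)
    singles <- data.table::rbindlist(lapply(seq_along(mids), function(i)
      mk_hit("TEc", mids[i], sample(c("+", "-"), 1),
             qname = paste0("s", i))))
    rmids <- runif(400, 50, 4950)
    raw <- data.table::rbindlist(lapply(seq_along(rmids), function(i)
      mk_hit("TEc", rmids[i], qname = paste0("r", i))))
    tal <- tally_end_center(singles, raw, spec, orientation_check = FALSE)
    tal$SE - tal$SC * tal$AE / tal$AC
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("confidence is monotone decreasing in SC", {
  vals <- vapply(0:9, function(sc) {
    tal <- data.table::data.table(family = "x", SE = 10L, SC = sc,
                                  AE = 40L, AC = 40L)
    estimate_de_novo(tal, 20, 100, 450, 466)$confidence
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("fragmented-copy ends activate only with enough reads", {
  lib <- te_library(c(TEf = random_dna(5000, seed = 66)))
  spec <- define_end_regions(lib, 466)
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = 10000L, end = 12000L, transposon = "TEf",
    strand = "+"))
  ann[, `:=`(te_start = 1500L, te_end = 3500L)]
  # fragment ends at consensus 1500 / 3500: center under the default spec
  singles3 <- data.table::rbindlist(c(
    lapply(1:3, function(i) mk_hit("TEf", 1550 + i, "-",
                                   qname = paste0("a", i))),
    lapply(1:3, function(i) mk_hit("TEf", 3450 - i, "+",
                                   qname = paste0("b", i)))))
  extra <- include_fragmented_copies(ann, lib, spec, singles3)
  expect_identical(nrow(extra), 2L)
  tal <- tally_end_center(singles3, NULL, spec, extra_ends = extra)
  expect_identical(tal$SE, 6L)
  # without the fragmented mode those reads are center-mapping
  tal0 <- tally_end_center(singles3, NULL, spec)
  expect_identical(tal0$SE, 0L)
  # one end short of support: nothing activates
  singles2 <- singles3[qname != "b3"]
  expect_identical(nrow(include_fragmented_copies(ann, lib, spec,
                                                  singles2)), 0L)
})

test_that("fragment spans can be inferred by aligning the copy sequence", {
  cons <- random_dna(4000, seed = 67)
  lib <- te_library(c(TEg = cons))
  frag <- substr(cons, 1001, 2800)
  genome <- c(chr1 = paste0(random_dna(2000), frag, random_dna(2000)))
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = 2000L, end = 2000L + nchar(frag),
    transposon = "TEg", strand = "+"))
  spans <- tescope:::infer_copy_spans(ann, lib, genome)
  expect_identical(spans$te_start, 1000L)
  expect_identical(spans$te_end, 2800L)
})

test_that("somatic simulation recovers per-genome insertion rates", {
  g <- synthetic_genome(c(chrA = 250000, chrB = 250000), seed = 71)
  lib <- synthetic_te_library(n_te = 5, len_range = c(2000, 3000),
                              n_sibling_pairs = 0, seed = 72)
  emb <- embed_te_copies(g, lib, copies_per_te = 1, spacing = 12000,
                         seed = 73)
  cfg <- simulation_config(n_genomes = 1500, n_germline = 0,
                           somatic_counts = c(TE02 = 3L, TE04 = 1L),
                           depth = 15, chimera_rate = 5e-4, seed = 74)
  sim <- simulate_population(emb$genome, lib, cfg,
                             annotation = emb$annotation)
  est <- estimate_denovo_rates(read_alignment_pairs(sim$sam), lib,
                               annotation = emb$annotation)
  truth <- data.table::fread(sim$truth["somatic"])
  r <- de_novo_ssr(est, truth)
  expect_lt(r$ssr, 1.5)
  expect_gt(r$pearson_r, 0.98)
  # families without simulated insertions stay near zero
  zero <- r$table[!family %in% truth$family]
  expect_true(all(zero$est < 0.35))
})
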