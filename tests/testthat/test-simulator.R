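test_that("population construction honours frequencies and partials", {
  g <- synthetic_genome(c(chrA = 150000, chrB = 150000), seed = 81)
  lib <- synthetic_te_library(n_te = 4, len_range = c(1500, 2200),
                              n_sibling_pairs = 0, seed = 82)
  cfg <- simulation_config(n_genomes = 400, n_germline = 20,
                           partial_fraction = 0.2, seed = 83)
  pop <- build_population(g, lib, cfg)
  expect_identical(nrow(pop$germline), 20L)
  # carriers per insertion equal frequency x genomes exactly
  carried <- rowSums(pop$carriers)
  expect_identical(unname(carried),
                   round(pop$germline$frequency * 400))
  # requested share of truncated insertions
  lens <- unname(lib$lengths[pop$germline$transposon])
  partial <- pop$germline$te_start > 0 | pop$germline$te_end < lens
  expect_identical(sum(partial), 4L)
  # spacing: at least two fragment lengths apart (global coordinates)
  expect_true(all(diff(sort(pop$germline$gpos)) >= 2 * cfg$frag_mean))
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  g <- synthetic_genome(c(chrA = 120000), seed = 84)
  lib <- synthetic_te_library(n_te = 3, len_range = c(1500, 2000),
                              n_sibling_pairs = 0, seed = 85)
  emb <- embed_te_copies(g, lib, copies_per_te = 1, spacing = 10000,
                         seed = 86)
  cfg <- simulation_config(n_genomes = 50, n_germline = 4, depth = 8,
                           chimera_rate = 0.002, seed = 87)
  s1 <- simulate_population(emb$genome, lib, cfg,
                            annotation = emb$annotation)
  s2 <- simulate_population(emb$genome, lib, cfg,
                            annotation = emb$annotation)
  expect_identical(unname(tools::md5sum(s1$sam)),
                   unname(tools::md5sum(s2$sam)))
  expect_identical(s1$population$germline, s2$population$germline)
  expect_identical(s1$chimeric_qnames, s2$chimeric_qnames)
  expect_identical(unname(tools::md5sum(s1$truth["germline"])),
                   unname(tools::md5sum(s2$truth["germline"])))
})

test_that("read yield matches the requested depth", {
  fix <- small_sim()
  pairs <- fix$pairs
  glen <- sum(nchar(fix$emb$genome))
  mapped_nt <- sum(pairs$end1 - pairs$pos1, na.rm = TRUE) +
    sum(pairs$end2 - pairs$pos2, na.rm = TRUE)
  depth <- mapped_nt / glen
  expect_lt(abs(depth - fix$cfg$depth) / fix$cfg$depth, 0.06)
})

test_that("error-free reads are exact substrings of their chromosome", {
  g <- synthetic_genome(c(chrA = 100000), seed = 88)
  lib <- synthetic_te_library(n_te = 2, len_range = c(1500, 1800),
                              n_sibling_pairs = 0, seed = 89)
  cfg <- simulation_config(n_genomes = 10, n_germline = 0, depth = 4,
                           error_rate = 0, seed = 90)
  sim <- simulate_population(g, lib, cfg)
  pairs <- read_alignment_pairs(sim$sam)
  full <- pairs[cigar1 == "100M" & mapped1 == TRUE]
  idx <- head(seq_len(nrow(full)), 50)
  ref <- substring(g[["chrA"]], full$pos1[idx] + 1L, full$pos1[idx] + 100L)
  expect_identical(full$seq1[idx], ref)
})

test_that("chimera injection flags exactly the replaced pairs", {
  g <- synthetic_genome(c(chrA = 150000), seed = 91)
  lib <- synthetic_te_library(n_te = 2, len_range = c(1500, 1800),
                              n_sibling_pairs = 0, seed = 92)
  cfg0 <- simulation_config(n_genomes = 20, n_germline = 0, depth = 10,
                            chimera_rate = 0, seed = 93)
  s0 <- simulate_population(g, lib, cfg0)
  expect_length(s0$chimeric_qnames, 0L)
  cfg1 <- simulation_config(n_genomes = 20, n_germline = 0, depth = 10,
                            chimera_rate = 0.01, seed = 93)
  s1 <- simulate_population(g, lib, cfg1)
  n <- s1$n_pairs
  expect_gt(length(s1$chimeric_qnames), 0L)
  # binomial count within 4 sd
  expect_lt(abs(length(s1$chimeric_qnames) - 0.01 * n),
            4 * sqrt(n * 0.01 * 0.99))
  expect_identical(anyDuplicated(s1$chimeric_qnames), 0L)
})

test_that("truth files carry the population design", {
  g <- synthetic_genome(c(chrA = 200000), seed = 94)
  lib <- synthetic_te_library(n_te = 4, len_range = c(1500, 2000),
                              n_sibling_pairs = 0, seed = 95)
  cfg <- simulation_config(n_genomes = 200, n_germline = 6,
                           somatic_counts = c(TE01 = 2L, TE03 = 1L),
                           depth = 2, seed = 96)
  sim <- simulate_population(g, lib, cfg)
  germ <- read_truth_germline(sim$truth["germline"])
  expect_identical(nrow(germ), 6L)
  expect_true(all(germ$frequency %in% c(0.25, 0.5, 0.75, 1)))
  som <- data.table::fread(sim$truth["somatic"])
  expect_identical(nrow(sim$population$somatic), 3L * 200L)
  expect_equal(som[family == "TE01", per_genome], 2)
  expect_equal(som[family == "TE03", per_genome], 1)
  expect_equal(sum(som$total), 600)
  # empty somatic config: empty table
  cfg0 <- simulation_config(n_genomes = 10, n_germline = 0, depth = 1,
                            seed = 97)
  sim0 <- simulate_population(g, lib, cfg0)
  expect_identical(nrow(data.table::fread(sim0$truth["somatic"])), 0L)
})

test_that("insertion placement rejects impossible spacing demands", {
  g <- synthetic_genome(c(chrA = 30000), seed = 98)
  lib <- synthetic_te_library(n_te = 2, len_range = c(1500, 1600),
                              n_sibling_pairs = 0, seed = 99)
  cfg <- simulation_config(n_genomes = 10, n_germline = 500, seed = 100)
  expect_error(build_population(g, lib, cfg), "too small")
})

test_that("junction-spanning support scales with depth x frequency", {
  fix <- small_sim()
  res <- detect_insertions(fix$pairs, fix$lib,
                           annotation = fix$emb$annotation)
  truth <- fix$sim$population$germline
  m <- match_calls(res$germline, truth, library = fix$lib)
  expect_gt(nrow(m), 0L)
  s <- res$germline$n_support[m$call_row]
  f <- truth$frequency[m$truth_row]
  # support grows with frequency (regression slope strongly positive)
  if (length(unique(f)) > 1L) {
    fit <- lm(s ~ f)
    expect_gt(coef(fit)[["f"]], 0)
  }
})
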