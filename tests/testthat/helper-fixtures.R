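# Shared fixtures for the unit tests: tiny libraries, pair-table rows and
# small simulations, all built in code.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_library <- function(seed = 7L) {
  set.seed(seed)
  te_library(c(
    alpha = random_dna(600),
    beta = random_dna(800),
    gamma = random_dna(500)
  ))
}

# one row of the read-pair table with sensible defaults, for unit tests
# that do not need a SAM file
pair_row <- function(chrom1 = "chr1", pos1 = 1000L, end1 = 1100L,
                     mapq1 = 60L, cigar1 = "100M", seq1 = strrep("A", 100),
                     strand1 = "+", mapped1 = TRUE, clip5_1 = 0L,
                     clip3_1 = 0L,
                     chrom2 = "chr1", pos2 = 1350L, end2 = 1450L,
                     mapq2 = 60L, cigar2 = "100M", seq2 = strrep("A", 100),
                     strand2 = "-", mapped2 = TRUE, clip5_2 = 0L,
                     clip3_2 = 0L,
                     proper = TRUE, tlen = 450L, qname = "q1",
                     n_secondary = 0L) {
  data.table::data.table(
    qname = qname, flag1 = 0L, chrom1 = chrom1, pos1 = pos1, end1 = end1,
    mapq1 = mapq1, cigar1 = cigar1, seq1 = seq1, strand1 = strand1,
    mapped1 = mapped1, clip5_1 = clip5_1, clip3_1 = clip3_1,
    flag2 = 0L, chrom2 = chrom2, pos2 = pos2, end2 = end2, mapq2 = mapq2,
    cigar2 = cigar2, seq2 = seq2, strand2 = strand2, mapped2 = mapped2,
    clip5_2 = clip5_2, clip3_2 = clip3_2, proper = proper, tlen = tlen,
    n_secondary = n_secondary)
}

# a supporting-read row for clustering tests
supp_row <- function(chrom = "chr1", anchor_pos, side, is_split = FALSE,
                     transposon = "alpha", family = transposon,
                     hit_start = 0L, hit_end = 100L, hit_strand = "-",
                     qname = NULL) {
  if (is.null(qname)) qname <- paste0("r", anchor_pos, side)
  data.table::data.table(
    qname = qname, chrom = chrom, anchor_pos = as.integer(anchor_pos),
    side = side, origin = "unmapped", is_split = is_split,
    transposon = transposon, family = family,
    hit_start = as.integer(hit_start), hit_end = as.integer(hit_end),
    hit_strand = hit_strand, identity = 1, score = 100L)
}

supp_table <- function(...) data.table::rbindlist(list(...))

write_test_sam <- function(records, seqinfo) {
  path <- tempfile(fileext = ".sam")
  tescope:::write_sam(records, path, seqinfo)
  path
}

sam_record <- function(qname, flag, chrom, pos, mapq = 60L, cigar = "100M",
                       mchrom = chrom, mpos = pos, tlen = 0L,
                       seq = strrep("A", 100)) {
  data.table::data.table(qname = qname, flag = as.integer(flag),
                         chrom = chrom, pos = as.integer(pos),
                         mapq = as.integer(mapq), cigar = cigar,
                         mchrom = mchrom, mpos = as.integer(mpos),
                         tlen = as.integer(tlen), seq = seq)
}

# brute-force clustering oracle: transitive closure of the pairwise
# linkage rule, used against the union-find implementation
oracle_clusters <- function(pos, side, f95) {
  n <- length(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) adj[i, j] <- tescope:::reads_linked(pos[i], side[i],
                                                    pos[j], side[j], f95)
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# small cached end-to-end simulation shared across test files
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (!is.null(.small_sim_cache$sim)) return(.small_sim_cache$sim)
  g <- synthetic_genome(c(chrA = 200000, chrB = 200000), seed = 11)
  lib <- synthetic_te_library(n_te = 5, len_range = c(1500, 2500),
                              n_sibling_pairs = 1, seed = 12)
  emb <- embed_te_copies(g, lib, copies_per_te = 1, spacing = 12000,
                         seed = 13)
  cfg <- simulation_config(n_genomes = 100, n_germline = 8, depth = 25,
                           chimera_rate = 0.001, seed = 14)
  sim <- simulate_population(emb$genome, lib, cfg,
                             annotation = emb$annotation)
  res <- list(sim = sim, lib = lib, emb = emb, cfg = cfg,
              pairs = read_alignment_pairs(sim$sam))
  .small_sim_cache$sim <- res
  res
}
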