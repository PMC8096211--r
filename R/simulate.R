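# Population sequencing simulator: builds a population of genomes carrying
# germline insertions (shared coordinates, fixed frequencies) and per-genome
# somatic insertions, then samples read-pairs and emits truth alignments in
# SAM together with truth tables -- no external aligner involved.
#
# The emitted alignments emulate a short-read aligner: a read portion maps
# only if it has >= min_anchor nt of mappable sequence; reads whose unique
# (non-transposon) content is shorter than min_anchor are reported at a
# genomic copy of the transposon with MAPQ 0 (multi-mapped) -- transposon
# families have several near-identical genomic copies, so their internal
# reads are never uniquely placeable; junction-overlapping reads carry
# soft-clips at the junction.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' @param sizes Named integer vector of chromosome lengths.
#' @param gc GC content.
#' @param seed Random seed.
#' @return Named character vector of chromosome sequences.
#' @export
synthetic_genome <- function(sizes = c(chrA = 2e6, chrB = 2e6), gc = 0.42,
                             seed = 1L) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(sizes, function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Generate a synthetic transposon consensus library
#'
#' Random consensus sequences with optional pairs of closely related
#' sibling subfamilies (grouped into one family), mimicking the ambiguity
#' of real transposon families.
#'
#' @param n_te Number of base consensus sequences.
#' @param len_range Consensus length range (nt).
#' @param n_sibling_pairs How many consensuses get a ~95%-identical sibling.
#' @param gc GC content.
#' @param seed Random seed.
#' @return A [te_library()].
#' @export
synthetic_te_library <- function(n_te = 40L, len_range = c(1500L, 6000L),
                                 n_sibling_pairs = 3L, gc = 0.45, seed = 1L) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  lens <- as.integer(round(runif(n_te, len_range[1], len_range[2])))
  seqs <- vapply(lens, function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("TE%02d", seq_len(n_te))
  fam <- setNames(names(seqs), names(seqs))
  if (n_sibling_pairs > 0L) {
    base <- names(seqs)[seq_len(min(n_sibling_pairs, n_te))]
    for (nm in base) {
      sib <- paste0(nm, "b")
      s <- strsplit(seqs[[nm]], "")[[1]]
      mut <- sample(length(s), round(0.05 * length(s)))
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
      seqs[sib] <- paste(s, collapse = "")
      fam[sib] <- nm
      fam[nm] <- nm
    }
  }
  te_library(seqs, family = fam)
}

# global<->chromosome coordinate helpers
chrom_offsets <- function(genome) {
  lens <- nchar(genome)
  off <- cumsum(c(0, unname(lens)))[seq_along(lens)]
  names(off) <- names(genome)
  off
}
global_to_chrom <- function(gpos, genome) {
  off <- chrom_offsets(genome)
  lens <- nchar(genome)
  idx <- findInterval(gpos, c(unname(off), sum(lens)),
                      rightmost.closed = FALSE)
  idx[idx > length(off)] <- length(off)
  data.table::data.table(chrom = names(off)[idx],
                         pos = gpos - unname(off)[idx])
}

# sample n global positions avoiding padded intervals and keeping a minimum
# spacing between picks; errors out when the genome cannot host them
sample_insertion_sites <- function(n, genome, avoid = NULL, pad = 1000L,
                                   spacing = 900L, edge = 2000L,
                                   max_tries = 50L) {
  total <- sum(nchar(genome))
  off <- chrom_offsets(genome)
  lens <- nchar(genome)
  # avoid chromosome edges and N runs
  avoid_iv <- data.table::rbindlist(list(
    data.table::data.table(s = unname(off), e = unname(off) + edge),
    data.table::data.table(s = unname(off) + unname(lens) - edge,
                           e = unname(off) + unname(lens))
  ))
  for (i in seq_along(genome)) {
    m <- gregexpr("N+", genome[[i]])[[1]]
    if (m[1] != -1L) {
      avoid_iv <- data.table::rbindlist(list(avoid_iv, data.table::data.table(
        s = off[i] + as.integer(m) - 1L - 200L,
        e = off[i] + as.integer(m) - 1L + attr(m, "match.length") + 200L)))
    }
  }
  if (!is.null(avoid) && nrow(avoid) > 0L) {
    gl <- off[avoid$chrom] + avoid$start
    avoid_iv <- data.table::rbindlist(list(avoid_iv, data.table::data.table(
      s = unname(gl) - pad, e = unname(gl) + (avoid$end - avoid$start) + pad)))
  }
  data.table::setkey(avoid_iv, s, e)
  picked <- integer(0)
  for (try in seq_len(max_tries)) {
    cand <- sort(as.integer(floor(runif(4L * n, 0, total))))
    if (nrow(avoid_iv)) {
      q <- data.table::data.table(s = cand, e = cand + 1L)
      ov <- data.table::foverlaps(q, avoid_iv, type = "any", which = TRUE,
                                  nomatch = NA)
      cand <- cand[!(seq_along(cand) %in% ov$xid[!is.na(ov$yid)])]
    }
    for (p in cand) {
      if (length(picked) == n) break
      if (all(abs(picked - p) >= spacing)) picked <- c(picked, p)
    }
    if (length(picked) == n) break
  }
  if (length(picked) < n) {
    stop("genome too small to place ", n,
         " insertions at the requested spacing")
  }
  sort(picked)
}

#' Embed annotated transposon copies into a reference genome
#'
#' Inserts `copies_per_te` full-length copies of every consensus (plus any
#' requested truncated copies) at spaced positions, returning the modified
#' genome and the matching repeat annotation. Embedded copies make
#' transposon-internal reads multi-mappable and give the same-transposon
#' filter something to act on, as in real genomes.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param library A [te_library()].
#' @param copies_per_te Full-length copies per consensus.
#' @param truncated Optional `data.frame(transposon, te_start, te_end)` of
#'   truncated copies to embed (consensus coordinates, 0-based half-open).
#' @param spacing Minimum distance between embedded copies.
#' @param seed Random seed.
#' @return List with `genome` (copies inserted) and `annotation` (a
#'   [repeat_annotation()] with extra `te_start`/`te_end` columns).
#' @export
embed_te_copies <- function(genome, library, copies_per_te = 2L,
                            truncated = NULL, spacing = 8000L, seed = 1L) {
  set.seed(seed)
  plan <- data.table::data.table(
    transposon = rep(names(library$entries), each = copies_per_te),
    te_start = 0L,
    te_end = rep(unname(library$lengths), each = copies_per_te))
  if (!is.null(truncated)) {
    plan <- data.table::rbindlist(list(
      plan, data.table::as.data.table(truncated)[
        , .(transposon, te_start = as.integer(te_start),
            te_end = as.integer(te_end))]))
  }
  plan[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  sites <- sample_insertion_sites(nrow(plan), genome, spacing = spacing)
  plan[, gpos := sample(sites)]
  data.table::setorder(plan, gpos)
  loc <- global_to_chrom(plan$gpos, genome)
  plan[, `:=`(chrom = loc$chrom, pos = loc$pos)]
  # insert sequences chromosome by chromosome, right to left
  newg <- genome
  for (ch in unique(plan$chrom)) {
    rows <- plan[chrom == ch][order(-pos)]
    s <- newg[[ch]]
    for (i in seq_len(nrow(rows))) {
      ins <- substr(library$entries[[rows$transposon[i]]],
                    rows$te_start[i] + 1L, rows$te_end[i])
      if (rows$strand[i] == "-") ins <- revcomp(ins)
      s <- paste0(substr(s, 1L, rows$pos[i]), ins,
                  substr(s, rows$pos[i] + 1L, nchar(s)))
    }
    newg[[ch]] <- s
  }
  # recompute annotation coordinates on the modified genome
  plan[, len := te_end - te_start]
  plan[, offs := cumsum(data.table::shift(len, fill = 0L)), by = chrom]
  ann <- plan[, .(chrom, start = pos + offs, end = pos + offs + len,
                  transposon, strand, te_start, te_end)]
  list(genome = newg, annotation = repeat_annotation(ann))
}

#' Simulation configuration
#'
#' Bundles the population and sequencing parameters of
#' [simulate_population()]. Defaults reproduce the benchmark design:
#' 10,000 genomes, 100-nt reads, 450 +- 10 nt fragments, germline
#' insertion frequencies 0.25/0.5/0.75/1.
#'
#' @param n_genomes Number of genomes in the population.
#' @param n_germline Number of germline insertions (0 for none).
#' @param frequencies Germline frequency levels, recycled across insertions.
#' @param partial_fraction Fraction of germline insertions that are
#'   truncated.
#' @param somatic_counts Named integer vector: somatic insertions per genome
#'   for each transposon (others get none).
#' @param somatic_spans Optional `data.frame(transposon, te_start, te_end)`:
#'   somatic insertions of these transposons insert only the given fragment.
#' @param read_length,frag_mean,frag_sd Read and fragment-length model.
#' @param depth Total genome-mapped sequencing depth across the population
#'   (x reference length).
#' @param chimera_rate Fraction of read-pairs replaced by chimeric pairs.
#' @param error_rate Per-base substitution error rate.
#' @param min_anchor Minimum mappable portion for the aligner emulation.
#' @param seed Random seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_genomes = 10000L, n_germline = 0L,
                              frequencies = c(0.25, 0.5, 0.75, 1),
                              partial_fraction = 0.1,
                              somatic_counts = NULL, somatic_spans = NULL,
                              read_length = 100L, frag_mean = 450,
                              frag_sd = 10, depth = 20,
                              chimera_rate = 0, error_rate = 0.001,
                              min_anchor = 20L, seed = 1L) {
  stopifnot(all(frequencies > 0), all(frequencies <= 1),
            chimera_rate >= 0, chimera_rate < 1, depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Build a population of genomes with germline and somatic insertions
#'
#' Germline insertions occupy the same coordinate in every carrier genome
#' (carriers drawn once per insertion at the configured frequency); somatic
#' insertions land at genome-specific uniform-random coordinates. Sites
#' avoid chromosome edges, N runs, annotated copies (1 kb pad) and keep at
#' least two fragment lengths of spacing.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param library A [te_library()].
#' @param config A [simulation_config()].
#' @param annotation Optional [repeat_annotation()] of embedded copies to
#'   avoid.
#' @return List of class `te_population`: `germline` truth table,
#'   `carriers` (logical matrix insertion x genome), `somatic` truth table.
#' @export
build_population <- function(genome, library, config, annotation = NULL) {
  set.seed(config$seed)
  spacing <- as.integer(2 * config$frag_mean)
  off <- chrom_offsets(genome)
  germline <- data.table::data.table(
    insertion_id = character(0), chrom = character(0), pos = integer(0),
    gpos = integer(0), transposon = character(0), strand = character(0),
    te_start = integer(0), te_end = integer(0), frequency = numeric(0))
  carriers <- NULL
  if (config$n_germline > 0L) {
    n <- config$n_germline
    sites <- sample_insertion_sites(n, genome, avoid = annotation,
                                    pad = 1000L, spacing = spacing)
    tes <- sample(names(library$entries), n, replace = TRUE)
    lens <- unname(library$lengths[tes])
    te_start <- integer(n)
    te_end <- lens
    n_partial <- round(config$partial_fraction * n)
    if (n_partial > 0L) {
      pidx <- sample(n, n_partial)
      for (i in pidx) {
        L <- lens[i]
        plen <- as.integer(round(runif(1, max(500L, 0.2 * L), 0.8 * L)))
        s <- as.integer(floor(runif(1, 0, L - plen)))
        te_start[i] <- s
        te_end[i] <- s + plen
      }
    }
    freq <- rep_len(config$frequencies, n)[sample(n)]
    loc <- global_to_chrom(sites, genome)
    germline <- data.table::data.table(
      insertion_id = sprintf("G%04d", seq_len(n)),
      chrom = loc$chrom, pos = loc$pos, gpos = sites,
      transposon = tes,
      strand = sample(c("+", "-"), n, replace = TRUE),
      te_start = te_start, te_end = te_end, frequency = freq)
    carriers <- matrix(FALSE, nrow = n, ncol = config$n_genomes)
    for (i in seq_len(n)) {
      k <- round(freq[i] * config$n_genomes)
      carriers[i, sample.int(config$n_genomes, k)] <- TRUE
    }
  }
  somatic <- data.table::data.table(
    insertion_id = character(0), genome_id = integer(0),
    chrom = character(0), pos = integer(0), gpos = integer(0),
    transposon = character(0), strand = character(0),
    te_start = integer(0), te_end = integer(0))
  if (!is.null(config$somatic_counts) && sum(config$somatic_counts) > 0L) {
    per_genome <- sum(config$somatic_counts)
    total <- per_genome * config$n_genomes
    tes <- rep(rep(names(config$somatic_counts),
                   times = config$somatic_counts), config$n_genomes)
    gids <- rep(seq_len(config$n_genomes), each = per_genome)
    # genome-specific uniform coordinates outside padded copies
    sites <- sample_somatic_sites(total, genome, annotation, pad = 1000L)
    lens <- unname(library$lengths[tes])
    te_start <- integer(total)
    te_end <- lens
    if (!is.null(config$somatic_spans)) {
      sp <- data.table::as.data.table(config$somatic_spans)
      for (r in seq_len(nrow(sp))) {
        sel <- tes == sp$transposon[r]
        te_start[sel] <- as.integer(sp$te_start[r])
        te_end[sel] <- as.integer(sp$te_end[r])
      }
    }
    loc <- global_to_chrom(sites, genome)
    somatic <- data.table::data.table(
      insertion_id = sprintf("S%06d", seq_len(total)),
      genome_id = gids, chrom = loc$chrom, pos = loc$pos, gpos = sites,
      transposon = tes, strand = sample(c("+", "-"), total, replace = TRUE),
      te_start = te_start, te_end = te_end)
  }
  structure(list(genome = genome, library = library, config = config,
                 annotation = annotation, germline = germline,
                 carriers = carriers, somatic = somatic),
            class = "te_population")
}

# uniform random sites avoiding padded annotation and chromosome edges;
# somatic sites need no mutual spacing across genomes
sample_somatic_sites <- function(n, genome, annotation, pad = 1000L,
                                 edge = 2000L) {
  total <- sum(nchar(genome))
  off <- chrom_offsets(genome)
  lens <- nchar(genome)
  avoid <- data.table::rbindlist(list(
    data.table::data.table(s = unname(off), e = unname(off) + edge),
    data.table::data.table(s = unname(off) + unname(lens) - edge,
                           e = unname(off) + unname(lens))))
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    gl <- off[annotation$chrom] + annotation$start
    avoid <- data.table::rbindlist(list(avoid, data.table::data.table(
      s = unname(gl) - pad,
      e = unname(gl) + (annotation$end - annotation$start) + pad)))
  }
  data.table::setkey(avoid, s, e)
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(floor(runif(ceiling(1.5 * (n - length(out))),
                                   0, total)))
    q <- data.table::data.table(s = cand, e = cand + 1L)
    ov <- data.table::foverlaps(q, avoid, type = "any", which = TRUE)
    bad <- unique(ov$xid[!is.na(ov$yid)])
    if (length(bad)) cand <- cand[-bad]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' @export
print.te_population <- function(x, ...) {
  cat("Simulated population:", x$config$n_genomes, "genomes\n")
  cat("  germline insertions:", nrow(x$germline), "\n")
  cat("  somatic insertions:", nrow(x$somatic), "\n")
  invisible(x)
}
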