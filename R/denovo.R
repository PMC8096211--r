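# Genome-wide de novo (singleton) insertion-rate estimation with chimera
# correction. Genuine supporting read-pairs can only reach as far into a
# transposon as the library fragment length allows, so they concentrate in
# the two consensus ends; chimeric artifacts land uniformly. Singleton
# reads mapping to the consensus center therefore estimate the chimera
# background, scaled by the end/center ratio of all consensus-mapped reads.

#' Define end and center regions of every consensus
#'
#' The end length is `f95 - 25` nt; each consensus gets the end intervals
#' `[0, L_end)` and `[len - L_end, len)` and the center
#' `[L_end, len - L_end)`. Transposons shorter than `2 * L_end` have no
#' center and are flagged.
#'
#' @param library A [te_library()].
#' @param f95 95th-percentile fragment length (bases).
#' @return `data.table` with one row per transposon: `transposon`,
#'   `family`, `len`, `l_end`, `end5_hi`, `end3_lo`, `center_defined`.
#' @export
define_end_regions <- function(library, f95) {
  l_end <- max(1L, as.integer(round(f95)) - 25L)
  len <- unname(library$lengths)
  data.table::data.table(
    transposon = names(library$entries),
    family = unname(library$family[names(library$entries)]),
    len = len,
    l_end = l_end,
    end5_hi = pmin(l_end, len),
    end3_lo = pmax(len - l_end, 0L),
    center_defined = len > 2L * l_end)
}

# interval table used for tallying: typed end intervals per transposon
# (type "start" expects minus-strand hits, "end" plus-strand hits)
end_interval_table <- function(spec, extra = NULL) {
  base <- data.table::rbindlist(list(
    spec[, .(transposon, family, lo = 0L, hi = end5_hi, type = "start")],
    spec[, .(transposon, family, lo = end3_lo, hi = len, type = "end")]))
  if (!is.null(extra) && nrow(extra)) {
    base <- data.table::rbindlist(list(base, extra), use.names = TRUE)
  }
  base
}

#' Identify usable fragmented-transposon end windows
#'
#' Truncated genomic copies of a transposon donate their fragment ends as
#' additional end intervals (the fragmented mode), provided enough
#' singleton reads support each fragment end (`min_fragment_support`,
#' default 3). Fragment consensus spans come from `te_start`/`te_end`
#' columns of the annotation when present, or are inferred by aligning the
#' copy sequence to the consensus when the genome is supplied.
#'
#' @param annotation A [repeat_annotation()].
#' @param library A [te_library()].
#' @param spec Output of [define_end_regions()].
#' @param singleton_hits Singleton supporting reads (with `transposon`,
#'   `hit_start`, `hit_end`, `hit_strand`).
#' @param genome Optional named character vector of chromosome sequences.
#' @param min_fragment_support Minimum singleton reads at each fragment
#'   end.
#' @return `data.table` of extra typed end intervals (possibly empty).
#' @export
include_fragmented_copies <- function(annotation, library, spec,
                                      singleton_hits, genome = NULL,
                                      min_fragment_support = 3L) {
  empty <- data.table::data.table(transposon = character(),
                                  family = character(), lo = integer(),
                                  hi = integer(), type = character())
  if (is.null(annotation) || nrow(annotation) == 0L) return(empty)
  ann <- data.table::as.data.table(annotation)
  ann <- ann[transposon %in% names(library$entries)]
  if (nrow(ann) == 0L) return(empty)
  if (!all(c("te_start", "te_end") %in% names(ann))) {
    if (is.null(genome)) return(empty)
    spans <- infer_copy_spans(ann, library, genome)
    ann[, `:=`(te_start = spans$te_start, te_end = spans$te_end)]
  }
  full_len <- unname(library$lengths[ann$transposon])
  frag <- ann[ann$te_end - ann$te_start < full_len]
  if (nrow(frag) == 0L) return(empty)
  frag <- unique(frag[, .(transposon, te_start, te_end)])
  l_end <- spec$l_end[1L]
  out <- vector("list", nrow(frag))
  sh <- data.table::as.data.table(singleton_hits)
  for (i in seq_len(nrow(frag))) {
    ts <- frag$te_start[i]; te <- frag$te_end[i]
    tp <- frag$transposon[i]
    s_lo <- ts; s_hi <- min(ts + l_end, te)
    e_lo <- max(te - l_end, ts); e_hi <- te
    mid <- (sh$hit_start + sh$hit_end) / 2
    n_s <- sum(sh$transposon == tp & sh$hit_strand == "-" &
                 mid >= s_lo & mid < s_hi)
    n_e <- sum(sh$transposon == tp & sh$hit_strand == "+" &
                 mid >= e_lo & mid < e_hi)
    if (n_s >= min_fragment_support && n_e >= min_fragment_support) {
      out[[i]] <- data.table::data.table(
        transposon = tp, family = unname(library$family[[tp]]),
        lo = c(s_lo, e_lo), hi = c(s_hi, e_hi),
        type = c("start", "end"))
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) empty else unique(res)
}

# consensus span of annotated copies via local alignment of the copy
# sequence against its consensus
infer_copy_spans <- function(ann, library, genome) {
  te_start <- integer(nrow(ann))
  te_end <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    s <- substr(genome[[ann$chrom[i]]], ann$start[i] + 1L, ann$end[i])
    if (ann$strand[i] == "-") s <- revcomp(s)
    a <- sw_align(s, library$entries[[ann$transposon[i]]])
    te_start[i] <- a$s_start
    te_end[i] <- a$s_end
  }
  list(te_start = te_start, te_end = te_end)
}

#' Tally end- and center-mapping reads per transposon family
#'
#' A singleton read is end-mapping when its consensus-hit midpoint falls in
#' an end interval and (with `orientation_check`) its strand points out of
#' the matching terminus: hits on the consensus minus strand belong to the
#' 5' (start) interval, plus-strand hits to the 3' (end) interval --
#' read-pairs supporting a genuine insertion always enter the transposon
#' from a terminus. All other singleton reads count as center-mapping. The
#' denominators `AE`/`AC` tally all consensus-mapped reads by midpoint
#' position alone.
#'
#' @param singleton_hits Singleton supporting reads (`transposon`,
#'   `hit_start`, `hit_end`, `hit_strand`, `side`).
#' @param raw_hits All consensus-mapped reads (`transposon`, `hit_start`,
#'   `hit_end`).
#' @param spec Output of [define_end_regions()].
#' @param orientation_check Enforce terminus orientation for singletons.
#' @param extra_ends Extra typed end intervals from
#'   [include_fragmented_copies()].
#' @return `data.table` per family: `family`, `SE`, `SC`, `AE`, `AC`.
#' @export
tally_end_center <- function(singleton_hits, raw_hits, spec,
                             orientation_check = TRUE, extra_ends = NULL) {
  iv <- end_interval_table(spec, extra_ends)
  fams <- sort(unique(spec$family))
  classify_reads <- function(hits, use_orientation) {
    hits <- data.table::as.data.table(hits)
    if (nrow(hits) == 0L) {
      return(data.table::data.table(family = character(), is_end = logical()))
    }
    hits[, mid := (hit_start + hit_end) / 2]
    hits[, rid := .I]
    j <- iv[hits, on = .(transposon, lo <= mid, hi > mid), nomatch = NULL,
            .(rid = i.rid, type = x.type,
              hit_strand = if (use_orientation) i.hit_strand else
                NA_character_)]
    if (use_orientation) {
      j <- j[(type == "start" & hit_strand == "-") |
               (type == "end" & hit_strand == "+")]
    }
    hits[, is_end := rid %in% j$rid]
    hits[, .(family = unname(spec$family[match(transposon,
                                               spec$transposon)]), is_end)]
  }
  s <- classify_reads(singleton_hits, orientation_check)
  r <- classify_reads(raw_hits, FALSE)
  tab <- data.table::data.table(family = fams)
  se <- s[, .(SE = sum(is_end), SC = sum(!is_end)), by = family]
  ra <- r[, .(AE = sum(is_end), AC = sum(!is_end)), by = family]
  tab <- merge(tab, se, by = "family", all.x = TRUE)
  tab <- merge(tab, ra, by = "family", all.x = TRUE)
  for (cl in c("SE", "SC", "AE", "AC")) {
    tab[is.na(get(cl)), (cl) := 0L]
  }
  tab[]
}

#' Chimera-corrected de novo insertion estimate per family
#'
#' The corrected singleton end-read count is
#' `D = max(0, SE - SC * AE / AC)` and the confidence score
#' `1 - min(1, SC * (AE/AC) / SE)` (0 when `SE = 0`). Read counts convert
#' to insertions per genome through the expected supporting-read yield of
#' a single-genome insertion,
#' `R_exp_total = total_depth * (frag_mean - yield_loss) / read_length`
#' (both insertion junctions combined, summed over the population), and an
#' optional cluster-censoring factor `exp(-3 * f95 * mu)` accounting for
#' singleton reads absorbed into clusters when supporting-read density
#' `mu` (reads/bp) is non-negligible.
#'
#' @param tallies Output of [tally_end_center()].
#' @param total_depth Population sequencing depth (x genome length).
#' @param read_length Read length (nt).
#' @param frag_mean Mean fragment length (nt).
#' @param f95 95th-percentile fragment length.
#' @param mu Named per-family supporting-read density (reads/bp), or a
#'   single value; 0 disables the censoring correction.
#' @param yield_loss Junction bases at which a spanning fragment yields no
#'   supporting read (unmappable anchor + unalignable clip).
#' @return `data.table` of class `denovo_estimate`, one row per family:
#'   tallies plus `corrected_reads`, `insertions_per_genome`, `confidence`.
#' @export
estimate_de_novo <- function(tallies, total_depth, read_length,
                             frag_mean, f95, mu = 0,
                             yield_loss = 40L) {
  dt <- data.table::as.data.table(tallies)
  ratio <- data.table::fifelse(dt$AC > 0L, dt$AE / dt$AC,
                               data.table::fifelse(dt$SC == 0L, 0, NA_real_))
  expected_chimera <- dt$SC * ratio
  corrected <- pmax(0, dt$SE - expected_chimera)
  confidence <- data.table::fifelse(
    dt$SE > 0L, 1 - pmin(1, expected_chimera / dt$SE), 0)
  mu_f <- if (length(mu) == 1L && is.null(names(mu))) {
    rep(mu, nrow(dt))
  } else {
    out <- rep(0, nrow(dt))
    hitm <- match(dt$family, names(mu))
    out[!is.na(hitm)] <- unname(mu[hitm[!is.na(hitm)]])
    out
  }
  p_singleton <- exp(-3 * f95 * mu_f)
  r_exp_total <- total_depth * (frag_mean - yield_loss) / read_length
  dt[, corrected_reads := corrected]
  dt[, insertions_per_genome := corrected / (p_singleton * r_exp_total)]
  dt[, confidence := confidence]
  dt[, p_singleton := p_singleton]
  data.table::setattr(dt, "class", c("denovo_estimate", class(dt)))
  dt[]
}

#' Estimate genome-wide de novo insertion rates per transposon family
#'
#' Orchestrates the de novo pipeline: germline calling (or a precomputed
#' [detect_insertions()] result), extraction and consensus alignment of
#' all raw non-unique reads, end/center tallies with optional fragmented
#' mode, and the chimera-corrected estimate.
#'
#' @param x SAM/BAM path or read-pair table.
#' @param library A [te_library()].
#' @param annotation Optional [repeat_annotation()].
#' @param calls Optional precomputed `te_calls` object for the same data.
#' @param fragmented Enable the fragmented-transposon mode.
#' @param min_fragment_support Minimum reads per fragment end.
#' @param orientation_check Enforce terminus orientation.
#' @param correct_clustering Apply the cluster-censoring factor.
#' @param genome Optional genome sequences (for fragment-span inference).
#' @param genome_length Total reference length; inferred from alignments
#'   when missing.
#' @param total_depth Population depth; inferred from alignments when
#'   missing.
#' @param ... Passed to [detect_insertions()] when `calls` is missing.
#' @return A [estimate_de_novo()] table (class `denovo_estimate`).
#' @export
estimate_denovo_rates <- function(x, library, annotation = NULL,
                                  calls = NULL, fragmented = FALSE,
                                  min_fragment_support = 3L,
                                  orientation_check = TRUE,
                                  correct_clustering = TRUE,
                                  genome = NULL, genome_length = NULL,
                                  total_depth = NULL, ...) {
  pairs <- if (is.character(x)) read_alignment_pairs(x) else
    data.table::as.data.table(x)
  if (is.null(calls)) {
    calls <- detect_insertions(pairs, library, annotation = annotation, ...)
  }
  fm <- calls$fragment_model
  read_length <- as.integer(stats::median(nchar(pairs$seq1)))
  if (is.null(genome_length)) {
    ends <- data.table::rbindlist(list(
      pairs[mapped1 == TRUE, .(chrom = chrom1, e = end1)],
      pairs[mapped2 == TRUE, .(chrom = chrom2, e = end2)]))
    genome_length <- sum(ends[, .(l = max(e)), by = chrom]$l)
  }
  if (is.null(total_depth)) {
    mapped_nt <- sum(pairs$mapped1 * (pairs$end1 - pairs$pos1), na.rm = TRUE) +
      sum(pairs$mapped2 * (pairs$end2 - pairs$pos2), na.rm = TRUE)
    total_depth <- mapped_nt / genome_length
  }
  frag_mean <- if (is.finite(fm$mean) && !is.na(fm$mean)) fm$mean else
    fm$f95 - 16.4  # normal approximation: mean ~= q95 - 1.645 sd
  spec <- define_end_regions(library, fm$f95)

  # de novo candidate reads: singleton calls (plus, under a frequency
  # threshold, any call below it) that survived the filters
  thr <- calls$params$freq_threshold
  dn_calls <- if (is.null(thr)) {
    calls$calls[class == "singleton"]
  } else {
    calls$calls[class == "singleton" | frequency < thr]
  }
  supp <- calls$supporting
  singleton_hits <- supp[cluster_id %in% dn_calls$cluster_id]

  # raw consensus-mapped reads (chimera denominator)
  raw <- extract_consensus_query_reads(pairs,
                                       mapq_unique = calls$params$mapq_unique,
                                       min_clip = calls$params$min_clip)
  raw_hits <- NULL
  if (nrow(raw)) {
    rh <- align_candidates(raw$seq, library,
                           max_divergence = calls$params$max_divergence,
                           min_aligned = calls$params$min_aligned)
    raw_hits <- rh[!is.na(transposon)]
  }
  extra <- NULL
  if (fragmented) {
    extra <- include_fragmented_copies(annotation, library, spec,
                                       singleton_hits, genome = genome,
                                       min_fragment_support =
                                         min_fragment_support)
  }
  tal <- tally_end_center(singleton_hits, raw_hits, spec,
                          orientation_check = orientation_check,
                          extra_ends = extra)
  mu <- 0
  if (correct_clustering) {
    sub <- calls$calls[n_support < calls$params$min_support]
    dens <- supp[cluster_id %in% sub$cluster_id][
      , .(n = .N), by = family]
    mu <- setNames(dens$n / genome_length, dens$family)
  }
  est <- estimate_de_novo(tal, total_depth = total_depth,
                          read_length = read_length,
                          frag_mean = frag_mean, f95 = fm$f95, mu = mu)
  est[]
}

#' @export
print.denovo_estimate <- function(x, ...) {
  cat("De novo insertion-rate estimates (", nrow(x), " families)\n", sep = "")
  top <- data.table::as.data.table(x)[order(-insertions_per_genome)]
  print(utils::head(top[, .(family, SE, SC, AE, AC,
                            corrected_reads = round(corrected_reads, 1),
                            insertions_per_genome =
                              round(insertions_per_genome, 2),
                            confidence = round(confidence, 2))], 10L),
        row.names = FALSE)
  invisible(x)
}
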