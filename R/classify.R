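# Read-pair classification: proper / discordant_candidate / split_candidate /
# uninformative, and extraction of the candidate reads (or clipped portions)
# destined for consensus alignment.

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify read pairs for transposon-insertion evidence
#'
#' Adds a `pair_class` column to the pair table:
#' * `discordant_candidate` — exactly one read uniquely mapped
#'   (MAPQ >= `mapq_unique`), the other unmapped or multi-mapped;
#' * `split_candidate` — properly mapped pair in which the 5' end of one
#'   read carries a soft-clip of at least `min_clip` nt;
#' * `proper` — properly and uniquely mapped, no qualifying clip;
#' * `uninformative` — everything else.
#'
#' @param pairs Read-pair table from [read_alignment_pairs()].
#' @param mapq_unique MAPQ at or above which a primary alignment counts as
#'   unique.
#' @param min_clip Minimum 5' soft-clip length for a split candidate.
#' @return The pair table with `pair_class` added (by reference).
#' @export
classify_pairs <- function(pairs, mapq_unique = 20L, min_clip = 10L) {
  dt <- data.table::as.data.table(pairs)
  u1 <- dt$mapped1 & dt$mapq1 >= mapq_unique
  u2 <- dt$mapped2 & dt$mapq2 >= mapq_unique
  disc <- xor(u1, u2)
  split_ <- !disc & dt$proper & u1 & u2 &
    (dt$clip5_1 >= min_clip | dt$clip5_2 >= min_clip)
  proper <- !disc & !split_ & dt$proper & u1 & u2
  dt[, pair_class := "uninformative"]
  dt[proper, pair_class := "proper"]
  dt[disc, pair_class := "discordant_candidate"]
  dt[split_, pair_class := "split_candidate"]
  dt[]
}

#' Extract candidate reads for consensus alignment
#'
#' For every discordant candidate the unmapped/multi-mapped read is the
#' candidate (full sequence); for every split candidate the 5'-clipped
#' portion is. Candidate sequences are reported in sequencing (read)
#' orientation. The anchor read retains its strand and the genomic
#' coordinate of its 3' end; `side` is `left` when the insertion lies to
#' the right of the anchor (anchor on `+`), `right` otherwise.
#'
#' @param pairs Classified pair table (see [classify_pairs()]).
#' @param mapq_unique MAPQ threshold used during classification.
#' @param min_clip Minimum 5' soft-clip length used during classification.
#' @return `data.table` with one row per candidate: `qname`, `chrom`,
#'   `anchor_pos` (anchor 3'-end / soft-clip boundary), `side`, `origin`
#'   (`unmapped`/`multimapped`/`softclip`), `is_split`, `candidate_seq`.
#' @export
extract_candidates <- function(pairs, mapq_unique = 20L, min_clip = 10L) {
  dt <- data.table::as.data.table(pairs)
  if (!"pair_class" %in% names(dt))
    dt <- classify_pairs(dt, mapq_unique, min_clip)
  out <- list()

  disc <- dt[pair_class == "discordant_candidate"]
  if (nrow(disc)) {
    anchor1 <- disc$mapped1 & disc$mapq1 >= mapq_unique
    cand_seq <- data.table::fifelse(anchor1, disc$seq2, disc$seq1)
    cand_strand <- data.table::fifelse(anchor1, disc$strand2, disc$strand1)
    cand_mapped <- data.table::fifelse(anchor1, disc$mapped2, disc$mapped1)
    # sequences of minus-strand records are stored reference-oriented
    flip <- cand_mapped & cand_strand == "-"
    cand_seq[flip] <- revcomp(cand_seq[flip])
    a_strand <- data.table::fifelse(anchor1, disc$strand1, disc$strand2)
    a_pos <- data.table::fifelse(anchor1, disc$pos1, disc$pos2)
    a_end <- data.table::fifelse(anchor1, disc$end1, disc$end2)
    # an anchor whose 3' end is soft-clipped ends exactly at the insertion
    # junction (the clipped tail belongs to the transposon): treat its 3'
    # end as a split (breakpoint-exact) coordinate
    a_clip3 <- data.table::fifelse(anchor1, disc$clip3_1, disc$clip3_2)
    out$disc <- data.table::data.table(
      qname = disc$qname,
      chrom = data.table::fifelse(anchor1, disc$chrom1, disc$chrom2),
      anchor_pos = data.table::fifelse(a_strand == "+", a_end, a_pos),
      side = data.table::fifelse(a_strand == "+", "left", "right"),
      origin = data.table::fifelse(cand_mapped, "multimapped", "unmapped"),
      is_split = a_clip3 >= min_clip,
      candidate_seq = cand_seq
    )
  }

  spl <- dt[pair_class == "split_candidate"]
  if (nrow(spl)) {
    use1 <- spl$clip5_1 >= min_clip &
      (spl$clip5_1 >= spl$clip5_2 | spl$clip5_2 < min_clip)
    cl_strand <- data.table::fifelse(use1, spl$strand1, spl$strand2)
    cl_pos <- data.table::fifelse(use1, spl$pos1, spl$pos2)
    cl_end <- data.table::fifelse(use1, spl$end1, spl$end2)
    cl_len <- data.table::fifelse(use1, spl$clip5_1, spl$clip5_2)
    cl_seq <- data.table::fifelse(use1, spl$seq1, spl$seq2)
    # 5' clip is the read prefix; for minus-strand records that prefix sits
    # at the right end of the stored (reference-oriented) sequence
    plus <- cl_strand == "+"
    cand <- character(nrow(spl))
    cand[plus] <- substr(cl_seq[plus], 1L, cl_len[plus])
    if (any(!plus)) {
      tail_part <- substr(cl_seq[!plus],
                          nchar(cl_seq[!plus]) - cl_len[!plus] + 1L,
                          nchar(cl_seq[!plus]))
      cand[!plus] <- revcomp(tail_part)
    }
    out$spl <- data.table::data.table(
      qname = spl$qname,
      chrom = data.table::fifelse(use1, spl$chrom1, spl$chrom2),
      anchor_pos = data.table::fifelse(plus, cl_pos, cl_end),
      side = data.table::fifelse(plus, "right", "left"),
      origin = "softclip",
      is_split = TRUE,
      candidate_seq = cand
    )
  }

  if (length(out) == 0L) {
    return(data.table::data.table(
      qname = character(), chrom = character(), anchor_pos = integer(),
      side = character(), origin = character(), is_split = logical(),
      candidate_seq = character()))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, anchor_pos, qname)
  res[]
}

# All reads that would be re-aligned to the consensus library regardless of
# pair context (unmapped, multi-mapped, or clipped) -- the "all raw reads"
# denominator of the de novo chimera correction. Sequences are returned in
# sequencing orientation.
extract_consensus_query_reads <- function(pairs, mapq_unique = 20L,
                                          min_clip = 10L) {
  dt <- data.table::as.data.table(pairs)
  grab <- function(mate) {
    mapped <- dt[[paste0("mapped", mate)]]
    mapq <- dt[[paste0("mapq", mate)]]
    nonuniq <- !mapped | mapq < mapq_unique
    clip <- dt[[paste0("clip5_", mate)]] >= min_clip
    keep <- nonuniq | clip
    if (!any(keep)) return(NULL)
    sq <- dt[[paste0("seq", mate)]][keep]
    st <- dt[[paste0("strand", mate)]][keep]
    flip <- mapped[keep] & st == "-"
    sq[flip] <- revcomp(sq[flip])
    data.table::data.table(qname = dt$qname[keep], mate = mate, seq = sq)
  }
  res <- data.table::rbindlist(list(grab(1L), grab(2L)))
  if (is.null(res) || nrow(res) == 0L) {
    return(data.table::data.table(qname = character(), mate = integer(),
                                  seq = character()))
  }
  res[]
}
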