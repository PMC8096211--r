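# Long-read benchmark curation: extract large insertion events from
# long-read alignments, validate them against the consensus library,
# merge nearby events and estimate insertion frequencies.

# parse one CIGAR into op/length vectors
cigar_ops <- function(cg) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
  toks <- regmatches(cg, list(m))[[1]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Extract large insertion events from long-read alignments
#'
#' One event per CIGAR insertion (I) operation of at least `min_len`
#' bases, with the inserted sequence and the genomic position of the
#' operation.
#'
#' @param path SAM/BAM of long-read alignments (or a record table).
#' @param min_len Minimum insertion length (default 300, shorter than any
#'   transposon of interest).
#' @return `data.table` of events: `qname`, `chrom`, `pos` (0-based),
#'   `len`, `seq`.
#' @export
extract_long_insertions <- function(path, min_len = 300L) {
  rec <- if (is.character(path)) read_sam_records(path) else
    data.table::as.data.table(path)
  rec <- rec[!has_flag(flag, FLAG_UNMAPPED) &
               !has_flag(flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY))]
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(rec))) {
    cg <- cigar_ops(rec$cigar[i])
    if (!any(cg$op == "I" & cg$len >= min_len)) next
    if (is.na(rec$seq[i]) || rec$seq[i] == "" || rec$seq[i] == "*") {
      skipped <- skipped + 1L
      next
    }
    rpos <- rec$pos[i]      # reference cursor (0-based)
    qpos <- 0L              # query cursor
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; ln <- cg$len[k]
      if (op == "I" && ln >= min_len) {
        out[[length(out) + 1L]] <- data.table::data.table(
          qname = rec$qname[i], chrom = rec$chrom[i], pos = rpos, len = ln,
          seq = substr(rec$seq[i], qpos + 1L, qpos + ln))
      }
      if (op %in% c("M", "=", "X")) { rpos <- rpos + ln; qpos <- qpos + ln }
      else if (op %in% c("D", "N")) rpos <- rpos + ln
      else if (op %in% c("I", "S")) qpos <- qpos + ln
    }
  }
  if (skipped > 0L) {
    warning(skipped, " record(s) with a large insertion but no sequence skipped")
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table::data.table(qname = character(), chrom = character(),
                                  pos = integer(), len = integer(),
                                  seq = character()))
  }
  res[]
}

#' Validate an insertion event against the consensus library
#'
#' The inserted sequence is aligned to the library; the event is a valid
#' transposon insertion when the aligned length exceeds half the insertion
#' length and the alignment starts within `end_window` nt of the
#' insertion's 5' end and ends within `end_window` nt of its 3' end.
#'
#' @param seq Inserted sequence.
#' @param library A [te_library()].
#' @param end_window Distance window at the two insert ends (nt).
#' @param max_divergence Maximum divergence for the alignment.
#' @return One-row `data.frame` (the accepted hit, with consensus
#'   `hit_start`/`hit_end`) or `NULL`.
#' @export
validate_te_insertion <- function(seq, library, end_window = 500L,
                                  max_divergence = 0.2) {
  hit <- align_candidates(seq, library, max_divergence = max_divergence,
                          min_aligned = 20L, method = "seed")
  if (is.na(hit$transposon[1L])) return(NULL)
  n <- nchar(seq)
  ok <- hit$aligned_length[1L] > n / 2 &&
    hit$q_start[1L] <= end_window &&
    hit$q_end[1L] >= n - end_window
  if (!ok) return(NULL)
  as.data.frame(hit[1L])
}

#' Merge validated insertion events into curated insertions
#'
#' Single-linkage merge of events within `merge_dist` per transposon and
#' chromosome; the breakpoint is the modal event position (ties to the
#' smallest); insertions with fewer than `min_reads` supporting reads are
#' dropped.
#'
#' @param events Validated events (`chrom`, `pos`, `transposon`, plus
#'   optional `hit_start`/`hit_end`).
#' @param merge_dist Merge distance (bp).
#' @param min_reads Minimum supporting reads retained.
#' @return `data.table` of curated insertions: `chrom`, `breakpoint`,
#'   `transposon`, `n_supporting`, `te_start`, `te_end`, `read_names`.
#' @export
merge_and_filter <- function(events, merge_dist = 50L, min_reads = 2L) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(chrom = character(), breakpoint = integer(),
                                  transposon = character(),
                                  n_supporting = integer(),
                                  te_start = integer(), te_end = integer(),
                                  read_names = character()))
  }
  data.table::setorder(ev, chrom, transposon, pos)
  ev[, grp := cumsum(c(1L, diff(pos) > merge_dist)),
     by = .(chrom, transposon)]
  out <- ev[, {
    tab <- table(pos)
    bp <- as.integer(names(tab)[tab == max(tab)][1L])
    list(breakpoint = bp, n_supporting = .N,
         te_start = if ("hit_start" %in% names(ev)) min(hit_start) else
           NA_integer_,
         te_end = if ("hit_end" %in% names(ev)) max(hit_end) else
           NA_integer_,
         read_names = paste(qname, collapse = ","))
  }, by = .(chrom, transposon, grp)]
  out[, grp := NULL]
  out <- out[n_supporting >= min_reads]
  data.table::setorder(out, chrom, breakpoint, transposon)
  out[]
}

#' Estimate the frequency of a curated long-read insertion
#'
#' Reads crossing the breakpoint by at least `cross` bases on both sides
#' are reference reads; reads split (clipped or carrying a large
#' insertion) within `cross` bp of the breakpoint are supporting reads,
#' counted twice when they split at both insertion ends. The frequency is
#' `S / (S + 2R)`, as in the short-read caller.
#'
#' @param breakpoint Breakpoint (0-based).
#' @param chrom Chromosome.
#' @param alignments Long-read record table (from [read_sam_records()])
#'   or SAM/BAM path.
#' @param events Extracted events (supporting evidence), e.g. from
#'   [extract_long_insertions()].
#' @param cross Crossing/split distance (bp).
#' @return List with `S`, `R`, `frequency`.
#' @export
longread_frequency <- function(breakpoint, chrom, alignments, events = NULL,
                               cross = 50L) {
  rec <- if (is.character(alignments)) read_sam_records(alignments) else
    data.table::as.data.table(alignments)
  keep <- !has_flag(rec$flag, FLAG_UNMAPPED) &
    !has_flag(rec$flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY)) &
    rec$chrom == chrom
  rec <- rec[which(keep)]
  rec[, end := pos + cigar_ref_width(cigar)]
  # split evidence: I-op events near the breakpoint, or clip boundaries
  supp <- 0L
  supp_q <- character(0)
  if (!is.null(events) && nrow(events)) {
    ev <- data.table::as.data.table(events)
    ev <- ev[which(ev$chrom == chrom & abs(ev$pos - breakpoint) <= cross)]
    n_per_read <- ev[, .N, by = qname]
    # a read carrying the full insertion traverses both insertion ends,
    # so it counts as two supporting reads
    supp <- 2L * nrow(n_per_read)
    supp_q <- n_per_read$qname
  }
  is_cl <- (cigar_clip_left(rec$cigar) > 0L &
              abs(rec$pos - breakpoint) <= cross) |
    (cigar_clip_right(rec$cigar) > 0L & abs(rec$end - breakpoint) <= cross)
  cl <- rec[which(is_cl & !rec$qname %in% supp_q)]
  supp <- supp + nrow(cl)
  is_supp <- rec$qname %in% c(supp_q, cl$qname)
  refr <- sum(!is_supp & rec$pos <= breakpoint - cross &
                rec$end >= breakpoint + cross)
  list(S = as.integer(supp), R = as.integer(refr),
       frequency = if (supp > 0L) supp / (supp + 2 * refr) else 0)
}

#' Curate a transposon-insertion benchmark from long-read alignments
#'
#' Full curation workflow: extract large CIGAR insertions, validate each
#' inserted sequence against the consensus library, merge nearby events,
#' drop single-read insertions, estimate frequencies, and flag insertions
#' falling into an annotated copy of the same transposon.
#'
#' @param path Long-read SAM/BAM.
#' @param library A [te_library()].
#' @param annotation Optional [repeat_annotation()] for the
#'   same-transposon flag.
#' @param min_insert_len Minimum insertion length.
#' @param merge_dist Merge distance (bp).
#' @param max_divergence Alignment divergence allowance.
#' @return `data.table` of curated insertions with `frequency`,
#'   `n_supporting`, `n_reference`, `te_start`, `te_end`,
#'   `in_same_te_copy`.
#' @export
curate_longread_insertions <- function(path, library, annotation = NULL,
                                       min_insert_len = 300L,
                                       merge_dist = 50L,
                                       max_divergence = 0.2) {
  rec <- read_sam_records(path)
  events <- extract_long_insertions(rec, min_len = min_insert_len)
  if (nrow(events) == 0L) {
    return(data.table::data.table(
      chrom = character(), breakpoint = integer(), transposon = character(),
      n_supporting = integer(), n_reference = integer(),
      frequency = numeric(), te_start = integer(), te_end = integer(),
      in_same_te_copy = logical(), read_names = character()))
  }
  val <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    h <- validate_te_insertion(events$seq[i], library,
                               max_divergence = max_divergence)
    if (!is.null(h)) {
      val[[i]] <- cbind(events[i, .(qname, chrom, pos, len)],
                        data.table::as.data.table(
                          h[c("transposon", "hit_start", "hit_end")]))
    }
  }
  val <- data.table::rbindlist(val)
  cur <- merge_and_filter(val, merge_dist = merge_dist)
  if (nrow(cur) == 0L) return(cur)
  freqs <- lapply(seq_len(nrow(cur)), function(i) {
    longread_frequency(cur$breakpoint[i], cur$chrom[i], rec, events,
                       cross = merge_dist)
  })
  cur[, n_supporting := vapply(freqs, function(f) f$S, integer(1))]
  cur[, n_reference := vapply(freqs, function(f) f$R, integer(1))]
  cur[, frequency := vapply(freqs, function(f) f$frequency, numeric(1))]
  cur[, in_same_te_copy := FALSE]
  if (!is.null(annotation) && nrow(annotation)) {
    ann <- data.table::as.data.table(annotation)
    for (i in seq_len(nrow(cur))) {
      sel <- ann$chrom == cur$chrom[i] & ann$transposon == cur$transposon[i] &
        ann$start <= cur$breakpoint[i] & ann$end >= cur$breakpoint[i]
      cur$in_same_te_copy[i] <- any(sel)
    }
  }
  cur[]
}
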