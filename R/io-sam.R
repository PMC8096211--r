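# SAM/BAM ingest. All positions are converted to 0-based half-open on the
# way in; conversions back to 1-based happen only when writing SAM.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

# reference-consumed width of a CIGAR string (M/D/N/=/X ops); vectorized
cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  w[simple] <- as.integer(sub("M$", "", cigar[simple]))
  rest <- which(!simple & !is.na(cigar) & cigar != "*")
  if (length(rest)) {
    w[rest] <- vapply(cigar[rest], function(cg) {
      m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
      toks <- regmatches(cg, list(m))[[1]]
      ops <- substring(toks, nchar(toks), nchar(toks))
      lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
      sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
  }
  w[is.na(cigar) | cigar == "*"] <- 0L
  w
}

# leading / trailing soft-clip lengths (reference orientation); vectorized
cigar_clip_left <- function(cigar) {
  out <- integer(length(cigar))
  m <- regexpr("^[0-9]+S", cigar)
  hit <- !is.na(m) & m == 1L
  out[hit] <- as.integer(sub("S.*$", "", cigar[hit]))
  out
}
cigar_clip_right <- function(cigar) {
  out <- integer(length(cigar))
  hit <- grepl("[0-9]S$", cigar)
  out[hit] <- as.integer(sub("^.*?([0-9]+)S$", "\\1", cigar[hit]))
  out
}

read_sam_records <- function(path) {
  bam <- path
  if (grepl("\\.sam(\\.gz)?$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "isize")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  data.table::data.table(
    qname = res$qname,
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,   # 0-based
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    seq = as.character(res$seq),
    tlen = as.integer(res$isize)
  )
}

#' Read paired-end alignments into a read-pair table
#'
#' Reads a SAM or BAM file and pairs the primary records of each template.
#' Secondary and supplementary records are not emitted as pairs; their count
#' per template is attached as evidence (`n_secondary`). Templates with a
#' number of primary records other than two are skipped with a warning.
#'
#' @param path SAM or BAM file of paired-end alignments.
#' @return A `data.table` with one row per template: for each mate
#'   (suffix `1`/`2` = first/second in pair) the columns `chrom`, `pos`
#'   (0-based leftmost mapped base), `end` (half-open), `mapq`, `cigar`,
#'   `seq`, `strand`, `mapped`, `clip5`/`clip3` (soft-clip lengths in read
#'   orientation); plus `qname`, `flag1`, `flag2`, `proper` (SAM proper-pair
#'   flag), `tlen` (template length of mate 1) and `n_secondary`.
#' @export
read_alignment_pairs <- function(path) {
  rec <- read_sam_records(path)
  if (nrow(rec) == 0L) return(empty_pair_table())
  sec <- has_flag(rec$flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY))
  nsec <- rec[sec, .N, by = qname]
  prim <- rec[!sec]
  prim[, mate := data.table::fifelse(has_flag(flag, FLAG_FIRST), 1L, 2L)]
  cnt <- prim[, .N, by = qname]
  bad <- cnt[N != 2L, qname]
  if (length(bad)) {
    warning(length(bad), " template(s) without exactly 2 primary records skipped")
    prim <- prim[!qname %in% bad]
  }
  if (nrow(prim) == 0L) return(empty_pair_table())
  prim[, `:=`(
    mapped = !has_flag(flag, FLAG_UNMAPPED),
    strand = data.table::fifelse(has_flag(flag, FLAG_REVERSE), "-", "+")
  )]
  prim[, end := pos + cigar_ref_width(cigar)]
  cl <- cigar_clip_left(prim$cigar)
  cr <- cigar_clip_right(prim$cigar)
  # 5'/3' clip in read orientation
  prim[, clip5 := data.table::fifelse(strand == "+", cl, cr)]
  prim[, clip3 := data.table::fifelse(strand == "+", cr, cl)]
  prim[mapped == FALSE, `:=`(clip5 = 0L, clip3 = 0L, end = NA_integer_,
                             pos = NA_integer_, chrom = NA_character_)]
  data.table::setorder(prim, qname, mate)
  m1 <- prim[mate == 1L]
  m2 <- prim[mate == 2L]
  stopifnot(identical(m1$qname, m2$qname))
  pairs <- data.table::data.table(
    qname = m1$qname,
    flag1 = m1$flag, chrom1 = m1$chrom, pos1 = m1$pos, end1 = m1$end,
    mapq1 = m1$mapq, cigar1 = m1$cigar, seq1 = m1$seq, strand1 = m1$strand,
    mapped1 = m1$mapped, clip5_1 = m1$clip5, clip3_1 = m1$clip3,
    flag2 = m2$flag, chrom2 = m2$chrom, pos2 = m2$pos, end2 = m2$end,
    mapq2 = m2$mapq, cigar2 = m2$cigar, seq2 = m2$seq, strand2 = m2$strand,
    mapped2 = m2$mapped, clip5_2 = m2$clip5, clip3_2 = m2$clip3,
    proper = has_flag(m1$flag, FLAG_PROPER),
    tlen = m1$tlen
  )
  pairs[, n_secondary := 0L]
  if (nrow(nsec)) {
    pairs[nsec, n_secondary := i.N, on = "qname"]
  }
  pairs[]
}

empty_pair_table <- function() {
  data.table::data.table(
    qname = character(), flag1 = integer(), chrom1 = character(),
    pos1 = integer(), end1 = integer(), mapq1 = integer(),
    cigar1 = character(), seq1 = character(), strand1 = character(),
    mapped1 = logical(), clip5_1 = integer(), clip3_1 = integer(),
    flag2 = integer(), chrom2 = character(), pos2 = integer(),
    end2 = integer(), mapq2 = integer(), cigar2 = character(),
    seq2 = character(), strand2 = character(), mapped2 = logical(),
    clip5_2 = integer(), clip3_2 = integer(), proper = logical(),
    tlen = integer(), n_secondary = integer()
  )
}

# Write a SAM file from a record table with 0-based `pos` columns.
# Used by the simulator (truth alignments) and by test fixtures.
write_sam <- function(records, path, seqinfo) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                     as.integer(seqinfo)), con)
  rec <- data.table::as.data.table(records)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                   rec$qname, rec$flag,
                   ifelse(is.na(rec$chrom), "*", rec$chrom),
                   ifelse(is.na(rec$pos), 0L, rec$pos + 1L),
                   rec$mapq, rec$cigar,
                   ifelse(is.na(rec$mchrom), "*",
                          ifelse(rec$mchrom == rec$chrom & !is.na(rec$chrom),
                                 "=", rec$mchrom)),
                   ifelse(is.na(rec$mpos), 0L, rec$mpos + 1L),
                   rec$tlen, rec$seq)
  writeLines(lines, con)
  invisible(path)
}
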