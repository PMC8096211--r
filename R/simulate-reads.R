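# Read-pair sampling and truth-SAM emission for the population simulator.

# per-fragment piece descriptor types
PIECE_REF <- 1L
PIECE_TE <- 2L

#' Simulate paired-end reads from a population, with truth alignments
#'
#' Fragments are drawn per genome proportionally to haplotype length;
#' fragment lengths are Normal(`frag_mean`, `frag_sd`) truncated at twice
#' the read length; reads come from both fragment ends (mate reverse-
#' complemented). Alignments are emitted directly from the known origin of
#' each read, emulating a short-read aligner: transposon-internal reads are
#' multi-mapped (MAPQ 0, placed at a genomic copy), junction reads carry
#' soft-clips, and reads with less than `min_anchor` nt of mappable
#' sequence are unmapped.
#'
#' @param population A [build_population()] result.
#' @param out_sam Output SAM path.
#' @param seed Random seed for read sampling (defaults to the config seed
#'   plus one so that population construction and read sampling draw from
#'   distinct streams).
#' @return List of class `te_readsim`: `sam` (path), `n_pairs`,
#'   `chimeric_qnames`, `records` invisibly dropped.
#' @export
simulate_read_pairs <- function(population, out_sam,
                                seed = population$config$seed + 1L) {
  cfg <- population$config
  set.seed(seed)
  genome <- population$genome
  lib <- population$library
  rl <- as.integer(cfg$read_length)
  fm <- cfg$frag_mean
  fs <- cfg$frag_sd
  off <- chrom_offsets(genome)
  lens <- nchar(genome)
  Lref <- sum(lens)
  gseq <- paste(genome, collapse = "")
  G <- cfg$n_genomes

  # ---- insertion catalog (germline + somatic) ------------------------------
  germ <- population$germline
  som <- population$somatic
  n_germ <- nrow(germ)
  cat_gpos <- c(germ$gpos, som$gpos)
  cat_len <- c(germ$te_end - germ$te_start, som$te_end - som$te_start)
  cat_te <- c(germ$transposon, som$transposon)
  cat_strand <- c(germ$strand, som$strand)
  cat_ts <- c(germ$te_start, som$te_start)
  cat_te_end <- c(germ$te_end, som$te_end)
  combo_key <- paste(cat_te, cat_strand, cat_ts, cat_te_end)
  ukey <- unique(combo_key)
  combo_id <- match(combo_key, ukey)
  combo_seq <- vapply(ukey, function(k) {
    p <- strsplit(k, " ")[[1]]
    s <- substr(lib$entries[[p[1]]], as.integer(p[3]) + 1L, as.integer(p[4]))
    if (p[2] == "-") revcomp(s) else s
  }, character(1), USE.NAMES = FALSE)

  # first full-length annotated copy of each transposon (multi-map target)
  copy1 <- integer(0)
  if (!is.null(population$annotation) && nrow(population$annotation)) {
    ann <- data.table::as.data.table(population$annotation)
    full <- ann[te_start == 0L][!duplicated(transposon)]
    copy1 <- setNames(unname(off[full$chrom]) + full$start, full$transposon)
  }

  # ---- fragment allocation -------------------------------------------------
  som_by_g <- if (nrow(som)) {
    split(seq_len(nrow(som)), factor(som$genome_id, levels = seq_len(G)))
  } else NULL
  extra_germ <- if (n_germ) {
    colSums(population$carriers * (germ$te_end - germ$te_start))
  } else rep(0, G)
  extra_som <- rep(0, G)
  if (nrow(som)) {
    agg <- som[, .(x = sum(te_end - te_start)), by = genome_id]
    extra_som[agg$genome_id] <- agg$x
  }
  Lg <- Lref + extra_germ + extra_som
  N <- as.integer(round(cfg$depth * mean(Lg) / (2 * rl)))
  cnt <- as.vector(stats::rmultinom(1L, N, prob = Lg))

  # ---- per-genome fragment placement ---------------------------------------
  f_type <- integer(N)    # 1 ref, 2 te, 3 complex
  f_fl <- integer(N)
  f_refstart <- integer(N)
  f_cat <- integer(N)
  f_off <- integer(N)
  cplx_pieces <- vector("list", 4096L)
  n_cplx <- 0L
  cursor <- 0L
  for (g in seq_len(G)) {
    nf <- cnt[g]
    if (nf == 0L) next
    sel <- integer(0)
    if (n_germ) sel <- which(population$carriers[, g])
    if (!is.null(som_by_g)) sel <- c(sel, som_by_g[[g]] + n_germ)
    k <- length(sel)
    if (k > 1L) sel <- sel[order(cat_gpos[sel])]
    ipos <- cat_gpos[sel]
    ilen <- cat_len[sel]
    cum <- if (k) cumsum(ilen) else numeric(0)
    cum0 <- c(0, cum)
    hstart <- ipos + cum0[seq_len(k)]
    hend <- ipos + cum
    hend0 <- c(-1, hend)
    Lhap <- Lref + (if (k) cum[k] else 0)
    fl <- pmax(2L * rl, as.integer(round(rnorm(nf, fm, fs))))
    u <- floor(runif(nf, 0, Lhap - fl))
    js <- findInterval(u, hstart)
    je <- findInterval(u + fl, hstart)
    in_s <- js >= 1L & u < hend0[js + 1L]
    in_e <- je >= 1L & (u + fl) <= hend0[je + 1L]
    idx <- cursor + seq_len(nf)
    f_fl[idx] <- fl
    pure_ref <- js == je & !in_s & !in_e
    pure_te <- js == je & in_s & in_e
    cplx <- !(pure_ref | pure_te)
    f_type[idx] <- data.table::fifelse(pure_ref, 1L,
                                       data.table::fifelse(pure_te, 2L, 3L))
    f_refstart[idx[pure_ref]] <- as.integer(u[pure_ref] -
                                              cum0[js[pure_ref] + 1L])
    f_cat[idx[pure_te]] <- sel[js[pure_te]]
    f_off[idx[pure_te]] <- as.integer(u[pure_te] - hstart[js[pure_te]])
    if (any(cplx)) {
      for (ci in which(cplx)) {
        cur <- u[ci]; endp <- u[ci] + fl[ci]
        pieces <- matrix(0L, nrow = 0L, ncol = 4L)
        while (cur < endp) {
          j <- findInterval(cur, hstart)
          if (j >= 1L && cur < hend[j]) {
            stop_at <- min(endp, hend[j])
            pieces <- rbind(pieces, c(PIECE_TE, sel[j],
                                      as.integer(cur - hstart[j]),
                                      as.integer(stop_at - cur)))
            cur <- stop_at
          } else {
            nxt <- if (j < k) hstart[j + 1L] else Inf
            stop_at <- min(endp, nxt)
            pieces <- rbind(pieces, c(PIECE_REF,
                                      as.integer(cur - cum0[j + 1L]), 0L,
                                      as.integer(stop_at - cur)))
            cur <- stop_at
          }
        }
        n_cplx <- n_cplx + 1L
        if (n_cplx > length(cplx_pieces)) {
          length(cplx_pieces) <- 2L * length(cplx_pieces)
        }
        cplx_pieces[[n_cplx]] <- list(frag = idx[ci], pieces = pieces)
      }
    }
    cursor <- cursor + nf
  }

  # drop fragments whose reference extent crosses a chromosome boundary
  bnd <- c(unname(off), Lref)
  ref_ok <- rep(TRUE, N)
  pr <- which(f_type == 1L)
  ci_s <- findInterval(f_refstart[pr], bnd)
  ci_e <- findInterval(f_refstart[pr] + f_fl[pr] - 1L, bnd)
  ref_ok[pr[ci_s != ci_e]] <- FALSE

  # ---- read records --------------------------------------------------------
  rec <- build_read_records(
    N, f_type, f_fl, f_refstart, f_cat, f_off,
    cplx_pieces[seq_len(n_cplx)], gseq, combo_seq, combo_id,
    cat_te, cat_strand, cat_ts, cat_te_end, copy1, rl,
    as.integer(cfg$min_anchor))
  rec <- rec[rep(ref_ok, each = 2L)]

  # MAPQ0 for reads mostly inside an annotated copy
  if (!is.null(population$annotation) && nrow(population$annotation)) {
    ann <- data.table::as.data.table(population$annotation)
    iv <- data.table::data.table(s = unname(off[ann$chrom]) + ann$start,
                                 e = unname(off[ann$chrom]) + ann$end)
    data.table::setkey(iv, s, e)
    mp <- which(rec$mapped & rec$mapq >= 20L)
    q <- data.table::data.table(s = rec$gpos[mp],
                                e = rec$gpos[mp] + rl)
    ov <- data.table::foverlaps(q, iv, type = "any", which = TRUE)
    ov <- ov[!is.na(yid)]
    if (nrow(ov)) {
      ovl <- pmin(q$e[ov$xid], iv$e[ov$yid]) - pmax(q$s[ov$xid], iv$s[ov$yid])
      mx <- data.table::data.table(xid = ov$xid, ovl = ovl)[
        , .(ovl = max(ovl)), by = xid]
      multi <- mx[ovl > rl - as.integer(cfg$min_anchor), xid]
      if (length(multi)) rec$mapq[mp[multi]] <- 0L
    }
  }

  # ---- chimeras ------------------------------------------------------------
  chim <- inject_chimeras(rec, cfg$chimera_rate)
  rec <- chim$records

  # ---- sequencing errors ---------------------------------------------------
  if (cfg$error_rate > 0) {
    nerr <- rbinom(nrow(rec), rl, cfg$error_rate)
    hit <- which(nerr > 0L)
    if (length(hit)) {
      rec$seq[hit] <- vapply(hit, function(i) {
        s <- rec$seq[i]
        p <- sample.int(nchar(s), nerr[i])
        for (pp in p) {
          b <- substr(s, pp, pp)
          substr(s, pp, pp) <- sample(setdiff(DNA_BASES, b), 1L)
        }
        s
      }, character(1))
    }
  }

  # ---- pair-level flags and SAM emission -----------------------------------
  sam <- finalize_and_write_sam(rec, out_sam, genome, off, fm)
  structure(list(sam = sam, n_pairs = sum(ref_ok),
                 chimeric_qnames = chim$chimeric_qnames, seed = seed),
            class = "te_readsim")
}

# assemble the two read records of every fragment
build_read_records <- function(N, f_type, f_fl, f_refstart, f_cat, f_off,
                               cplx, gseq, combo_seq, combo_id,
                               cat_te, cat_strand, cat_ts, cat_te_end,
                               copy1, rl, min_anchor) {
  qn <- sprintf("F%07d", seq_len(N))
  n_rec <- 2L * N
  mapped <- logical(n_rec); gpos <- rep(NA_integer_, n_rec)
  cigar <- rep("*", n_rec); mapq <- integer(n_rec)
  seqs <- character(n_rec); strand <- rep("+", n_rec)
  i1 <- 2L * seq_len(N) - 1L   # read1 rows
  i2 <- i1 + 1L

  cons_off_of <- function(cat, a, span) {
    # consensus-forward offset of an inserted-sequence slice [a, a+span)
    data.table::fifelse(cat_strand[cat] == "+", cat_ts[cat] + a,
                        cat_te_end[cat] - a - span)
  }
  place_multi <- function(cat, a, span) {
    co <- cons_off_of(cat, a, span)
    unname(copy1[cat_te[cat]]) + co
  }

  # pure reference fragments
  pr <- which(f_type == 1L)
  if (length(pr)) {
    st <- f_refstart[pr]; fl <- f_fl[pr]
    s1 <- substring(gseq, st + 1L, st + rl)
    s2 <- substring(gseq, st + fl - rl + 1L, st + fl)
    mapped[i1[pr]] <- TRUE; gpos[i1[pr]] <- st
    cigar[i1[pr]] <- paste0(rl, "M"); mapq[i1[pr]] <- 60L
    seqs[i1[pr]] <- s1
    mapped[i2[pr]] <- TRUE; gpos[i2[pr]] <- st + fl - rl
    cigar[i2[pr]] <- paste0(rl, "M"); mapq[i2[pr]] <- 60L
    seqs[i2[pr]] <- s2; strand[i2[pr]] <- "-"
  }

  # pure transposon-interior fragments: both reads multi-mapped
  pt <- which(f_type == 2L)
  if (length(pt)) {
    cat <- f_cat[pt]; a <- f_off[pt]; fl <- f_fl[pt]
    cs <- combo_seq[combo_id[cat]]
    s1 <- substring(cs, a + 1L, a + rl)
    s2f <- substring(cs, a + fl - rl + 1L, a + fl)
    mapped[i1[pt]] <- TRUE
    gpos[i1[pt]] <- as.integer(place_multi(cat, a, rl))
    cigar[i1[pt]] <- paste0(rl, "M"); mapq[i1[pt]] <- 0L
    seqs[i1[pt]] <- s1
    mapped[i2[pt]] <- TRUE
    gpos[i2[pt]] <- as.integer(place_multi(cat, a + fl - rl, rl))
    cigar[i2[pt]] <- paste0(rl, "M"); mapq[i2[pt]] <- 0L
    seqs[i2[pt]] <- revcomp(s2f)   # stored sequenced-orientation, strand "+"
  }

  # complex (junction-spanning) fragments
  for (cp in cplx) {
    fid <- cp$frag
    p <- cp$pieces
    fl <- f_fl[fid]
    # fragment-forward sequence
    pseq <- character(nrow(p))
    for (r in seq_len(nrow(p))) {
      if (p[r, 1L] == PIECE_REF) {
        pseq[r] <- substring(gseq, p[r, 2L] + 1L, p[r, 2L] + p[r, 4L])
      } else {
        cs <- combo_seq[combo_id[p[r, 2L]]]
        pseq[r] <- substring(cs, p[r, 3L] + 1L, p[r, 3L] + p[r, 4L])
      }
    }
    fseq <- paste(pseq, collapse = "")
    pb <- cumsum(c(0L, p[, 4L]))   # piece boundaries in fragment coords
    emulate <- function(a, b, row_i, is_read2) {
      fw <- substr(fseq, a + 1L, b)
      touch <- which(pb[-length(pb)] < b & pb[-1L] > a)
      types <- p[touch, 1L]
      if (all(types == PIECE_REF) && length(touch) == 1L) {
        r <- touch
        mapped[row_i] <<- TRUE
        gpos[row_i] <<- p[r, 2L] + (a - pb[r])
        cigar[row_i] <<- paste0(rl, "M"); mapq[row_i] <<- 60L
        seqs[row_i] <<- fw
        if (is_read2) strand[row_i] <<- "-"
      } else if (all(types == PIECE_TE) && length(touch) == 1L) {
        r <- touch
        cat <- p[r, 2L]
        mapped[row_i] <<- TRUE
        mapq[row_i] <<- 0L
        gpos[row_i] <<- as.integer(place_multi(cat, p[r, 3L] + (a - pb[r]),
                                               b - a))
        cigar[row_i] <<- paste0(rl, "M")
        seqs[row_i] <<- if (is_read2) revcomp(fw) else fw
      } else if (length(touch) == 2L && sum(types == PIECE_REF) == 1L) {
        rr <- touch[types == PIECE_REF]
        tt <- touch[types == PIECE_TE]
        ref_len <- as.integer(min(b, pb[rr + 1L]) - max(a, pb[rr]))
        te_len <- rl - ref_len
        if (ref_len >= min_anchor) {
          mapped[row_i] <<- TRUE
          gpos[row_i] <<- p[rr, 2L] + (max(a, pb[rr]) - pb[rr])
          mapq[row_i] <<- 60L
          cigar[row_i] <<- if (rr < tt) paste0(ref_len, "M", te_len, "S")
                           else paste0(te_len, "S", ref_len, "M")
          seqs[row_i] <<- fw
          if (is_read2) strand[row_i] <<- "-"
        } else {
          mapped[row_i] <<- FALSE
          mapq[row_i] <<- 0L
          seqs[row_i] <<- if (is_read2) revcomp(fw) else fw
        }
      } else {
        mapped[row_i] <<- FALSE
        mapq[row_i] <<- 0L
        seqs[row_i] <<- if (is_read2) revcomp(fw) else fw
      }
    }
    emulate(0L, rl, i1[fid], FALSE)
    emulate(fl - rl, fl, i2[fid], TRUE)
  }

  # no placement target (e.g. no annotated copy): report unmapped
  bad <- mapped & is.na(gpos)
  if (any(bad)) {
    mapped[bad] <- FALSE
    mapq[bad] <- 0L
    cigar[bad] <- "*"
  }
  data.table::data.table(
    qname = rep(qn, each = 2L),
    mate = rep(c(1L, 2L), N),
    mapped = mapped, gpos = gpos, cigar = cigar, mapq = mapq,
    strand = strand, seq = seqs)
}

#' Replace a fraction of read-pairs with chimeric pairs
#'
#' A chimeric pair combines two reads from independent random fragments,
#' emulating ligation artifacts of library construction. Operates on the
#' simulator's read-record table (two rows per pair): the second read of
#' each selected pair is replaced by the second read of a random donor
#' fragment.
#'
#' @param records Read-record table from the simulator.
#' @param rate Fraction of pairs to replace (in `[0, 1)`).
#' @return List with `records` (modified) and `chimeric_qnames`.
#' @export
inject_chimeras <- function(records, rate) {
  stopifnot(rate >= 0, rate < 1)
  n_pairs <- nrow(records) / 2L
  if (rate == 0 || n_pairs < 2L) {
    return(list(records = records, chimeric_qnames = character(0)))
  }
  n_chim <- rbinom(1L, n_pairs, rate)
  if (n_chim == 0L) {
    return(list(records = records, chimeric_qnames = character(0)))
  }
  targets <- sample.int(n_pairs, n_chim)
  donors <- sample.int(n_pairs, n_chim, replace = TRUE)
  same <- donors == targets
  while (any(same)) {
    donors[same] <- sample.int(n_pairs, sum(same), replace = TRUE)
    same <- donors == targets
  }
  t2 <- 2L * targets          # read2 rows of targets
  d2 <- 2L * donors
  keep_qname <- records$qname[t2]
  cols <- setdiff(names(records), c("qname", "mate"))
  for (cl in cols) {
    data.table::set(records, t2, cl, records[[cl]][d2])
  }
  list(records = records, chimeric_qnames = keep_qname)
}

# compute pair flags / mate fields and write the SAM file
finalize_and_write_sam <- function(rec, out_sam, genome, off, frag_mean) {
  n <- nrow(rec) / 2L
  i1 <- 2L * seq_len(n) - 1L
  i2 <- i1 + 1L
  w1 <- cigar_ref_width(rec$cigar[i1])
  w2 <- cigar_ref_width(rec$cigar[i2])
  m1 <- rec$mapped[i1]; m2 <- rec$mapped[i2]
  p1 <- rec$gpos[i1]; p2 <- rec$gpos[i2]
  e1 <- p1 + w1; e2 <- p2 + w2
  loc1 <- global_to_chrom(data.table::fifelse(m1, p1, 0L), genome)
  loc2 <- global_to_chrom(data.table::fifelse(m2, p2, 0L), genome)
  same_chrom <- m1 & m2 & loc1$chrom == loc2$chrom
  span <- pmax(e1, e2, na.rm = FALSE) - pmin(p1, p2, na.rm = FALSE)
  proper <- same_chrom & rec$strand[i1] == "+" & rec$strand[i2] == "-" &
    !is.na(span) & span > 0L & span <= 3 * frag_mean & p1 <= p2
  proper[is.na(proper)] <- FALSE
  tlen1 <- data.table::fifelse(proper, span, 0L)
  flag1 <- 1L + 64L +
    data.table::fifelse(proper, 2L, 0L) +
    data.table::fifelse(m1, 0L, 4L) +
    data.table::fifelse(m2, 0L, 8L) +
    data.table::fifelse(rec$strand[i1] == "-", 16L, 0L) +
    data.table::fifelse(rec$strand[i2] == "-", 32L, 0L)
  flag2 <- 1L + 128L +
    data.table::fifelse(proper, 2L, 0L) +
    data.table::fifelse(m2, 0L, 4L) +
    data.table::fifelse(m1, 0L, 8L) +
    data.table::fifelse(rec$strand[i2] == "-", 16L, 0L) +
    data.table::fifelse(rec$strand[i1] == "-", 32L, 0L)
  out <- data.table::data.table(
    qname = rec$qname[c(rbind(i1, i2))],
    flag = as.integer(c(rbind(flag1, flag2))),
    chrom = c(rbind(data.table::fifelse(m1, loc1$chrom, NA_character_),
                    data.table::fifelse(m2, loc2$chrom, NA_character_))),
    pos = c(rbind(data.table::fifelse(m1, loc1$pos, NA_integer_),
                  data.table::fifelse(m2, loc2$pos, NA_integer_))),
    mapq = rec$mapq[c(rbind(i1, i2))],
    cigar = rec$cigar[c(rbind(i1, i2))],
    mchrom = c(rbind(data.table::fifelse(m2, loc2$chrom, NA_character_),
                     data.table::fifelse(m1, loc1$chrom, NA_character_))),
    mpos = c(rbind(data.table::fifelse(m2, loc2$pos, NA_integer_),
                   data.table::fifelse(m1, loc1$pos, NA_integer_))),
    tlen = as.integer(c(rbind(tlen1, -tlen1))),
    seq = rec$seq[c(rbind(i1, i2))])
  write_sam(out, out_sam, setNames(nchar(genome), names(genome)))
  out_sam
}
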