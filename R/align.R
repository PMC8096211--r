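# Local alignment of candidate reads against the transposon consensus
# library. Scoring is bwa-mem-like: match +1, mismatch -2, gap open -3,
# gap extend -1. A hit is reported only if identity >= 1 - max_divergence
# and the aligned length reaches min_aligned; ties between equal scores go
# to the longer aligned length, then the lexicographically first name.

SW_MATCH <- 1L
SW_MISMATCH <- -2L
SW_GAP_OPEN <- 3L
SW_GAP_EXTEND <- 1L

sw_align <- function(query, subject) {
  .sw_align_cpp(query, subject, SW_MATCH, SW_MISMATCH, SW_GAP_OPEN,
                SW_GAP_EXTEND)
}

# pick the best row among per-target alignment results (already thresholded)
best_hit_row <- function(hits) {
  hits <- hits[order(-hits$score, -hits$aligned_len, hits$transposon), ]
  hits[1L, , drop = FALSE]
}

#' Align one candidate sequence to the consensus library
#'
#' Smith-Waterman local alignment against both strands of every library
#' entry; returns the single best hit or `NULL`. The reported `strand` is
#' the consensus strand matched by the candidate as given (`-` means the
#' reverse complement of the candidate matches the consensus forward
#' strand); `hit_start`/`hit_end` are 0-based half-open on the consensus
#' forward strand.
#'
#' @param seq Candidate DNA sequence (character scalar).
#' @param library A [te_library()].
#' @param max_divergence Maximum sequence divergence (1 - identity).
#' @param min_aligned Minimum aligned length (nt).
#' @return One-row `data.frame` (`transposon`, `family`, `hit_start`,
#'   `hit_end`, `strand`, `aligned_length`, `identity`, `score`) or `NULL`.
#' @export
align_candidate <- function(seq, library, max_divergence = 0.1,
                            min_aligned = 20L) {
  stopifnot(inherits(library, "te_library"), length(seq) == 1L)
  rc <- revcomp(seq)
  rows <- list()
  for (nm in names(library$entries)) {
    subject <- library$entries[[nm]]
    for (std in c("+", "-")) {
      q <- if (std == "+") seq else rc
      a <- sw_align(q, subject)
      if (a$aligned_len >= min_aligned &&
          a$matches >= (1 - max_divergence) * a$aligned_len) {
        # query coordinates reported on the sequence as given
        qs <- if (std == "+") a$q_start else nchar(seq) - a$q_end
        qe <- if (std == "+") a$q_end else nchar(seq) - a$q_start
        rows[[length(rows) + 1L]] <- data.frame(
          transposon = nm, family = unname(library$family[[nm]]),
          hit_start = a$s_start, hit_end = a$s_end, strand = std,
          q_start = qs, q_end = qe,
          aligned_length = a$aligned_len,
          identity = a$matches / a$aligned_len, score = a$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  best_hit_row(do.call(rbind, rows))
}

# ---- seeded batch alignment ------------------------------------------------

build_seed_index <- function(library, k = 12L, stride = 1L) {
  idx <- lapply(names(library$entries), function(nm) {
    s <- library$entries[[nm]]
    if (nchar(s) < k) return(NULL)
    starts <- seq(1L, nchar(s) - k + 1L, by = stride)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           entry = nm, spos = starts - 1L)
  })
  idx <- data.table::rbindlist(idx)
  data.table::setkey(idx, kmer)
  structure(list(index = idx, k = k), class = "te_seed_index")
}

query_seeds <- function(seqs, index, stride = 4L) {
  k <- index$k
  qk <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
    data.table::data.table(qid = i, qpos = starts - 1L,
                           kmer = substring(s, starts, starts + k - 1L))
  })
  qk <- data.table::rbindlist(qk)
  if (nrow(qk) == 0L) return(NULL)
  hits <- index$index[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag := spos - qpos]
  # strongest diagonal per (query, entry)
  modal_diag <- function(d) {
    ud <- unique(d)
    ud[which.max(tabulate(match(d, ud)))]
  }
  hits[, .(nseed = .N, diag = modal_diag(diag)), by = .(qid, entry)]
}

#' Align many candidate sequences to the consensus library
#'
#' Batch version of [align_candidate()]. With `method = "seed"` an exact
#' k-mer index restricts the Smith-Waterman search to a window around the
#' best seeded diagonal of each (query, entry, strand) combination --
#' identical results to the exhaustive search whenever a seed exists, at a
#' small fraction of the cost. `method = "exhaustive"` runs the full search
#' for every query.
#'
#' @param seqs Character vector of candidate sequences.
#' @param library A [te_library()].
#' @param max_divergence,min_aligned As in [align_candidate()].
#' @param method `"seed"` or `"exhaustive"`.
#' @param k Seed k-mer length.
#' @return `data.table` with one row per query (in input order):
#'   columns of [align_candidate()] plus `qid`; queries without an
#'   acceptable hit have `NA` fields.
#' @export
align_candidates <- function(seqs, library, max_divergence = 0.1,
                             min_aligned = 20L,
                             method = c("seed", "exhaustive"), k = 12L) {
  method <- match.arg(method)
  n <- length(seqs)
  empty <- data.table::data.table(
    qid = seq_len(n), transposon = NA_character_, family = NA_character_,
    hit_start = NA_integer_, hit_end = NA_integer_, strand = NA_character_,
    q_start = NA_integer_, q_end = NA_integer_,
    aligned_length = NA_integer_, identity = NA_real_, score = NA_integer_)
  if (n == 0L) return(empty[0L])
  if (method == "exhaustive") {
    for (i in seq_len(n)) {
      h <- align_candidate(seqs[[i]], library, max_divergence, min_aligned)
      if (!is.null(h)) {
        data.table::set(empty, i, names(h), as.list(h))
      }
    }
    return(empty)
  }
  index <- build_seed_index(library, k = k)
  rcs <- revcomp(seqs)
  fwd <- query_seeds(seqs, index)
  rev_ <- query_seeds(rcs, index)
  if (!is.null(fwd)) fwd[, strand := "+"]
  if (!is.null(rev_)) rev_[, strand := "-"]
  seeds <- data.table::rbindlist(list(fwd, rev_))
  if (is.null(seeds) || nrow(seeds) == 0L) return(empty)
  lens <- library$lengths
  pad <- 60L
  qv <- data.table::fifelse(seeds$strand == "+", seqs[seeds$qid],
                            rcs[seeds$qid])
  qlen <- nchar(qv)
  slen <- unname(lens[seeds$entry])
  lo <- pmax(0L, seeds$diag - pad)
  hi <- pmin(slen, seeds$diag + qlen + pad)
  sv <- substring(library$entries[seeds$entry], lo + 1L, hi)
  am <- .sw_align_pairs_cpp(qv, sv, SW_MATCH, SW_MISMATCH, SW_GAP_OPEN,
                            SW_GAP_EXTEND)
  ok <- am[, "aligned_len"] >= min_aligned &
    am[, "matches"] >= (1 - max_divergence) * am[, "aligned_len"]
  res <- data.table::data.table(
    qid = seeds$qid[ok],
    transposon = seeds$entry[ok],
    family = unname(library$family[seeds$entry[ok]]),
    hit_start = am[ok, "s_start"] + lo[ok],
    hit_end = am[ok, "s_end"] + lo[ok],
    strand = seeds$strand[ok],
    q_start = data.table::fifelse(seeds$strand[ok] == "+",
                                  am[ok, "q_start"],
                                  qlen[ok] - am[ok, "q_end"]),
    q_end = data.table::fifelse(seeds$strand[ok] == "+", am[ok, "q_end"],
                                qlen[ok] - am[ok, "q_start"]),
    aligned_length = am[ok, "aligned_len"],
    identity = am[ok, "matches"] / am[ok, "aligned_len"],
    score = am[ok, "score"])
  if (nrow(res) == 0L) return(empty)
  data.table::setorder(res, qid, -score, -aligned_length, transposon)
  best <- res[!duplicated(qid)]
  out <- empty[0L]
  out <- data.table::rbindlist(list(
    best,
    empty[!qid %in% best$qid]), use.names = TRUE)
  data.table::setorder(out, qid)
  out[]
}

#' Attach consensus hits to candidate reads
#'
#' Aligns every candidate sequence to the library and keeps those with an
#' acceptable hit, producing the supporting-read table consumed by the
#' clustering step.
#'
#' @param candidates Candidate table from [extract_candidates()].
#' @param library A [te_library()].
#' @param max_divergence,min_aligned,method Passed to [align_candidates()].
#' @return `data.table` of supporting reads: candidate columns plus
#'   `transposon`, `family`, `hit_start`, `hit_end`, `hit_strand`,
#'   `identity`, `score`.
#' @export
assign_supporting_reads <- function(candidates, library,
                                    max_divergence = 0.1, min_aligned = 20L,
                                    method = "seed") {
  cand <- data.table::as.data.table(candidates)
  if (nrow(cand) == 0L) {
    return(data.table::data.table(
      qname = character(), chrom = character(), anchor_pos = integer(),
      side = character(), origin = character(), is_split = logical(),
      transposon = character(), family = character(),
      hit_start = integer(), hit_end = integer(), hit_strand = character(),
      identity = numeric(), score = integer()))
  }
  hits <- align_candidates(cand$candidate_seq, library,
                           max_divergence = max_divergence,
                           min_aligned = min_aligned, method = method)
  keep <- !is.na(hits$transposon)
  out <- cbind(
    cand[keep, .(qname, chrom, anchor_pos, side, origin, is_split)],
    hits[keep, .(transposon, family, hit_start, hit_end,
                 hit_strand = strand, identity, score)])
  data.table::setorder(out, chrom, anchor_pos, qname)
  out[]
}
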