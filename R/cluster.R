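# Clustering of supporting reads and insertion-call construction.
#
# Two supporting reads join the same cluster when they are anchored on the
# same side of an insertion and less than f95 apart, or on opposite sides
# and less than 2*f95 apart (f95 = 95th-percentile fragment length).
# Clustering is single linkage (transitive closure of the pairwise rule),
# applied per chromosome and per transposon family.

# pairwise linkage rule: same side closer than f95; opposite sides closer
# than 2*f95 and convergent (the left-side anchor must not lie right of the
# right-side anchor -- reads on opposite sides of one insertion point
# towards each other across the junction)
reads_linked <- function(pos_i, side_i, pos_j, side_j, f95) {
  d <- abs(pos_i - pos_j)
  if (side_i == side_j) return(d < f95)
  left_pos <- if (side_i == "left") pos_i else pos_j
  right_pos <- if (side_i == "left") pos_j else pos_i
  d < 2 * f95 && left_pos <= right_pos
}

# union-find over one chromosome/family block; positions must be sorted
cluster_block <- function(pos, side, f95) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i - 1L
    while (j >= 1L && pos[i] - pos[j] < 2 * f95) {
      if (reads_linked(pos[i], side[i], pos[j], side[j], f95)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j - 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster supporting reads
#'
#' Single-linkage clustering of supporting reads under the two distance
#' rules (same side: `< f95`; opposite sides: `< 2*f95`), per chromosome
#' and transposon family.
#'
#' @param reads Supporting-read table from [assign_supporting_reads()].
#' @param f95 95th-percentile fragment length (bases).
#' @param by_family Cluster within family (default) or across all reads of
#'   a chromosome.
#' @return The table with a `cluster_id` column added; every read belongs
#'   to exactly one cluster.
#' @export
cluster_supporting_reads <- function(reads, f95, by_family = TRUE) {
  dt <- data.table::as.data.table(reads)
  if (nrow(dt) == 0L) {
    dt[, cluster_id := integer(0)]
    return(dt[])
  }
  keys <- if (by_family) c("chrom", "family") else "chrom"
  data.table::setorderv(dt, c(keys, "anchor_pos"))
  dt[, cluster_id := cluster_block(anchor_pos, side, f95), by = keys]
  # globally unique ids
  dt[, cluster_id := .GRP, by = c(keys, "cluster_id")]
  dt[]
}

#' Call the breakpoint of a read cluster
#'
#' With split reads present the breakpoint is their modal soft-clip
#' coordinate (ties to the smallest); otherwise the mean of the anchor
#' 3'-end coordinates, rounded half-up.
#'
#' @param cluster One cluster of supporting reads (rows of the table from
#'   [cluster_supporting_reads()]).
#' @return Integer breakpoint (0-based).
#' @export
call_breakpoint <- function(cluster) {
  stopifnot(nrow(cluster) > 0L)
  if (any(cluster$is_split)) {
    p <- cluster$anchor_pos[cluster$is_split]
    tab <- table(p)
    as.integer(names(tab)[tab == max(tab)][1L])
  } else {
    as.integer(floor(mean(cluster$anchor_pos) + 0.5))
  }
}

#' Classify a read cluster as 1p1, 2p or singleton
#'
#' @param cluster One cluster of supporting reads.
#' @return `"1p1"` (reads on both sides), `"2p"` (two or more reads on one
#'   side only) or `"singleton"` (exactly one read).
#' @export
classify_cluster <- function(cluster) {
  if (nrow(cluster) == 1L) return("singleton")
  if (all(c("left", "right") %in% cluster$side)) "1p1" else "2p"
}

#' Insertion frequency from supporting and reference read counts
#'
#' `p = S / (S + 2R)`: each supporting read-pair witnesses one of the two
#' insertion junctions while a reference pair spans the intact site, hence
#' the factor two.
#'
#' @param S Number of supporting read-pairs (`>= 1`).
#' @param R Number of reference read-pairs (`>= 0`).
#' @return Frequency in (0, 1].
#' @export
estimate_insertion_frequency <- function(S, R) {
  stopifnot(all(S >= 1L), all(R >= 0L))
  S / (S + 2 * R)
}

#' Count reference read-pairs at insertion breakpoints
#'
#' A reference read-pair is a properly mapped, unsplit pair whose fragment
#' span crosses the breakpoint by more than 20 bp on each side.
#'
#' @param calls Table with `chrom` and `breakpoint` columns.
#' @param pairs Read-pair table (classification optional).
#' @param mapq_unique MAPQ uniqueness threshold.
#' @param min_cross Minimum bases by which the fragment must cross the
#'   breakpoint on each side (exclusive bound: strictly more than
#'   `min_cross`).
#' @return Integer vector of reference counts, aligned with `calls` rows.
#' @export
count_reference_reads <- function(calls, pairs, mapq_unique = 20L,
                                  min_cross = 20L) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(integer(0))
  dt <- data.table::as.data.table(pairs)
  ok <- dt$proper & dt$mapped1 & dt$mapped2 &
    dt$mapq1 >= mapq_unique & dt$mapq2 >= mapq_unique &
    dt$clip5_1 == 0L & dt$clip3_1 == 0L &
    dt$clip5_2 == 0L & dt$clip3_2 == 0L
  frag <- dt[ok, .(chrom = chrom1,
                   s = pmin(pos1, pos2),
                   e = pmax(end1, end2))]
  q <- calls[, .(chrom, lo = breakpoint - min_cross - 1L,
                 hi = breakpoint + min_cross + 1L)]
  q[, row := .I]
  if (nrow(frag) == 0L) return(integer(nrow(calls)))
  cnt <- frag[q, on = .(chrom, s <= lo, e >= hi), .N, by = .EACHI]
  as.integer(cnt$N)
}

#' Predict the consensus-coordinate ends of the inserted transposon
#'
#' Envelope of the consensus hits of a cluster: minimum hit start and
#' maximum hit end (hit coordinates are already normalised to the consensus
#' forward strand, so hits from both strands combine directly).
#'
#' @param cluster One cluster of supporting reads.
#' @return Integer vector `c(te_start, te_end)`.
#' @export
predict_te_ends <- function(cluster) {
  c(min(cluster$hit_start), max(cluster$hit_end))
}

# majority insertion strand implied by side/hit-strand geometry:
# a left-side mate reads into the transposon terminus in reverse, so
# (left, -) and (right, +) imply a plus-orientation insertion.
cluster_strand <- function(cluster) {
  plus <- (cluster$side == "left") == (cluster$hit_strand == "-")
  if (sum(plus) >= sum(!plus)) "+" else "-"
}

#' Build insertion calls from supporting reads
#'
#' Runs clustering, breakpoint calling, classification, transposon-end
#' prediction, reference-read counting and frequency estimation, producing
#' one call per cluster labeled with its dominant transposon.
#'
#' @param reads Supporting-read table from [assign_supporting_reads()].
#' @param pairs Full read-pair table (for reference reads).
#' @param f95 95th-percentile fragment length.
#' @param mapq_unique MAPQ uniqueness threshold.
#' @return `data.table` of insertion calls: `chrom`, `breakpoint`,
#'   `transposon`, `family`, `strand`, `class`, `n_support`,
#'   `n_support_5p`, `n_support_3p`, `n_reference`, `frequency`,
#'   `te_start`, `te_end`, `cluster_id`.
#' @export
call_insertions <- function(reads, pairs, f95, mapq_unique = 20L) {
  dt <- cluster_supporting_reads(reads, f95)
  if (nrow(dt) == 0L) return(empty_call_table())
  calls <- dt[, {
    tab <- sort(table(transposon), decreasing = TRUE)
    dom <- names(tab)[tab == max(tab)]
    dom <- sort(dom)[1L]
    ends <- predict_te_ends(.SD)
    list(
      chrom = chrom[1L],
      breakpoint = call_breakpoint(.SD),
      transposon = dom,
      family = family[match(dom, transposon)],
      strand = cluster_strand(.SD),
      class = classify_cluster(.SD),
      n_support = .N,
      n_support_5p = sum(side == "left"),
      n_support_3p = sum(side == "right"),
      te_start = ends[1L],
      te_end = ends[2L]
    )
  }, by = cluster_id]
  calls[, n_reference := count_reference_reads(calls, pairs, mapq_unique)]
  calls[, frequency := estimate_insertion_frequency(n_support, n_reference)]
  data.table::setcolorder(calls, c("chrom", "breakpoint", "transposon",
                                   "family", "strand", "class", "n_support",
                                   "n_support_5p", "n_support_3p",
                                   "n_reference", "frequency", "te_start",
                                   "te_end", "cluster_id"))
  data.table::setorder(calls, chrom, breakpoint, transposon)
  calls[]
}

empty_call_table <- function() {
  data.table::data.table(
    chrom = character(), breakpoint = integer(), transposon = character(),
    family = character(), strand = character(), class = character(),
    n_support = integer(), n_support_5p = integer(),
    n_support_3p = integer(), n_reference = integer(),
    frequency = numeric(), te_start = integer(), te_end = integer(),
    cluster_id = integer())
}
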