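# False-positive filters: same-transposon annotation + blacklist,
# high-coverage regions, and same-position merging.

annotation_families <- function(annotation, library = NULL) {
  fam <- annotation$transposon
  if (!is.null(library)) {
    known <- fam %in% names(library$family)
    fam[known] <- unname(library$family[fam[known]])
  }
  fam
}

#' Remove insertions falling into an annotated copy of the same transposon
#'
#' A call is removed when its breakpoint lies within an annotated interval
#' of the same transposon or family, padded by `pad` bases on each side
#' (clusters without split reads locate breakpoints only to within the
#' fragment length, so the pad defaults to `f95` when the caller supplies
#' it). Removed breakpoints join a blacklist; any call of any family at a
#' blacklisted position is then removed too.
#'
#' @param calls Insertion-call table.
#' @param annotation A [repeat_annotation()].
#' @param library Optional [te_library()] used to map annotation names to
#'   families.
#' @param blacklist Optional existing blacklist (`data.table` with `chrom`,
#'   `breakpoint`).
#' @param pad Pad (bases) applied to annotation intervals.
#' @return List with `kept`, `removed` and the updated `blacklist`.
#' @export
filter_same_transposon <- function(calls, annotation, library = NULL,
                                   blacklist = NULL, pad = 0L) {
  calls <- data.table::as.data.table(calls)
  if (is.null(blacklist)) {
    blacklist <- data.table::data.table(chrom = character(),
                                        breakpoint = integer())
  }
  if (nrow(calls) == 0L) {
    return(list(kept = calls, removed = calls, blacklist = blacklist))
  }
  ann <- data.table::as.data.table(annotation)
  hit <- rep(FALSE, nrow(calls))
  if (nrow(ann) > 0L) {
    ann <- data.table::data.table(
      chrom = ann$chrom,
      lo = ann$start - as.integer(pad),
      hi = ann$end + as.integer(pad),
      ann_fam = annotation_families(ann, library))
    q <- calls[, .(chrom, bp = breakpoint, call_fam = family,
                   row = .I)]
    ov <- ann[q, on = .(chrom, lo <= bp, hi >= bp), nomatch = NULL,
              .(row = i.row, ann_fam = x.ann_fam, call_fam = i.call_fam)]
    hit[unique(ov[ann_fam == call_fam, row])] <- TRUE
  }
  newbl <- unique(data.table::rbindlist(list(
    blacklist, calls[hit, .(chrom, breakpoint)])))
  bl_hit <- !is.na(newbl[calls, on = .(chrom, breakpoint), which = TRUE])
  removed <- hit | bl_hit
  list(kept = calls[!removed], removed = calls[removed], blacklist = newbl)
}

#' Genome-wide read-depth profile in fixed windows
#'
#' Depth per non-overlapping window, computed as the number of mapped read
#' alignments starting in the window scaled to nucleotide coverage.
#'
#' @param pairs Read-pair table.
#' @param window Window size (bases).
#' @param genome_lengths Optional named vector of chromosome lengths; when
#'   absent, lengths are inferred from the rightmost alignment.
#' @return List of class `coverage_profile`: `window`, `depth`
#'   (`data.table` of `chrom`, `win_start`, `coverage`) and `mean_depth`.
#' @export
coverage_profile <- function(pairs, window = 1000L, genome_lengths = NULL) {
  dt <- data.table::as.data.table(pairs)
  reads <- data.table::rbindlist(list(
    dt[mapped1 == TRUE, .(chrom = chrom1, pos = pos1, len = end1 - pos1)],
    dt[mapped2 == TRUE, .(chrom = chrom2, pos = pos2, len = end2 - pos2)]))
  if (nrow(reads) == 0L) stop("no mapped reads; mean depth is zero")
  if (is.null(genome_lengths)) {
    genome_lengths <- reads[, .(len = max(pos) + 1L), by = chrom]
    genome_lengths <- setNames(genome_lengths$len, genome_lengths$chrom)
  }
  mean_len <- mean(reads$len)
  reads[, win_start := (pos %/% window) * window]
  depth <- reads[, .(coverage = .N * mean_len / window),
                 by = .(chrom, win_start)]
  # include empty windows in the genome-wide mean
  n_windows <- sum(ceiling(genome_lengths / window))
  mean_depth <- sum(depth$coverage) / n_windows
  if (mean_depth <= 0) stop("mean depth is zero")
  structure(list(window = as.integer(window), depth = depth,
                 mean_depth = mean_depth),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("Coverage profile: %d-bp windows, mean depth %.2fx (%d windows with reads)\n",
              x$window, x$mean_depth, nrow(x$depth)))
  invisible(x)
}

#' Remove insertions in abnormally high-coverage regions
#'
#' A call is removed when the read depth of the window containing its
#' breakpoint reaches `ratio` times the genome-wide mean; such windows
#' typically reflect sequences collapsed in the reference assembly.
#'
#' @param calls Insertion-call table.
#' @param pairs Read-pair table (or a precomputed [coverage_profile()]
#'   passed as `profile`).
#' @param window Window size (bases).
#' @param ratio Depth ratio threshold.
#' @param profile Optional precomputed coverage profile.
#' @return List with `kept` and `removed`.
#' @export
filter_high_coverage <- function(calls, pairs = NULL, window = 1000L,
                                 ratio = 5, profile = NULL) {
  calls <- data.table::as.data.table(calls)
  if (is.null(profile)) profile <- coverage_profile(pairs, window)
  if (nrow(calls) == 0L) return(list(kept = calls, removed = calls))
  q <- calls[, .(chrom, win_start = (breakpoint %/% profile$window) *
                   profile$window)]
  cov <- profile$depth[q, on = .(chrom, win_start), x.coverage]
  cov[is.na(cov)] <- 0
  removed <- cov >= ratio * profile$mean_depth
  list(kept = calls[!removed], removed = calls[removed])
}

#' Merge insertion calls at exactly the same genomic position
#'
#' Calls sharing (chrom, breakpoint) collapse into one call labeled with
#' the transposon having the most supporting reads (ties to the
#' lexicographically first name); supporting reads are summed and the
#' frequency re-estimated.
#'
#' @param calls Insertion-call table.
#' @return Merged call table.
#' @export
merge_same_position <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(calls)
  merged <- calls[, {
    o <- order(-n_support, transposon)
    w <- o[1L]
    S <- sum(n_support)
    n5 <- sum(n_support_5p)
    n3 <- sum(n_support_3p)
    cls <- if (S == 1L) "singleton" else if (n5 > 0L && n3 > 0L) "1p1" else "2p"
    list(transposon = transposon[w], family = family[w], strand = strand[w],
         class = cls, n_support = S, n_support_5p = n5, n_support_3p = n3,
         n_reference = n_reference[w],
         frequency = estimate_insertion_frequency(S, n_reference[w]),
         te_start = te_start[w], te_end = te_end[w],
         cluster_id = cluster_id[w])
  }, by = .(chrom, breakpoint)]
  data.table::setcolorder(merged, names(empty_call_table()))
  data.table::setorder(merged, chrom, breakpoint, transposon)
  merged[]
}

#' Apply all three insertion filters in order
#'
#' Same-transposon + blacklist filter, then the high-coverage filter, then
#' the same-position merge.
#'
#' @param calls Insertion-call table from [call_insertions()].
#' @param annotation A [repeat_annotation()] (or `NULL` to skip).
#' @param pairs Read-pair table (for the coverage profile).
#' @param library Optional [te_library()].
#' @param pad Annotation pad for the same-transposon filter.
#' @param window,ratio High-coverage filter parameters.
#' @return List with `calls` (filtered + merged), `removed_same_te`,
#'   `removed_coverage`, `blacklist`.
#' @export
apply_insertion_filters <- function(calls, annotation, pairs,
                                    library = NULL, pad = 0L,
                                    window = 1000L, ratio = 5) {
  st <- if (!is.null(annotation)) {
    filter_same_transposon(calls, annotation, library, pad = pad)
  } else {
    list(kept = data.table::as.data.table(calls),
         removed = empty_call_table(),
         blacklist = data.table::data.table(chrom = character(),
                                            breakpoint = integer()))
  }
  hc <- filter_high_coverage(st$kept, pairs, window = window, ratio = ratio)
  list(calls = merge_same_position(hc$kept),
       removed_same_te = st$removed,
       removed_coverage = hc$removed,
       blacklist = st$blacklist)
}
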