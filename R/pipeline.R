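#' Detect transposon insertions from paired-end alignments
#'
#' Full germline calling pipeline: fragment-length model, read-pair
#' classification, consensus alignment of candidate reads, clustering,
#' breakpoint calling, frequency estimation and the three false-positive
#' filters. Insertions of class 1p1/2p with at least `min_support`
#' supporting reads (and, when a frequency threshold applies, frequency at
#' or above it) are reported as germline; singleton calls are retained in
#' the result for de novo rate estimation.
#'
#' @param x SAM/BAM path or a read-pair table from
#'   [read_alignment_pairs()].
#' @param library A [te_library()].
#' @param annotation Optional [repeat_annotation()] (same-transposon
#'   filter is skipped without it).
#' @param min_support Minimum supporting read-pairs for a reported
#'   germline insertion.
#' @param mapq_unique MAPQ at or above which a read counts as uniquely
#'   mapped.
#' @param min_clip Minimum 5' soft-clip length for split candidates.
#' @param max_divergence Maximum divergence for consensus hits.
#' @param min_aligned Minimum aligned length for consensus hits.
#' @param f95 Manual 95th-percentile fragment length (otherwise estimated).
#' @param genome_count Number of genomes in the starting material; when
#'   given, the germline/de novo frequency threshold is set to
#'   `2 / genome_count`.
#' @param freq_threshold Explicit frequency threshold (overrides
#'   `genome_count`). Calls below it are treated as de novo candidates,
#'   not germline.
#' @param annotation_pad Pad applied to annotation intervals in the
#'   same-transposon filter; defaults to the estimated `f95` (breakpoints
#'   of clusters without split reads are only accurate to within the
#'   fragment length).
#' @param window,coverage_ratio High-coverage filter parameters.
#' @param align_method `"seed"` or `"exhaustive"` consensus alignment.
#' @return Object of class `te_calls`: list with `germline` (reported
#'   calls), `calls` (all filtered calls incl. singletons), `supporting`
#'   (clustered supporting reads), `fragment_model`, `removed_same_te`,
#'   `removed_coverage`, `blacklist`, `params`.
#' @export
detect_insertions <- function(x, library, annotation = NULL,
                              min_support = 5L, mapq_unique = 20L,
                              min_clip = 10L, max_divergence = 0.1,
                              min_aligned = 20L, f95 = NULL,
                              genome_count = NULL, freq_threshold = NULL,
                              annotation_pad = NULL, window = 1000L,
                              coverage_ratio = 5,
                              align_method = "seed") {
  pairs <- if (is.character(x)) read_alignment_pairs(x) else
    data.table::as.data.table(x)
  fm <- estimate_fragment_model(pairs, mapq_unique = mapq_unique, f95 = f95)
  pairs <- classify_pairs(pairs, mapq_unique = mapq_unique,
                          min_clip = min_clip)
  cand <- extract_candidates(pairs, mapq_unique = mapq_unique,
                             min_clip = min_clip)
  supp <- assign_supporting_reads(cand, library,
                                  max_divergence = max_divergence,
                                  min_aligned = min_aligned,
                                  method = align_method)
  raw_calls <- call_insertions(supp, pairs, fm$f95,
                               mapq_unique = mapq_unique)
  if (is.null(annotation_pad)) annotation_pad <- as.integer(round(fm$f95))
  filt <- apply_insertion_filters(raw_calls, annotation, pairs,
                                  library = library, pad = annotation_pad,
                                  window = window, ratio = coverage_ratio)
  calls <- filt$calls
  if (is.null(freq_threshold) && !is.null(genome_count)) {
    freq_threshold <- 2 / genome_count
  }
  germline <- calls[class %in% c("1p1", "2p") & n_support >= min_support]
  if (!is.null(freq_threshold)) {
    germline <- germline[frequency >= freq_threshold]
  }
  supp_clustered <- cluster_supporting_reads(supp, fm$f95)
  structure(list(
    germline = germline, calls = calls, supporting = supp_clustered,
    fragment_model = fm,
    removed_same_te = filt$removed_same_te,
    removed_coverage = filt$removed_coverage,
    blacklist = filt$blacklist,
    params = list(min_support = min_support, mapq_unique = mapq_unique,
                  min_clip = min_clip, max_divergence = max_divergence,
                  min_aligned = min_aligned,
                  freq_threshold = freq_threshold,
                  annotation_pad = annotation_pad, window = window,
                  coverage_ratio = coverage_ratio)),
    class = "te_calls")
}

#' @export
print.te_calls <- function(x, ...) {
  cat("Transposon insertion calls\n")
  cat(sprintf("  f95 = %.0f; %d supporting reads in %d clusters\n",
              x$fragment_model$f95, nrow(x$supporting),
              length(unique(x$supporting$cluster_id))))
  cat(sprintf("  %d filtered calls (%d germline at >= %d reads; %d singleton)\n",
              nrow(x$calls), nrow(x$germline), x$params$min_support,
              sum(x$calls$class == "singleton")))
  cat(sprintf("  removed: %d same-transposon, %d high-coverage\n",
              nrow(x$removed_same_te), nrow(x$removed_coverage)))
  invisible(x)
}

#' @export
summary.te_calls <- function(object, ...) {
  print(object)
  if (nrow(object$germline)) {
    cat("\nGermline calls by class:\n")
    print(table(object$germline$class))
    cat("\nFrequency quartiles:\n")
    print(quantile(object$germline$frequency))
  }
  invisible(object)
}
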