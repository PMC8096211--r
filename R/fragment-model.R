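#' Estimate the fragment-length model of a sequencing library
#'
#' Collects absolute template lengths from read-pairs that map entirely,
#' properly and uniquely to the reference (no soft-clips, both mates with
#' mapping quality at or above `mapq_unique`, nonzero TLEN) and summarises
#' them. The key statistic is `f95`, the 95th-percentile fragment length
#' (linear-interpolation quantile), which drives supporting-read clustering
#' and the definition of transposon end regions.
#'
#' @param pairs Read-pair table from [read_alignment_pairs()].
#' @param mapq_unique Minimum MAPQ for a read to count as uniquely mapped.
#' @param min_pairs Minimum number of usable pairs; below this an error asks
#'   for a manual `f95`.
#' @param f95 Optional manual override; when given, `pairs` may be `NULL`.
#' @return Object of class `fragment_model`: list with `f95`, `mean`, `sd`,
#'   `n_pairs_sampled` and the raw `sample` (unless overridden).
#' @export
estimate_fragment_model <- function(pairs, mapq_unique = 20L,
                                    min_pairs = 100L, f95 = NULL) {
  if (!is.null(f95)) {
    return(structure(list(f95 = as.numeric(f95), mean = NA_real_,
                          sd = NA_real_, n_pairs_sampled = 0L,
                          sample = numeric(0)),
                     class = "fragment_model"))
  }
  dt <- data.table::as.data.table(pairs)
  ok <- dt$proper & dt$mapped1 & dt$mapped2 &
    dt$mapq1 >= mapq_unique & dt$mapq2 >= mapq_unique &
    dt$clip5_1 == 0L & dt$clip3_1 == 0L &
    dt$clip5_2 == 0L & dt$clip3_2 == 0L &
    !is.na(dt$tlen) & dt$tlen != 0L
  lens <- abs(dt$tlen[ok])
  if (length(lens) < min_pairs) {
    stop("only ", length(lens), " properly and uniquely mapped unsplit ",
         "pairs available (need >= ", min_pairs, "); supply f95 manually")
  }
  structure(
    list(f95 = as.numeric(quantile(lens, 0.95, names = FALSE, type = 7)),
         mean = mean(lens), sd = sd(lens),
         n_pairs_sampled = length(lens), sample = lens),
    class = "fragment_model"
  )
}

#' @export
print.fragment_model <- function(x, ...) {
  cat("Fragment-length model:", x$n_pairs_sampled, "pairs sampled\n")
  cat(sprintf("  f95 = %.1f, mean = %.1f, sd = %.1f\n",
              x$f95, x$mean, x$sd))
  invisible(x)
}
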