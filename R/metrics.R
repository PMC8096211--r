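# Benchmark metrics: scoring caller output against simulation truth.

#' Match insertion calls to truth records
#'
#' Greedy one-to-one matching by breakpoint distance within `max_dist`
#' (closest pairs first). With `family_aware`, a call only matches a truth
#' record of the same transposon family.
#'
#' @param calls Call table with `chrom`, `breakpoint`, `family` (or
#'   `transposon`).
#' @param truth Truth table with `chrom`, `pos`, `transposon`.
#' @param library Optional [te_library()] for family mapping.
#' @param max_dist Maximum breakpoint distance (bp).
#' @param family_aware Require family agreement.
#' @return `data.table` of matched pairs: `call_row`, `truth_row`,
#'   `distance`, plus call/truth frequency and end columns when present.
#' @export
match_calls <- function(calls, truth, library = NULL, max_dist = 50L,
                        family_aware = TRUE) {
  calls <- data.table::as.data.table(calls)
  truth <- data.table::as.data.table(truth)
  empty <- data.table::data.table(call_row = integer(),
                                  truth_row = integer(),
                                  distance = integer())
  if (nrow(calls) == 0L || nrow(truth) == 0L) return(empty)
  fam_of <- function(te) {
    if (is.null(library)) return(te)
    known <- te %in% names(library$family)
    te[known] <- unname(library$family[te[known]])
    te
  }
  cf <- if ("family" %in% names(calls)) calls$family else
    fam_of(calls$transposon)
  tf <- fam_of(truth$transposon)
  cand <- data.table::CJ(call_row = seq_len(nrow(calls)),
                         truth_row = seq_len(nrow(truth)))
  cand[, distance := abs(calls$breakpoint[call_row] - truth$pos[truth_row])]
  cand <- cand[calls$chrom[call_row] == truth$chrom[truth_row] &
                 distance <= max_dist]
  if (family_aware) cand <- cand[cf[call_row] == tf[truth_row]]
  if (nrow(cand) == 0L) return(empty)
  data.table::setorder(cand, distance, call_row, truth_row)
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ci <- cand$call_row[i]; ti <- cand$truth_row[i]
    if (!used_c[ci] && !used_t[ti]) {
      keep[i] <- TRUE
      used_c[ci] <- TRUE
      used_t[ti] <- TRUE
    }
  }
  out <- cand[keep]
  if ("frequency" %in% names(calls)) out[, freq_call := calls$frequency[call_row]]
  if ("frequency" %in% names(truth)) out[, freq_truth := truth$frequency[truth_row]]
  for (cl in c("te_start", "te_end")) {
    if (cl %in% names(calls)) out[, (paste0(cl, "_call")) := calls[[cl]][call_row]]
    if (cl %in% names(truth)) out[, (paste0(cl, "_truth")) := truth[[cl]][truth_row]]
  }
  out[]
}

#' Sensitivity, precision and F1 of insertion detection
#'
#' @param calls Call table (already thresholded at the desired support).
#' @param truth Truth table.
#' @param library,max_dist,family_aware Passed to [match_calls()].
#' @return List with `sensitivity`, `precision`, `f1`, `tp`, `n_calls`,
#'   `n_truth` and the `matches` table.
#' @export
detection_metrics <- function(calls, truth, library = NULL, max_dist = 50L,
                              family_aware = TRUE) {
  truth <- data.table::as.data.table(truth)
  if (nrow(truth) == 0L) stop("empty truth set: sensitivity undefined")
  calls <- data.table::as.data.table(calls)
  m <- match_calls(calls, truth, library, max_dist, family_aware)
  tp <- nrow(m)
  sens <- tp / nrow(truth)
  prec <- if (nrow(calls) > 0L) tp / nrow(calls) else NA_real_
  f1 <- if (!is.na(prec) && (sens + prec) > 0) {
    2 * sens * prec / (sens + prec)
  } else 0
  list(sensitivity = sens, precision = prec, f1 = f1, tp = tp,
       n_calls = nrow(calls), n_truth = nrow(truth), matches = m)
}

#' Mean absolute frequency error over matched insertions
#'
#' @param matches Matched-pair table from [match_calls()] (needs
#'   `freq_call` and `freq_truth`).
#' @return Mean of `|estimated - true|`.
#' @export
frequency_error <- function(matches) {
  stopifnot(nrow(matches) >= 1L)
  mean(abs(matches$freq_call - matches$freq_truth))
}

#' Mean breakpoint distance over matched insertions
#'
#' @param matches Matched-pair table from [match_calls()].
#' @param accurate_tol Distance (bp) under which a breakpoint counts as
#'   accurately located.
#' @return List with `mean_distance` and `frac_accurate`.
#' @export
breakpoint_distance <- function(matches, accurate_tol = 5L) {
  list(mean_distance = mean(matches$distance),
       frac_accurate = mean(matches$distance <= accurate_tol))
}

#' Mean transposon-end distance over matched insertions
#'
#' Average over both consensus ends of the absolute difference between
#' predicted and simulated end coordinates.
#'
#' @param matches Matched-pair table with `te_start_call`/`te_end_call`
#'   and `te_start_truth`/`te_end_truth`.
#' @return Mean distance (nt).
#' @export
te_end_distance <- function(matches) {
  mean(c(abs(matches$te_start_call - matches$te_start_truth),
         abs(matches$te_end_call - matches$te_end_truth)))
}

#' Sum of squared residuals of de novo insertion rates
#'
#' `SSR = sum over families of (estimated - simulated insertions per
#' genome)^2`, including families with zero simulated insertions; also
#' reports the Pearson correlation across families.
#'
#' @param estimates A `denovo_estimate` table (or any table with `family`
#'   and `insertions_per_genome`).
#' @param truth Table with `family` and `per_genome` (simulated rates);
#'   families absent from it count as zero.
#' @return List with `ssr`, `pearson_r` and the per-family table.
#' @export
de_novo_ssr <- function(estimates, truth) {
  est <- data.table::as.data.table(estimates)
  tru <- data.table::as.data.table(truth)
  fams <- union(est$family, tru$family)
  tab <- data.table::data.table(family = fams)
  m1 <- match(tab$family, est$family)
  tab[, est := ifelse(is.na(m1), 0, est$insertions_per_genome[m1])]
  m2 <- match(tab$family, tru$family)
  tab[, sim := ifelse(is.na(m2), 0, tru$per_genome[m2])]
  tab[is.na(est), est := 0]
  r <- if (nrow(tab) > 2L && sd(tab$est) > 0 && sd(tab$sim) > 0) {
    stats::cor(tab$est, tab$sim)
  } else NA_real_
  list(ssr = sum((tab$est - tab$sim)^2), pearson_r = r, table = tab[])
}

#' Supporting-read end bias and terminal CG content per family
#'
#' `bias = log2((n_5' + 1) / (n_3' + 1))` over per-side supporting-read
#' counts, together with the CG fraction of the first and last
#' `terminus_width` nucleotides of each consensus -- low-complexity or
#' extreme-CG termini attract fewer reads, which this diagnostic exposes.
#'
#' @param calls Call table with `transposon`, `n_support_5p`,
#'   `n_support_3p`.
#' @param library A [te_library()].
#' @param terminus_width Terminal window (nt).
#' @return `data.table` per transposon: read counts, `bias`, `cg_5p`,
#'   `cg_3p`.
#' @export
end_bias_and_cg <- function(calls, library, terminus_width = 40L) {
  calls <- data.table::as.data.table(calls)
  cg <- function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    mean(strsplit(s, "")[[1]] %in% c("C", "G"))
  }
  tab <- data.table::data.table(transposon = names(library$entries))
  tab[, cg_5p := vapply(library$entries, function(s)
    cg(substr(s, 1L, terminus_width)), numeric(1))]
  tab[, cg_3p := vapply(library$entries, function(s)
    cg(substr(s, nchar(s) - terminus_width + 1L, nchar(s))), numeric(1))]
  cnt <- calls[, .(n_5p = sum(n_support_5p), n_3p = sum(n_support_3p)),
               by = transposon]
  tab <- merge(tab, cnt, by = "transposon", all.x = TRUE)
  tab[is.na(n_5p), n_5p := 0L]
  tab[is.na(n_3p), n_3p := 0L]
  tab[, bias := log2((n_5p + 1) / (n_3p + 1))]
  tab[]
}
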