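#' Write insertion calls to a TSV file
#'
#' One row per insertion, deterministically sorted by (chrom, start,
#' transposon). Columns: `chrom`, `start` (0-based), `end`,
#' `transposon_strand` (`name:strand`), `class` (`1p1`/`2p`/`singleton`),
#' `n_support_5p`, `n_support_3p`, `n_reference`, `frequency` (6 decimals),
#' `te_start`, `te_end`.
#'
#' @param calls An insertion-call table (see [detect_insertions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(calls, path) {
  cols <- c("chrom", "start", "end", "transposon_strand", "class",
            "n_support_5p", "n_support_3p", "n_reference", "frequency",
            "te_start", "te_end")
  dt <- data.table::as.data.table(calls)
  if (nrow(dt) == 0L) {
    out <- data.table::setnames(
      data.table::as.data.table(sapply(cols, function(x) character(0),
                                       simplify = FALSE)), cols)
    data.table::fwrite(out, path, sep = "\t")
    return(invisible(path))
  }
  out <- data.table::data.table(
    chrom = dt$chrom,
    start = dt$breakpoint,
    end = dt$breakpoint + 1L,
    transposon_strand = paste0(dt$transposon, ":", dt$strand),
    class = dt$class,
    n_support_5p = dt$n_support_5p,
    n_support_3p = dt$n_support_3p,
    n_reference = dt$n_reference,
    frequency = sprintf("%.6f", dt$frequency),
    te_start = dt$te_start,
    te_end = dt$te_end
  )
  data.table::setorder(out, chrom, start, transposon_strand)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an insertion table written by [write_insertion_table()]
#'
#' @param path TSV path.
#' @return A `data.table` with the caller's call columns (`breakpoint`,
#'   `transposon`, `strand`, `class`, support counts, `frequency`,
#'   `te_start`, `te_end`).
#' @export
read_insertion_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = "frequency"))
  if (nrow(tab) == 0L) {
    return(data.table::data.table(
      chrom = character(), breakpoint = integer(), transposon = character(),
      strand = character(), class = character(), n_support_5p = integer(),
      n_support_3p = integer(), n_reference = integer(),
      frequency = numeric(), te_start = integer(), te_end = integer()))
  }
  data.table::data.table(
    chrom = as.character(tab$chrom),
    breakpoint = as.integer(tab$start),
    transposon = sub(":[+-]$", "", tab$transposon_strand),
    strand = sub("^.*:", "", tab$transposon_strand),
    class = tab$class,
    n_support_5p = as.integer(tab$n_support_5p),
    n_support_3p = as.integer(tab$n_support_3p),
    n_reference = as.integer(tab$n_reference),
    frequency = as.numeric(tab$frequency),
    te_start = as.integer(tab$te_start),
    te_end = as.integer(tab$te_end)
  )
}
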