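#' Read a repeat annotation of the reference genome
#'
#' Reads transposon-copy intervals either from a BED6 file (0-based
#' half-open, pass-through) or from a RepeatMasker `.out` file (1-based
#' inclusive, converted). The returned table drives the same-transposon
#' filter and the fragmented-copy (`-T`) mode.
#'
#' @param path Annotation file.
#' @param dialect `"bed"` (BED6: chrom, start, end, name, score, strand) or
#'   `"repeatmasker"` (RepeatMasker `.out`).
#' @return A `data.table` of class `repeat_annotation` with columns
#'   `chrom`, `start`, `end` (0-based half-open), `transposon`, `strand`.
#' @export
read_repeat_annotation <- function(path, dialect = c("bed", "repeatmasker")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "bed") {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 4L) stop("BED annotation needs >= 4 columns")
    if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]]))
      stop("non-numeric coordinates in BED annotation")
    ann <- data.table::data.table(
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]),
      transposon = as.character(tab[[4]]),
      strand = if (ncol(tab) >= 6L) as.character(tab[[6]]) else "+"
    )
  } else {
    lines <- readLines(path)
    # skip the 2-3 header lines (column banner + blank)
    body <- grep("^\\s*[0-9]", lines, value = TRUE)
    if (length(body) == 0L) {
      ann <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), transposon = character(),
                                    strand = character())
    } else {
      fields <- strsplit(trimws(body), "\\s+")
      n <- vapply(fields, length, integer(1))
      if (any(n < 10L)) stop("malformed RepeatMasker row (needs >= 10 fields)")
      get <- function(i) vapply(fields, `[[`, character(1), i)
      starts <- suppressWarnings(as.integer(get(6)))
      ends <- suppressWarnings(as.integer(get(7)))
      if (anyNA(starts) || anyNA(ends))
        stop("non-numeric coordinates in RepeatMasker annotation")
      ann <- data.table::data.table(
        chrom = get(5),
        start = starts - 1L,          # 1-based inclusive -> 0-based half-open
        end = ends,
        transposon = get(10),
        strand = data.table::fifelse(get(9) %in% c("C", "-"), "-", "+")
      )
    }
  }
  if (any(ann$start >= ann$end))
    stop("annotation interval with end <= start")
  data.table::setattr(ann, "class",
                      c("repeat_annotation", class(ann)))
  ann[]
}

#' Construct a repeat annotation from a data frame
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `transposon`
#'   and optionally `strand` (0-based half-open coordinates).
#' @return A `repeat_annotation` table.
#' @export
repeat_annotation <- function(df) {
  ann <- data.table::as.data.table(df)
  if (!"strand" %in% names(ann)) ann[, strand := "+"]
  stopifnot(all(c("chrom", "start", "end", "transposon") %in% names(ann)))
  if (any(ann$start >= ann$end)) stop("annotation interval with end <= start")
  data.table::setattr(ann, "class", c("repeat_annotation", class(ann)))
  ann[]
}
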