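#' Read a FASTA file into a named vector of uppercase DNA sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' package-wide sequence contract: sequences are uppercased, restricted to
#' the A/C/G/T/N alphabet, and empty records are an error.
#'
#' @param path Path to a FASTA file (gzip-transparent).
#' @return Named character vector, one element per record; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # IUPAC ambiguity codes are collapsed to N rather than rejected
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  seqs
}

#' Write named DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a transposon consensus library
#'
#' Bundles consensus sequences with an optional family grouping. Without a
#' grouping, every consensus is its own family (related subfamilies can be
#' grouped so that reads mapping ambiguously among them are treated
#' together downstream).
#'
#' @param seqs Named character vector of consensus sequences, or a FASTA
#'   path.
#' @param family Optional named character vector mapping transposon name to
#'   family label, or a two-column TSV path (name, family). Transposons not
#'   listed default to their own name.
#' @return An object of class `te_library` with elements `entries`
#'   (named sequences), `family` (named family labels) and `lengths`.
#' @export
te_library <- function(seqs, family = NULL) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs))) {
    seqs <- read_fasta(seqs)
  }
  if (length(seqs) == 0L || is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("library requires named, nonempty consensus sequences")
  if (any(!nzchar(seqs))) stop("library contains an empty consensus sequence")
  fam <- setNames(names(seqs), names(seqs))
  if (!is.null(family)) {
    if (is.character(family) && length(family) == 1L && file.exists(family)) {
      tab <- read.table(family, sep = "\t", header = FALSE,
                        col.names = c("name", "family"),
                        stringsAsFactors = FALSE)
      family <- setNames(tab$family, tab$name)
    }
    known <- intersect(names(family), names(seqs))
    fam[known] <- family[known]
  }
  structure(
    list(entries = toupper(seqs), family = fam,
         lengths = setNames(nchar(seqs), names(seqs))),
    class = "te_library"
  )
}

#' @export
print.te_library <- function(x, ...) {
  cat("Transposon consensus library:", length(x$entries), "entries,",
      length(unique(x$family)), "families\n")
  cat("  lengths:", min(x$lengths), "-", max(x$lengths), "nt\n")
  invisible(x)
}

#' @export
length.te_library <- function(x) length(x$entries)
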