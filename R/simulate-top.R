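#' Write simulation truth files
#'
#' Germline truth goes to a BED6+2 file (chrom, start, end, transposon,
#' frequency, strand, te_start, te_end); somatic truth to a TSV of
#' per-family insertions per genome.
#'
#' @param population A [build_population()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
emit_truth <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  germ_path <- file.path(dir, "truth_germline.bed")
  som_path <- file.path(dir, "truth_somatic.tsv")
  g <- population$germline
  gb <- data.table::data.table(
    chrom = g$chrom, start = g$pos, end = g$pos + 1L,
    transposon = g$transposon, frequency = g$frequency, strand = g$strand,
    te_start = g$te_start, te_end = g$te_end)
  data.table::fwrite(gb, germ_path, sep = "\t", col.names = FALSE)
  fam <- population$library$family
  s <- population$somatic
  if (nrow(s)) {
    fam_of <- unname(fam[s$transposon])
    agg <- data.table::data.table(family = fam_of)[
      , .(total = .N), by = family]
    agg[, per_genome := total / population$config$n_genomes]
  } else {
    agg <- data.table::data.table(family = character(), total = integer(),
                                  per_genome = numeric())
  }
  data.table::fwrite(agg, som_path, sep = "\t")
  c(germline = germ_path, somatic = som_path)
}

#' Read a germline truth BED written by [emit_truth()]
#'
#' @param path Path to the truth BED.
#' @return `data.table` with `chrom`, `pos`, `transposon`, `frequency`,
#'   `strand`, `te_start`, `te_end`.
#' @export
read_truth_germline <- function(path) {
  tab <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "transposon", "frequency", "strand",
                                         "te_start", "te_end"))
  tab[, .(chrom, pos = start, transposon, frequency, strand,
          te_start, te_end)]
}

#' Simulate a sequenced population end to end
#'
#' Convenience wrapper: builds the population, samples read-pairs with
#' chimeras and errors, writes the truth SAM and truth tables.
#'
#' @param genome Named character vector of chromosome sequences (typically
#'   from [embed_te_copies()]).
#' @param library A [te_library()].
#' @param config A [simulation_config()].
#' @param annotation Optional [repeat_annotation()] of embedded copies.
#' @param out_dir Output directory.
#' @return List of class `te_simulation`: `population`, `sam`,
#'   `truth` (paths), `chimeric_qnames`, `n_pairs`.
#' @export
simulate_population <- function(genome, library, config, annotation = NULL,
                                out_dir = tempfile("tesim")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- build_population(genome, library, config, annotation)
  rs <- simulate_read_pairs(pop, file.path(out_dir, "reads.sam"))
  truth <- emit_truth(pop, out_dir)
  structure(list(population = pop, sam = rs$sam, truth = truth,
                 chimeric_qnames = rs$chimeric_qnames,
                 n_pairs = rs$n_pairs, out_dir = out_dir),
            class = "te_simulation")
}

#' @export
print.te_simulation <- function(x, ...) {
  cat("Population simulation:", x$n_pairs, "read pairs ->", x$sam, "\n")
  print(x$population)
  invisible(x)
}

#' Write a repeat annotation to BED6
#'
#' @param annotation A [repeat_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(annotation, path) {
  ann <- data.table::as.data.table(annotation)
  out <- ann[, .(chrom, start, end, transposon, score = 0L, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
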