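#' Simulate the standard benchmark experiment
#'
#' Builds the full benchmark scenario on a synthetic genome: a consensus
#' library with sibling subfamilies, a reference carrying two annotated
#' copies of every consensus, and either the germline design (400
#' insertions at frequencies 0.25/0.5/0.75/1, 10% truncated) or the
#' somatic design (per-genome family counts 8/4/3/2/1/1/1 across 10,000
#' genomes, the fourth family inserting only a fixed truncated fragment
#' that also exists as an annotated genomic copy).
#'
#' @param scenario `"germline"` or `"somatic"`.
#' @param seed Master seed; all internal seeds derive from it.
#' @param depth Total genome-mapped sequencing depth.
#' @param chimera_rate Chimeric read-pair fraction.
#' @param n_genomes Population size.
#' @param chrom_sizes Chromosome sizes of the synthetic genome.
#' @param n_te Number of consensus transposons.
#' @param n_germline Germline insertion count (germline scenario).
#' @param out_dir Simulation output directory.
#' @return List: `sim` (a `te_simulation`), `library`, `annotation`,
#'   `genome`, `somatic_families` (somatic scenario), `config`.
#' @export
benchmark_simulation <- function(scenario = c("germline", "somatic"),
                                 seed = 1L, depth = 20,
                                 chimera_rate = 5e-4, n_genomes = 10000L,
                                 chrom_sizes = c(chrA = 2e6, chrB = 2e6),
                                 n_te = 40L, n_germline = 400L,
                                 out_dir = tempfile("tebench")) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 5L)
  genome0 <- synthetic_genome(chrom_sizes, seed = seeds[1])
  lib <- synthetic_te_library(n_te = n_te, len_range = c(1500L, 6000L),
                              n_sibling_pairs = 3L, seed = seeds[2])
  somatic_counts <- NULL
  somatic_spans <- NULL
  truncated <- NULL
  fams <- NULL
  if (scenario == "somatic") {
    lens <- lib$lengths
    base <- names(lens)[lens >= 3000L & !grepl("b$", names(lens))]
    fams <- base[seq_len(7L)]
    frag_te <- fams[4L]
    half <- as.integer(lens[[frag_te]] / 2)
    somatic_spans <- data.frame(transposon = frag_te,
                                te_start = half - 1000L,
                                te_end = half + 1000L)
    truncated <- somatic_spans
    somatic_counts <- setNames(c(8L, 4L, 3L, 2L, 1L, 1L, 1L), fams)
  }
  emb <- embed_te_copies(genome0, lib, copies_per_te = 2L,
                         truncated = truncated, spacing = 9000L,
                         seed = seeds[3])
  cfg <- simulation_config(
    n_genomes = n_genomes,
    n_germline = if (scenario == "germline") n_germline else 0L,
    somatic_counts = somatic_counts, somatic_spans = somatic_spans,
    depth = depth, chimera_rate = chimera_rate, seed = seeds[4])
  sim <- simulate_population(emb$genome, lib, cfg,
                             annotation = emb$annotation,
                             out_dir = out_dir)
  list(sim = sim, library = lib, annotation = emb$annotation,
       genome = emb$genome, somatic_families = fams, config = cfg)
}
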