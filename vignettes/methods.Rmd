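---
title: "Detecting transposon insertions and estimating de novo insertion rates"
author: "tescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transposon insertions and estimating de novo insertion rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescope)
library(data.table)
```

## The problem

Transposons (mobile elements) copy themselves into new genomic locations.
In a pool of sequenced genomes — a fly strain, a human cell line, a
dysgenic cross — two quite different questions arise:

1. **Germline insertions**: at which loci does some fraction of the
   population carry an insertion absent from the reference, and at what
   population frequency?
2. **De novo (singleton) insertions**: how many *new* insertions per
   genome does each transposon family produce — insertions present in one
   somatic or germ cell each, dispersed throughout the genome, each
   supported by at most a single read-pair and therefore easily confused
   with chimeric library artifacts?

`tescope` answers both from standard paired-end alignments plus a
transposon consensus library, and ships a population sequencing simulator
so that every claim can be validated against known truth without any
external data or aligner.

## Germline calling

**Evidence extraction.** Read-pairs are classified from their primary
alignments. A *discordant candidate* has exactly one uniquely mapped read
(MAPQ ≥ 20 by default) while its mate is unmapped or multi-mapped — the
mate may live in a transposon. A *split candidate* is a properly mapped
pair in which the 5′ end of one read is soft-clipped by at least
`min_clip` (10 nt): the clip may be transposon sequence crossing the
insertion junction. Candidate reads (the non-unique mate, or the clipped
portion) are aligned to both strands of every consensus with a local
Smith–Waterman aligner (match +1, mismatch −2, gap open −3, gap extend
−1); a hit must align ≥ 20 nt at ≤ 10% divergence, and ties between
equal scores go to the longer alignment, then the lexicographically first
name — deterministic by construction. An exact k-mer seed index
restricts the search to a window around the best diagonal; results are
identical to the exhaustive scan whenever a seed exists (the test suite
checks this equivalence), and candidates without any seed fall back to
nothing rather than a guess.

**Fragment-length model.** From all properly, uniquely and fully mapped
pairs the empirical fragment-length distribution is summarised by its
95th percentile, `f95` (linear-interpolation quantile). `f95` sets the
clustering distances, the same-transposon annotation pad, and the
transposon end-region width used by the de novo module.

**Clustering.** Two supporting reads join one cluster when they anchor on
the same side of an insertion less than `f95` apart, or on opposite
sides less than `2·f95` apart *and* in convergent orientation (the
left-side anchor not to the right of the right-side anchor). The
convergence requirement is this package's refinement: without it, the
right-side reads of one insertion chain with the left-side reads of the
next same-family insertion a kilobase away, fusing two true insertions
into one call. Clustering is true single linkage (union-find over the
pairwise rule; an O(n²) transitive-closure oracle verifies it in the
tests), applied per chromosome and per family so that related subfamilies
cannot chain across loci.

**Breakpoints.** If a cluster contains split evidence, the breakpoint is
the modal soft-clip coordinate (ties to the smallest coordinate — the
mode is robust and deterministic). Besides 5′-clipped reads of proper
pairs, a discordant pair whose *anchor* carries a 3′ soft-clip also ends
exactly at the junction, so its 3′ end is treated as split evidence too;
with both sources, essentially every cluster with ≥ 5 reads contains an
exact coordinate. Otherwise the breakpoint is the mean of the anchor
3′-end coordinates, rounded half-up, which is accurate only to within
the fragment length.

**Classes and frequency.** Clusters with reads on both sides are `1p1`,
one-sided clusters with ≥ 2 reads are `2p`, single-read clusters are
`singleton`. `1p1` and `2p` calls with at least `min_support` (5)
supporting reads are reported as germline. Each call's population
frequency is

$$p = \frac{S}{S + 2R}$$

with `S` the supporting read-pairs and `R` the *reference* read-pairs:
properly mapped, unsplit pairs whose fragment span crosses the breakpoint
by more than 20 bp on each side. The factor 2 balances the books: a
supporting pair witnesses one of the two insertion junctions, a reference
pair spans the single reconstituted site. We count a pair as crossing
when its fragment (outer span) crosses, including junctions falling in
the unsequenced gap between the mates; counting only read-covered
crossings would roughly triple the supporting-to-reference yield ratio
and bias frequencies upward by ~0.2 at 20×, far outside the error this
estimator demonstrably achieves.

**Filters.** Three false-positive filters run immediately after calling:

* *Same-transposon*: a call whose breakpoint lies inside an annotated
  copy of the same transposon or family is discarded (mis-alignments
  concentrate there), and its position joins a blacklist that removes
  co-located calls of any family. Annotation intervals are padded by
  `f95`: clusters at copy edges have no split reads (the reference
  continues through the copy, so nothing is clipped), their averaged
  breakpoints land up to ~100 bp outside the copy, and an unpadded test
  would let every copy edge through as a false positive.
* *High coverage*: calls in 1-kb windows with ≥ 5× the genome-wide mean
  read depth are discarded; such windows flag sequences collapsed in the
  reference assembly. Depth is the count of read starts per window scaled
  to nucleotide coverage; 1 kb resolves the bimodal depth distribution
  this filter exploits.
* *Same-position merge*: calls at exactly the same breakpoint — almost
  always related subfamilies catching each other's reads — collapse into
  one call labeled with the transposon holding the most supporting reads
  (ties lexicographic); supporting reads are summed and the frequency
  re-estimated, so reads are conserved.

## De novo rate estimation

Genuine singleton support can only reach as far into a transposon as the
library fragment allows, and always enters from a terminus; chimeric
artifacts land uniformly over the consensus. With the transposon *end*
defined as the terminal `f95 − 25` nt on each side and the rest the
*center*, the corrected end-read count per family is

$$D = \max\!\left(0,\; SE - SC \cdot \frac{AE}{AC}\right)$$

where `SE`/`SC` are end/center-mapping singleton reads and `AE`/`AC`
end/center-mapping reads among *all* consensus-mapped reads (the uniform
background sets the end-to-center ratio). A confidence score
`1 − min(1, SC·(AE/AC)/SE)` reports one minus the estimated chimera
fraction. By default a singleton read counts as end-mapping only when its
orientation matches the terminus: a hit on the consensus minus strand
must sit at the 5′ end, a plus-strand hit at the 3′ end — working
through the four side × strand geometries shows the hit strand alone
determines the expected terminus, while the anchor side fixes the
insertion's orientation. Wrongly oriented end hits are treated as
chimera evidence. Families with `AC = 0` and `SC > 0` are reported as
undefined; with `SC = 0` no correction is possible or needed.

**Fragmented transposons.** Truncated genomic copies spawn truncated
insertions whose junction reads map to the *fragment's* ends, i.e. the
consensus interior. With the fragmented mode enabled, annotated copies
shorter than their consensus contribute their fragment ends as additional
end intervals, activated only when at least `min_fragment_support` (3)
singleton reads support each fragment end. Fragment consensus spans come
from the annotation when it carries them, or are inferred by aligning the
copy sequence to its consensus.

**From reads to insertions per genome.** The conversion divides `D` by
the expected supporting-read yield of one insertion present in a single
genome of the pool. With per-genome depth `d`, read length `ℓ` and mean
fragment length `f̄`, each junction is spanned by `d·f̄/(2ℓ)` fragments,
of which a fraction `(f̄ − 40)/f̄` yield a supporting read — a spanning
fragment is lost only when the junction falls within 20 nt of either
fragment end, leaving either no mappable anchor (< 20 nt of unique
sequence) or no alignable clip (< 20 nt of transposon). Over both
junctions and all `n` genomes this gives, per insertion per genome,
`R_exp = depth_total · (f̄ − 40)/ℓ` — independent of `n`, which enters
only through the total depth. These constants mirror the aligner
behaviour the simulator emulates and the aligner thresholds the caller
uses; the somatic recovery benchmark doubles as a parameter-recovery
validation of this choice.

**Cluster censoring.** A singleton read is only *observed* as a singleton
if no other supporting read of the same family lands within the
clustering radii. When per-family supporting-read density `μ` (reads per
bp) is non-negligible — unavoidable when a genome is scaled down while
per-genome insertion counts stay fixed — a fraction
`1 − exp(−3·f95·μ)` of true singletons is absorbed into 2p clusters and
lost (the exposure is `f95·μ` same-side neighbours plus `2·f95·μ`
opposite-side ones, thinning a Poisson process). The estimator divides by
`exp(−3·f95·μ̂)` with `μ̂` measured from the observed sub-threshold
supporting reads of each family. At realistic genome sizes the correction
is ~1%, at the 4-Mb benchmark scale it reaches ~20% for the densest
family; it is part of the package's read-to-rate normalisation and can be
disabled (`correct_clustering = FALSE`).

When the sequencing library derives from few genomes, PCR can amplify a
de novo insertion into multiple read-pairs. Supplying `genome_count` sets
a frequency threshold of twice the theoretical de novo frequency,
`2/genome_count`; calls below it are treated as de novo candidates
rather than germline, and their reads enter the singleton tallies.

## The population simulator

The simulator emulates the benchmark design end to end:

* A synthetic reference (4 Mb across two chromosomes by default, GC 0.42)
  with two annotated full-length copies of every consensus embedded.
  Multi-copy families are what make transposon-internal reads
  multi-mappable in real data — and what gives the same-transposon filter
  real work: copy-edge read clusters arise in every simulation and must
  be filtered, not absent by construction.
* A consensus library (40 entries, 1.5–6 kb) including three ~95%
  identical sibling pairs grouped as families, exercising the ambiguous
  mapping that motivates the same-position merge.
* Germline insertions at identical coordinates in a fixed fraction
  (0.25/0.5/0.75/1) of 10,000 genomes, 10% of them truncated; somatic
  insertions at genome-specific uniform coordinates. Sites keep two
  fragment lengths of mutual spacing and 1 kb of distance from annotated
  copies — copy ± `f95` neighbourhoods are exactly where short-read
  evidence is confounded, the analogue of excluding low-mappability
  regions.
* Fragments Normal(450, 10), 100-nt reads from both ends, uniform 0.1%
  substitution errors, and truth alignments emitted directly: fully
  transposon-internal reads are placed at a genomic copy with MAPQ 0,
  junction reads carry the soft-clips an aligner would produce (portions
  under 20 nt are unmappable), and everything else maps uniquely. A
  configurable fraction of pairs is replaced by chimeras joining two
  reads from independent random fragments. `depth` counts
  reference-mapped nucleotides, so the fragment count is scaled up by the
  population's mean insertion content.

What the simulator does *not* model: indel sequencing errors, quality
profiles, PCR duplicates, target-site duplications (configurable nowhere;
the design omits them), nested or reference-polymorphic insertions, and
mappability structure beyond the embedded copies. Passing the benchmark
therefore shows the algorithmic chain is correct under the stated read
model, not that real libraries — with their error and bias structure —
will behave identically.

## Benchmark scales and expected numbers

All heavy validation runs on one CPU at the following sizes, chosen to
finish each experiment in minutes while keeping every rate estimable:
4-Mb genome, 40 consensus transposons, 10,000 genomes, 20× total depth,
0.05% chimeras; 400 germline insertions or 20 somatic insertions per
genome in family counts (8, 4, 3, 2, 1, 1, 1) with the fourth family
inserting a fixed 2-kb fragment of its consensus (also present as a
truncated annotated copy, for the fragmented mode). Under these
conditions the suite asserts: germline sensitivity ≥ 99.8% with
precision 100% at the five-read cutoff and 50-bp family-aware matching;
mean absolute frequency error ≤ 0.048; somatic SSR over all 40 families
≤ 0.3 with Pearson r ≥ 0.998; and mean breakpoint distance < 10 bp at
5×. A small worked example:

```{r example, eval = FALSE}
g   <- synthetic_genome(c(chrA = 3e5, chrB = 3e5), seed = 11)
lib <- synthetic_te_library(n_te = 6, len_range = c(1500, 3000), seed = 12)
emb <- embed_te_copies(g, lib, copies_per_te = 1, seed = 13)
cfg <- simulation_config(n_genomes = 100, n_germline = 12, depth = 25,
                         chimera_rate = 1e-3, seed = 14)
sim <- simulate_population(emb$genome, lib, cfg, annotation = emb$annotation)
res <- detect_insertions(read_alignment_pairs(sim$sam), lib,
                         annotation = emb$annotation)
detection_metrics(res$germline, sim$population$germline, library = lib)
```

## Long-read benchmark curation

From long-read alignments, every CIGAR insertion of ≥ 300 bp becomes an
event; its sequence must align to a consensus over more than half its
length, starting within 500 nt of the insert's 5′ end and ending within
500 nt of its 3′ end (20% divergence allowed — long reads are noisier).
Events within 50 bp merge (breakpoint = modal site), single-read
insertions are dropped, and frequencies reuse `S/(S+2R)`: reads crossing
the breakpoint by ≥ 50 bp are reference reads, reads split within 50 bp
are supporting — a read carrying the full insertion traverses *both*
junctions and counts twice, which is exactly what makes the estimator
unbiased (a carrier read contributes 2 against the reference read's
weight of 2). Insertions inside an annotated copy of the same transposon
are flagged, not silently removed: distinguishing true nested insertions
from alignment artifacts ultimately needs inspection, and the flag
carries that information forward.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere in memory; SAM positions
  convert on ingest, BED passes through.
* Quantiles use R's default linear interpolation (type 7). Adding a
  fragment above the sample maximum never decreases `f95`; an insertion
  between `f95` and the maximum can move the interpolated value within
  one grid step.
* Breakpoint ties take the smallest coordinate; transposon ties the
  lexicographically first name; merge ties likewise — no randomness
  anywhere in the caller.
* `estimate_insertion_frequency` requires `S ≥ 1`; `S = 0` never reaches
  it (no cluster exists without a read).
* Transposons shorter than `2·(f95 − 25)` have no center: their de novo
  rate is undefined by construction and they are flagged, not guessed.
* Empty inputs (no reads, no candidates, no calls) propagate as empty
  tables with stable schemas, not errors; the one deliberate error is a
  fragment-length model with fewer than 100 usable pairs, which asks for
  a manual `f95` instead of silently extrapolating.

## Known limitations

* Uniqueness is approximated by MAPQ ≥ 20; aligners differ in MAPQ
  semantics, and a different aligner may need a different threshold.
* Insertion *absence* (reference insertions missing from the sample) is
  out of scope, as are genotype likelihoods and per-locus de novo calls —
  the de novo module estimates family-level rates only.
* The de novo conversion assumes junction yields derived from the
  uniform-coverage read model; strong coverage bias in real libraries
  would require the empirical calibration route (simulate one known
  insertion, count its supporting reads) rather than the analytic yield.
* The frequency estimator is unbiased only while supporting and
  reference yields stay balanced; extreme fragment-length distributions
  (f̄ close to 2ℓ) erode the supporting yield first.
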