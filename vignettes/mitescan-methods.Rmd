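---
title: "MITE discovery and family evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MITE discovery and family evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

`mitescan` annotates miniature inverted-repeat transposable elements
(MITEs) from their structural signature and summarises their family
evolution and genomic context. This vignette documents the models behind
each stage, the parameters that matter and their defaults, the design
choices made where the design was genuinely open, and what the
simulation-based tests do and do not demonstrate about real data.

## The structural model of a MITE

A MITE copy is modelled as

```
... [TSD] [TIR5' ... internal ... TIR3'] [TSD] ...
```

where the element span (what coordinates refer to throughout, 0-based
half-open) excludes the TSD; `TIR3'` is the reverse complement of
`TIR5'` up to a mismatch budget; and the two TSD instances are exact
copies of each other, since a target-site duplication is by definition
host sequence duplicated on insertion. Default structural bounds follow
the canon for this element class: TIR 8–50 bp, TSD 2–30 bp, element
100–600 bp.

## Mining: seed-and-extend inverted-repeat detection

The scanner indexes exact 8-mers and pairs each word with downstream
occurrences of its reverse complement; each pair fixes an
inverted-repeat diagonal `d = start + end`. On a diagonal, every element
span in the legal length range is scored for its maximal TIR under the
rules:

* both boundary pairs of the inverted-repeat alignment must match (an
  alignment is trimmed to matching ends);
* cumulative mismatches ≤ `floor(0.10 · t)` for TIR length `t`;
* the TIR must contain at least one run of 8 consecutive exact matches —
  the word-hit requirement every seeded search inherits. Sensitivity is
  therefore bounded the way BLAST-family tools are bounded: an
  inverted repeat so diverged that no 8-word survives is invisible to
  both the scanner and, by the same rule, the brute-force oracle the
  tests compare against.

A span becomes a candidate only if an exact TSD (longest length first)
flanks it on both sides, the element contains no `N`, and — for
homopolymer TSDs — the repeated base does not continue past the TSD on
either side (otherwise any poly-A tract would manufacture TSDs).

**Shadow resolution.** Overlapping candidates sharing more than half of
the shorter span are resolved deterministically by keeping the candidate
with the greatest `tir_len + tsd_len`, then the longer TSD, then the
leftmost start. This composite ranking is forced by two structural
artefacts that single-key rankings cannot handle: (i) because the two
TSD copies are identical, a span widened by δ into the duplication
always carries a TIR longer by δ *and* an exact inner direct repeat of
length `TSD − 2δ` masquerading as its TSD, so "longest TIR first"
systematically displaces the true span for any TSD of length ≥ 4 (TA/AT
duplications are their own reverse complements, so the widened TIR pairs
perfectly); (ii) a palindromic substring inside a TIR hands a *narrowed*
span a spurious long "TSD", so "longest TSD first" fails in the opposite
direction. The sum dominates both artefacts at the true configuration.

The scan runs on the forward strand only: an inverted-repeat element
presents the identical structure on both strands, so a reverse-strand
pass would merely duplicate every call. The census stage, which searches
with a single representative orientation, does align both strands.

## Families

Candidates cluster by single linkage over global pairwise identity
(Needleman–Wunsch, match +1, mismatch −1, linear gap −2; identity =
matching columns / alignment length) with an edge when identity exceeds
0.8; components under 3 members are dropped as unreplicated structure.
The family representative is the member whose length is closest to the
component's median (ties to the lowest coordinate) — a typical, real
sequence rather than a consensus, so downstream homology search mirrors
searching with an actual family member.

## Pseudo-element filtering

Three member-level flags reproduce the artifact classes that inflate
structure-only mining: (a) any `N` in the element; (b) tandem simple
repeats — at least 80% of positions covered by maximal exact tandem runs
of period ≤ 6 (at least two full units); (c) nested in a larger repeat —
both 50-bp genomic flanks occurring more than 20 times at ≥ 90%
identity. The source material filters at family level without stating a
member threshold; the package rejects a family when more than 50% of
members carry any flag, which tolerates a single sequencing artifact
inside a genuine family. The filter is idempotent.

## Copy census

Each representative is aligned genome-wide (both strands) by exact
12-word seeding and local Smith–Waterman extension (match +1, mismatch
−1, gap open 2 / extend 1). A hit is a copy when identity > 0.90 and
representative coverage > 0.80, with a 50-column minimum alignment
standing in for an E-value cutoff — at these identity levels the
identity and coverage thresholds, not the score statistics, are the
operative filters. A copy is *intact* when both TIR spans of the
representative are fully covered and each aligns at ≥ 90% identity
("complete TIR" is not quantified in the source; this 100%-span + 90%
identity rule is the package's documented operationalisation). Because
local alignment trims terminal mismatch columns, alignments are
re-extended ungapped to the representative ends before the TIR rule is
applied; otherwise a single substitution in the last base of a TIR
would misclassify an intact copy. Overlapping hits deduplicate by best
score, then leftmost.

Superfamily labels come from TSD/TIR composition, first match wins:
TSD `TA` → Stowaway-like; `TWA`/`TDA` → Tourist-like; an 8-bp
nonspecific TSD whose TIR head matches the `CAGTGGCGGAT` motif class at
≥ 80% → Pegasus-like; otherwise novel.

## Family evolution

**Alignment and consensus.** Members are census-guaranteed near-identical
to the representative, the regime where center-star alignment is within
known bounds of the optimal multiple alignment; it also removes an
external aligner dependency. Consensus: per-column majority base among
A/C/G/T, ties alphabetical (the historical consensus builders do not
publish their tie rule; alphabetical is deterministic), gap-majority
columns omitted.

**Insertion ages.** For each member, the Kimura two-parameter distance
to the consensus over shared ungapped sites,
`k = −½·ln((1−2P−Q)·√(1−2Q))` with P/Q the transition/transversion
proportions, converted to years by `T = k/2r` with
`r = 1.56×10⁻⁸` substitutions/site/year — the fruit-fly neutral rate
conventionally borrowed for the silkworm, overridable everywhere it is
used. Saturated members (`1−2P−Q ≤ 0` or `1−2Q ≤ 0`) are reported `NA`
and flagged rather than clipped.

**Sliding diversity.** π per 20-column window (step 20, trailing partial
window dropped), windows indexed on ungapped consensus coordinates so
profiles are comparable across members; pairwise deletion of gapped
site-pairs (whether the historical implementation deleted listwise or
pairwise is unstated; pairwise keeps partial windows informative). A
window is *variable* at ≥ mean + 2 SD and *conserved* at ≤ mean − 2 SD
(floored at zero); when the SD is zero or undefined every window is
*intermediate*, since the ±2 SD bands collapse onto the mean and would
otherwise label every window both ways. Note that π as the mean over
sequence pairs carries the usual n/(n−1) small-sample factor; the
frequency-weighted form `π·(n−1)/n` is the quantity exactly invariant
under duplicating the row set, and that is what the property tests
assert.

**Median-joining networks.** Identical rows condense into haplotypes
with multiplicities (gap = fifth state); the minimum spanning *network*
(union of all tied minimum spanning trees, Kruskal by distance class)
connects them; median (Steiner) vectors — column majorities of node
triplets adjacent in the network — are added greedily while each
strictly shortens the minimum spanning tree, then obsolete medians are
pruned. This is the ε = 0 variant of the median-joining heuristic, the
canonical default; larger ε is out of scope. All orderings and
tie-breaks are lexicographic in the haplotype string, so the network is
independent of input order. The *star statistic* — the fraction of other
nodes adjacent to the highest-multiplicity node — operationalises the
topological reading of such networks: ≥ 0.9 for a recent burst (one
dominant haplotype, short branches), ≤ 0.5 for an old expansion (no
dominant centre, long branches). Median vectors have multiplicity 0 and
can never be the modal node, which is what makes the statistic sensitive
to whether the ancestral haplotype is still segregating.

## Genomic context

Each copy is classified **by its midpoint** into exactly one category —
exon, intron, 5′-flank, 3′-flank (nearest gene within 5 kb, side by the
gene's strand), intergenic — so category counts are mutually exclusive
and sum to the copy total. Midpoint-versus-any-overlap is not stated in
the source; midpoint is chosen and, crucially, the randomised null uses
the *identical* classifier, so observed-vs-null comparisons are
convention-consistent. Ties between two equidistant genes resolve to
the 5′-flank (arbitrary, documented, deterministic). Flank distance bins
are half-open: ≤ 500, (500, 3000], (3000, 5000].

The null samples fragments of up to 10 kb uniformly (truncated at
sequence ends) and classifies each fragment's midpoint; 5,000 draws by
default, matching the published control size. Chromosome-distribution
χ² uses length-proportional expectations with df = n−1; in-gene
enrichment is a 2×2 χ² without continuity correction (a published
"P = 0.0" is reported here as p < 1e-15); density correlation is Pearson
on per-Mb densities with df = n−2; and the germline-silencing statistic
is `(1 − expressed/total)^n`.

## The synthetic-genome generator

`simulate_genome()` is first-class, tested code: it defines the
conditions under which every recovery claim is measured.

* **Background**: i.i.d. nucleotides at 62% AT, the silkworm genome-wide
  value; per-family internal regions default to 65% AT (the family table
  ranges 44–73%).
* **Families**: `example_family_specs()` takes TSD motif, TIR and
  element size verbatim from three published families spanning the three
  diagnostic TSD classes (TA, ATT, 8-bp nonspecific). Degenerate motif
  letters (W, D, N) are sampled per copy.
* **Mutation**: each site of a copy receives Poisson(k) substitution
  events, each a transition with probability κ/(κ+2) (κ = 2 by
  default) — exactly the process the K2P distance inverts, so dating
  recovery is a calibrated end-to-end check. Per-copy k is fixed at
  `divergence_mean` or gamma-distributed around it; the within-family
  divergence distribution of real MITE families is not published, so
  mean and dispersion are free parameters. No indels are simulated;
  coverage and intactness are instead exercised by explicit truncation
  (one terminal TIR plus ≥ 10 bp, capped so truncated copies usually
  remain censusable).
* **Placement**: genes (2–4 exons, introns ≥ 500 bp) are placed ≥ 13 kb
  apart and ≥ 12 kb from chromosome ends — the latter so that every
  gene ± 5 kb region lies where the 10-kb-fragment midpoint distribution
  is exactly uniform, making the analytic-coverage convergence oracle
  exact. Insertion categories are drawn from weights defaulting to the
  published silkworm category layout (17/0/25/23/35% for
  5′-flank/exon/intron/3′-flank/intergenic; exon insertions, rare in
  real data, must be enabled explicitly). Margins keep each copy's
  midpoint category stable under the classifier, and flank corridors
  accept one insertion each so later insertions cannot push an earlier
  one past the 5-kb limit.
* **Structural unambiguity**: after placing an untruncated copy whose
  TIRs are mutation-free, the locus is re-scanned in a local window and
  the flanking background resampled (bounded rejection) until the
  planted candidate wins shadow resolution at its exact coordinates.
  This is what makes "recall = 1 with exact coordinates" a well-posed
  target even for palindromic TSDs, whose maximal inverted repeat
  genuinely extends through the duplication; without the guard, roughly
  8% of TA-flanked copies would be annotated one duplication-width wide.
  Planted masters are also resampled away from the simple-repeat filter
  rule (cover < 0.75) and from chance inward TIR extension.
* **Decoys**: one family per pseudo-element class — tandem-simple
  internal regions, an embedded `NNNNNNNN` run, and elements whose
  flanking 60-bp units are planted 22 further times (nested-in-repeat
  mimics) — all intergenic, all truth-labelled with `decoy_class`.

**What the simulations do not show.** The generator emulates the
statistical structure the pipeline assumes, not real genomes: no indel
divergence within families, no retrotransposon background, no nested
real elements, no assembly gaps apart from planted N-runs, uniform base
composition rather than isochore structure, and far smaller genomes
(60–300 kb in the tests) than the ~430 Mb assembly the original census
ran on. Passing recovery tests therefore demonstrates correctness of the
algorithms under their stated model, not that genome-scale counts on a
real assembly would match any published total; those depend on the
assembly and on unpublished internals of the original mining tool and
are deliberately not reproduction targets.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script — genomes of
60–300 kb, families of 7–150 copies, 5,000–50,000 null draws, ten seeds
for the recall/rejection sweeps — were chosen so that every stochastic
check sits comfortably inside its 3-standard-error band while the whole
suite stays desk-scale. The brute-force scan oracle is quadratic and is
run on windows ≤ 2 kb. Percentages reported in census tables round half
away from zero, matching the published table style. All stochastic
stages take explicit seeds and restore the caller's RNG state.

## Command-line interface

`inst/exec/mitescan` wraps the stages as subcommands (`simulate`,
`mine`, `filter`, `census`, `evolve`, `context`) with plain flags
mirroring the function arguments (e.g.
`mitescan mine --genome genome.fa --tir-min 8 --tir-max 50 ...`);
configuration is deliberately flag-based rather than file-based, the
flags being few and self-documenting. Every stochastic subcommand
requires `--seed`.

## Known limitations

* Center-star alignment is exact only relative to its center; for
  families near the 0.8 identity floor a progressive aligner could
  differ in gap placement.
* The miner's sensitivity to TIRs lacking any exact 8-word (possible
  above ~10% TIR divergence) is bounded by the seed requirement, as in
  any seeded search; the census, with its 12-word seeds on 200+ bp
  homology, is the stage meant to recover diverged copies.
* The median-joining implementation supports ε = 0 only and targets the
  small per-family haplotype sets this analysis produces (tens of
  haplotypes), not population-scale datasets.
* Secondary-structure free energies, database annotation of families,
  GO enrichment of neighbouring genes and expression-profile extraction
  are out of scope; of the germline analysis only the closed-form
  probability statistic is computed.
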