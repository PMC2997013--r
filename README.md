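# mitescan

Structure-based discovery and evolutionary analysis of **miniature
inverted-repeat transposable elements (MITEs)** in assembled genomes,
with a truth-labelled synthetic-genome simulator for end-to-end
validation.

MITEs are short (~100–600 bp), non-autonomous DNA transposons that occur
in high copy number, are AT-rich, and are recognisable purely from their
structure: a **terminal inverted repeat** (TIR, 8–50 bp) at each end and
an identical **target-site duplication** (TSD, 2–30 bp) immediately
flanking both ends. In the silkworm *Bombyx mori*, 17 such families
totalling 5,785 copies (~0.4% of the genome) have been described, most
of them inserted in or near genes. `mitescan` re-implements that entire
computational workflow as a tested, reusable R pipeline:

1. **Mining** — seed-and-extend scan for TIR+TSD structures
   (`scan_mite_candidates()`), all-pairs global-identity clustering into
   families (identity > 0.8, ≥ 3 members; `cluster_mite_families()`).
2. **Pseudo-element filtering** — N-containing, tandem-simple-repeat and
   nested-in-repeat artifacts flagged per member and filtered per family
   (`filter_mite_families()`).
3. **Copy census** — genome-wide homology search with a family
   representative (identity > 90%, coverage > 80%, both strands), each
   copy called *intact* (both complete TIRs) or *fragmentary*
   (`homology_search()`, `census_families()`), superfamily labels from
   TSD/TIR composition (`classify_superfamily()`).
4. **Family evolution** — center-star alignment and majority consensus;
   per-copy insertion ages from the Kimura two-parameter distance *k* to
   the consensus via **T = k / 2r** with r = 1.56×10⁻⁸
   substitutions/site/year; sliding-window nucleotide diversity π
   (20 bp windows, ±2 SD conserved/variable calls); median-joining
   haplotype networks with a star-topology statistic separating recent
   bursts from old expansions.
5. **Genomic context** — midpoint classification of every copy into
   exon / intron / 5′-flank / 3′-flank (< 5 kb) / intergenic, a
   randomised 10-kb-fragment-midpoint null, χ² tests for chromosomal
   distribution and in-gene enrichment, per-Mb density correlation, and
   the germline-silencing probability P = (1 − expressed/total)ⁿ.
6. **Simulation** — `simulate_genome()` plants families with chosen TIR,
   TSD motif, copy number, divergence and truncation fraction among gene
   models on an AT-matched background, and `add_decoys()` plants the
   three pseudo-element classes; every element is truth-labelled.

All functions take and return tibbles, so stages chain with the pipe;
`tidy()`/`glance()` methods and `plot_*()`/`autoplot()` functions cover
the result objects. A thin CLI (`inst/exec/mitescan`) exposes the stages
as subcommands.

## Worked example

```r
library(mitescan)

sim <- simulate_genome(example_family_specs(n_copies = c(20, 10, 10)),
                       genome_length = 150000, gene_density = 25, seed = 1)
sim
#> <mite_simulation> 1 chromosome(s), 162520 bp; 4 genes; 40 planted elements (0 decoys)

cand <- scan_mite_candidates(sim$genome)
fams <- cluster_mite_families(cand)
fams[, c("family_id", "n_members", "tir_len", "tsd")]
#> # A tibble: 3 × 4
#>   family_id n_members tir_len tsd
#>   <chr>         <int>   <int> <chr>
#> 1 FAM001           10      15 ACTACACG
#> 2 FAM002           20      20 TA
#> 3 FAM003           10      19 ATT

copies <- census_families(fams, sim$genome)
table(copies$family_id, copies$intact)
#>          TRUE
#>   FAM001   10
#>   FAM002   20
#>   FAM003   10

ctx <- classify_insertions(copies, sim$genes)
nul <- simulate_null(sim$genome, sim$genes, n = 5000, seed = 2)
enrichment_test(ctx, nul)
#> <in-gene enrichment, observed vs null (2x2)>
#>   X-squared = 0.79136, df = 1, p = 0.374
```

Every planted copy is recovered (the three family sizes match the
planted 20/10/10), all copies are intact as planted, and — because the
simulator places insertions at the genome-wide category rates rather
than preferentially near genes — the observed-vs-null enrichment test is
properly non-significant here.

The published silkworm tables ship as fixtures:

```r
table_consistency_report()$totals
#> # A tibble: 1 × 4
#>   total_copies n_intact n_fragmentary gene_region_pct
#>          <int>    <int>         <int>           <int>
#> 1         5785     3337          2448              66
germline_silencing_prob()
#> [1] 0.0002397675
```

5,785 census copies split into 3,337 intact and 2,448 fragmentary; 66%
of copies lie in gene regions; the probability that the five genes
nearest the piRNA-carrying family are all germline-silent by chance is
about 2.4×10⁻⁴.

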