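test_that("an exact planted copy is found with identity and coverage 1", {
  rep <- rand_dna(250, 33)
  g <- paste0(rand_dna(3000, 34), rep, rand_dna(3000, 35))
  hits <- homology_search(as_genome(g), rep)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
  expect_equal(hits$start, 3000L)
  expect_equal(hits$end, 3250L)
  expect_equal(hits$strand, "+")
})

test_that("reverse-strand copies are found with forward coordinates", {
  rep <- rand_dna(250, 36)
  g <- paste0(rand_dna(2000, 37), revcomp(rep), rand_dna(2000, 38))
  hits <- homology_search(as_genome(g), rep)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 2000L)
  expect_equal(hits$end, 2250L)
})

test_that("identity and coverage thresholds drop diverged/truncated copies", {
  rep <- rand_dna(300, 39)
  # 15% mutated copy: global identity below 0.90 (alignment oracle)
  set.seed(40)
  mut <- strsplit(rep, "")[[1]]
  sites <- sample(300, 45)
  mut[sites] <- vapply(mut[sites], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  mut <- paste(mut, collapse = "")
  expect_lt(pairwise_identity(rep, mut), 0.90)
  g <- paste0(rand_dna(1500, 41), mut, rand_dna(1500, 42))
  expect_equal(nrow(homology_search(as_genome(g), rep)), 0L)

  # 70% truncation: coverage 0.70 < 0.80
  tr <- substr(rep, 1, 210)
  g2 <- paste0(rand_dna(1500, 43), tr, rand_dna(1500, 44))
  expect_equal(nrow(homology_search(as_genome(g2), rep)), 0L)
})

test_that("intact calling follows the TIR-span rule", {
  tir <- "TGAGTCGACTATTATCAAAG"
  rep <- paste0(tir, rand_dna(238, 45), revcomp(tir))
  # exact full-length copy: intact
  g <- paste0(rand_dna(1000, 46), rep, rand_dna(1000, 47))
  h <- homology_search(as_genome(g), rep, tir_len = 20L)
  expect_true(h$intact)
  # copy missing the last 30 bp (3' TIR gone, coverage ~0.89): fragmentary
  g2 <- paste0(rand_dna(1000, 48), substr(rep, 1, 248), rand_dna(1000, 49))
  h2 <- homology_search(as_genome(g2), rep, tir_len = 20L)
  expect_equal(nrow(h2), 1L)
  expect_gt(h2$coverage, 0.80)
  expect_false(h2$intact)
})

test_that("census recovers planted intact fractions under truncation", {
  specs <- family_spec("tf", "TGAGTCGACTATTATCAAAG", "TA", n_copies = 100,
                       internal_length = 238, divergence_mean = 0.005,
                       truncation_fraction = 0.3)
  sim <- simulate_genome(specs, genome_length = 250000, gene_density = 0,
                         seed = 19)
  fams <- families_from_truth(sim)
  intact_idx <- which(sim$truth$intact)[1]
  rep_seq <- substr(sim$genome$seq[1], sim$truth$start[intact_idx] + 1,
                    sim$truth$end[intact_idx])
  copies <- homology_search(sim$genome, rep_seq, tir_len = 20L)
  expect_equal(nrow(copies), 100L)
  frac <- mean(copies$intact)
  p <- mean(sim$truth$intact)
  se <- sqrt(0.3 * 0.7 / 100)
  expect_lt(abs(frac - 0.7), 3 * se)
  expect_equal(sum(copies$intact), sum(sim$truth$intact))
})

test_that("copy-number recall and precision hold at moderate divergence", {
  # divergence here is copy-to-representative (about twice the per-copy
  # divergence from the family master)
  for (sd in c(83, 84)) {
    specs <- example_family_specs(n_copies = c(15, 8, 8),
                                  divergence_mean = 0.02)
    sim <- simulate_genome(specs, genome_length = 90000, gene_density = 0,
                           seed = sd)
    fams <- families_from_truth(sim)
    copies <- census_families(fams, sim$genome)
    tr <- sim$truth
    found <- mapply(function(s, e, ch) {
      any(copies$chrom == ch &
            pmin(copies$end, e) - pmax(copies$start, s) > 0.5 * (e - s))
    }, tr$start, tr$end, tr$chrom)
    prec <- mapply(function(s, e, ch) {
      any(tr$chrom == ch &
            pmin(tr$end, e) - pmax(tr$start, s) > 0.5 * (e - s))
    }, copies$start, copies$end, copies$chrom)
    expect_gte(mean(found), 0.98)
    expect_gte(mean(prec), 0.98)
  }
})

test_that("census counts are invariant under reverse-complementing the genome", {
  specs <- example_family_specs(n_copies = c(8, 5, 5),
                                divergence_mean = 0.01)
  sim <- simulate_genome(specs, genome_length = 70000, gene_density = 0,
                         seed = 87)
  fams <- families_from_truth(sim)
  fwd <- census_families(fams, sim$genome)
  rcg <- sim$genome
  rcg$seq <- revcomp(rcg$seq)
  rev <- census_families(fams, rcg)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(dplyr::count(rev, .data$family_id)$n,
               dplyr::count(fwd, .data$family_id)$n)
  expect_equal(sum(rev$intact), sum(fwd$intact))
  # coordinates mirror
  expect_setequal(rcg$length[match(rev$chrom, rcg$chrom)] - rev$end,
                  fwd$start)
})

test_that("intact plus fragmentary equals total in the census summary", {
  specs <- example_family_specs(n_copies = c(10, 6, 6),
                                truncation_fraction = 0.3)
  sim <- simulate_genome(specs, genome_length = 80000, gene_density = 0,
                         seed = 89)
  fams <- families_from_truth(sim)
  fams$tir_len <- nchar(example_family_specs()$tir)[
    match(fams$family_id, example_family_specs()$family_id)]
  copies <- census_families(fams, sim$genome)
  summ <- census_summary(copies, fams, sim$genome)
  expect_equal(summ$n_total, summ$n_intact + summ$n_fragmentary)
  expect_equal(summ$full_length_pct,
               full_length_pct(summ$n_fragmentary, summ$n_intact))
})

test_that("superfamily classification follows the TSD/TIR rules", {
  expect_equal(classify_superfamily("TA", "GATATGTGTCGTTCG")$label,
               "Stowaway-like")
  expect_equal(classify_superfamily("TWA", "GGGTCAATTCCC")$label,
               "Tourist-like")
  expect_equal(classify_superfamily("TAA", "GGGTCAATTCCC")$label,
               "Tourist-like")  # concrete instance of TWA
  expect_equal(classify_superfamily("TDA", "TGCTGGAACC")$label,
               "Tourist-like")
  expect_equal(classify_superfamily("ATATAT", "GTGGGATT")$label, "novel")
  expect_equal(classify_superfamily("ATT", "GGTAGTTTTCC")$label, "novel")
  # 8-bp nonspecific TSD + TIR head near CAGTGGCGGAT: Pegasus-like
  expect_equal(classify_superfamily("NNNNNNNN", "CAAGGGCGGATCCAG")$label,
               "Pegasus-like")
  expect_equal(classify_superfamily("NNNNNNNN", "CAGTGGCGTACCTA")$label,
               "Pegasus-like")
  # 8-bp TSD but unrelated TIR: novel
  expect_equal(classify_superfamily("NNNNNNNN", "TTTTACGATCGGA")$label,
               "novel")
})

test_that("degenerate TSD motifs are reconstructed from instances", {
  expect_equal(tsd_motif_consensus(c("TA", "TA", "TA")), "TA")
  expect_equal(tsd_motif_consensus(c("TAA", "TTA", "TAA")), "TWA")
  expect_equal(tsd_motif_consensus(c("TAA", "TGA", "TTA")), "TDA")
  expect_equal(tsd_motif_consensus(c("ACGTACGT", "CGTACGTA", "GTACGTAC",
                                     "TACGTACG")),
               "NNNNNNNN")
})

test_that("representative length bounds are enforced", {
  expect_error(homology_search(as_genome(rand_dna(1000, 90)),
                               rand_dna(80, 91)),
               class = "mitescan_parameter_error")
})
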