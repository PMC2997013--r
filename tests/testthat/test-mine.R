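test_that("a homogeneous sequence yields no candidates", {
  expect_equal(nrow(scan_mite_candidates(as_genome(strrep("A", 5000)))), 0L)
  expect_equal(nrow(scan_mite_candidates(as_genome("ACGT"))), 0L)
})

test_that("a planted element is recovered at exact coordinates", {
  # single zero-divergence copy planted by the generator (which
  # guarantees local structural unambiguity), TIR/TSD of a TA family
  spec <- family_spec("one", "TGAGTCGACTATTATCAAAG", "TA", n_copies = 1,
                      internal_length = 238)
  sim <- simulate_genome(spec, genome_length = 5000, gene_density = 0,
                         seed = 7)
  cand <- scan_mite_candidates(sim$genome)
  tr <- sim$truth
  hit <- cand[cand$start == tr$start & cand$end == tr$end, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$tsd, "TA")
  expect_equal(hit$tir_len, 20L)
  expect_equal(hit$tir_mismatches, 0L)
  expect_identical(hit$tir3, revcomp(hit$tir5))
})

test_that("elements longer than 600 bp are not reported", {
  tir <- "TGAGTCGACTATTATCAAAG"
  internal <- rand_dna(700 - 40, 55)
  elem <- paste0(tir, internal, revcomp(tir))
  g <- paste0(rand_dna(800, 56), "TA", elem, "TA", rand_dna(800, 57))
  cand <- scan_mite_candidates(as_genome(g))
  expect_false(any(cand$end - cand$start == 700))
})

test_that("scanner equals the exhaustive brute-force oracle on short sequences", {
  # window with a planted element
  spec <- family_spec("one", "GGTAGTTTTCCAATTACAG", "ATT", n_copies = 1,
                      internal_length = 380)
  sim <- simulate_genome(spec, genome_length = 2000, gene_density = 0,
                         seed = 13)
  got <- scan_mite_candidates(sim$genome)
  got$chrom <- "w"
  want <- brute_force_scan(sim$genome$seq)
  expect_equal(as.data.frame(got), as.data.frame(want))
  expect_true(nrow(got) >= 1)

  # plain random windows (usually containing chance candidates)
  for (sd in c(71, 72)) {
    seqstr <- rand_dna(700, sd)
    got <- scan_mite_candidates(as_genome(seqstr))
    got$chrom <- "w"
    expect_equal(as.data.frame(got),
                 as.data.frame(brute_force_scan(seqstr)))
  }
})

test_that("homopolymer TSDs extending into a base run are rejected", {
  # element flanked by "AA" but embedded in a longer A-run on one side
  tir <- "TGAGTCGACTATTATCAAAG"
  internal <- rand_dna(160, 91)
  elem <- paste0(tir, internal, revcomp(tir))
  left <- sub("A+$", "CG", rand_dna(300, 92))
  right <- sub("^A+", "GC", rand_dna(300, 93))
  with_run <- paste0(left, "AAA", elem, "AA", right)   # run extends left TSD
  cand <- scan_mite_candidates(as_genome(with_run))
  s <- nchar(left) + 3
  expect_false(any(cand$start == s & cand$tsd == "AA"))
})

test_that("relaxing the TIR mismatch budget never shrinks the raw candidate set", {
  for (sd in c(81, 82)) {
    seqstr <- rand_dna(4000, sd)
    p_strict <- default_scan_params(); p_strict$max_tir_mismatch <- 0
    p_loose <- default_scan_params(); p_loose$max_tir_mismatch <- 0.15
    strict <- scan_mite_candidates(as_genome(seqstr), p_strict,
                                   resolve = FALSE)
    loose <- scan_mite_candidates(as_genome(seqstr), p_loose,
                                  resolve = FALSE)
    key <- function(x) paste(x$start, x$end)
    expect_true(all(key(strict) %in% key(loose)))
    idx <- match(key(strict), key(loose))
    expect_true(all(loose$tir_len[idx] >= strict$tir_len))
  }
})

test_that("pairwise identity follows the stated alignment scoring", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  # one 2-bp deletion: 8 matches over 10 columns
  expect_equal(pairwise_identity("ACGTACGTAA", "ACGTGTAA"), 0.8)
  expect_error(pairwise_identity("", "ACGT"),
               class = "mitescan_undefined_input")
})

test_that("families need at least 3 members and follow single linkage", {
  base <- rand_dna(200, 61)
  mut <- function(s, pos) {
    substr(s, pos, pos) <- "A"
    s
  }
  cand <- tibble::tibble(
    chrom = "c1", start = seq(0, 1000, length.out = 6)[1:6] * 1L,
    end = 0L, tir_len = 10L, tsd_len = 2L, tir5 = "x", tir3 = "x",
    tsd = "TA", tir_mismatches = 0L,
    seq = c(base, mut(base, 11), mut(base, 51), mut(base, 91),
            mut(base, 131), rand_dna(200, 62)))
  cand$end <- cand$start + 200L
  fams <- cluster_mite_families(cand)
  expect_equal(nrow(fams), 1L)
  expect_equal(fams$n_members, 5L)

  # two identical candidates only: below the member threshold
  fams2 <- cluster_mite_families(cand[1:2, ])
  expect_equal(nrow(fams2), 0L)

  # three identical copies form a family
  cand3 <- cand[c(1, 1, 1), ]
  cand3$start <- c(0L, 500L, 1000L)
  cand3$end <- cand3$start + 200L
  expect_equal(cluster_mite_families(cand3)$n_members, 3L)
})

test_that("clustering agrees with an all-pairs identity-matrix oracle", {
  sim <- simulate_genome(example_family_specs(n_copies = c(6, 4, 4),
                                              divergence_mean = 0.02),
                         genome_length = 60000, gene_density = 0, seed = 55)
  cand <- scan_mite_candidates(sim$genome)
  fams <- cluster_mite_families(cand)

  # oracle: explicit identity matrix + connected components (igraph)
  n <- nrow(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <-
        pairwise_identity(cand$seq[i], cand$seq[j]) > 0.8
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  big <- table(comp)
  want_sizes <- sort(as.integer(big[big >= 3]))
  expect_equal(sort(fams$n_members), want_sizes)

  # representative is a member with length closest to the family median
  for (i in seq_len(nrow(fams))) {
    mem <- fams$members[[i]]
    med <- stats::median(nchar(mem$seq))
    expect_equal(abs(nchar(fams$representative[i]) - med),
                 min(abs(nchar(mem$seq) - med)))
  }
})

test_that("zero-divergence planted families are recovered completely", {
  specs <- example_family_specs(n_copies = c(12, 6, 6))
  sim <- simulate_genome(specs, genome_length = 120000, seed = 77)
  cand <- scan_mite_candidates(sim$genome)
  tr <- sim$truth
  found <- mapply(function(s, e) any(cand$start == s & cand$end == e),
                  tr$start, tr$end)
  expect_equal(mean(found), 1)
  fams <- cluster_mite_families(cand)
  expect_equal(nrow(fams), 3L)
  expect_equal(sort(fams$n_members), c(6L, 6L, 12L))
})
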