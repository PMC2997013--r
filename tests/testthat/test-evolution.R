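test_that("identical members align without gaps", {
  aln <- align_family(rep("ACGTACGTGG", 3))
  expect_equal(aln$rows, rep("ACGTACGTGG", 3))
  expect_equal(consensus_sequence(aln), "ACGTACGTGG")
})

test_that("a substitution appears as one polymorphic column", {
  aln <- align_family(c("ACGTACGT", "ACGTACGT", "ACGAACGT"))
  m <- do.call(rbind, strsplit(aln$rows, ""))
  poly <- which(apply(m, 2, function(c) length(unique(c)) > 1))
  expect_equal(poly, 4L)
})

test_that("a deletion puts gap columns in that row only", {
  aln <- align_family(c("ACGTACGTAA", "ACGTACGTAA", "ACGTGTAA"))
  expect_equal(aln$rows[3], "ACGT--GTAA")
  expect_equal(aln$rows[1], "ACGTACGTAA")
})

test_that("an insertion relative to the center pads other rows with gaps", {
  aln <- align_family(c("ACGTACGT", "ACGTTTACGT", "ACGTACGT"))
  expect_equal(nchar(aln$rows[1]), 10L)
  expect_equal(sum(strsplit(aln$rows[1], "")[[1]] == "-"), 2L)
  expect_equal(sum(strsplit(aln$rows[2], "")[[1]] == "-"), 0L)
})

test_that("consensus majority, tie and gap-majority rules hold", {
  aln <- structure(list(rows = c("AAC-", "AAC-", "CCCA"),
                        ids = c("a", "b", "c"),
                        col_ref = c(1L, 2L, 3L, 4L)),
                   class = "mite_alignment")
  # col1 A,A,C -> A; col2 A,A,C -> A; col3 C -> C; col4 -,-,A -> omitted
  expect_equal(consensus_sequence(aln), "AAC")
  aln2 <- structure(list(rows = c("A", "A", "C", "C"), ids = letters[1:4],
                         col_ref = 1L), class = "mite_alignment")
  expect_equal(consensus_sequence(aln2), "A")  # tie -> alphabetical
})

test_that("K2P distance matches the closed form and errors on saturation", {
  expect_equal(k2p_distance("GATTACA", "GATTACA"), 0)
  expect_equal(k2p_distance("GATTACA", "GACTACA"), -0.5 * log(5 / 7),
               tolerance = 1e-12)
  expect_equal(round(k2p_distance("GATTACA", "GACTACA"), 6), 0.168236)
  expect_error(k2p_distance("AAAA", "CCAA"),
               class = "mitescan_saturation_error")
  expect_error(k2p_distance("----", "AAAA"),
               class = "mitescan_undefined_input")
  expect_error(k2p_distance("AA", "AAA"), class = "mitescan_undefined_input")
  # symmetry
  a <- rand_dna(200, 21); b <- mutate_sequence(a, 0.05)$seq
  expect_equal(k2p_distance(a, b), k2p_distance(b, a))
})

test_that("K2P agrees with the ape reference implementation", {
  set.seed(99)
  for (i in 1:5) {
    a <- rand_dna(300, 100 + i)
    b <- mutate_sequence(a, 0.06)$seq
    bin <- ape::as.DNAbin(t(sapply(strsplit(c(a, b), ""), identity)))
    want <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(k2p_distance(a, b), want, tolerance = 1e-10)
  }
})

test_that("K2P reduces to the p-distance for small divergence", {
  a <- strrep("ACGT", 250)
  b <- paste0("G", substr(a, 2, 500), "A", substr(a, 502, 1000))
  chars_a <- strsplit(a, "")[[1]]; chars_b <- strsplit(b, "")[[1]]
  p <- mean(chars_a != chars_b)
  expect_lte(p, 0.01)
  expect_equal(k2p_distance(a, b), p, tolerance = 1e-3)
})

test_that("insertion ages follow T = k / 2r", {
  expect_equal(insertion_age(0), 0)
  expect_equal(insertion_age(0.0312), 1e6)
  expect_equal(insertion_age(0.1248), 4e6)
  expect_equal(insertion_age(0.0312, rate = 3.12e-8), 5e5)
  expect_error(insertion_age(0.1, rate = 0),
               class = "mitescan_parameter_error")
  expect_error(insertion_age(-0.1), class = "mitescan_parameter_error")
})

test_that("planted divergence is recovered through consensus ages", {
  specs <- family_spec("age", "TGAGTCGACTATTATCAAAG", "TA", n_copies = 120,
                       internal_length = 238, divergence_mean = 0.0312)
  sim <- simulate_genome(specs, genome_length = 250000, gene_density = 0,
                         seed = 3)
  seqs <- substring(sim$genome$seq[1], sim$truth$start + 1, sim$truth$end)
  aln <- align_family(seqs)
  ages <- family_ages(aln)
  se <- stats::sd(ages$k) / sqrt(nrow(ages))
  expect_lt(abs(mean(ages$k) - 0.0312), 3 * se)
  expect_lt(abs(mean(ages$t_my) - 1.0), 3 * se / (2 * 1.56e-8) / 1e6)
})

test_that("sliding pi handles the documented small cases", {
  # 4 identical rows: all windows 0, sd 0, all intermediate
  aln <- align_family(rep(strrep("ACGT", 10), 4))
  dp <- sliding_pi(aln)
  expect_equal(dp$windows$pi, c(0, 0))
  expect_equal(dp$sd_pi, 0)
  expect_true(all(dp$windows$class == "intermediate"))

  # 2 rows, one mismatch in window 1 of a 40-column alignment
  a <- strrep("ACGT", 10)
  b <- paste0("T", substr(a, 2, 40))
  dp2 <- sliding_pi(align_family(c(a, b)))
  expect_equal(dp2$windows$pi, c(0.05, 0))

  # 3 rows, one row differs at one site: mean of pairwise {1,1,0}/20
  c3 <- c(a, a, b)
  dp3 <- sliding_pi(align_family(c3))
  expect_equal(dp3$windows$pi[1], (2 / 3) / 20, tolerance = 1e-12)
})

test_that("pi is invariant under row order and set duplication", {
  set.seed(51)
  rows <- vapply(1:6, function(i) mutate_sequence(strrep("ACGT", 15),
                                                  0.05)$seq, character(1))
  dp <- sliding_pi(align_family(rows, representative = rows[1]))
  dp_perm <- sliding_pi(align_family(rev(rows), representative = rows[1]))
  expect_equal(sort(dp$windows$pi), sort(dp_perm$windows$pi))
  # duplicating the set leaves the frequency-weighted diversity
  # pi * (n-1)/n unchanged (the pairwise mean itself carries the n/(n-1)
  # small-sample factor)
  dp_dup <- sliding_pi(align_family(c(rows, rows),
                                    representative = rows[1]))
  n <- length(rows)
  expect_equal(dp_dup$windows$pi * (2 * n - 1) / (2 * n),
               dp$windows$pi * (n - 1) / n, tolerance = 1e-12)
})

test_that("trailing partial windows are dropped", {
  aln <- align_family(rep(strrep("ACGT", 12) , 3))  # 48 columns
  dp <- sliding_pi(aln)
  expect_equal(nrow(dp$windows), 2L)
  expect_equal(max(dp$windows$end), 40)
})

test_that("haplotype condensation and simple network topologies", {
  net <- mj_network(rep("AAAAAAAA", 10))
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(net$nodes$multiplicity, 10L)
  expect_equal(nrow(net$edges), 0L)

  # star: dominant ancestor plus two singleton derivatives
  h0 <- strrep("A", 12)
  ha <- paste0("C", substr(h0, 2, 12))
  hb <- paste0(substr(h0, 1, 11), "G")
  net2 <- mj_network(c(rep(h0, 10), ha, hb))
  expect_equal(sum(net2$nodes$multiplicity), 12L)
  expect_equal(nrow(net2$edges), 2L)
  expect_true(all(net2$edges$distance == 1))
  center <- net2$nodes$node_id[net2$nodes$haplotype == h0]
  expect_true(all(center %in% c(net2$edges$from, net2$edges$to)))
  expect_equal(star_statistic(net2), 1)

  # path: serial accumulation of two mutations
  hab <- paste0("C", substr(h0, 2, 11), "G")
  net3 <- mj_network(c(h0, ha, hab))
  expect_equal(nrow(net3$edges), 2L)
  expect_true(all(net3$edges$distance == 1))
  deg <- table(c(net3$edges$from, net3$edges$to))
  mid <- net3$nodes$node_id[net3$nodes$haplotype == ha]
  expect_equal(unname(deg[as.character(mid)]), 2L)
})

test_that("network multiplicities always sum to the input count", {
  for (sd in 1:4) {
    haps <- simulate_burst_haplotypes(n = 18, seed = sd)
    net <- mj_network(haps)
    expect_equal(sum(net$nodes$multiplicity), 18L)
  }
})

test_that("the network equals the MST on tree-like haplotype sets", {
  # tree-like: every internal node sampled, so no median vector helps;
  # oracle = igraph MST + exhaustive check that no triplet median
  # shortens the tree (Steiner check)
  h0 <- strrep("T", 16)
  mut_at <- function(h, i, b) {
    substr(h, i, i) <- b
    h
  }
  haps <- c(h0,
            mut_at(h0, 2, "A"), mut_at(mut_at(h0, 2, "A"), 5, "C"),
            mut_at(h0, 9, "G"), mut_at(mut_at(h0, 9, "G"), 13, "A"),
            mut_at(h0, 15, "C"))
  net <- mj_network(haps)
  expect_false(any(net$nodes$is_median))

  d <- outer(haps, haps, Vectorize(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }))
  g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                           mode = "undirected")
  mst <- igraph::mst(g)
  expect_equal(sum(net$edges$distance),
               sum(igraph::E(mst)$weight))
  expect_equal(nrow(net$edges), igraph::ecount(mst))

  # exhaustive Steiner check: no triplet median improves the MST
  cmb <- utils::combn(length(haps), 3)
  base_len <- sum(igraph::E(mst)$weight)
  for (z in seq_len(ncol(cmb))) {
    trio <- haps[cmb[, z]]
    med <- mitescan:::median_vector(trio[1], trio[2], trio[3])
    all_h <- unique(c(haps, med))
    d2 <- outer(all_h, all_h, Vectorize(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }))
    g2 <- igraph::graph_from_adjacency_matrix(d2, weighted = TRUE,
                                              mode = "undirected")
    expect_gte(sum(igraph::E(igraph::mst(g2))$weight), base_len)
  }
})

test_that("median vectors reconstruct an unsampled ancestor", {
  # three copies, each with one private mutation: the ancestor is the
  # Steiner point (3 edges of length 1 instead of 2 edges of length 2)
  h0 <- strrep("G", 14)
  mut_at <- function(h, i, b) { substr(h, i, i) <- b; h }
  haps <- c(mut_at(h0, 2, "A"), mut_at(h0, 6, "T"), mut_at(h0, 11, "C"))
  net <- mj_network(haps)
  expect_equal(sum(net$nodes$is_median), 1L)
  expect_equal(net$nodes$haplotype[net$nodes$is_median], h0)
  expect_equal(sum(net$edges$distance), 3L)
})

test_that("star statistic separates recent bursts from old expansions", {
  burst <- star_statistic(mj_network(simulate_burst_haplotypes(seed = 2)))
  old <- star_statistic(
    mj_network(simulate_old_expansion_haplotypes(seed = 2)))
  expect_gte(burst, 0.9)
  expect_lte(old, 0.5)
})

test_that("network construction is input-order independent", {
  haps <- simulate_burst_haplotypes(n = 15, seed = 8)
  n1 <- mj_network(haps)
  n2 <- mj_network(rev(haps))
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
})
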