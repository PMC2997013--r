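mk_gene <- function(gene_id, chrom, start, end, strand,
                    exons = tibble::tibble(start = start, end = end)) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start,
                 end = end, strand = strand, exons = list(exons))
}

test_that("midpoint classification covers exon, intron, flank, intergenic", {
  g1 <- mk_gene("g1", "c1", 10000L, 12000L, "+")
  cp <- tibble::tibble(chrom = "c1", start = 10500L, end = 10700L)
  ctx <- classify_insertions(cp, g1)
  expect_equal(as.character(ctx$category), "exon")
  expect_equal(ctx$distance, 0L)

  g2 <- mk_gene("g1", "c1", 10000L, 12000L, "+",
                exons = tibble::tibble(start = c(10000L, 11500L),
                                       end = c(10400L, 12000L)))
  ctx2 <- classify_insertions(cp, g2)
  expect_equal(as.character(ctx2$category), "intron")

  cp3 <- tibble::tibble(chrom = "c1", start = 6100L, end = 6200L)
  ctx3 <- classify_insertions(cp3, g2)       # midpoint 6150, gene at 10000
  expect_equal(as.character(ctx3$category), "flank5")
  expect_equal(ctx3$distance, 3850L)

  cp4 <- tibble::tibble(chrom = "c1", start = 100L, end = 200L)
  expect_equal(as.character(classify_insertions(cp4, g2)$category),
               "intergenic")

  # negative strand flips flank sides
  g3 <- mk_gene("g1", "c1", 10000L, 12000L, "-")
  expect_equal(as.character(classify_insertions(cp3, g3)$category),
               "flank3")

  # unannotated chromosome: intergenic with a warning
  cp5 <- tibble::tibble(chrom = "c9", start = 100L, end = 200L)
  expect_warning(ctx5 <- classify_insertions(cp5, g2), "c9")
  expect_equal(as.character(ctx5$category), "intergenic")
})

test_that("classification matches generator truth labels exactly", {
  sim <- simulate_genome(example_family_specs(n_copies = c(20, 10, 10)),
                         genome_length = 180000, gene_density = 25,
                         seed = 14)
  ctx <- classify_insertions(sim$truth, sim$genes)
  expect_equal(as.character(ctx$category), sim$truth$category_truth)
})

test_that("flank bins are half-open with an inclusive lowest bin", {
  g <- mk_gene("g1", "c1", 100000L, 105000L, "+")
  mk_ctx <- function(d) {
    tibble::tibble(chrom = "c1", start = 100000L - d, end = 100000L - d,
                   category = factor("flank5", levels = mitescan:::CATEGORY_LEVELS),
                   nearest_gene = "g1", distance = d)
  }
  ctx <- dplyr::bind_rows(mk_ctx(500L), mk_ctx(501L), mk_ctx(3850L),
                          mk_ctx(3000L))
  fb <- flank_bins(ctx)
  get <- function(bin) fb$n[fb$category == "flank5" & fb$bin == bin]
  expect_equal(get("<=500"), 1L)
  expect_equal(get("500-3000"), 2L)
  expect_equal(get("3000-5000"), 1L)
  # empty input: zero-filled grid
  fb0 <- flank_bins(ctx[0, ])
  expect_true(all(fb0$n == 0L))
  expect_equal(nrow(fb0), 6L)
})

test_that("chromosome distribution test matches hand-computed values", {
  r0 <- chrom_distribution_test(c(10, 10), c(1e6, 1e6))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 1)

  r1 <- chrom_distribution_test(c(20, 10), c(1e6, 1e6))
  expect_equal(r1$statistic, 10 / 3, tolerance = 1e-6)
  expect_equal(r1$p_value, stats::pchisq(10 / 3, 1, lower.tail = FALSE))

  r28 <- chrom_distribution_test(rep(10, 28), rep(1e6, 28))
  expect_equal(r28$df, 27)

  expect_error(chrom_distribution_test(c(1, 2), c(0, 1e6)),
               class = "mitescan_parameter_error")
})

test_that("chi-square statistic is invariant under relabeling and scales with n", {
  counts <- c(30, 10, 25, 50)
  lens <- c(2e6, 1e6, 1.5e6, 3e6)
  a <- chrom_distribution_test(counts, lens)
  perm <- c(3, 1, 4, 2)
  b <- chrom_distribution_test(counts[perm], lens[perm])
  expect_equal(a$statistic, b$statistic)
  c2 <- chrom_distribution_test(counts * 3, lens)
  expect_equal(c2$statistic, a$statistic * 3, tolerance = 1e-12)
})

test_that("null simulation is seed-reproducible and converges to coverage", {
  sim <- simulate_genome(example_family_specs(n_copies = c(5, 3, 3)),
                         genome_length = 150000, gene_density = 25,
                         seed = 26)
  n1 <- simulate_null(sim$genome, sim$genes, n = 2000, seed = 5)
  n2 <- simulate_null(sim$genome, sim$genes, n = 2000, seed = 5)
  expect_identical(n1$category_fractions, n2$category_fractions)
  expect_equal(sum(n1$category_fractions), 1)

  # analytic gene +/- flank coverage (interval union oracle)
  g <- sim$genes
  iv <- cbind(pmax(0, g$start - 5000), pmin(sim$genome$length, g$end + 5000))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; cur <- c(-1, -1)
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] > cur[2]) {
      tot <- tot + max(0, cur[2] - cur[1]); cur <- iv[i, ]
    } else cur[2] <- max(cur[2], iv[i, 2])
  }
  tot <- tot + max(0, cur[2] - cur[1])
  cover <- tot / sum(sim$genome$length)

  n3 <- simulate_null(sim$genome, sim$genes, n = 20000, seed = 6)
  se <- sqrt(cover * (1 - cover) / 20000)
  expect_lt(abs(n3$in_gene_fraction - cover), 3 * se + 0.003)
})

test_that("enrichment test reproduces the textbook 2x2 chi-square", {
  e0 <- enrichment_test(c(50, 50), c(50, 50))
  expect_equal(e0$statistic, 0)

  e1 <- enrichment_test(c(66, 34), c(39, 61))
  # textbook formula: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  want <- 200 * (66 * 61 - 34 * 39)^2 / (100 * 100 * 105 * 95)
  expect_equal(e1$statistic, want, tolerance = 1e-10)
  expect_lt(e1$p_value, 2e-4)
  expect_equal(e1$df, 1)

  # identical proportions at different n
  e2 <- enrichment_test(c(40, 60), c(80, 120))
  expect_equal(e2$statistic, 0, tolerance = 1e-12)
})

test_that("density correlation reports r^2 and df = n - 2", {
  lens <- rep(1e6, 28)
  genes <- seq(100, 370, by = 10)
  mites <- genes * 3
  r <- density_correlation(mites, genes, lens)
  expect_equal(r$r_squared, 1)
  expect_equal(r$df, 26)

  # exactly orthogonal density vectors: r^2 = 0 by construction
  xo <- c(rep(1, 14), rep(3, 14)) * 100
  yo <- rep(c(10, 20), 14)  # cor(xo, yo) == 0 by construction
  r3 <- density_correlation(xo, yo, lens)
  expect_lt(r3$r_squared, 1e-20)

  expect_error(density_correlation(rep(5, 28), genes, lens),
               class = "mitescan_undefined_input")
})

test_that("germline silencing probability matches the closed form", {
  expect_equal(germline_silencing_prob(8431, 10393, 5),
               (1 - 8431 / 10393)^5)
  expect_equal(germline_silencing_prob(10, 10, 3), 0)
  expect_equal(germline_silencing_prob(0, 10, 3), 1)
  expect_error(germline_silencing_prob(5, 0, 1),
               class = "mitescan_parameter_error")
})

test_that("per-family category counts sum to the family totals", {
  sim <- simulate_genome(example_family_specs(n_copies = c(15, 8, 8)),
                         genome_length = 150000, gene_density = 25,
                         seed = 33)
  ctx <- classify_insertions(
    dplyr::mutate(sim$truth, family_id = .data$family_id), sim$genes)
  tab <- as.data.frame.matrix(table(ctx$family_id, ctx$category))
  expect_equal(unname(rowSums(tab)),
               as.vector(table(sim$truth$family_id)[rownames(tab)]))
})
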