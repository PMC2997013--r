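# Genomic context of MITE copies: midpoint-based insertion-site
# classification against gene models, flank distance bins, chromosome
# distribution and enrichment chi-square tests, density correlation, and
# the germline-silencing probability statistic.

CATEGORY_LEVELS <- c("flank5", "exon", "intron", "flank3", "intergenic")

# classify one midpoint on one chromosome against its gene table
classify_midpoint <- function(mid, genes, flank_limit) {
  inside <- which(genes$start <= mid & mid < genes$end)
  if (length(inside) > 0) {
    g <- genes[inside[1], ]
    ex <- g$exons[[1]]
    in_exon <- any(ex$start <= mid & mid < ex$end)
    return(list(category = if (in_exon) "exon" else "intron",
                nearest_gene = g$gene_id, distance = 0L))
  }
  if (nrow(genes) == 0) {
    return(list(category = "intergenic", nearest_gene = NA_character_,
                distance = NA_integer_))
  }
  # distance to each gene span (0 if overlapping, handled above)
  d_left <- genes$start - mid   # positive when gene is to the right
  d_right <- mid - genes$end + 1L  # positive when gene is to the left
  dist <- pmax(d_left, d_right)
  near <- which(dist > 0 & dist <= flank_limit)
  if (length(near) == 0) {
    return(list(category = "intergenic", nearest_gene = NA_character_,
                distance = NA_integer_))
  }
  # nearest gene; exact tie -> the one giving a 5' flank (documented)
  near <- near[order(dist[near])]
  best_d <- dist[near[1]]
  tied <- near[dist[near] == best_d]
  side_of <- function(gi) {
    gene_right <- genes$start[gi] > mid
    if (genes$strand[gi] == "+") {
      if (gene_right) "flank5" else "flank3"
    } else {
      if (gene_right) "flank3" else "flank5"
    }
  }
  sides <- vapply(tied, side_of, character(1))
  pick <- if (any(sides == "flank5")) tied[sides == "flank5"][1] else tied[1]
  list(category = side_of(pick), nearest_gene = genes$gene_id[pick],
       distance = as.integer(best_d))
}

#' Classify MITE copies by genomic context
#'
#' Each copy is assigned exactly one category from its midpoint: `exon`
#' when the midpoint overlaps an exon, `intron` when it overlaps a gene
#' but no exon, `flank5`/`flank3` when the nearest gene lies within
#' `flank_limit` (side determined by the gene's strand; exact distance
#' ties resolve to `flank5`), else `intergenic`. Copies on chromosomes
#' absent from the annotation are intergenic, with a warning.
#'
#' @param copies tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes gene tibble from [read_gene_gff3()] or
#'   [simulate_genome()].
#' @param flank_limit flank distance in bp (default 5000, the
#'   close-to-gene rule).
#' @return `copies` with `category`, `nearest_gene`, `distance` columns.
#' @export
classify_insertions <- function(copies, genes, flank_limit = 5000) {
  if (nrow(copies) == 0) {
    return(dplyr::mutate(copies, category = character(),
                         nearest_gene = character(), distance = integer()))
  }
  unknown <- setdiff(unique(copies$chrom), unique(genes$chrom))
  if (length(unknown) > 0 && nrow(genes) > 0) {
    warn(paste0("classify_insertions(): no gene annotation for ",
                paste(unknown, collapse = ", "),
                "; copies there are intergenic."))
  }
  mids <- (copies$start + copies$end) %/% 2L
  category <- character(nrow(copies))
  nearest <- rep(NA_character_, nrow(copies))
  distance <- rep(NA_integer_, nrow(copies))

  for (ch in unique(copies$chrom)) {
    rows <- which(copies$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    m <- mids[rows]
    if (nrow(g) == 0) {
      category[rows] <- "intergenic"
      next
    }
    g <- g[order(g$start), , drop = FALSE]
    overlapping <- nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])
    if (overlapping) {
      # rare general case: per-midpoint scan
      res <- purrr::map(m, classify_midpoint, genes = g,
                        flank_limit = flank_limit)
      category[rows] <- vapply(res, `[[`, character(1), "category")
      nearest[rows] <- vapply(res, `[[`, character(1), "nearest_gene")
      distance[rows] <- vapply(res, function(x) as.integer(x$distance),
                               integer(1))
      next
    }
    idx <- findInterval(m, g$start)            # last gene starting <= mid
    inside <- idx >= 1 & m < ifelse(idx >= 1, g$end[pmax(idx, 1)], NA)
    inside[is.na(inside)] <- FALSE
    # exon vs intron for midpoints inside a gene
    for (gi in unique(idx[inside])) {
      sel <- rows[inside & idx == gi]
      ex <- g$exons[[gi]]
      ei <- findInterval(mids[sel], ex$start)
      in_ex <- ei >= 1 & mids[sel] < ex$end[pmax(ei, 1)]
      category[sel] <- ifelse(in_ex, "exon", "intron")
      nearest[sel] <- g$gene_id[gi]
      distance[sel] <- 0L
    }
    out <- which(!inside)
    if (length(out) > 0) {
      mo <- m[out]
      io <- idx[out]
      d_prev <- ifelse(io >= 1, mo - g$end[pmax(io, 1)] + 1L, NA_integer_)
      d_next <- ifelse(io < nrow(g), g$start[pmin(io + 1L, nrow(g))] - mo,
                       NA_integer_)
      d_prev[is.na(d_prev)] <- .Machine$integer.max
      d_next[is.na(d_next)] <- .Machine$integer.max
      side_cat <- function(gi, gene_right) {
        ifelse((g$strand[gi] == "+") == gene_right, "flank5", "flank3")
      }
      best <- pmin(d_prev, d_next)
      ok <- best <= flank_limit
      use_next <- d_next <= d_prev  # exact tie: prefer... resolve below
      gi_pick <- ifelse(use_next, io + 1L, io)
      cat_pick <- side_cat(pmax(gi_pick, 1), use_next)
      # exact tie between the two genes: prefer the 5' flank assignment
      tie <- d_prev == d_next & ok
      if (any(tie)) {
        alt_cat <- side_cat(pmax(io[tie], 1), FALSE)
        swap <- cat_pick[tie] != "flank5" & alt_cat == "flank5"
        gi_pick[tie][swap] <- io[tie][swap]
        cat_pick[tie][swap] <- "flank5"
      }
      sel <- rows[out]
      category[sel] <- ifelse(ok, cat_pick, "intergenic")
      nearest[sel] <- ifelse(ok, g$gene_id[pmax(gi_pick, 1)], NA_character_)
      distance[sel] <- ifelse(ok, as.integer(best), NA_integer_)
    }
  }
  copies$category <- factor(category, levels = CATEGORY_LEVELS)
  copies$nearest_gene <- nearest
  copies$distance <- distance
  copies
}

#' Bin flank insertions by distance to the gene
#'
#' Flank categories are subdivided into half-open distance bins
#' (default `<=500`, `(500, 3000]`, `(3000, 5000]`).
#'
#' @param contexts tibble from [classify_insertions()].
#' @param bins upper bin edges.
#' @return counts per `(category, bin)` with zero-filled combinations.
#' @export
flank_bins <- function(contexts, bins = c(500, 3000, 5000)) {
  labs <- c(paste0("<=", bins[1]),
            paste0(utils::head(bins, -1), "-", utils::tail(bins, -1)))
  fl <- contexts[contexts$category %in% c("flank5", "flank3"), , drop = FALSE]
  out <- tidyr::expand_grid(category = c("flank5", "flank3"), bin = labs)
  if (nrow(fl) == 0) {
    out$n <- 0L
    return(out)
  }
  fl$bin <- as.character(cut(fl$distance, breaks = c(0, bins), labels = labs,
                             include.lowest = TRUE, right = TRUE))
  counts <- dplyr::count(fl, category = as.character(.data$category),
                         .data$bin)
  out <- dplyr::left_join(out, counts, by = c("category", "bin"))
  out$n <- ifelse(is.na(out$n), 0L, out$n)
  out
}

#' Chi-square test of copy counts across chromosomes
#'
#' Tests the observed per-chromosome copy counts against expectations
#' proportional to chromosome length, with `df = n - 1`.
#'
#' @param counts observed copies per chromosome.
#' @param lengths chromosome lengths in bp (same order).
#' @return an object of class `mitescan_chisq`: list with `statistic`,
#'   `df`, `p_value`, `observed`, `expected`, `method`.
#' @export
#' @examples
#' chrom_distribution_test(c(20, 10), c(1e6, 1e6))
chrom_distribution_test <- function(counts, lengths) {
  if (length(counts) != length(lengths) || length(counts) < 2) {
    abort("chrom_distribution_test(): need matching counts/lengths (>= 2).",
          class = "mitescan_parameter_error")
  }
  if (any(lengths <= 0)) {
    abort("chrom_distribution_test(): zero-length chromosome.",
          class = "mitescan_parameter_error")
  }
  if (sum(counts) == 0) {
    abort("chrom_distribution_test(): no copies.",
          class = "mitescan_undefined_input")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, p = lengths / sum(lengths)))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, observed = counts,
                 expected = unname(ht$expected),
                 method = "chromosome distribution vs length-proportional"),
            class = "mitescan_chisq")
}

#' @export
print.mitescan_chisq <- function(x, ...) {
  cat("<", x$method, ">\n  X-squared = ", signif(x$statistic, 5),
      ", df = ", x$df, ", p ",
      if (x$p_value < 1e-15) "< 1e-15" else paste0("= ", signif(x$p_value, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Randomised insertion null by fragment-midpoint sampling
#'
#' Samples `n` fragments of up to `fragment` bp uniformly from the genome
#' (truncated at sequence ends), takes each fragment's midpoint as a
#' presumptive insertion site, and classifies it with the same
#' midpoint classifier as the observed copies.
#'
#' @param genome genome tibble.
#' @param genes gene tibble.
#' @param n number of draws (default 5000, the published control size).
#' @param fragment fragment length in bp.
#' @param flank_limit passed to [classify_insertions()].
#' @param seed RNG seed (required for reproducibility).
#' @return an object of class `mite_null_sim`: list with `contexts`
#'   (classified midpoints with an `has_N` flag), `category_fractions`,
#'   `in_gene_fraction`, `n`, `seed`.
#' @export
simulate_null <- function(genome, genes, n = 5000, fragment = 10000,
                          flank_limit = 5000, seed) {
  if (missing(seed)) abort("simulate_null(): seed is required.",
                           class = "mitescan_parameter_error")
  if (sum(genome$length) <= fragment) {
    abort("simulate_null(): genome shorter than one fragment.",
          class = "mitescan_parameter_error")
  }
  with_seed(seed, {
    ci <- sample(seq_len(nrow(genome)), n, replace = TRUE,
                 prob = genome$length)
    fs <- vapply(ci, function(i) {
      sample.int(genome$length[i], 1L) - 1L  # fragment start, 0-based
    }, integer(1))
    fe <- pmin(fs + fragment, genome$length[ci])  # truncated at the end
    mids <- (fs + fe) %/% 2L
    draws <- tibble(chrom = genome$chrom[ci], start = mids,
                    end = mids + 1L)
    ctx <- classify_insertions(draws, genes, flank_limit = flank_limit)
    frag_seq <- substr(genome$seq[ci], fs + 1L, fe)
    ctx$has_N <- grepl("N", frag_seq, fixed = TRUE)
    fr <- table(ctx$category) / n
    structure(list(contexts = ctx,
                   category_fractions = stats::setNames(as.numeric(fr),
                                                        names(fr)),
                   in_gene_fraction = unname(1 - fr[["intergenic"]]),
                   n = n, seed = seed),
              class = "mite_null_sim")
  })
}

#' @export
print.mite_null_sim <- function(x, ...) {
  cat("<mite_null_sim> n = ", x$n, ", seed = ", x$seed,
      "; in-gene fraction = ", round(x$in_gene_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' Enrichment of in-gene insertions against the null
#'
#' 2x2 chi-square test (no continuity correction by default) of the
#' in-gene proportion, observed copies versus null draws. In-gene means
#' any category other than intergenic (gene body or 5 kb flank).
#'
#' @param contexts observed contexts from [classify_insertions()] (or a
#'   length-2 count vector `c(in_gene, not_in_gene)`).
#' @param null a `mite_null_sim` (or a length-2 count vector).
#' @param correct apply Yates continuity correction.
#' @return a `mitescan_chisq` (with `expected_warning` flag when any
#'   expected cell is below 1).
#' @export
enrichment_test <- function(contexts, null, correct = FALSE) {
  as_counts <- function(x) {
    if (is.numeric(x) && length(x) == 2) return(x)
    if (inherits(x, "mite_null_sim")) x <- x$contexts
    ing <- sum(x$category != "intergenic")
    c(ing, nrow(x) - ing)
  }
  obs <- as_counts(contexts)
  nul <- as_counts(null)
  tabl <- rbind(observed = obs, null = nul)
  colnames(tabl) <- c("in_gene", "intergenic")
  ht <- suppressWarnings(stats::chisq.test(tabl, correct = correct))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, observed = tabl,
                 expected = ht$expected,
                 expected_warning = any(ht$expected < 1),
                 method = "in-gene enrichment, observed vs null (2x2)"),
            class = "mitescan_chisq")
}

#' Correlation between MITE density and gene density across chromosomes
#'
#' Pearson correlation of per-Mb densities; reports `r_squared`,
#' two-sided `p` from the t-transform, and `df = n - 2`.
#'
#' @param mite_counts,gene_counts per-chromosome counts.
#' @param lengths chromosome lengths in bp.
#' @return one-row tibble: `r`, `r_squared`, `p_value`, `df`, `n`.
#' @export
density_correlation <- function(mite_counts, gene_counts, lengths) {
  n <- length(lengths)
  if (n < 3 || length(mite_counts) != n || length(gene_counts) != n) {
    abort("density_correlation(): need >= 3 chromosomes with matching vectors.",
          class = "mitescan_parameter_error")
  }
  md <- mite_counts / (lengths / 1e6)
  gd <- gene_counts / (lengths / 1e6)
  if (stats::sd(md) == 0 || stats::sd(gd) == 0) {
    abort("density_correlation(): zero variance in a density vector.",
          class = "mitescan_undefined_input")
  }
  ht <- stats::cor.test(md, gd)
  tibble(r = unname(ht$estimate), r_squared = unname(ht$estimate)^2,
         p_value = ht$p.value, df = unname(ht$parameter), n = n)
}

#' Probability that sampled genes are all germline-silent
#'
#' `(1 - expressed/total)^n_genes`: the chance that `n_genes` randomly
#' selected genes are all among those not expressed in ovary or testis.
#' Defaults reproduce the published statistic (8431 of 10393 microarray
#' genes expressed in germline tissue; 5 genes nearest to the
#' piRNA-carrying family).
#'
#' @param expressed number of genes expressed in the germline tissues.
#' @param total total assayed genes.
#' @param n_genes number of sampled genes.
#' @return probability.
#' @export
#' @examples
#' germline_silencing_prob() # about 2.4e-4
germline_silencing_prob <- function(expressed = 8431, total = 10393,
                                    n_genes = 5) {
  if (total <= 0) {
    abort("germline_silencing_prob(): total must be > 0.",
          class = "mitescan_parameter_error")
  }
  if (expressed < 0 || expressed > total || n_genes < 0) {
    abort("germline_silencing_prob(): need 0 <= expressed <= total, n >= 0.",
          class = "mitescan_parameter_error")
  }
  (1 - expressed / total)^n_genes
}
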