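# Synthetic genomes with planted, truth-labelled MITE families.
#
# The generator emulates the statistical structure the analysis assumes:
# an i.i.d. background at a target AT content, gene models with
# exon/intron structure, planted element copies (TSD + TIR + internal +
# revcomp(TIR) + TSD) mutated under a two-rate substitution model, a
# configurable fraction of TIR-truncated copies, and decoy pseudo-elements.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, at_content = 0.62) {
  p <- c(at_content / 2, (1 - at_content) / 2, (1 - at_content) / 2,
         at_content / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Draw a concrete TSD instance from a degenerate motif (IUPAC subset).
sample_tsd <- function(motif) {
  chars <- seq_chars(motif)
  draw <- function(ch) {
    switch(ch,
           A = "A", C = "C", G = "G", T = "T",
           W = sample(c("A", "T"), 1),
           D = sample(c("A", "G", "T"), 1),
           N = sample(BASES, 1),
           abort(paste0("sample_tsd(): unsupported motif letter '", ch, "'."),
                 class = "mitescan_parameter_error"))
  }
  paste(vapply(chars, draw, character(1)), collapse = "")
}

#' Mutate a sequence under a two-rate (transition-weighted) model
#'
#' Each site receives a Poisson(`k`) number of substitution events; each
#' event is a transition with probability `kappa / (kappa + 2)` and
#' otherwise one of the two transversions. `k` is therefore the expected
#' number of substitutions per site, the quantity the Kimura two-parameter
#' distance estimates.
#'
#' @param seq nucleotide string (ACGT).
#' @param k expected substitutions per site.
#' @param ts_tv_ratio transition/transversion rate ratio kappa.
#' @return a list with `seq` (mutated string), `n_events` (total
#'   substitution events) and `k_realized` (`n_events` / length).
#' @export
mutate_sequence <- function(seq, k, ts_tv_ratio = 2) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (k < 0) abort("mutate_sequence(): k must be >= 0.",
                   class = "mitescan_parameter_error")
  nev <- stats::rpois(L, k)
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 2)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (i in which(nev > 0)) {
    b <- chars[i]
    for (e in seq_len(nev[i])) {
      b <- if (stats::runif(1) < p_ts) transition[[b]] else
        sample(transversions[[b]], 1)
    }
    chars[i] <- b
  }
  list(seq = paste(chars, collapse = ""), n_events = sum(nev),
       k_realized = sum(nev) / L)
}

#' Specify a MITE family for the synthetic-genome generator
#'
#' @param family_id family name.
#' @param tir TIR sequence (8-50 bp).
#' @param tsd_motif TSD motif over `ACGTWDN` (W = A/T, D = A/G/T, N = any);
#'   degenerate letters are sampled per copy.
#' @param n_copies number of copies to plant.
#' @param internal_length length of the internal (between-TIR) region;
#'   total element length `2 * nchar(tir) + internal_length` must lie in
#'   `[100, 600]`.
#' @param divergence_mean expected substitutions/site per copy (`k`).
#' @param divergence_cv coefficient of variation of per-copy `k` (0 =
#'   every copy at `divergence_mean`; otherwise gamma-distributed).
#' @param truncation_fraction fraction of copies losing one terminal TIR
#'   plus at least 10 bp.
#' @param at_content AT content of the internal region.
#' @return one-row tibble (rows from several calls bind into a spec table).
#' @export
family_spec <- function(family_id, tir, tsd_motif, n_copies,
                        internal_length, divergence_mean = 0,
                        divergence_cv = 0, truncation_fraction = 0,
                        at_content = 0.65) {
  tir <- toupper(tir)
  if (nchar(tir) < 8 || nchar(tir) > 50) {
    abort("family_spec(): TIR length must be in [8, 50].",
          class = "mitescan_parameter_error")
  }
  total <- 2L * nchar(tir) + as.integer(internal_length)
  if (total < 100 || total > 600) {
    abort("family_spec(): total element length must be in [100, 600].",
          class = "mitescan_parameter_error")
  }
  if (truncation_fraction < 0 || truncation_fraction > 1) {
    abort("family_spec(): truncation_fraction must be in [0, 1].",
          class = "mitescan_parameter_error")
  }
  if (divergence_mean < 0) {
    abort("family_spec(): divergence_mean must be >= 0.",
          class = "mitescan_parameter_error")
  }
  tibble(family_id = family_id, tir = tir, tsd_motif = toupper(tsd_motif),
         n_copies = as.integer(n_copies),
         internal_length = as.integer(internal_length),
         element_length = total, divergence_mean = divergence_mean,
         divergence_cv = divergence_cv,
         truncation_fraction = truncation_fraction,
         at_content = at_content)
}

#' Example family specifications modelled on the silkworm families
#'
#' Three specs borrowing TSD motif, TIR and element size from well-known
#' silkworm families (a Stowaway-like TA family, a novel ATT family, and
#' a Pegasus-like 8-bp-TSD family; see [silkworm_family_table()]).
#'
#' @param n_copies copies per family (recycled).
#' @param divergence_mean,truncation_fraction passed to [family_spec()]
#'   (recycled).
#' @return a spec tibble with three rows.
#' @export
example_family_specs <- function(n_copies = c(60, 30, 30),
                                 divergence_mean = 0,
                                 truncation_fraction = 0) {
  n <- rep_len(n_copies, 3)
  k <- rep_len(divergence_mean, 3)
  tr <- rep_len(truncation_fraction, 3)
  fam <- silkworm_family_table()
  pick <- function(id, i) {
    row <- fam[fam$family_id == id, ]
    family_spec(paste0(id, "-like"), row$tir, row$tsd_motif, n[i],
                internal_length = row$size_bp - 2L * nchar(row$tir),
                divergence_mean = k[i], truncation_fraction = tr[i])
  }
  dplyr::bind_rows(pick("BmMITE-2", 1), pick("BmMITE-9", 2),
                   pick("BmMITE-13", 3))
}

# ---- gene models -----------------------------------------------------------

# Sample one gene's exon/intron layout; returns list(length, exons rel. 0).
sample_gene_layout <- function() {
  n_ex <- sample(2:4, 1)
  ex_len <- sample(150:400, n_ex, replace = TRUE)
  in_len <- sample(500:1500, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(0, head(ex_len, -1) + in_len))
  list(length = sum(ex_len) + sum(in_len),
       exons = tibble(start = starts, end = starts + ex_len))
}

# Place n non-overlapping intervals of the given lengths in [edge, L-edge]
# with at least min_gap between them. Returns start positions.
place_intervals <- function(total_len, lens, min_gap, edge) {
  n <- length(lens)
  if (n == 0) return(integer(0))
  slack <- total_len - 2 * edge - sum(lens) - (n - 1) * min_gap
  if (slack < 0) {
    abort("simulate_genome(): infeasible packing (too many/large features).",
          class = "mitescan_packing_error")
  }
  u <- stats::runif(n + 1)
  gaps <- floor(slack * u / sum(u))
  starts <- edge + cumsum(gaps[seq_len(n)]) +
    cumsum(c(0, head(lens, -1))) + (seq_len(n) - 1) * min_gap
  as.integer(starts)
}

# ---- placement of insertion points -----------------------------------------

# Sample an insertion point for one category given gene models on one
# chromosome (original background coordinates, 0-based). Flank corridors
# accept at most one point each (tracked by the caller via zone ids).
sample_point <- function(category, genes, chrom_len, margin_edge = 1200) {
  if (category == "intergenic" || nrow(genes) == 0) {
    return(list(point = NA_integer_, zone = NA_character_, retry = TRUE))
  }
  g <- genes[sample(nrow(genes), 1), ]
  if (category == "intron") {
    ex <- g$exons[[1]]
    if (nrow(ex) < 2) return(list(point = NA_integer_, zone = NA, retry = TRUE))
    i <- sample(nrow(ex) - 1, 1)
    lo <- ex$end[i] + 120L
    hi <- ex$start[i + 1] - 120L
    if (hi < lo) return(list(point = NA_integer_, zone = NA, retry = TRUE))
    return(list(point = sample(lo:hi, 1), zone = NA_character_, retry = FALSE))
  }
  if (category == "exon") {
    ex <- g$exons[[1]]
    i <- sample(nrow(ex), 1)
    lo <- ex$start[i] + 40L
    hi <- ex$end[i] - 40L
    if (hi < lo) return(list(point = NA_integer_, zone = NA, retry = TRUE))
    return(list(point = sample(lo:hi, 1), zone = NA_character_, retry = FALSE))
  }
  upstream <- (category == "flank5") == (g$strand == "+")
  if (upstream) {
    lo <- g$start - 4200L; hi <- g$start - 400L
    zone <- paste0(g$gene_id, ":up")
  } else {
    lo <- g$end + 400L; hi <- g$end + 4200L
    zone <- paste0(g$gene_id, ":down")
  }
  if (lo < margin_edge || hi > chrom_len - margin_edge) {
    return(list(point = NA_integer_, zone = NA, retry = TRUE))
  }
  list(point = sample(lo:hi, 1), zone = zone, retry = FALSE)
}

sample_intergenic_point <- function(genes, chrom_len, margin_edge = 1200) {
  for (try in 1:400) {
    p <- sample(seq(margin_edge, chrom_len - margin_edge), 1)
    if (nrow(genes) == 0 ||
        all(p < genes$start - 5400 | p > genes$end + 5400)) {
      return(p)
    }
  }
  abort("simulate_genome(): could not place an intergenic point.",
        class = "mitescan_packing_error")
}

# ---- assembly --------------------------------------------------------------

# Apply TSD host overwrites and segment insertions to one chromosome.
# insertions: tibble(point, segment, elem_off, elem_len, ...extra truth cols)
# overwrites: tibble(at, text) applied to the background first.
assemble_chrom <- function(bg, overwrites, insertions, genes) {
  if (nrow(overwrites) > 0) {
    for (i in seq_len(nrow(overwrites))) {
      substr(bg, overwrites$at[i] + 1L,
             overwrites$at[i] + nchar(overwrites$text[i])) <-
        overwrites$text[i]
    }
  }
  ins <- insertions[order(insertions$point), , drop = FALSE]
  pts <- ins$point
  lens <- nchar(ins$segment)
  cum_before <- c(0, cumsum(lens))[seq_along(lens)]
  # final sequence
  pieces <- character(2 * nrow(ins) + 1)
  prev <- 0L
  for (i in seq_len(nrow(ins))) {
    pieces[2 * i - 1] <- substr(bg, prev + 1L, pts[i])
    pieces[2 * i] <- ins$segment[i]
    prev <- pts[i]
  }
  pieces[2 * nrow(ins) + 1] <- substr(bg, prev + 1L, nchar(bg))
  seq <- paste(pieces, collapse = "")

  shift <- function(x) {
    x + c(0, cumsum(lens))[findInterval(x - 0.5, pts) + 1L]
  }
  ins$final_start <- as.integer(pts + cum_before + ins$elem_off)
  ins$final_end <- as.integer(ins$final_start + ins$elem_len)

  if (nrow(genes) > 0) {
    genes$exons <- purrr::map2(genes$exons, seq_len(nrow(genes)), function(ex, i) {
      tibble(start = as.integer(shift(ex$start)), end = as.integer(shift(ex$end)))
    })
    genes$start <- as.integer(shift(genes$start))
    genes$end <- as.integer(shift(genes$end))
  }
  list(seq = seq, insertions = ins, genes = genes)
}

# Check, on a locally assembled window, that the planted candidate wins
# shadow resolution at its exact span. Used for rejection sampling of the
# flanking background so planted loci are structurally unambiguous.
locus_unambiguous <- function(left, tsd, elem, right, params) {
  local <- paste0(left, tsd, elem, tsd, right)
  s <- nchar(left) + nchar(tsd)
  e <- s + nchar(elem)
  cand <- scan_mite_candidates(tibble(chrom = "w", seq = local,
                                      length = nchar(local)),
                               params = params)
  ours <- cand[cand$start == s & cand$end == e, ]
  if (nrow(ours) != 1) return(FALSE)
  # no surviving overlapping candidate displacing it
  ov <- cand[pmin(cand$end, e) - pmax(cand$start, s) >
               0.5 * pmin(cand$end - cand$start, e - s), ]
  nrow(ov) == 1
}

#' Generate a synthetic genome with planted MITE families
#'
#' Builds an i.i.d. background at the requested AT content, places
#' non-overlapping gene models, then plants each family copy as
#' `TSD + element + TSD` at an insertion point whose genomic category
#' (exon, intron, 5'/3' flank, intergenic) is drawn from
#' `category_weights`. Copies are mutated under the two-rate model of
#' [mutate_sequence()]; a configurable fraction is truncated (one terminal
#' TIR plus at least 10 bp removed). Every planted element is recorded in
#' a truth table.
#'
#' Flanking background at each planted locus is resampled (bounded
#' rejection) until the planted candidate is the unique winner of the
#' structural scan at its exact coordinates, so that zero-divergence
#' recovery is well-defined even for palindromic TSDs whose maximal
#' inverted repeat would otherwise extend through the TSD.
#'
#' @param specs spec table from [family_spec()] rows.
#' @param genome_length total genome length in bp.
#' @param n_chrom number of chromosomes (equal sizes).
#' @param gene_density genes per Mb.
#' @param at_content background AT fraction (default 0.62, the silkworm
#'   genome-wide value).
#' @param ts_tv_ratio transition/transversion rate ratio kappa.
#' @param category_weights named weights over
#'   `c("flank5","exon","intron","flank3","intergenic")` for insertion
#'   categories; defaults follow the published silkworm category layout
#'   with exon insertions disabled.
#' @param seed integer RNG seed (required; the output is a pure function
#'   of the configuration and seed).
#' @return an object of class `mite_simulation`: a list with `genome`
#'   (tibble `chrom`,`seq`,`length`), `genes`, `truth` (tibble `chrom`,
#'   `start`, `end`, `family_id`, `tsd`, `k_drawn`, `k_planted`, `intact`,
#'   `truncated_side`, `category_truth`, `decoy_class`), `specs`, and
#'   `params`.
#' @export
simulate_genome <- function(specs,
                            genome_length = 200000,
                            n_chrom = 1,
                            gene_density = 20,
                            at_content = 0.62,
                            ts_tv_ratio = 2,
                            category_weights = c(flank5 = 0.17, exon = 0,
                                                 intron = 0.25, flank3 = 0.23,
                                                 intergenic = 0.35),
                            seed) {
  if (missing(seed)) abort("simulate_genome(): seed is required.",
                           class = "mitescan_parameter_error")
  stopifnot(is.data.frame(specs))
  total_planted <- sum(specs$n_copies * (specs$element_length + 20))
  if (total_planted >= genome_length) {
    abort("simulate_genome(): infeasible packing (planted length >= genome).",
          class = "mitescan_packing_error")
  }
  cats <- c("flank5", "exon", "intron", "flank3", "intergenic")
  w <- category_weights[cats]
  w[is.na(w)] <- 0
  params <- default_scan_params()

  with_seed(seed, {
    chrom_len <- rep(genome_length %/% n_chrom, n_chrom)
    chrom_len[n_chrom] <- chrom_len[n_chrom] + genome_length %% n_chrom
    chrom_ids <- paste0("chr", seq_len(n_chrom))

    # masters
    masters <- purrr::pmap(specs, function(family_id, tir, tsd_motif,
                                           n_copies, internal_length,
                                           element_length, divergence_mean,
                                           divergence_cv, truncation_fraction,
                                           at_content, ...) {
      repeat {
        internal <- random_dna(internal_length, at_content)
        ich <- seq_chars(internal)
        # break chance inward TIR extension at the master level
        ok <- all(ich[1:3] != vapply(ich[internal_length - 0:2],
                                     function(b) chartr("ACGT", "TGCA", b),
                                     character(1)))
        # and keep masters clear of the simple-repeat pseudo-element rule
        if (ok && !is_simple_repeat(paste0(tir, internal, revcomp(tir)),
                                    min_cover = 0.75)) {
          break
        }
      }
      paste0(tir, internal, revcomp(tir))
    })

    genomes <- list(); gene_all <- list(); truth_all <- list()

    # Assign genes and copies to chromosomes proportional to length.
    n_genes_total <- round(gene_density * genome_length / 1e6)
    gene_chrom <- sort(sample(seq_len(n_chrom), n_genes_total, replace = TRUE,
                              prob = chrom_len))
    copy_tbl <- tidyr::uncount(specs[, c("family_id", "tsd_motif",
                                         "truncation_fraction",
                                         "divergence_mean", "divergence_cv")],
                               weights = specs$n_copies)
    copy_tbl$tir_len <- rep(nchar(specs$tir), specs$n_copies)
    copy_tbl$master <- rep(unlist(masters), specs$n_copies)
    copy_tbl$chrom_i <- sample(seq_len(n_chrom), nrow(copy_tbl),
                               replace = TRUE, prob = chrom_len)

    for (ci in seq_len(n_chrom)) {
      L <- chrom_len[ci]
      bg <- random_dna(L, at_content)

      n_genes <- sum(gene_chrom == ci)
      layouts <- purrr::map(seq_len(n_genes), ~sample_gene_layout())
      glens <- vapply(layouts, `[[`, numeric(1), "length")
      gstarts <- place_intervals(L, glens, min_gap = 13000, edge = 12000)
      genes <- if (n_genes > 0) {
        dplyr::bind_rows(purrr::map(seq_len(n_genes), function(i) {
          tibble(gene_id = sprintf("%s.g%02d", chrom_ids[ci], i),
                 chrom = chrom_ids[ci],
                 start = gstarts[i],
                 end = gstarts[i] + as.integer(glens[i]),
                 strand = sample(c("+", "-"), 1),
                 exons = list(tibble(
                   start = layouts[[i]]$exons$start + gstarts[i],
                   end = layouts[[i]]$exons$end + gstarts[i])))
        }))
      } else {
        tibble(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               exons = list())
      }

      copies <- copy_tbl[copy_tbl$chrom_i == ci, , drop = FALSE]
      overwrites <- list(); insertions <- list()
      used_points <- integer(0); used_zones <- character(0)

      for (k in seq_len(nrow(copies))) {
        cp <- copies[k, ]
        # draw category honouring zone availability and gene presence
        placed <- FALSE
        for (attempt in 1:300) {
          category <- if (n_genes == 0 || sum(w) == 0) "intergenic" else
            sample(cats, 1, prob = w)
          if (category == "intergenic") {
            p <- sample_intergenic_point(genes, L)
            zone <- NA_character_
          } else {
            sp <- sample_point(category, genes, L)
            if (sp$retry || (!is.na(sp$zone) && sp$zone %in% used_zones)) next
            p <- sp$point; zone <- sp$zone
          }
          if (length(used_points) > 0 && min(abs(used_points - p)) < 900) next
          placed <- TRUE
          break
        }
        if (!placed) {
          abort("simulate_genome(): infeasible packing of insertion points.",
                class = "mitescan_packing_error")
        }
        used_points <- c(used_points, p)
        if (!is.na(zone)) used_zones <- c(used_zones, zone)

        tsd <- sample_tsd(cp$tsd_motif)
        Lt <- nchar(tsd)
        kdrawn <- if (cp$divergence_cv > 0 && cp$divergence_mean > 0) {
          shape <- 1 / cp$divergence_cv^2
          stats::rgamma(1, shape = shape,
                        scale = cp$divergence_mean / shape)
        } else cp$divergence_mean
        mut <- mutate_sequence(cp$master, kdrawn, ts_tv_ratio)
        elem <- mut$seq
        E0 <- nchar(elem)
        truncated <- stats::runif(1) < cp$truncation_fraction
        trunc_side <- NA_character_
        if (truncated) {
          cut <- cp$tir_len + 10L +
            sample.int(max(1L, min(20L, floor(0.19 * E0) - cp$tir_len - 10L)), 1)
          cut <- min(cut, E0 - 100L)
          trunc_side <- sample(c("5p", "3p"), 1)
          elem <- if (trunc_side == "5p") substr(elem, cut + 1L, E0) else
            substr(elem, 1L, E0 - cut)
        }
        E <- nchar(elem)

        # local structural-unambiguity guard (bounded rejection on flanks);
        # only meaningful when both TIR arms are mutation-free, the case
        # exact-coordinate recovery is defined for
        tl <- cp$tir_len
        tirs_clean <- !truncated &&
          substr(elem, 1, tl) == substr(cp$master, 1, tl) &&
          substr(elem, E0 - tl + 1, E0) == substr(cp$master, E0 - tl + 1, E0)
        lctx <- substr(bg, p - 39, p)
        rctx <- substr(bg, p + Lt + 1, p + Lt + 40)
        if (tirs_clean) {
          for (g in 1:25) {
            if (locus_unambiguous(lctx, tsd, elem, rctx, params)) break
            lctx <- random_dna(40, at_content)
            rctx <- random_dna(40, at_content)
          }
          # homopolymer-TSD guard is subsumed: the scan itself rejects
          # run-extended TSDs, so the rejection loop handles it.
        }
        overwrites[[length(overwrites) + 1]] <-
          tibble(at = c(p - 40L, p, p + Lt),
                 text = c(lctx, tsd, rctx))
        insertions[[length(insertions) + 1]] <-
          tibble(point = p + Lt, segment = paste0(elem, tsd),
                 elem_off = 0L, elem_len = E,
                 family_id = cp$family_id, tsd = tsd,
                 k_drawn = kdrawn, k_planted = mut$k_realized,
                 intact = !truncated, truncated_side = trunc_side,
                 category_truth = category, decoy_class = NA_character_)
      }

      ins_tbl <- if (length(insertions) > 0) dplyr::bind_rows(insertions) else
        tibble(point = integer(), segment = character(), elem_off = integer(),
               elem_len = integer(), family_id = character(), tsd = character(),
               k_drawn = numeric(), k_planted = numeric(), intact = logical(),
               truncated_side = character(), category_truth = character(),
               decoy_class = character())
      ov_tbl <- if (length(overwrites) > 0) dplyr::bind_rows(overwrites) else
        tibble(at = integer(), text = character())
      asm <- assemble_chrom(bg, ov_tbl, ins_tbl, genes)
      genomes[[ci]] <- tibble(chrom = chrom_ids[ci], seq = asm$seq,
                              length = nchar(asm$seq))
      gene_all[[ci]] <- asm$genes
      tr <- asm$insertions
      truth_all[[ci]] <- tibble(chrom = chrom_ids[ci],
                                start = tr$final_start, end = tr$final_end,
                                family_id = tr$family_id, tsd = tr$tsd,
                                k_drawn = tr$k_drawn, k_planted = tr$k_planted,
                                intact = tr$intact,
                                truncated_side = tr$truncated_side,
                                category_truth = tr$category_truth,
                                decoy_class = tr$decoy_class)
    }

    structure(list(
      genome = dplyr::bind_rows(genomes),
      genes = dplyr::bind_rows(gene_all),
      truth = dplyr::bind_rows(truth_all),
      specs = specs,
      params = list(genome_length = genome_length, n_chrom = n_chrom,
                    gene_density = gene_density, at_content = at_content,
                    ts_tv_ratio = ts_tv_ratio,
                    category_weights = w, seed = seed)
    ), class = "mite_simulation")
  })
}

#' @export
print.mite_simulation <- function(x, ...) {
  cat("<mite_simulation> ", nrow(x$genome), " chromosome(s), ",
      sum(x$genome$length), " bp; ", nrow(x$genes), " genes; ",
      nrow(x$truth), " planted elements (",
      sum(!is.na(x$truth$decoy_class)), " decoys)\n", sep = "")
  invisible(x)
}

#' Add decoy pseudo-elements to a synthetic genome
#'
#' Plants three decoy classes mirroring the pseudo-MITE artifacts the
#' filtering stage must reject: (a) elements whose internal region is a
#' tandem simple repeat of period 1-6, (b) elements containing a run of
#' `N`s, and (c) elements nested in high-copy repeats (their 50 bp flanks
#' are planted at least 20 more times elsewhere in the genome). Each class
#' forms one decoy family of identical copies, inserted intergenically.
#'
#' @param sim a `mite_simulation`.
#' @param n_simple,n_nrun,n_nested copies per decoy class (0 disables).
#' @param seed RNG seed.
#' @return the updated `mite_simulation` (truth rows gain `decoy_class`
#'   labels `decoy_simple`, `decoy_nrun`, `decoy_nested`).
#' @export
add_decoys <- function(sim, n_simple = 0, n_nrun = 0, n_nested = 0, seed) {
  stopifnot(inherits(sim, "mite_simulation"))
  if (missing(seed)) abort("add_decoys(): seed is required.",
                           class = "mitescan_parameter_error")
  with_seed(seed, {
    mk_tir <- function() random_dna(14, 0.5)
    classes <- list()
    if (n_simple > 0) {
      tir <- mk_tir()
      period <- sample(1:6, 1)
      unit <- random_dna(period, 0.6)
      internal <- paste(rep(unit, ceiling(220 / period)), collapse = "")
      internal <- substr(internal, 1, 220)
      classes$decoy_simple <- list(
        elem = paste0(tir, internal, revcomp(tir)), n = n_simple, tsd = "TA")
    }
    if (n_nrun > 0) {
      tir <- mk_tir()
      internal <- random_dna(220, 0.6)
      substr(internal, 100, 107) <- "NNNNNNNN"
      classes$decoy_nrun <- list(
        elem = paste0(tir, internal, revcomp(tir)), n = n_nrun, tsd = "TA")
    }
    nested_units <- NULL
    if (n_nested > 0) {
      tir <- mk_tir()
      internal <- random_dna(220, 0.6)
      tsd <- "TA"
      ul <- random_dna(60, 0.5)  # left repeat unit (ends just before TSD)
      ur <- random_dna(60, 0.5)  # right repeat unit (starts just after TSD)
      classes$decoy_nested <- list(
        elem = paste0(tir, internal, revcomp(tir)), n = n_nested, tsd = tsd,
        wrap_left = paste0(ul, tsd), wrap_right = paste0(tsd, ur))
      nested_units <- c(paste0(ul, tsd), paste0(tsd, ur))
    }
    if (length(classes) == 0) return(sim)

    for (ci in seq_len(nrow(sim$genome))) {
      chrom <- sim$genome$chrom[ci]
      bg <- sim$genome$seq[ci]
      L <- nchar(bg)
      genes <- sim$genes[sim$genes$chrom == chrom, , drop = FALSE]
      occupied <- sim$truth[sim$truth$chrom == chrom, , drop = FALSE]
      planted <- as.integer((occupied$start + occupied$end) / 2)
      used <- integer(0)

      # decoys only need to clear planted elements (and their scored
      # flanks); among themselves a small separation suffices because
      # insertions at distinct cut points never overlap
      pick_point <- function() {
        for (try in 1:2000) {
          p <- sample(seq(1200, L - 1200), 1)
          ok_gene <- nrow(genes) == 0 ||
            all(p < genes$start - 5400 | p > genes$end + 5400)
          ok_planted <- length(planted) == 0 || min(abs(planted - p)) > 900
          ok_used <- length(used) == 0 || min(abs(used - p)) > 250
          if (ok_gene && ok_planted && ok_used) {
            used <<- c(used, p)
            return(p)
          }
        }
        abort("add_decoys(): could not place a decoy.",
              class = "mitescan_packing_error")
      }

      insertions <- list()
      for (cls in names(classes)) {
        spec <- classes[[cls]]
        for (i in seq_len(spec$n)) {
          p <- pick_point()
          if (cls == "decoy_nested") {
            seg <- paste0(spec$wrap_left, spec$elem, spec$wrap_right)
            off <- nchar(spec$wrap_left)
          } else {
            seg <- paste0(spec$tsd, spec$elem, spec$tsd)
            off <- nchar(spec$tsd)
          }
          insertions[[length(insertions) + 1]] <-
            tibble(point = p, segment = seg, elem_off = off,
                   elem_len = nchar(spec$elem),
                   family_id = cls, tsd = spec$tsd,
                   k_drawn = 0, k_planted = 0, intact = TRUE,
                   truncated_side = NA_character_,
                   category_truth = "intergenic", decoy_class = cls)
        }
      }
      # high-copy flank units for the nested class
      if (!is.null(nested_units)) {
        for (u in nested_units) {
          for (i in 1:22) {
            p <- pick_point()
            insertions[[length(insertions) + 1]] <-
              tibble(point = p, segment = u, elem_off = 0L,
                     elem_len = 0L, family_id = NA_character_,
                     tsd = NA_character_, k_drawn = NA_real_,
                     k_planted = NA_real_, intact = NA,
                     truncated_side = NA_character_,
                     category_truth = NA_character_,
                     decoy_class = "repeat_unit")
          }
        }
      }

      ins_tbl <- dplyr::bind_rows(insertions)
      asm <- assemble_chrom(bg, tibble(at = integer(), text = character()),
                            ins_tbl, genes)
      # shift existing truth coordinates on this chromosome
      pts <- sort(ins_tbl$point)
      lens <- nchar(ins_tbl$segment[order(ins_tbl$point)])
      shift <- function(x) x + c(0, cumsum(lens))[findInterval(x - 0.5, pts) + 1L]
      idx <- sim$truth$chrom == chrom
      sim$truth$start[idx] <- as.integer(shift(sim$truth$start[idx]))
      sim$truth$end[idx] <- as.integer(shift(sim$truth$end[idx]))

      sim$genome$seq[ci] <- asm$seq
      sim$genome$length[ci] <- nchar(asm$seq)
      sim$genes[sim$genes$chrom == chrom, ] <- asm$genes
      new_tr <- asm$insertions
      new_tr <- new_tr[new_tr$decoy_class != "repeat_unit", , drop = FALSE]
      sim$truth <- dplyr::bind_rows(
        sim$truth,
        tibble(chrom = chrom, start = new_tr$final_start,
               end = new_tr$final_end, family_id = new_tr$family_id,
               tsd = new_tr$tsd, k_drawn = new_tr$k_drawn,
               k_planted = new_tr$k_planted, intact = new_tr$intact,
               truncated_side = new_tr$truncated_side,
               category_truth = new_tr$category_truth,
               decoy_class = new_tr$decoy_class))
    }
    sim$truth <- dplyr::arrange(sim$truth, .data$chrom, .data$start)
    sim
  })
}

#' Write a synthetic genome to disk
#'
#' Emits `genome.fa`, `genes.gff3` and `truth.tsv` under `dir`.
#'
#' @param sim a `mite_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_gff3(sim$genes, file.path(dir, "genes.gff3"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
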