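# Independent oracles and construction helpers shared across tests.

# Exhaustive brute-force structural scan: enumerates every (start, end)
# span and every TIR/TSD length combination with direct string
# comparisons, applying the same acceptance rules as the scanner but
# without any seeding/diagonal machinery. Quadratic; for short sequences.
brute_force_scan <- function(seqstr, p = default_scan_params()) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(chars)
  out <- list()
  for (s in seq(p$tsd_min, n - p$len_min - p$tsd_min)) {
    for (e in seq(s + p$len_min, min(s + p$len_max, n - p$tsd_min))) {
      len <- e - s
      tcap <- min(p$tir_max, len %/% 2)
      if (tcap < p$tir_min) next
      a <- chars[(s + 1):(s + tcap)]
      b <- unname(comp[chars[e:(e - tcap + 1)]])
      m <- a == b
      m[is.na(m)] <- FALSE
      if (!m[1]) next
      # largest t: boundary pairs match, mismatch budget, 8-exact run
      best_t <- 0L; best_mm <- NA_integer_
      mm <- cumsum(!m)
      for (t in seq(p$tir_min, tcap)) {
        if (!m[t] || mm[t] > floor(p$max_tir_mismatch * t)) next
        runs <- rle(m[1:t])
        if (max(runs$lengths[runs$values]) < p$seed_word) next
        best_t <- t; best_mm <- mm[t]
      }
      if (best_t == 0) next
      elem <- chars[(s + 1):e]
      if (any(!elem %in% c("A", "C", "G", "T"))) next
      # longest exact TSD with the homopolymer-run rejection rule
      tsd <- NULL
      for (L in seq(min(p$tsd_max, s, n - e), p$tsd_min)) {
        if (L < p$tsd_min) break
        left <- chars[(s - L + 1):s]
        right <- chars[(e + 1):(e + L)]
        if (any(!left %in% c("A", "C", "G", "T"))) next
        if (!all(left == right)) next
        if (length(unique(left)) == 1) {
          bch <- left[1]
          if ((s - L >= 1 && chars[s - L] == bch) ||
              (e + L < n && chars[e + L + 1] == bch)) next
        }
        tsd <- list(tsd = paste(left, collapse = ""), len = L)
        break
      }
      if (is.null(tsd)) next
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = "w", start = s, end = e, tir_len = best_t,
        tsd_len = tsd$len,
        tir5 = paste(chars[(s + 1):(s + best_t)], collapse = ""),
        tir3 = paste(chars[(e - best_t + 1):e], collapse = ""),
        tsd = tsd$tsd, tir_mismatches = best_mm,
        seq = paste(elem, collapse = ""))
    }
  }
  if (length(out) == 0) {
    return(scan_mite_candidates(tibble::tibble(chrom = "w", seq = "ACGT",
                                               length = 4))[0, ])
  }
  cand <- dplyr::bind_rows(out)
  # same greedy shadow resolution, reimplemented
  ord <- order(-(cand$tir_len + cand$tsd_len), -cand$tsd_len,
               cand$start, cand$end)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j])
      if (ov > 0.5 * min(cand$end[i] - cand$start[i],
                         cand$end[j] - cand$start[j])) {
        ok <- FALSE; break
      }
    }
    kept[i] <- ok
  }
  cand <- cand[kept, , drop = FALSE]
  cand[order(cand$start, cand$end), , drop = FALSE]
}

# Brute-force tandem-repeat cover fraction (periods 1..max_period),
# counting positions inside any maximal >= 2-unit exact tandem run.
brute_repeat_cover <- function(seqstr, max_period = 6) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  n <- length(chars)
  covered <- logical(n)
  for (p in seq_len(max_period)) {
    for (s in seq_len(n - 2 * p + 1)) {
      len <- 0
      while (s + p + len <= n && chars[s + len] == chars[s + p + len]) {
        len <- len + 1
      }
      if (len >= p) covered[s:(s + p + len - 1)] <- TRUE
    }
  }
  mean(covered)
}

# Count occurrences of a pattern in a genome allowing 10% mismatches
# (independent of the package's matcher: plain substring hamming loop).
brute_count_hits <- function(pattern, seqstr, max_mm = floor(0.1 * nchar(pattern))) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  L <- length(pc)
  tot <- 0L
  for (s in seq_len(length(sc) - L + 1)) {
    if (sum(sc[s:(s + L - 1)] != pc) <= max_mm) tot <- tot + 1L
  }
  tot
}

# Simple genome tibble from a bare string.
as_genome <- function(seq, chrom = "chr1") {
  tibble::tibble(chrom = chrom, seq = seq, length = nchar(seq))
}

# Random DNA string under a local seed.
rand_dna <- function(n, seed, at = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# Build family tibbles straight from a simulation's truth table (used to
# test filtering and evolution stages independently of the miner).
families_from_truth <- function(sim, min_members = 1) {
  seqs <- stats::setNames(sim$genome$seq, sim$genome$chrom)
  tr <- sim$truth
  fams <- lapply(split(seq_len(nrow(tr)), tr$family_id), function(ix) {
    g <- tr[ix, ]
    mem <- tibble::tibble(
      chrom = g$chrom, start = g$start, end = g$end,
      tir_len = 10L, tsd_len = nchar(g$tsd),
      tir5 = NA_character_, tir3 = NA_character_, tsd = g$tsd,
      tir_mismatches = 0L,
      seq = substr(seqs[g$chrom], g$start + 1, g$end))
    tibble::tibble(family_id = g$family_id[1], n_members = nrow(mem),
                   representative = mem$seq[1], rep_index = 1L,
                   tir_len = 10L, tsd = mem$tsd[1], members = list(mem))
  })
  out <- dplyr::bind_rows(fams)
  out[out$n_members >= min_members, , drop = FALSE]
}

# Two-epoch haplotype sets for network-topology tests: a recent burst
# (dominant ancestral haplotype, few very young derivatives) versus an
# old expansion (every copy carries many private mutations).
simulate_burst_haplotypes <- function(n = 25, L = 120, k = 0.004, seed = 1) {
  set.seed(seed)
  master <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  vapply(seq_len(n), function(i) mutate_sequence(master, k)$seq, character(1))
}

simulate_old_expansion_haplotypes <- function(n = 14, L = 120, k = 0.08,
                                              seed = 1) {
  set.seed(seed)
  master <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  vapply(seq_len(n), function(i) mutate_sequence(master, k)$seq, character(1))
}
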