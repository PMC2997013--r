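# Structure-based MITE candidate detection and family clustering.
#
# Detection is seed-and-extend on inverted-repeat diagonals: exact
# seed words pair a position with a downstream occurrence of its reverse
# complement; every element span (start, end) on such a diagonal is then
# scored for a maximal terminal inverted repeat (TIR) under a mismatch
# budget, and accepted only if an exact target-site duplication (TSD)
# flanks the span on both sides.

#' Default parameters of the structural scan
#'
#' TIR length 8-50 bp, TSD length 2-30 bp, element length 100-600 bp,
#' seed word size 8, and at most 10\% TIR mismatches.
#'
#' @return a named list.
#' @export
default_scan_params <- function() {
  list(tir_min = 8L, tir_max = 50L, tsd_min = 2L, tsd_max = 30L,
       len_min = 100L, len_max = 600L, seed_word = 8L,
       max_tir_mismatch = 0.10)
}

# TIR acceptance at fixed (s, e, t) against a pairing match vector m
# (m[u] TRUE when element position u pairs with its mirror under
# complement). Rules: both boundary pairs match (no mismatch at either end
# of the inverted-repeat alignment); cumulative mismatches <=
# floor(rate * t); at least one run of `seed_word` consecutive matches
# (the word hit a seeded search needs). Returns the largest valid t.
max_tir_len <- function(m, tir_min, tir_max, rate, seed_word) {
  tmax <- min(length(m), tir_max)
  if (tmax < tir_min || !m[1]) return(list(t = 0L, mismatches = NA_integer_))
  mm <- cumsum(!m[seq_len(tmax)])
  best <- 0L
  run <- 0L
  longest_run <- integer(tmax)
  for (i in seq_len(tmax)) {
    run <- if (m[i]) run + 1L else 0L
    longest_run[i] <- max(if (i > 1) longest_run[i - 1] else 0L, run)
  }
  for (t in seq(tir_min, tmax)) {
    if (m[t] && mm[t] <= floor(rate * t) && longest_run[t] >= seed_word) {
      best <- t
    }
  }
  list(t = best, mismatches = if (best > 0) mm[best] else NA_integer_)
}

# Longest exact TSD flanking [s, e) (0-based half-open) in `chars`.
# Rejects homopolymer TSDs whose base run extends past the TSD on either
# side (poly-A style artifacts), and TSDs containing N.
find_tsd <- function(chars, s, e, tsd_min, tsd_max) {
  n <- length(chars)
  lmax <- min(tsd_max, s, n - e)
  if (lmax < tsd_min) return(NULL)
  for (L in seq(lmax, tsd_min)) {
    left <- chars[(s - L + 1):s]
    right <- chars[(e + 1):(e + L)]
    if (anyNA(match(left, BASES))) next
    if (!all(left == right)) next
    if (length(unique(left)) == 1) {
      b <- left[1]
      before <- if (s - L >= 1) chars[s - L] else ""
      after <- if (e + L < n) chars[e + L + 1] else ""
      if (identical(before, b) || identical(after, b)) next
    }
    return(list(tsd = paste(left, collapse = ""), len = L))
  }
  NULL
}

# Greedy shadow resolution: candidates sharing > 50% of the shorter span
# are resolved keeping the one with the most structural support
# (tir_len + tsd_len), then the longer TSD, then the leftmost start.
# Neither TIR length nor TSD length alone ranks correctly: identical TSD
# copies flanking an element always offer the span widened into the
# duplication a TIR longer by delta with an exact inner direct repeat of
# length TSD - 2*delta, while a palindromic substring inside the TIR
# offers a narrowed span a spurious long "TSD"; the sum dominates both
# artefacts for the true configuration.
resolve_shadows <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  ord <- order(-(cand$tir_len + cand$tsd_len), -cand$tsd_len,
               cand$start, cand$end)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (cand$chrom[i] != cand$chrom[j]) next
      ov <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j])
      if (ov > 0.5 * min(cand$end[i] - cand$start[i],
                         cand$end[j] - cand$start[j])) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

scan_one_sequence <- function(chrom, seqstr, p) {
  code <- encode_seq(seqstr)
  n <- length(code)
  if (n < p$len_min + 2 * p$tsd_min) {
    return(NULL)
  }
  w <- p$seed_word
  fw <- kmer_codes(code, w)
  rc <- kmer_codes_rc(code, w)
  ok_f <- !is.na(fw)
  ok_r <- !is.na(rc)

  # seed pairs: the word starting at i pairs (as reverse complement) with
  # the forward word starting at j, j downstream within the element span.
  # Each pair fixes one inverted-repeat diagonal d = s + e (0-based).
  r_tbl <- tibble(code = rc[ok_r], i = which(ok_r))
  f_tbl <- tibble(code = fw[ok_f], j = which(ok_f))
  joined <- dplyr::inner_join(r_tbl, f_tbl, by = "code",
                              relationship = "many-to-many")
  gap <- joined$j - joined$i
  joined <- joined[gap >= w & gap <= p$len_max - w, , drop = FALSE]
  if (nrow(joined) == 0) return(NULL)
  cand_diags <- unique(joined$i + joined$j + w - 2L)

  chars <- seq_chars(seqstr)
  comp_map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (d in cand_diags) {
    # spans [s, e) with s + e = d (0-based half-open); pairs (x, d - 1 - x)
    s_lo <- max(p$tsd_min, as.integer(ceiling((d - p$len_max) / 2)))
    s_hi <- (d - p$len_min) %/% 2L
    if (s_hi < s_lo) next
    x_lo <- max(s_lo, d - n)
    x_hi <- min((d - 2L) %/% 2L, s_hi + p$tir_max - 1L)
    if (x_hi < x_lo) next
    xs <- x_lo:x_hi
    a <- chars[xs + 1L]
    b <- chars[d - xs]
    m_diag <- a == unname(comp_map[b])
    m_diag[is.na(m_diag)] <- FALSE
    for (s in s_lo:s_hi) {
      e <- d - s
      if (e + p$tsd_min > n) next
      len <- e - s
      tcap <- min(p$tir_max, len %/% 2L)
      if (tcap < p$tir_min) next
      i1 <- s - x_lo + 1L
      if (i1 < 1 || i1 > length(m_diag) || !m_diag[i1]) next
      m <- m_diag[i1:min(i1 + tcap - 1L, length(m_diag))]
      if (length(m) < p$tir_min) next
      tt <- max_tir_len(m, p$tir_min, min(tcap, length(m)),
                        p$max_tir_mismatch, p$seed_word)
      if (tt$t == 0) next
      elem <- chars[(s + 1):e]
      if (any(!elem %in% BASES)) next
      tsd <- find_tsd(chars, s, e, p$tsd_min, p$tsd_max)
      if (is.null(tsd)) next
      out[[length(out) + 1]] <- tibble(
        chrom = chrom, start = s, end = e,
        tir_len = tt$t, tsd_len = tsd$len,
        tir5 = paste(chars[(s + 1):(s + tt$t)], collapse = ""),
        tir3 = paste(chars[(e - tt$t + 1):e], collapse = ""),
        tsd = tsd$tsd, tir_mismatches = tt$mismatches,
        seq = paste(elem, collapse = ""))
    }
  }
  if (length(out) == 0) return(NULL)
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Scan a genome for structural MITE candidates
#'
#' Finds element spans carrying a terminal inverted repeat (8-50 bp, at
#' most 10\% mismatches by default, seed-word anchored) flanked on both
#' sides by an identical exact target-site duplication (2-30 bp), with
#' element length 100-600 bp and no undetermined base inside the element.
#' Overlapping candidates sharing more than half their span are resolved
#' deterministically (greatest TIR+TSD length, then longer TSD, then
#' leftmost). The
#' scan works on the forward strand; an inverted-repeat element presents
#' the same structure on either strand.
#'
#' @param genome genome tibble (`chrom`, `seq`) from [read_genome_fasta()]
#'   or [simulate_genome()].
#' @param params scan parameters, see [default_scan_params()].
#' @param resolve apply shadow resolution (`FALSE` returns every raw
#'   candidate span).
#' @return a tibble of candidates: `chrom`, `start`, `end` (0-based
#'   half-open, TSD excluded), `tir_len`, `tsd_len`, `tir5`, `tir3`,
#'   `tsd`, `tir_mismatches`, `seq`; ordered by coordinate.
#' @export
scan_mite_candidates <- function(genome, params = default_scan_params(),
                                 resolve = TRUE) {
  stopifnot(all(c("chrom", "seq") %in% names(genome)))
  res <- purrr::map2(genome$chrom, genome$seq,
                     function(ch, sq) scan_one_sequence(ch, sq, params))
  res <- dplyr::bind_rows(res[!vapply(res, is.null, logical(1))])
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  tir_len = integer(), tsd_len = integer(),
                  tir5 = character(), tir3 = character(), tsd = character(),
                  tir_mismatches = integer(), seq = character()))
  }
  if (!resolve) {
    return(res[order(res$chrom, res$start, res$end), , drop = FALSE])
  }
  resolve_shadows(res)
}

#' Global-alignment identity between two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1 and
#' a linear gap penalty of -2; identity is the number of matching columns
#' divided by the alignment length.
#'
#' @param a,b nucleotide strings.
#' @return identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("AAAA", "AAAT") # 0.75
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("pairwise_identity(): empty sequence.",
          class = "mitescan_undefined_input")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  sum(pa == sa & pa != "-") / length(pa)
}

#' Cluster MITE candidates into families
#'
#' Single-linkage components of the graph whose edges connect candidate
#' pairs with global identity above `min_identity`; components with fewer
#' than `min_members` candidates are dropped. The family representative is
#' the member whose length is closest to the component's median length
#' (ties: lowest coordinate).
#'
#' @param candidates candidate tibble from [scan_mite_candidates()].
#' @param min_identity identity threshold (edge if identity > threshold).
#' @param min_members minimum family size.
#' @return a tibble with one row per family: `family_id`, `n_members`,
#'   `representative` (sequence), `rep_index` (row in `members`),
#'   `tir_len`, `tsd` (modal TSD), and a list-column `members` of the
#'   member candidate rows.
#' @export
cluster_mite_families <- function(candidates, min_identity = 0.8,
                                  min_members = 3) {
  n <- nrow(candidates)
  if (n == 0) {
    return(tibble(family_id = character(), n_members = integer(),
                  representative = character(), rep_index = integer(),
                  tir_len = integer(), tsd = character(), members = list()))
  }
  # cluster over unique sequences; duplicates rejoin their exemplar
  uniq <- match(candidates$seq, candidates$seq)
  ex <- sort(unique(uniq))
  nu <- length(ex)
  parent <- seq_len(nu)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  useq <- candidates$seq[ex]
  lens <- nchar(useq)
  # shared-word prescreen: sequences related above the identity threshold
  # share exact 10-mers with near-certainty, random pairs rarely do
  words <- purrr::map(useq, function(s) {
    unique(stats::na.omit(kmer_codes(encode_seq(s), 10L)))
  })
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (i in seq_len(max(nu - 1, 0))) {
    js <- (i + 1):nu
    js <- js[pmin(lens[i], lens[js]) / pmax(lens[i], lens[js]) > min_identity]
    js <- js[vapply(js, function(j) find(j) != find(i), logical(1))]
    js <- js[vapply(js, function(j) any(words[[i]] %in% words[[j]]),
                    logical(1))]
    if (length(js) == 0) next
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(useq[js]), useq[i], type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    pa <- as.character(Biostrings::alignedPattern(alns))
    sa <- as.character(Biostrings::alignedSubject(alns))
    idents <- vapply(seq_along(js), function(z) {
      p <- seq_chars(pa[z]); s <- seq_chars(sa[z])
      sum(p == s & p != "-") / length(p)
    }, numeric(1))
    for (z in which(idents > min_identity)) {
      parent[find(js[z])] <- find(i)
    }
  }
  comp_u <- vapply(seq_len(nu), find, integer(1))
  comp <- comp_u[match(uniq, ex)]
  groups <- split(seq_len(n), comp)
  groups <- groups[lengths(groups) >= min_members]
  if (length(groups) == 0) {
    return(tibble(family_id = character(), n_members = integer(),
                  representative = character(), rep_index = integer(),
                  tir_len = integer(), tsd = character(), members = list()))
  }
  # deterministic family order: by first member coordinate
  first_pos <- vapply(groups, function(g) {
    min(candidates$start[g] + 1e9 * match(candidates$chrom[g],
                                          sort(unique(candidates$chrom))))
  }, numeric(1))
  groups <- groups[order(first_pos)]
  fams <- purrr::imap(groups, function(g, nm) {
    mem <- candidates[g, , drop = FALSE]
    med <- stats::median(nchar(mem$seq))
    dist <- abs(nchar(mem$seq) - med)
    ri <- which(dist == min(dist))
    ri <- ri[order(mem$chrom[ri], mem$start[ri])][1]
    tsd_mode <- names(sort(table(mem$tsd), decreasing = TRUE))[1]
    tibble(n_members = nrow(mem), representative = mem$seq[ri],
           rep_index = ri, tir_len = mem$tir_len[ri], tsd = tsd_mode,
           members = list(mem))
  })
  out <- dplyr::bind_rows(fams)
  out <- dplyr::mutate(out, family_id = sprintf("FAM%03d", dplyr::row_number()),
                       .before = 1)
  out
}
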