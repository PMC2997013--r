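# Genome-wide homology census: seed-and-extend local alignment of a
# family representative against both strands, identity/coverage
# filtering, intact vs fragmentary calling from TIR coverage, and
# TSD/TIR-based superfamily classification.

# Exact seed hits of all w-words of `qcode` in `gcode`; returns tibble
# (qpos, gpos), 1-based.
seed_hits <- function(qcode, gcode, w) {
  qw <- kmer_codes(qcode, w)
  gw <- kmer_codes(gcode, w)
  q_tbl <- tibble(code = qw[!is.na(qw)], qpos = which(!is.na(qw)))
  g_tbl <- tibble(code = gw[!is.na(gw)], gpos = which(!is.na(gw)))
  dplyr::inner_join(q_tbl, g_tbl, by = "code",
                    relationship = "many-to-many")[, c("qpos", "gpos")]
}

# Cluster projected hit starts (gpos - qpos) into windows to align.
hit_windows <- function(hits, rep_len, seq_len, pad = 25L) {
  proj <- sort(unique(hits$gpos - hits$qpos + 1L))
  grp <- cumsum(c(TRUE, diff(proj) > 40L))
  out <- tibble(proj = proj, grp = grp)
  out <- dplyr::summarise(dplyr::group_by(out, .data$grp),
                          lo = min(.data$proj), hi = max(.data$proj))
  tibble(start = pmax(1L, out$lo - pad),
         end = pmin(seq_len, out$hi + rep_len - 1L + pad))
}

align_stats <- function(aln) {
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  list(pa = pa, sa = sa,
       matches = sum(pa == sa & pa != "-"),
       alen = length(pa),
       p_start = Biostrings::start(Biostrings::pattern(aln)),
       p_end = Biostrings::end(Biostrings::pattern(aln)),
       s_start = Biostrings::start(Biostrings::subject(aln)),
       s_end = Biostrings::end(Biostrings::subject(aln)),
       score = Biostrings::score(aln))
}

#' Intact call for an aligned census hit
#'
#' A copy is intact when both TIR spans of the representative are fully
#' covered by the alignment and each TIR aligns at or above
#' `min_tir_identity` (gap columns count as mismatches).
#'
#' @param aligned_pattern,aligned_subject aligned strings (equal length,
#'   `-` for gaps), pattern = representative.
#' @param p_start,p_end first/last representative position covered by the
#'   alignment (1-based).
#' @param rep_len representative length.
#' @param tir_len TIR length on the representative.
#' @param min_tir_identity per-TIR identity threshold.
#' @return `TRUE`/`FALSE`.
#' @export
classify_intact <- function(aligned_pattern, aligned_subject, p_start, p_end,
                            rep_len, tir_len, min_tir_identity = 0.9) {
  if (p_start > 1 || p_end < rep_len) return(FALSE)
  pa <- seq_chars(aligned_pattern)
  sa <- seq_chars(aligned_subject)
  # map alignment columns to representative positions
  ppos <- cumsum(pa != "-") + p_start - 1L
  ppos[pa == "-"] <- NA_integer_
  tir_id <- function(lo, hi) {
    cols <- which(!is.na(ppos) & ppos >= lo & ppos <= hi)
    # include gap columns interior to the TIR span as mismatch columns
    if (length(cols) == 0) return(0)
    span <- min(cols):max(cols)
    sum(pa[span] == sa[span] & pa[span] != "-") / length(span)
  }
  tir_id(1L, tir_len) >= min_tir_identity &&
    tir_id(rep_len - tir_len + 1L, rep_len) >= min_tir_identity
}

#' Homology census of one representative against a genome
#'
#' Seed-and-extend local alignment (exact seed words, Smith-Waterman
#' extension with match +1, mismatch -1, gap open 2 / extend 1) on both
#' strands. Hits must exceed `min_identity` (matches / alignment length)
#' and `min_coverage` (aligned representative fraction) and span at least
#' `min_aln_len` aligned columns. Hits overlapping by more than half of
#' the shorter span are deduplicated keeping the best score, then the
#' leftmost.
#'
#' @param genome genome tibble.
#' @param representative representative sequence (100-600 bp).
#' @param min_identity,min_coverage census thresholds (strict `>`).
#' @param tir_len TIR length of the family on the representative (for the
#'   intact call); `NULL` skips intact calling.
#' @param min_aln_len minimum alignment length in columns.
#' @param seed_word exact seed word size.
#' @return tibble of copies: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `coverage`, `score`, `intact`.
#' @export
homology_search <- function(genome, representative, min_identity = 0.90,
                            min_coverage = 0.80, tir_len = NULL,
                            min_aln_len = 50L, seed_word = 12L) {
  rep_len <- nchar(representative)
  if (rep_len < 100 || rep_len > 600) {
    abort("homology_search(): representative length must be in [100, 600].",
          class = "mitescan_parameter_error")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  qcode <- encode_seq(representative)
  hits_all <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    n <- nchar(genome$seq[ci])
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") genome$seq[ci] else revcomp(genome$seq[ci])
      gcode <- encode_seq(sseq)
      hits <- seed_hits(qcode, gcode, seed_word)
      if (nrow(hits) == 0) next
      wins <- hit_windows(hits, rep_len, n)
      for (wi in seq_len(nrow(wins))) {
        wseq <- substr(sseq, wins$start[wi], wins$end[wi])
        aln <- Biostrings::pairwiseAlignment(representative, wseq,
                                             type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 2, gapExtension = 1)
        st <- align_stats(aln)
        identity <- st$matches / st$alen
        coverage <- (st$p_end - st$p_start + 1) / rep_len
        if (st$alen < min_aln_len || identity <= min_identity ||
            coverage <= min_coverage) next
        # strand-local coordinates -> forward-strand 0-based half-open
        ls <- wins$start[wi] + st$s_start - 2L  # 0-based
        le <- wins$start[wi] + st$s_end - 1L
        if (strand == "+") {
          gs <- ls; ge <- le
        } else {
          gs <- n - le; ge <- n - ls
        }
        intact <- if (!is.null(tir_len)) {
          # Local alignment trims terminal mismatch columns; re-extend
          # ungapped to the representative ends (where the subject window
          # has sequence) so the TIR-span intact rule sees the full TIRs.
          pa <- as.character(Biostrings::alignedPattern(aln))
          sa <- as.character(Biostrings::alignedSubject(aln))
          p1 <- st$p_start; p2 <- st$p_end
          lpad <- p1 - 1L
          if (lpad > 0 && st$s_start - 1L >= lpad) {
            pa <- paste0(substr(representative, 1, lpad), pa)
            sa <- paste0(substr(wseq, st$s_start - lpad, st$s_start - 1L), sa)
            p1 <- 1L
          }
          rpad <- rep_len - p2
          if (rpad > 0 && nchar(wseq) - st$s_end >= rpad) {
            pa <- paste0(pa, substr(representative, p2 + 1L, rep_len))
            sa <- paste0(sa, substr(wseq, st$s_end + 1L, st$s_end + rpad))
            p2 <- rep_len
          }
          classify_intact(pa, sa, p1, p2, rep_len, tir_len)
        } else NA
        hits_all[[length(hits_all) + 1]] <- tibble(
          chrom = chrom, start = as.integer(gs), end = as.integer(ge),
          strand = strand, identity = identity, coverage = coverage,
          score = st$score, intact = intact)
      }
    }
  }
  if (length(hits_all) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), identity = numeric(),
                  coverage = numeric(), score = numeric(), intact = logical()))
  }
  out <- dplyr::bind_rows(hits_all)
  out <- dplyr::distinct(out)
  # overlap dedup, best score first then leftmost
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  kept <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (out$chrom[i] != out$chrom[j]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
      if (ov > 0.5 * min(out$end[i] - out$start[i],
                         out$end[j] - out$start[j])) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  out <- out[kept, , drop = FALSE]
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Census all families against a genome
#'
#' Runs [homology_search()] for every family representative and binds the
#' per-family copy tables.
#'
#' @param families family tibble from [cluster_mite_families()] (or any
#'   tibble with `family_id`, `representative`, `tir_len`).
#' @param genome genome tibble.
#' @param ... passed to [homology_search()].
#' @return tibble of copies with a `family_id` column.
#' @export
census_families <- function(families, genome, ...) {
  res <- purrr::map2(families$family_id, seq_len(nrow(families)),
                     function(fid, i) {
    cp <- homology_search(genome, families$representative[i],
                          tir_len = families$tir_len[i], ...)
    if (nrow(cp) > 0) cp$family_id <- fid
    cp
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) out <- dplyr::relocate(out, "family_id")
  out
}

#' Position-wise degenerate consensus of observed TSD instances
#'
#' Reduces a set of equal-length TSD strings to a motif over
#' `ACGT`, `W` (A/T), `D` (A/G/T) and `N`. Instances whose length differs
#' from the modal length are ignored.
#'
#' @param tsds character vector of TSD instances.
#' @return motif string.
#' @export
tsd_motif_consensus <- function(tsds) {
  lens <- nchar(tsds)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  tsds <- tsds[lens == modal]
  mat <- do.call(rbind, strsplit(tsds, ""))
  reduce <- function(col) {
    u <- sort(unique(col[col %in% BASES]))
    if (length(u) == 1) return(u)
    if (setequal(u, c("A", "T"))) return("W")
    if (setequal(u, c("A", "G", "T"))) return("D")
    "N"
  }
  paste(apply(mat, 2, reduce), collapse = "")
}

# Does a concrete-or-degenerate TSD string match a degenerate pattern?
# Every position's observed base set must be contained in the pattern's.
motif_matches <- function(x, pattern) {
  if (nchar(x) != nchar(pattern)) return(FALSE)
  sets <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
               D = c("A", "G", "T"), N = BASES)
  xs <- seq_chars(x)
  ps <- seq_chars(pattern)
  all(vapply(seq_along(xs), function(i) {
    all(sets[[xs[i]]] %in% sets[[ps[i]]])
  }, logical(1)))
}

#' Default superfamily classification rules
#'
#' TSD `TA` diagnoses Stowaway-like families; `TWA`/`TDA` Tourist-like;
#' an 8-bp nonspecific TSD combined with a TIR whose head matches the
#' `CAGTGGCGGAT` motif class at >= 80% identity diagnoses Pegasus-like.
#' Anything else is novel.
#'
#' @return tibble of ordered rules (first match wins).
#' @export
default_superfamily_rules <- function() {
  tibble::tribble(
    ~rule_id,        ~tsd_pattern, ~tir_head,      ~min_tir_identity, ~label,
    "stowaway_tsd",  "TA",         NA,             NA,                "Stowaway-like",
    "tourist_twa",   "TWA",        NA,             NA,                "Tourist-like",
    "tourist_tda",   "TDA",        NA,             NA,                "Tourist-like",
    "pegasus_8bp",   "NNNNNNNN",   "CAGTGGCGGAT",  0.8,               "Pegasus-like"
  )
}

#' Classify a family into a MITE superfamily
#'
#' Applies the first matching rule of `rules` to the family's TSD motif
#' (and, where the rule requires it, the head of its TIR consensus).
#'
#' @param tsd_motif TSD motif (concrete instance or degenerate motif).
#' @param tir_consensus TIR consensus sequence.
#' @param rules rules tibble, see [default_superfamily_rules()].
#' @return a list with `label` and `rule_id` (`NA` rule for novel).
#' @export
#' @examples
#' classify_superfamily("TA", "GATATGTGTCGTTCG")$label      # Stowaway-like
#' classify_superfamily("TWA", "GGGCCTGTGC")$label          # Tourist-like
#' classify_superfamily("ATATAT", "GTGGGATT")$label         # novel
classify_superfamily <- function(tsd_motif, tir_consensus,
                                 rules = default_superfamily_rules()) {
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (!motif_matches(tsd_motif, r$tsd_pattern)) next
    if (!is.na(r$tir_head)) {
      head_len <- nchar(r$tir_head)
      if (nchar(tir_consensus) < head_len) next
      a <- seq_chars(substr(tir_consensus, 1, head_len))
      b <- seq_chars(r$tir_head)
      if (mean(a == b) < r$min_tir_identity) next
    }
    return(list(label = r$label, rule_id = r$rule_id))
  }
  list(label = "novel", rule_id = NA_character_)
}

#' Per-family census summary (published-table shaped)
#'
#' Summarises a copy table into the per-family layout of the published
#' family census: copy counts split intact/fragmentary, the full-length
#' percentage, AT content, the TSD motif consensus and the superfamily
#' label.
#'
#' @param copies copy tibble from [census_families()] (needs `family_id`,
#'   `intact`, and copy sequences via `genome`).
#' @param families family tibble (for TSD and TIR).
#' @param genome genome tibble (to extract copy sequences for AT content).
#' @return one row per family.
#' @export
census_summary <- function(copies, families, genome) {
  seqs <- stats::setNames(genome$seq, genome$chrom)
  per_fam <- dplyr::group_by(copies, .data$family_id)
  out <- dplyr::summarise(
    per_fam,
    n_total = dplyr::n(),
    n_intact = sum(.data$intact, na.rm = TRUE),
    n_fragmentary = sum(!.data$intact, na.rm = TRUE),
    at_content_pct = as.integer(round_half_away(100 * mean(vapply(
      seq_len(dplyr::n()),
      function(i) at_content(substr(seqs[[.data$chrom[i]]],
                                    .data$start[i] + 1L, .data$end[i])),
      numeric(1))))),
    .groups = "drop"
  )
  out$full_length_pct <- full_length_pct(out$n_fragmentary, out$n_intact)
  fam_idx <- match(out$family_id, families$family_id)
  out$tsd_motif <- vapply(fam_idx, function(i) {
    tsd_motif_consensus(families$members[[i]]$tsd)
  }, character(1))
  out$tir <- vapply(fam_idx, function(i) {
    substr(families$representative[i], 1, families$tir_len[i])
  }, character(1))
  cls <- purrr::map2(out$tsd_motif, out$tir, classify_superfamily)
  out$superfamily <- vapply(cls, `[[`, character(1), "label")
  out
}
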