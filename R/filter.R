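# Pseudo-MITE filtering: three artifact classes are flagged per member
# (undetermined bases, simple-repeat composition, nested-in-repeat
# context) and families in which flagged members dominate are rejected.

#' Does a sequence contain undetermined bases?
#'
#' @param seq character vector of nucleotide strings.
#' @return logical vector: `TRUE` iff the sequence contains at least one N.
#' @export
has_undetermined <- function(seq) {
  grepl("N", seq, fixed = TRUE)
}

#' Is a sequence essentially a tandem simple repeat?
#'
#' A sequence is called simple when at least `min_cover` of its positions
#' lie inside maximal exact tandem repeats of period at most `max_period`
#' (at least two full unit copies). Runs are detected by exact
#' self-overlap at each period and scored greedily longest-first.
#'
#' @param seq nucleotide string (length >= 20).
#' @param min_cover minimum covered fraction.
#' @param max_period maximum repeat period.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' is_simple_repeat(strrep("AT", 10))  # TRUE
#' is_simple_repeat(strrep("ACG", 100)) # TRUE
is_simple_repeat <- function(seq, min_cover = 0.8, max_period = 6) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 20) {
    abort("is_simple_repeat(): sequence shorter than 20 bp.",
          class = "mitescan_undefined_input")
  }
  runs <- list()
  for (p in seq_len(max_period)) {
    if (n < 2 * p) next
    eq <- chars[(p + 1):n] == chars[1:(n - p)]   # self-overlap at lag p
    eq[is.na(eq)] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (z in which(r$values & r$lengths >= p)) {
      # run of matches of length m at lag p covers m + p positions
      runs[[length(runs) + 1]] <-
        c(start = starts[z], len = r$lengths[z] + p, period = p)
    }
  }
  if (length(runs) == 0) return(FALSE)
  runs <- do.call(rbind, runs)
  runs <- runs[order(-runs[, "len"]), , drop = FALSE]
  covered <- logical(n)
  for (i in seq_len(nrow(runs))) {
    covered[runs[i, "start"]:(runs[i, "start"] + runs[i, "len"] - 1)] <- TRUE
  }
  mean(covered) >= min_cover
}

#' Is a candidate nested inside a high-copy repeat?
#'
#' `TRUE` iff both `flank`-bp genomic flanks of the candidate each occur
#' more than `max_flank_hits` times in the genome at >= 90% identity
#' (counted by exact seed words plus a mismatch-tolerant full-window
#' comparison). A candidate at a sequence edge with a missing flank
#' returns `FALSE`.
#'
#' @param candidate one-row candidate tibble (`chrom`, `start`, `end`).
#' @param genome genome tibble.
#' @param flank flank width in bp.
#' @param max_flank_hits occurrence threshold.
#' @return `TRUE`/`FALSE`.
#' @export
is_nested_in_repeat <- function(candidate, genome, flank = 50,
                                max_flank_hits = 20) {
  ch <- genome[genome$chrom == candidate$chrom, ]
  if (nrow(ch) != 1) {
    abort("is_nested_in_repeat(): candidate chromosome not in genome.",
          class = "mitescan_parameter_error")
  }
  n <- nchar(ch$seq)
  s <- candidate$start
  e <- candidate$end
  if (s - flank < 0 || e + flank > n) return(FALSE)
  left <- substr(ch$seq, s - flank + 1, s)
  right <- substr(ch$seq, e + 1, e + flank)
  count_hits <- function(pat) {
    tot <- 0L
    for (i in seq_len(nrow(genome))) {
      subj <- Biostrings::DNAString(gsub("[^ACGTN]", "N", genome$seq[i]))
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = floor(0.1 * flank),
                                    with.indels = FALSE)
      tot <- tot + length(m)
    }
    tot
  }
  count_hits(left) > max_flank_hits && count_hits(right) > max_flank_hits
}

#' Filter pseudo-MITE families
#'
#' Evaluates the three pseudo-element flags for every family member and
#' rejects a family when more than half of its members carry at least one
#' flag. Per-member flags are retained in the report either way.
#'
#' @param families family tibble from [cluster_mite_families()].
#' @param genome genome tibble (needed for the nested-in-repeat flag;
#'   omit to skip that flag).
#' @param max_member_fraction a family is pseudo when the flagged-member
#'   fraction exceeds this value (default 0.5).
#' @return a list with `kept` (family tibble), `rejected` (family tibble
#'   with a `reject_reason`), and `report` (per-member tibble of flags).
#' @export
filter_mite_families <- function(families, genome = NULL,
                                 max_member_fraction = 0.5) {
  if (nrow(families) == 0) {
    return(list(kept = families, rejected = families[0, ],
                report = tibble(family_id = character(),
                                chrom = character(), start = integer(),
                                end = integer(), has_N = logical(),
                                simple_repeat = logical(),
                                nested_in_repeat = logical(),
                                flagged = logical())))
  }
  reports <- purrr::map2(families$family_id, families$members, function(fid, mem) {
    has_n <- has_undetermined(mem$seq)
    simple <- vapply(mem$seq, function(s) is_simple_repeat(s), logical(1),
                     USE.NAMES = FALSE)
    nested <- if (!is.null(genome)) {
      vapply(seq_len(nrow(mem)), function(i) {
        is_nested_in_repeat(mem[i, ], genome)
      }, logical(1))
    } else rep(FALSE, nrow(mem))
    tibble(family_id = fid, chrom = mem$chrom, start = mem$start,
           end = mem$end, has_N = has_n, simple_repeat = simple,
           nested_in_repeat = nested,
           flagged = has_n | simple | nested)
  })
  report <- dplyr::bind_rows(reports)
  frac <- vapply(reports, function(r) mean(r$flagged), numeric(1))
  reject <- frac > max_member_fraction
  rejected <- families[reject, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reject_reason <- vapply(which(reject), function(i) {
      r <- reports[[i]]
      flags <- c(has_N = mean(r$has_N), simple_repeat = mean(r$simple_repeat),
                 nested_in_repeat = mean(r$nested_in_repeat))
      paste0(names(which.max(flags)), " (",
             round(100 * max(flags)), "% of members)")
    }, character(1))
  }
  list(kept = families[!reject, , drop = FALSE], rejected = rejected,
       report = report)
}
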