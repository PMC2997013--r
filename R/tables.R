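#' Published per-family census of the 17 silkworm MITE families
#'
#' Packaged fixture mirroring the published family table for the silkworm
#' (Bombyx mori) MITE complement: per family, the TSD motif, TIR sequence,
#' consensus size, AT content, the number of fragmentary copies (`n_fragmentary`),
#' the number of full-length (intact) copies (`n_full_length`) with the printed
#' full-length percentage, and the superfamily/known-family label. Degenerate
#' TSD letters follow IUPAC (W = A/T, D = A/G/T, N = any).
#'
#' @return a tibble with one row per family.
#' @export
#' @examples
#' fam <- silkworm_family_table()
#' sum(fam$n_fragmentary) + sum(fam$n_full_length)
silkworm_family_table <- function() {
  tibble::tribble(
    ~family_id,   ~tsd_motif,  ~tir,                                                         ~size_bp, ~at_content_pct, ~n_fragmentary, ~n_full_length, ~full_length_pct_printed, ~known_family,
    "BmMITE-1",   "WW",        "TCGATGGCTCCAATGAACACTAC",                                    234L,     68L,             216L,           44L,            17L,                      "Novel",
    "BmMITE-2",   "TA",        "TGAGTCGACTATTATCAAAG",                                       278L,     67L,             419L,           2371L,          85L,                      "Hoshidandy",
    "BmMITE-3",   "TA",        "GATATGTGTCGTTCG",                                            306L,     54L,             12L,            34L,            74L,                      "Stowaway-like",
    "BmMITE-4",   "TWA",       "GGGTCAATTCCCACTGAAAGAGCAGCGGC",                              567L,     44L,             9L,             7L,             44L,                      "Tourist-like",
    "BmMITE-5",   "TWA",       "AGCCTTGTTCGCACTAAGCGAGTATTTTAGTCGAGTACCGAGTAATTTAGTGGCTAAA", 213L,     61L,             53L,            81L,            60L,                      "Tourist-like",
    "BmMITE-6",   "TWA",       "GGGCCTGTGCACACCACGTTTTTTAA",                                 270L,     52L,             11L,            8L,             42L,                      "Tourist-like",
    "BmMITE-7",   "TDA",       "TGCTGGAACCACACTGCG",                                         548L,     55L,             7L,             13L,            65L,                      "Organdy",
    "BmMITE-8",   "TA",        "TATATCGACGCTTGAAAGGCAAAC",                                   266L,     67L,             1364L,          147L,           10L,                      "Stowaway-like",
    "BmMITE-9",   "ATT",       "GGTAGTTTTCCAATTACAG",                                        418L,     63L,             75L,            88L,            54L,                      "Novel",
    "BmMITE-10",  "ATAT",      "CGTCGCTGTCAAACCAAAATCTGCTATGTGCAA",                          258L,     70L,             142L,           159L,           53L,                      "Novel",
    "BmMITE-11",  "ATATAT",    "GTGGGATT",                                                   238L,     67L,             1L,             15L,            94L,                      "Novel",
    "BmMITE-12",  "TTCATTT",   "TTACTTTGCA",                                                 210L,     73L,             20L,            121L,           86L,                      "Novel",
    "BmMITE-13",  "NNNNNNNN",  "CAAGGGCGGATCCAG",                                            263L,     59L,             69L,            171L,           71L,                      "Pegasus-like",
    "BmMITE-14",  "NNNNNNNN",  "CAGTGGCGGATTA",                                              431L,     59L,             12L,            22L,            65L,                      "Pegasus-like",
    "BmMITE-15",  "NNNNNNNN",  "CAGTGGCGTACCTA",                                             300L,     65L,             0L,             9L,             100L,                     "Pegasus-like",
    "BmMITE-16",  "NNNNNNNN",  "CAGTGGCGGATTT",                                              265L,     55L,             18L,            25L,            58L,                      "Pegasus-like",
    "BmMITE-17",  "TTACTGTAT", "GCGCGCGAGTTCATGT",                                           494L,     59L,             20L,            22L,            52L,                      "Novel"
  )
}

#' Published insertion-site categories of the silkworm MITE copies
#'
#' Packaged fixture mirroring the published per-family insertion-site
#' table: copies analysed per family, counts by category (5'-flank < 5 kb,
#' exon, intron, 3'-flank < 5 kb) and the printed gene-region total, plus the
#' published genome-wide `Total` row and the randomised-insertion `Control`
#' row (n = 5000). Values are stored verbatim as printed, including the two
#' rows whose printed total differs from the sum of the category columns
#' (see [table_consistency_report()]).
#'
#' @param include_summary_rows include the `Total` and `Control` rows
#'   (default `TRUE`).
#' @return a tibble with one row per family (plus summary rows).
#' @export
silkworm_insertion_table <- function(include_summary_rows = TRUE) {
  tbl <- tibble::tribble(
    ~family_id,  ~n_copies, ~flank5, ~exon, ~intron, ~flank3, ~in_gene_region_printed,
    "BmMITE-1",  260L,      38L,     3L,    53L,     61L,     155L,
    "BmMITE-2",  2790L,     482L,    15L,   651L,    643L,    1791L,
    "BmMITE-3",  46L,       12L,     0L,    16L,     15L,     43L,
    "BmMITE-4",  16L,       2L,      2L,    3L,      8L,      15L,
    "BmMITE-5",  134L,      22L,     8L,    26L,     25L,     81L,
    "BmMITE-6",  19L,       3L,      4L,    6L,      3L,      16L,
    "BmMITE-7",  20L,       4L,      0L,    8L,      4L,      16L,
    "BmMITE-8",  1511L,     225L,    23L,   431L,    365L,    1044L,
    "BmMITE-9",  163L,      40L,     0L,    26L,     58L,     124L,
    "BmMITE-10", 301L,      32L,     0L,    96L,     57L,     185L,
    "BmMITE-11", 16L,       1L,      0L,    2L,      3L,      6L,
    "BmMITE-12", 141L,      18L,     0L,    16L,     21L,     55L,
    "BmMITE-13", 240L,      54L,     2L,    42L,     49L,     147L,
    "BmMITE-14", 34L,       7L,      0L,    16L,     7L,      30L,
    "BmMITE-15", 9L,        5L,      1L,    1L,      2L,      11L,
    "BmMITE-16", 43L,       14L,     1L,    9L,      10L,     34L,
    "BmMITE-17", 42L,       3L,      1L,    25L,     12L,     41L,
    "Total",     5785L,     962L,    60L,   1427L,   1343L,   3794L,
    "Control",   5000L,     712L,    152L,  453L,    653L,    1970L
  )
  if (!include_summary_rows) {
    tbl <- tbl[!tbl$family_id %in% c("Total", "Control"), ]
  }
  tbl
}

#' Full-length percentage of a family census
#'
#' Integer percentage of full-length copies, `100 * FLC / (FC + FLC)`,
#' rounded half away from zero (the convention of the published family
#' table).
#'
#' @param n_fragmentary,n_full_length copy counts (vectors recycle).
#' @return integer percentage vector.
#' @export
#' @examples
#' full_length_pct(419, 2371) # 85
#' full_length_pct(0, 9)      # 100
full_length_pct <- function(n_fragmentary, n_full_length) {
  total <- n_fragmentary + n_full_length
  if (any(total <= 0)) {
    abort("full_length_pct(): family with zero copies.",
          class = "mitescan_undefined_input")
  }
  as.integer(round_half_away(100 * n_full_length / total))
}

#' Gene-region percentage
#'
#' Integer percentage of copies falling in gene regions (gene body plus
#' 5 kb flanks), rounded half away from zero.
#'
#' @param in_region,total counts.
#' @return integer percentage vector.
#' @export
#' @examples
#' gene_region_pct(3794, 5785) # 66
gene_region_pct <- function(in_region, total) {
  if (any(total <= 0)) {
    abort("gene_region_pct(): zero total.", class = "mitescan_undefined_input")
  }
  as.integer(round_half_away(100 * in_region / total))
}

#' Consistency report over the packaged census tables
#'
#' Recomputes the arithmetic of the packaged family and insertion-site
#' tables: grand totals, per-family full-length percentages, gene-region
#' percentages, and row-sum checks. Printed values that disagree with the
#' recomputed sums are flagged rather than corrected (the published
#' insertion table contains two such rows).
#'
#' @param family_table per-family census fixture
#'   (default [silkworm_family_table()]).
#' @param insertion_table insertion-site fixture
#'   (default [silkworm_insertion_table()]).
#' @return a list with elements `totals` (one-row tibble: `total_copies`,
#'   `n_intact`, `n_fragmentary`, `gene_region_pct`), `family` (per-family
#'   tibble with recomputed `full_length_pct`), and `insertion` (per-row
#'   tibble with recomputed category sums and a `consistent` flag).
#' @export
table_consistency_report <- function(family_table = silkworm_family_table(),
                                     insertion_table = silkworm_insertion_table()) {
  fam <- dplyr::mutate(
    family_table,
    n_total = .data$n_fragmentary + .data$n_full_length,
    full_length_pct = full_length_pct(.data$n_fragmentary, .data$n_full_length)
  )
  fam$pct_matches_printed <-
    if ("full_length_pct_printed" %in% names(fam)) {
      fam$full_length_pct == fam$full_length_pct_printed
    } else NA

  ins <- dplyr::mutate(
    insertion_table,
    category_sum = .data$flank5 + .data$exon + .data$intron + .data$flank3,
    consistent = .data$category_sum == .data$in_gene_region_printed
  )

  fam_rows <- ins$family_id %in% c("Total", "Control") == FALSE
  total_copies <- sum(fam$n_total)
  total_row <- ins[ins$family_id == "Total", ]
  grp <- if (nrow(total_row) == 1) {
    gene_region_pct(total_row$in_gene_region_printed, total_row$n_copies)
  } else {
    gene_region_pct(sum(ins$in_gene_region_printed[fam_rows]),
                    sum(ins$n_copies[fam_rows]))
  }

  list(
    totals = tibble(
      total_copies = total_copies,
      n_intact = sum(fam$n_full_length),
      n_fragmentary = sum(fam$n_fragmentary),
      gene_region_pct = grp
    ),
    family = fam,
    insertion = ins
  )
}
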