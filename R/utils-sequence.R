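#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Base ordering used for every lexicographic tie-break in the package.
BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' N is preserved; input must already be normalised to `ACGTN`.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

# Integer encoding A=0 C=1 G=2 T=3, NA for anything else (i.e. N).
encode_seq <- function(x) {
  chars <- seq_chars(x)
  code <- match(chars, BASES) - 1L
  code
}

decode_seq <- function(code) {
  paste(BASES[code + 1L], collapse = "")
}

# Complement of the integer encoding (3 - code); NA propagates.
comp_code <- function(code) 3L - code

#' Normalise a nucleotide string to the ACGTN alphabet
#'
#' Upper-cases and maps every character outside `ACGT` (IUPAC ambiguity
#' codes included) to `N`.
#'
#' @param x character vector.
#' @return character vector.
#' @export
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' AT content of a sequence
#'
#' Fraction (A+T)/(A+C+G+T); `N` is excluded from the denominator.
#'
#' @param seq character vector of nucleotide strings.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' at_content("AATT")
#' at_content("ATGC")
at_content <- function(seq) {
  vapply(seq, function(s) {
    chars <- seq_chars(toupper(s))
    acgt <- chars[chars %in% BASES]
    if (length(acgt) == 0) {
      abort("at_content(): sequence has no determined (ACGT) bases.",
            class = "mitescan_undefined_input")
    }
    mean(acgt %in% c("A", "T"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Rounding helper: round half away from zero (R's round() is banker's).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Rolling k-mer codes over an encoded sequence. Returns an integer-ish
# numeric vector of length n-w+1 (NA where the window touches an N).
kmer_codes <- function(code, w) {
  n <- length(code)
  if (n < w) return(numeric(0))
  out <- numeric(n - w + 1L)
  for (k in seq_len(w)) {
    out <- out + code[k:(n - w + k)] * 4^(w - k)
  }
  out
}

# Codes of the reverse complement of each w-window (as a forward word).
kmer_codes_rc <- function(code, w) {
  n <- length(code)
  if (n < w) return(numeric(0))
  out <- numeric(n - w + 1L)
  for (k in seq_len(w)) {
    out <- out + (3 - code[k:(n - w + k)]) * 4^(k - 1)
  }
  out
}
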