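#' Read a genome FASTA file
#'
#' Sequences are upper-cased and any character outside `ACGTN` (IUPAC
#' ambiguity codes included) is mapped to `N`. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `chrom`, `seq`, `length` (bp), one row per
#'   record.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("read_genome_fasta(): file not found: ", path),
          class = "mitescan_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(paste0("read_genome_fasta(): ", path,
                 ": empty file (no FASTA record at line 1)."),
          class = "mitescan_parse_error")
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("read_genome_fasta(): ", path, ": line ", first,
                 ": expected a FASTA header ('>'), got: ",
                 substr(lines[first], 1, 30)),
          class = "mitescan_parse_error")
  }
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0) {
    abort(paste0("read_genome_fasta(): ", path,
                 ": no records parsed (line ", first, ")."),
          class = "mitescan_parse_error")
  }
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- unname(normalize_seq(as.character(dss)))
  tibble(chrom = ids, seq = seqs, length = nchar(seqs))
}

#' Write a genome tibble to FASTA
#'
#' @param genome tibble with columns `chrom` and `seq`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(all(c("chrom", "seq") %in% names(genome)))
  dss <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$chrom))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Accepts `gene`, `mRNA`/`transcript` and `exon` features; exon `Parent`
#' attributes are resolved through transcripts to their gene. 1-based
#' inclusive GFF coordinates are converted to the package's internal
#' 0-based half-open convention. Genes without any exon feature receive a
#' single exon spanning the whole gene.
#'
#' @param path path to a GFF3 file.
#' @return a tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` and a list-column `exons` of tibbles
#'   with `start`/`end`.
#' @export
read_gene_gff3 <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("read_gene_gff3(): file not found: ", path),
          class = "mitescan_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("read_gene_gff3(): no feature lines found.",
          class = "mitescan_parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    abort(paste0("read_gene_gff3(): malformed feature line (", lines[bad[1]],
                 "): expected 9 tab-separated columns."),
          class = "mitescan_parse_error")
  }
  feat <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    type = vapply(fields, `[[`, "", 3),
    start1 = as.integer(vapply(fields, `[[`, "", 4)),
    end1 = as.integer(vapply(fields, `[[`, "", 5)),
    strand = vapply(fields, `[[`, "", 7),
    attrs = vapply(fields, `[[`, "", 9)
  )
  attr_val <- function(attrs, key) {
    m <- regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs)
    vapply(regmatches(attrs, m),
           function(g) if (length(g) >= 2) g[2] else NA_character_,
           character(1))
  }
  feat$id <- attr_val(feat$attrs, "ID")
  feat$parent <- attr_val(feat$attrs, "Parent")

  genes <- feat[feat$type == "gene", ]
  if (nrow(genes) == 0) {
    abort("read_gene_gff3(): no gene features found.",
          class = "mitescan_parse_error")
  }
  # Map transcript IDs to their gene so exon Parents resolve either way.
  tx <- feat[feat$type %in% c("mRNA", "transcript"), ]
  parent_of <- stats::setNames(tx$parent, tx$id)
  exons <- feat[feat$type == "exon", ]
  exon_gene <- ifelse(exons$parent %in% genes$id, exons$parent,
                      unname(parent_of[exons$parent]))
  if (nrow(exons) > 0 && anyNA(exon_gene)) {
    abort(paste0("read_gene_gff3(): exon with unresolvable Parent: ",
                 exons$attrs[which(is.na(exon_gene))[1]]),
          class = "mitescan_validation_error")
  }

  gene_rows <- purrr::pmap(
    list(genes$id, genes$chrom, genes$start1, genes$end1, genes$strand),
    function(gid, chrom, s1, e1, strand) {
      if (is.na(gid)) {
        abort("read_gene_gff3(): gene feature without an ID attribute.",
              class = "mitescan_validation_error")
      }
      if (!strand %in% c("+", "-")) {
        warn(paste0("read_gene_gff3(): gene ", gid,
                    " has strand '", strand, "'; defaulting to '+'."))
        strand <- "+"
      }
      ex <- exons[which(exon_gene == gid), ]
      if (nrow(ex) == 0) {
        ex_tbl <- tibble(start = s1 - 1L, end = e1)
      } else {
        ex_tbl <- tibble(start = ex$start1 - 1L, end = ex$end1)
        ex_tbl <- ex_tbl[order(ex_tbl$start), ]
        if (any(ex_tbl$start < s1 - 1L) || any(ex_tbl$end > e1)) {
          off <- which(ex_tbl$start < s1 - 1L | ex_tbl$end > e1)[1]
          abort(paste0("read_gene_gff3(): exon [",
                       ex_tbl$start[off] + 1L, ",", ex_tbl$end[off],
                       "] outside span of gene ", gid,
                       " [", s1, ",", e1, "]."),
                class = "mitescan_validation_error")
        }
        if (nrow(ex_tbl) > 1 &&
            any(ex_tbl$start[-1] < ex_tbl$end[-nrow(ex_tbl)])) {
          abort(paste0("read_gene_gff3(): overlapping exons in gene ", gid, "."),
                class = "mitescan_validation_error")
        }
      }
      tibble(gene_id = gid, chrom = chrom, start = s1 - 1L, end = e1,
             strand = strand, exons = list(ex_tbl))
    }
  )
  dplyr::bind_rows(gene_rows)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_gff3()]: internal 0-based half-open coordinates
#' are converted back to 1-based inclusive at the boundary. Each gene gets
#' one `mRNA` child carrying its exons.
#'
#' @param genes gene tibble as returned by [read_gene_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    tid <- paste0(g$gene_id, ".t1")
    writeLines(c(
      paste(g$chrom, "mitescan", "gene", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "mitescan", "mRNA", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", tid, ";Parent=", g$gene_id), sep = "\t"),
      paste(g$chrom, "mitescan", "exon", ex$start + 1L, ex$end, ".",
            g$strand, ".", paste0("Parent=", tid), sep = "\t")
    ), con)
  }
  invisible(path)
}

#' Write MITE copies as BED6
#'
#' Coordinates are emitted natively 0-based half-open. The score column
#' carries identity in per-mille (0-1000).
#'
#' @param copies tibble with `chrom`, `start`, `end`, `family_id`,
#'   `identity`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_copies_bed <- function(copies, path) {
  lines <- paste(copies$chrom, copies$start, copies$end, copies$family_id,
                 round(copies$identity * 1000), copies$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
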