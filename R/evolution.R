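# Per-family evolutionary analytics: center-star multiple alignment,
# majority consensus, Kimura two-parameter distances and insertion ages,
# sliding-window nucleotide diversity, and median-joining haplotype
# networks.

#' Center-star multiple alignment of family members
#'
#' Every member is globally aligned to the representative (match +1,
#' mismatch -1, linear gap -2); columns are merged on representative
#' coordinates, with insertion columns (relative to the representative)
#' padded with gaps in all other rows. Members are census-guaranteed
#' near-identical to the representative, where center-star alignment is
#' within known bounds of the optimum.
#'
#' @param seqs character vector of member sequences (named or not).
#' @param representative the center sequence (default: first member).
#' @return an object of class `mite_alignment`: list with `rows` (aligned
#'   strings, equal length), `ids`, and `col_ref` (representative position
#'   per column, `NA` for insertion columns).
#' @export
align_family <- function(seqs, representative = NULL) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  seqs <- unname(seqs)
  keep <- nchar(seqs) > 0
  if (!all(keep)) {
    warn(paste0("align_family(): excluding ", sum(!keep),
                " empty member(s)."))
    seqs <- seqs[keep]; ids <- ids[keep]
  }
  if (length(seqs) < 2) {
    abort("align_family(): need at least 2 members.",
          class = "mitescan_undefined_input")
  }
  if (is.null(representative)) representative <- seqs[[1]]
  L <- nchar(representative)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), representative, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  pa <- as.character(Biostrings::alignedPattern(alns))   # members
  sa <- as.character(Biostrings::alignedSubject(alns))   # representative

  # per member: base matched to each representative position, plus
  # insertion strings keyed by the representative position they follow
  parsed <- purrr::map(seq_along(seqs), function(i) {
    p <- seq_chars(pa[i]); s <- seq_chars(sa[i])
    rpos <- cumsum(s != "-")
    matched <- character(L)
    ins <- vector("list", L + 1)  # ins[[k+1]] follows rep position k
    for (col in seq_along(p)) {
      if (s[col] != "-") {
        matched[rpos[col]] <- p[col]
      } else {
        key <- rpos[col] + 1L
        ins[[key]] <- c(ins[[key]], p[col])
      }
    }
    list(matched = matched, ins = ins)
  })
  ins_len <- vapply(0:L, function(k) {
    max(vapply(parsed, function(x) length(x$ins[[k + 1]]), integer(1)))
  }, integer(1))

  rows <- vapply(parsed, function(x) {
    pieces <- character(0)
    for (k in 0:L) {
      insert <- x$ins[[k + 1]] %||% character(0)
      pieces <- c(pieces,
                  paste(c(insert, rep("-", ins_len[k + 1] - length(insert))),
                        collapse = ""))
      if (k < L) pieces <- c(pieces, x$matched[k + 1])
    }
    paste(pieces, collapse = "")
  }, character(1))
  col_ref <- integer(0)
  for (k in 0:L) {
    col_ref <- c(col_ref, rep(NA_integer_, ins_len[k + 1]))
    if (k < L) col_ref <- c(col_ref, k + 1L)
  }
  structure(list(rows = rows, ids = ids, col_ref = col_ref),
            class = "mite_alignment")
}

#' @export
print.mite_alignment <- function(x, ...) {
  cat("<mite_alignment> ", length(x$rows), " rows x ",
      nchar(x$rows[1]), " columns\n", sep = "")
  invisible(x)
}

# character matrix (rows x columns) of an alignment
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

# Per-column consensus characters: majority base among A,C,G,T (ties
# alphabetical); NA for columns where gaps are in the majority.
consensus_cols <- function(aln) {
  m <- alignment_matrix(aln)
  apply(m, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return(NA_character_)
    counts <- table(factor(col[col %in% BASES], levels = BASES))
    if (sum(counts) == 0) return(NA_character_)
    BASES[which.max(counts)]  # which.max takes the first (alphabetical) tie
  })
}

#' Majority consensus of a family alignment
#'
#' Per column, the majority base among `A`, `C`, `G`, `T` (ties broken
#' alphabetically); columns with a gap majority are omitted.
#'
#' @param aln a `mite_alignment`.
#' @return ungapped consensus string.
#' @export
consensus_sequence <- function(aln) {
  cc <- consensus_cols(aln)
  paste(cc[!is.na(cc)], collapse = "")
}

#' Kimura two-parameter distance
#'
#' `k = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over shared ungapped sites of
#' two equal-length (aligned) sequences.
#'
#' @param a,b aligned sequences of equal length (`-` allowed).
#' @return distance in substitutions/site (`>= 0`).
#' @export
#' @examples
#' k2p_distance("GATTACA", "GACTACA") # one transition among 7 sites
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("k2p_distance(): sequences must be aligned (equal length).",
          class = "mitescan_undefined_input")
  }
  x <- seq_chars(toupper(a))
  y <- seq_chars(toupper(b))
  ok <- x %in% BASES & y %in% BASES
  n <- sum(ok)
  if (n == 0) {
    abort("k2p_distance(): no shared ungapped sites.",
          class = "mitescan_undefined_input")
  }
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[x] == purine[y])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf(paste0("k2p_distance(): saturation (P=%.3f, Q=%.3f); ",
                         "distance undefined."), P, Q),
          class = "mitescan_saturation_error")
  }
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

#' Insertion age from divergence
#'
#' `T = k / (2 r)` with `r` the neutral substitution rate per site per
#' year (default 1.56e-8, the fruit-fly neutral rate commonly applied to
#' the silkworm).
#'
#' @param k substitutions/site (vectorised).
#' @param rate substitution rate per site per year.
#' @return age in years.
#' @export
#' @examples
#' insertion_age(0.0312) # 1e6 years
insertion_age <- function(k, rate = 1.56e-8) {
  if (rate <= 0) {
    abort("insertion_age(): rate must be > 0.",
          class = "mitescan_parameter_error")
  }
  if (any(k < 0)) {
    abort("insertion_age(): k must be >= 0.",
          class = "mitescan_parameter_error")
  }
  k / (2 * rate)
}

#' Per-member insertion ages of a family
#'
#' K2P distance of every member row to the family consensus, converted to
#' years via [insertion_age()]. Members whose distance is saturated get
#' `NA` with a flag.
#'
#' @param aln a `mite_alignment`.
#' @param rate substitution rate per site per year.
#' @return tibble: `member`, `k`, `t_years`, `t_my`, `saturated`.
#' @export
family_ages <- function(aln, rate = 1.56e-8) {
  cc <- consensus_cols(aln)
  keep <- !is.na(cc)
  cons <- paste(cc[keep], collapse = "")
  m <- alignment_matrix(aln)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  ks <- vapply(rows, function(r) {
    tryCatch(k2p_distance(r, cons),
             mitescan_saturation_error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
  tibble(member = aln$ids, k = ks,
         t_years = ifelse(is.na(ks), NA_real_, ks / (2 * rate)),
         t_my = ifelse(is.na(ks), NA_real_, ks / (2 * rate) / 1e6),
         saturated = is.na(ks))
}

#' Sliding-window nucleotide diversity of a family alignment
#'
#' Windows are indexed on ungapped consensus coordinates (gap-majority
#' columns dropped), default width 20 and step 20; a trailing partial
#' window is dropped. Per window, pi is the average over all sequence
#' pairs of differences per compared site, site-pairs containing a gap
#' excluded. Windows at least two sample standard deviations above the
#' mean are classed `variable`; at or below the mean minus two standard
#' deviations (floored at zero) `conserved`; all windows are
#' `intermediate` when the standard deviation is zero or undefined.
#'
#' @param aln a `mite_alignment`.
#' @param window,step window width and step in consensus positions.
#' @return an object of class `mite_diversity`: list with `windows`
#'   (tibble `start`, `end` 0-based half-open consensus coordinates, `pi`,
#'   `n_comparable`, `class`), `mean_pi`, `sd_pi`.
#' @export
sliding_pi <- function(aln, window = 20, step = 20) {
  cc <- consensus_cols(aln)
  keep <- which(!is.na(cc))
  if (length(keep) < window) {
    abort("sliding_pi(): alignment shorter than one window.",
          class = "mitescan_undefined_input")
  }
  m <- alignment_matrix(aln)[, keep, drop = FALSE]
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  starts <- seq(0, length(keep) - window, by = step)
  res <- purrr::map(starts, function(s0) {
    cols <- (s0 + 1):(s0 + window)
    pis <- numeric(0)
    ncomp <- 0L
    for (z in seq_len(ncol(pairs))) {
      x <- m[pairs[1, z], cols]
      y <- m[pairs[2, z], cols]
      ok <- x %in% BASES & y %in% BASES
      if (!any(ok)) next
      pis <- c(pis, sum(x[ok] != y[ok]) / sum(ok))
      ncomp <- ncomp + sum(ok)
    }
    tibble(start = s0, end = s0 + window,
           pi = if (length(pis) > 0) mean(pis) else NA_real_,
           n_comparable = ncomp)
  })
  win <- dplyr::bind_rows(res)
  mean_pi <- mean(win$pi, na.rm = TRUE)
  sd_pi <- stats::sd(win$pi, na.rm = TRUE)
  cls <- rep("intermediate", nrow(win))
  if (!is.na(sd_pi) && sd_pi > 0) {
    thr_var <- mean_pi + 2 * sd_pi
    thr_con <- max(0, mean_pi - 2 * sd_pi)
    cls[!is.na(win$pi) & win$pi >= thr_var] <- "variable"
    cls[!is.na(win$pi) & win$pi <= thr_con] <- "conserved"
  }
  win$class <- cls
  structure(list(windows = win, mean_pi = mean_pi, sd_pi = sd_pi),
            class = "mite_diversity")
}

#' @export
print.mite_diversity <- function(x, ...) {
  cat("<mite_diversity> ", nrow(x$windows), " windows; mean pi ",
      signif(x$mean_pi, 4), ", sd ", signif(x$sd_pi, 4), "\n", sep = "")
  print(table(x$windows$class))
  invisible(x)
}

# ---- median-joining networks ----------------------------------------------

hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

dist_matrix <- function(haps) {
  n <- length(haps)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  sp <- strsplit(haps, "", fixed = TRUE)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(sp[[i]] != sp[[j]])
    }
  }
  d
}

# Prim MST total length with deterministic tie-break (lowest index).
mst_length <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nx <- cand[which.min(best[cand])]
    total <- total + best[nx]
    in_tree[nx] <- TRUE
    best <- pmin(best, d[nx, ])
  }
  total
}

# Minimum spanning network (union of all MSTs): Kruskal by distance
# class, adding every edge joining distinct components at its class
# before merging.
msn_edges <- function(d) {
  n <- nrow(d)
  if (n <= 1) {
    return(tibble(from = integer(), to = integer(), distance = integer()))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)])
  pairs <- pairs[ord, , drop = FALSE]
  dist_sorted <- d[upper.tri(d)][ord]
  edges <- list()
  for (dv in unique(dist_sorted)) {
    sel <- which(dist_sorted == dv)
    add <- pairs[sel[vapply(sel, function(z) {
      find(pairs[z, 1]) != find(pairs[z, 2])
    }, logical(1))], , drop = FALSE]
    for (r in seq_len(nrow(add))) {
      edges[[length(edges) + 1]] <-
        tibble(from = add[r, 1], to = add[r, 2], distance = as.integer(dv))
    }
    for (r in seq_len(nrow(add))) {
      parent[find(add[r, 1])] <- find(add[r, 2])
    }
  }
  dplyr::bind_rows(edges)
}

# Column-majority median of three sequences; ties (all three distinct)
# take the state of the first sequence.
median_vector <- function(a, b, c) {
  x <- seq_chars(a); y <- seq_chars(b); z <- seq_chars(c)
  out <- x
  for (i in seq_along(x)) {
    if (y[i] == z[i]) out[i] <- y[i]   # majority (or x already equal)
  }
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Condenses aligned sequences into haplotypes with multiplicities and
#' builds a minimum spanning network over Hamming distances (gaps count
#' as a fifth state). Median (Steiner) vectors of node triplets connected
#' in the network are added greedily while they strictly shorten the
#' minimum spanning tree (the epsilon = 0 variant of the median-joining
#' heuristic); obsolete medians are pruned. Node order and all
#' tie-breaks are lexicographic in the haplotype sequence, so the result
#' does not depend on input order.
#'
#' @param sequences character vector of equal-length (aligned) sequences.
#' @param epsilon tolerance parameter; only the canonical 0 is supported.
#' @return an object of class `mite_network`: list with `nodes` (tibble
#'   `node_id`, `haplotype`, `multiplicity`, `is_median`) and `edges`
#'   (tibble `from`, `to`, `distance` in node ids).
#' @export
mj_network <- function(sequences, epsilon = 0) {
  if (length(sequences) == 0) {
    abort("mj_network(): need at least one sequence.",
          class = "mitescan_undefined_input")
  }
  if (length(unique(nchar(sequences))) != 1) {
    abort("mj_network(): sequences must be aligned (equal length).",
          class = "mitescan_undefined_input")
  }
  if (epsilon != 0) {
    abort("mj_network(): only epsilon = 0 is supported.",
          class = "mitescan_parameter_error")
  }
  tab <- table(sequences)
  haps <- sort(names(tab))
  mult <- as.integer(tab[haps])
  is_med <- rep(FALSE, length(haps))

  repeat {
    d <- dist_matrix(haps)
    base_len <- mst_length(d)
    ed <- msn_edges(d)
    # adjacency for triplet enumeration
    n <- length(haps)
    adj <- matrix(FALSE, n, n)
    if (nrow(ed) > 0) {
      adj[cbind(ed$from, ed$to)] <- TRUE
      adj[cbind(ed$to, ed$from)] <- TRUE
    }
    cand <- character(0)
    if (n >= 2) {
      for (u in seq_len(n)) {
        nb <- which(adj[u, ])
        if (length(nb) < 2) next
        cmb <- utils::combn(nb, 2)
        for (z in seq_len(ncol(cmb))) {
          m <- median_vector(haps[u], haps[cmb[1, z]], haps[cmb[2, z]])
          if (!(m %in% haps)) cand <- c(cand, m)
        }
      }
    }
    cand <- sort(unique(cand))
    if (length(cand) == 0) break
    gains <- vapply(cand, function(m) {
      base_len - mst_length(dist_matrix(c(haps, m)))
    }, numeric(1))
    best <- which(gains > 0)
    if (length(best) == 0) break
    pick <- best[which.max(gains[best])]  # first max: lexicographic tie-break
    haps <- c(haps, cand[pick])
    mult <- c(mult, 0L)
    is_med <- c(is_med, TRUE)
    ord <- order(haps)
    haps <- haps[ord]; mult <- mult[ord]; is_med <- is_med[ord]
  }

  # prune medians whose removal does not lengthen the MST
  repeat {
    removed <- FALSE
    for (i in which(is_med)) {
      d_with <- mst_length(dist_matrix(haps))
      d_without <- mst_length(dist_matrix(haps[-i]))
      if (d_without <= d_with) {
        haps <- haps[-i]; mult <- mult[-i]; is_med <- is_med[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  d <- dist_matrix(haps)
  ed <- msn_edges(d)
  structure(list(
    nodes = tibble(node_id = seq_along(haps), haplotype = haps,
                   multiplicity = mult, is_median = is_med),
    edges = ed
  ), class = "mite_network")
}

#' @export
print.mite_network <- function(x, ...) {
  cat("<mite_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_median), " median), ", nrow(x$edges), " edges; ",
      sum(x$nodes$multiplicity), " sequences\n", sep = "")
  invisible(x)
}

#' Star-topology statistic of a haplotype network
#'
#' Fraction of the other nodes adjacent to the modal (highest
#' multiplicity) node. Near 1 for a star around a dominant haplotype
#' (recent burst expansion); low when no dominant center exists (old
#' expansion with long branches).
#'
#' @param net a `mite_network`.
#' @return fraction in `[0, 1]` (1 for a single-node network).
#' @export
star_statistic <- function(net) {
  n <- nrow(net$nodes)
  if (n <= 1) return(1)
  center <- net$nodes$node_id[order(-net$nodes$multiplicity,
                                    net$nodes$haplotype)][1]
  nb <- unique(c(net$edges$to[net$edges$from == center],
                 net$edges$from[net$edges$to == center]))
  length(nb) / (n - 1)
}

#' Export a haplotype network in DOT format
#'
#' @param net a `mite_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(net, path) {
  lines <- c("graph mite_network {",
             sprintf("  n%d [label=\"%d\", width=%.2f, shape=circle];",
                     net$nodes$node_id, net$nodes$multiplicity,
                     0.3 + 0.1 * sqrt(net$nodes$multiplicity)),
             sprintf("  n%d -- n%d [label=\"%d\"];",
                     net$edges$from, net$edges$to, net$edges$distance),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a haplotype network to an igraph object
#'
#' Requires the igraph package.
#'
#' @param net a `mite_network`.
#' @return an igraph graph with `multiplicity`, `is_median` vertex
#'   attributes and a `distance` edge attribute.
#' @export
as_igraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("as_igraph(): the igraph package is not installed.",
          class = "mitescan_parameter_error")
  }
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$node_id,
                          multiplicity = net$nodes$multiplicity,
                          is_median = net$nodes$is_median))
  g
}
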