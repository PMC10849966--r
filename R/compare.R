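as_genome_strings <- function(genomes) {
  if (inherits(genomes, "consensus_genome")) genomes <- list(genomes)
  if (is.list(genomes)) {
    genomes <- vapply(genomes, function(g) {
      if (inherits(g, "consensus_genome")) setNames(g$sequence, g$name)
      else as.character(g)
    }, character(1))
  }
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    names(genomes) <- paste0("genome", seq_along(genomes))
  }
  toupper(genomes)
}

#' Pairwise differences between two consensus genomes
#'
#' Counts strict base mismatches over the positions covered in both
#' genomes: any position that is N (or a non-ACGT symbol) in either
#' genome is excluded from both counts.
#'
#' @param g1,g2 Sequences (strings of equal length) or
#'   [call_consensus()] results.
#' @return A list with `n_diff` and `n_compared`.
#' @export
pairwise_differences <- function(g1, g2) {
  s <- as_genome_strings(list(g1, g2))
  if (nchar(s[1]) != nchar(s[2])) {
    abort("genomes must have equal length",
          class = "ancientmt_invalid_argument")
  }
  a <- seq_chars(s[[1]])
  b <- seq_chars(s[[2]])
  both <- a %in% DNA_BASES & b %in% DNA_BASES
  list(n_diff = sum(a[both] != b[both]), n_compared = sum(both))
}

#' Pairwise difference matrix over a set of genomes
#'
#' @param genomes Named character vector of equal-length sequences, or a
#'   list of sequences / [call_consensus()] results.
#' @return An object of class `difference_matrix` with fields `ids`,
#'   `n_diff` and `n_compared` (symmetric matrices, zero diagonal on
#'   `n_diff`).
#' @export
difference_matrix <- function(genomes) {
  s <- as_genome_strings(genomes)
  k <- length(s)
  if (k < 2L) {
    abort("need at least two genomes", class = "ancientmt_invalid_argument")
  }
  if (length(unique(nchar(s))) != 1L) {
    abort("genomes must have equal length",
          class = "ancientmt_invalid_argument")
  }
  m <- vapply(s, seq_chars, character(nchar(s[1])))
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  ids <- names(s)
  n_diff <- matrix(0L, k, k, dimnames = list(ids, ids))
  n_compared <- matrix(0L, k, k, dimnames = list(ids, ids))
  diag(n_compared) <- colSums(valid)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      v <- valid[, i] & valid[, j]
      d <- sum(m[v, i] != m[v, j])
      n_diff[i, j] <- n_diff[j, i] <- d
      n_compared[i, j] <- n_compared[j, i] <- sum(v)
    }
  }
  structure(list(ids = ids, n_diff = n_diff, n_compared = n_compared),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat(sprintf("<difference_matrix> %d genomes\n", length(x$ids)))
  print(x$n_diff)
  invisible(x)
}

#' Zero-difference (matriline) groups
#'
#' Finds maximal groups of genomes with no pairwise differences among
#' them over the jointly covered positions. Grouping uses maximal
#' cliques of the zero-difference graph rather than connected
#' components, because zero-difference is not transitive when coverage
#' differs between genomes. Pairs whose joint coverage is below
#' `min_overlap` are never linked (a zero over few positions is
#' uninformative) and are reported in the `low_overlap_pairs` attribute.
#'
#' @param matrix A [difference_matrix()] result.
#' @param min_overlap Minimum jointly covered positions for a pair to
#'   count as zero-difference (default 1000).
#' @return A tibble with one row per maximal group: `group_id`, `size`,
#'   `members` (list-column, sorted ids). Groups are ordered by
#'   decreasing size, then lexicographically by first member.
#' @export
zero_difference_groups <- function(matrix, min_overlap = 1000) {
  ids <- matrix$ids
  adj <- matrix$n_diff == 0L & matrix$n_compared >= min_overlap
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 1)
  members <- lapply(cliques, function(cl) sort(ids[as.integer(cl)]))
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1L))
  members <- members[ord]

  low <- which(matrix$n_diff == 0L & matrix$n_compared < min_overlap &
                 upper.tri(matrix$n_diff), arr.ind = TRUE)
  low_pairs <- tibble(id_a = ids[low[, 1]], id_b = ids[low[, 2]],
                      n_compared = matrix$n_compared[low])

  out <- tibble(
    group_id = seq_along(members),
    size = lengths(members),
    members = members
  )
  attr(out, "low_overlap_pairs") <- low_pairs
  attr(out, "min_overlap") <- min_overlap
  out
}

#' Tidy a difference matrix into a long pair table
#'
#' @param x A [difference_matrix()] result.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id_a`, `id_b`,
#'   `n_diff`, `n_compared`.
#' @export
tidy.difference_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$n_diff), arr.ind = TRUE)
  tibble(
    id_a = x$ids[idx[, 1]], id_b = x$ids[idx[, 2]],
    n_diff = x$n_diff[idx], n_compared = x$n_compared[idx]
  ) |>
    dplyr::arrange(.data$id_a, .data$id_b)
}

#' Write difference matrices as TSV
#'
#' @param matrix A [difference_matrix()] result.
#' @param diff_path,compared_path Output paths for the `n_diff` and
#'   `n_compared` matrices.
#' @return `diff_path`, invisibly.
#' @export
write_difference_matrix <- function(matrix, diff_path, compared_path = NULL) {
  write_mat <- function(m, path) {
    df <- as.data.frame(m)
    df <- cbind(id = rownames(m), df)
    readr::write_tsv(as_tibble(df), path)
  }
  write_mat(matrix$n_diff, diff_path)
  if (!is.null(compared_path)) write_mat(matrix$n_compared, compared_path)
  invisible(diff_path)
}
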