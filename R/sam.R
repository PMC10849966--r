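#' Write simulated fragments as a SAM file
#'
#' Emits one record per fragment with the mandatory 11 fields, an `@SQ`
#' header line carrying the reference length, and an `@CO` comment
#' documenting the circular convention: a fragment spanning the origin is
#' written as a single record whose alignment extends past the reference
#' end, and reference positions are to be interpreted modulo the
#' reference length ("rotated" linearisation). [read_sam()] undoes the
#' rotation. Reverse-strand fragments are emitted reverse-complemented
#' (SEQ is reference orientation), so read-orientation C->T damage
#' appears as G->A in the written sequence, as in real aDNA alignments.
#'
#' @param fragments Observation-level fragments tibble.
#' @param ref A [reference_genome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(fragments, ref, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
    paste0("@CO\tcircular:rotated - alignments may extend past LN; ",
           "reference positions are modulo LN")
  )
  if (nrow(fragments) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  L <- ref$length
  dat <- fragments |>
    dplyr::mutate(offset = (.data$ref_pos - .data$ref_start) %% L) |>
    dplyr::arrange(.data$fragment_id, .data$offset)
  meta <- dat |>
    dplyr::summarise(
      seq = paste(.data$base, collapse = ""),
      ref_start = .data$ref_start[1],
      strand = .data$strand[1],
      mapq = .data$mapq[1],
      read_length = .data$read_length[1],
      .by = "fragment_id"
    )
  records <- sprintf(
    "frag%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
    meta$fragment_id,
    ifelse(meta$strand == "-", 16L, 0L),
    ref$name,
    meta$ref_start + 1L,
    meta$mapq,
    meta$read_length,
    meta$seq
  )
  writeLines(c(header, records), path)
  invisible(path)
}

parse_cigar <- function(cigar, line) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    abort(sprintf("malformed CIGAR '%s' at line %d", cigar, line),
          class = "ancientmt_parse_error")
  }
  list(len = as.integer(sub("[A-Z=]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

#' Read a SAM file into the observation-level fragments tibble
#'
#' Parses the mandatory fields and walks the CIGAR: M/=/X consume both
#' reference and read, I and S consume the read only, D and N consume
#' the reference only, H consumes neither. Unmapped records (FLAG 0x4)
#' are skipped and counted. Reference positions are wrapped modulo the
#' reference length for circular references (the writer's rotated
#' convention).
#'
#' @param path SAM path.
#' @param ref A [reference_genome()]; the `@SQ` header must match its
#'   name and length.
#' @return Fragments tibble (see [simulate_fragments()]) with attribute
#'   `n_skipped_unmapped`.
#' @export
read_sam <- function(path, ref) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  if (length(sq) > 0L) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq[1])
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq[1]))
    if (sn != ref$name || ln != ref$length) {
      abort(sprintf("@SQ header (%s, %d) does not match reference (%s, %d)",
                    sn, ln, ref$name, ref$length),
            class = "ancientmt_parse_error")
    }
  }
  recs <- lines[!is_header]
  if (length(recs) == 0L) {
    out <- tibble(fragment_id = integer(), ref_start = integer(),
                  strand = character(), mapq = integer(),
                  read_length = integer(), ref_pos = integer(),
                  read_pos = integer(), base = character())
    attr(out, "n_skipped_unmapped") <- 0L
    attr(out, "ref_name") <- ref$name
    return(out)
  }
  fields <- strsplit(recs, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0L) {
    abort(sprintf("SAM record with fewer than 11 fields at line %d",
                  sum(is_header) + bad[1]),
          class = "ancientmt_parse_error")
  }
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  unmapped <- bitwAnd(flag, 4L) > 0L
  n_skipped <- sum(unmapped)

  L <- ref$length
  keep <- which(!unmapped)

  # fast path: plain single-run match CIGARs (the overwhelmingly common
  # case for merged aDNA fragments) expand fully vectorised
  cigars <- vapply(fields[keep], `[`, character(1), 6L)
  simple <- grepl("^[0-9]+M$", cigars)
  obs_simple <- NULL
  if (any(simple)) {
    ks <- keep[simple]
    pos0 <- vapply(fields[ks], function(f) as.integer(f[4]), integer(1)) - 1L
    mq <- vapply(fields[ks], function(f) as.integer(f[5]), integer(1))
    seqs <- vapply(fields[ks], `[`, character(1), 10L)
    lens <- as.integer(sub("M$", "", cigars[simple]))
    if (any(lens != nchar(seqs))) {
      bad <- which(lens != nchar(seqs))[1]
      abort(sprintf("CIGAR length disagrees with SEQ at line %d",
                    sum(is_header) + ks[bad]),
            class = "ancientmt_parse_error")
    }
    rev <- bitwAnd(flag[ks], 16L) > 0L
    idx <- rep.int(seq_along(ks), lens)
    j <- sequence(lens) - 1L
    read_pos <- j
    mrev <- rev[idx]
    read_pos[mrev] <- lens[idx][mrev] - 1L - j[mrev]
    obs_simple <- tibble(
      fragment_id = match(ks, keep)[idx],
      ref_start = pos0[idx],
      strand = c("+", "-")[1L + rev[idx]],
      mapq = mq[idx],
      read_length = lens[idx],
      ref_pos = as.integer((pos0[idx] + j) %% L),
      read_pos = as.integer(read_pos),
      base = unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    )
  }

  keep_complex <- keep[!simple]
  obs <- vector("list", length(keep_complex))
  for (k in seq_along(keep_complex)) {
    i <- keep_complex[k]
    f <- fields[[i]]
    pos0 <- as.integer(f[4]) - 1L
    cig <- parse_cigar(f[6], sum(is_header) + i)
    seqc <- seq_chars(f[10])
    read_len <- length(seqc)
    rev <- bitwAnd(flag[i], 16L) > 0L

    ref_off <- integer(0)  # 0-based offsets from pos0
    qpos <- integer(0)     # 0-based index into SEQ
    r <- 0L; q <- 0L
    for (j in seq_along(cig$op)) {
      n <- cig$len[j]
      switch(cig$op[j],
        "M" = , "=" = , "X" = {
          ref_off <- c(ref_off, r + seq_len(n) - 1L)
          qpos <- c(qpos, q + seq_len(n) - 1L)
          r <- r + n; q <- q + n
        },
        "I" = , "S" = { q <- q + n },
        "D" = , "N" = { r <- r + n },
        "H" = , "P" = NULL
      )
    }
    if (q > read_len) {
      abort(sprintf("CIGAR consumes more read bases than SEQ at line %d",
                    sum(is_header) + i),
            class = "ancientmt_parse_error")
    }
    obs[[k]] <- tibble(
      fragment_id = match(i, keep),
      ref_start = pos0,
      strand = if (rev) "-" else "+",
      mapq = as.integer(f[5]),
      read_length = read_len,
      ref_pos = as.integer((pos0 + ref_off) %% L),
      read_pos = if (rev) read_len - 1L - qpos else qpos,
      base = seqc[qpos + 1L]
    )
  }
  out <- dplyr::bind_rows(c(list(obs_simple), obs)) |>
    dplyr::arrange(.data$fragment_id, .data$read_pos)
  attr(out, "n_skipped_unmapped") <- n_skipped
  attr(out, "ref_name") <- ref$name
  out
}
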