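keep_frag_attrs <- function(out, from) {
  attr(out, "error_rate") <- attr(from, "error_rate")
  attr(out, "ref_name") <- attr(from, "ref_name")
  out
}

#' Filter fragments on length and mapping quality
#'
#' Removes fragments shorter than `min_length` bp or with mapping quality
#' below `min_mapq` (strict removal: a 35 bp, MQ 25 fragment is retained).
#' These are the standard ancient-DNA alignment filters. Removal counts
#' per criterion are attached as attribute `filter_counts` and reported
#' via a message.
#'
#' @param fragments Observation-level fragments tibble.
#' @param min_length Minimum read length in bp (default 35).
#' @param min_mapq Minimum mapping quality (default 25).
#' @param quiet Suppress the count message.
#' @return Filtered fragments tibble, input order preserved.
#' @export
filter_fragments <- function(fragments, min_length = 35, min_mapq = 25,
                             quiet = FALSE) {
  meta <- dplyr::distinct(fragments, .data$fragment_id, .data$read_length,
                          .data$mapq)
  short <- meta$read_length < min_length
  lowmq <- meta$mapq < min_mapq
  counts <- tibble(
    criterion = c("short", "low_mapq", "retained"),
    n = c(sum(short), sum(lowmq), sum(!short & !lowmq))
  )
  keep_ids <- meta$fragment_id[!short & !lowmq]
  out <- dplyr::filter(fragments, .data$fragment_id %in% keep_ids)
  out <- keep_frag_attrs(out, fragments)
  attr(out, "filter_counts") <- counts
  if (!quiet) {
    inform(sprintf(
      "filter_fragments: %d retained, %d removed (<%d bp), %d removed (MQ<%d)",
      counts$n[3], counts$n[1], min_length, counts$n[2], min_mapq))
  }
  out
}

#' Collapse PCR duplicates
#'
#' Fragments sharing (start, end, strand) — the standard key for merged
#' single-end aDNA fragments — are collapsed to one representative per
#' key. The representative's base at each position is the majority base
#' among the duplicates; ties become N. Its id is the smallest member id
#' and its mapping quality the maximum over members.
#'
#' @param fragments Observation-level fragments tibble.
#' @param quiet Suppress the count message.
#' @return Deduplicated fragments tibble with attribute `dedup_counts`.
#' @export
deduplicate <- function(fragments, quiet = FALSE) {
  if (nrow(fragments) == 0L) {
    attr(fragments, "dedup_counts") <- c(n_in = 0L, n_out = 0L)
    return(fragments)
  }
  dat <- fragments |>
    dplyr::mutate(.key = paste(.data$ref_start,
                               .data$ref_start + .data$read_length,
                               .data$strand, sep = ":"))
  meta <- dat |>
    dplyr::distinct(.data$.key, .data$fragment_id, .data$ref_start,
                    .data$strand, .data$mapq, .data$read_length) |>
    dplyr::summarise(
      fragment_id = min(.data$fragment_id),
      ref_start = .data$ref_start[1],
      strand = .data$strand[1],
      mapq = max(.data$mapq),
      read_length = .data$read_length[1],
      n_members = dplyr::n(),
      .by = ".key"
    )
  calls <- dat |>
    dplyr::count(.data$.key, .data$ref_pos, .data$read_pos, .data$base) |>
    dplyr::mutate(.max = max(.data$n), .by = c(".key", "ref_pos")) |>
    dplyr::filter(.data$n == .data$.max) |>
    dplyr::summarise(
      base = if (dplyr::n() > 1L) "N" else .data$base[1],
      .by = c(".key", "ref_pos", "read_pos")
    )
  out <- calls |>
    dplyr::inner_join(meta, by = ".key") |>
    dplyr::arrange(.data$fragment_id, .data$read_pos) |>
    dplyr::select("fragment_id", "ref_start", "strand", "mapq",
                  "read_length", "ref_pos", "read_pos", "base")
  out <- keep_frag_attrs(out, fragments)
  attr(out, "dedup_counts") <- c(n_in = nrow(meta) + sum(meta$n_members - 1L),
                                 n_out = nrow(meta))
  if (!quiet) {
    inform(sprintf("deduplicate: %d fragments -> %d distinct (start,end,strand) keys",
                   sum(meta$n_members), nrow(meta)))
  }
  out
}

#' Build per-site pileups on the (circular) reference
#'
#' Aggregates observations into per-position base counts, both raw and
#' after applying an optional mask (used for terminal damage masking).
#' N observations never count. A fragment wrapping the circular origin
#' contributes to positions at both ends of the linearised reference.
#'
#' @param fragments Observation-level fragments tibble (filtered and
#'   deduplicated upstream).
#' @param ref A [reference_genome()].
#' @param mask Either `NULL` (masked counts equal raw counts), a logical
#'   vector with one element per observation row (`TRUE` = exclude from
#'   the masked counts), or a function `f(fragments, ref)` returning one.
#' @param zero_fill If `TRUE` (default) every reference position appears,
#'   zero-filled where uncovered; otherwise only covered positions.
#' @return A tibble with columns `pos` (1-based), `A`, `C`, `G`, `T`,
#'   `coverage`, and masked counterparts `A_masked` ... `coverage_masked`.
#' @export
pileup <- function(fragments, ref, mask = NULL, zero_fill = TRUE) {
  if (is.function(mask)) mask <- mask(fragments, ref)
  if (is.null(mask)) mask <- rep(FALSE, nrow(fragments))
  if (length(mask) != nrow(fragments)) {
    abort("`mask` must have one element per observation row",
          class = "ancientmt_invalid_argument")
  }
  count_wide <- function(d) {
    d |>
      dplyr::count(.data$ref_pos, .data$base) |>
      tidyr::pivot_wider(names_from = "base", values_from = "n",
                         values_fill = 0L)
  }
  fill_bases <- function(w) {
    for (b in DNA_BASES) if (!b %in% names(w)) w[[b]] <- 0L
    w[, c("ref_pos", DNA_BASES)]
  }
  ok <- fragments$base != "N"
  raw <- fill_bases(count_wide(fragments[ok, ]))
  msk <- fill_bases(count_wide(fragments[ok & !mask, ]))
  names(msk)[-1] <- paste0(DNA_BASES, "_masked")

  base_tbl <- if (zero_fill) {
    tibble(ref_pos = 0:(ref$length - 1L))
  } else {
    dplyr::distinct(raw["ref_pos"]) |> dplyr::arrange(.data$ref_pos)
  }
  out <- base_tbl |>
    dplyr::left_join(raw, by = "ref_pos") |>
    dplyr::left_join(msk, by = "ref_pos") |>
    dplyr::mutate(dplyr::across(-"ref_pos", ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(
      coverage = .data$A + .data$C + .data$G + .data$T,
      coverage_masked = .data$A_masked + .data$C_masked + .data$G_masked +
        .data$T_masked,
      pos = .data$ref_pos + 1L
    ) |>
    dplyr::select("pos", dplyr::all_of(DNA_BASES), "coverage",
                  dplyr::all_of(paste0(DNA_BASES, "_masked")),
                  "coverage_masked")
  out
}
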