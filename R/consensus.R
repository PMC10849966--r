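#' Consensus calling parameters
#'
#' Defaults follow the standard ancient-mtDNA reconstruction rules:
#' a site is called when at least 5 masked fragments cover it and the
#' top base has at least 80% support (inclusive at exactly 0.80), after
#' ignoring C->T substitutions within 7 positions of either read end.
#'
#' @param min_coverage Minimum masked coverage per site (fragments).
#' @param min_support Minimum top-base fraction, in (0.5, 1].
#' @param mask_window Terminal read positions whose C->T observations
#'   are ignored.
#' @param mode `"all_fragments"` or `"deaminated_only"`; see
#'   [select_mode()].
#' @param contamination_threshold Contamination fraction above which
#'   `deaminated_only` is selected (default 0.05).
#' @return An object of class `consensus_params`.
#' @export
consensus_params <- function(min_coverage = 5, min_support = 0.80,
                             mask_window = 7, mode = "all_fragments",
                             contamination_threshold = 0.05) {
  if (min_support <= 0.5 || min_support > 1) {
    abort("`min_support` must lie in (0.5, 1]",
          class = "ancientmt_invalid_argument")
  }
  stopifnot_scalar_number(min_coverage, "min_coverage", lower = 1)
  stopifnot_scalar_number(mask_window, "mask_window", lower = 0)
  mode <- match.arg(mode, c("all_fragments", "deaminated_only"))
  structure(
    list(min_coverage = as.integer(min_coverage), min_support = min_support,
         mask_window = as.integer(mask_window), mode = mode,
         contamination_threshold = contamination_threshold),
    class = "consensus_params"
  )
}

#' Choose the consensus mode from a contamination estimate
#'
#' Libraries with estimated present-day contamination below the
#' threshold use all fragments; at or above it, only deaminated
#' fragments (exactly at the threshold the conservative
#' `deaminated_only` branch is taken, since neither side is specified
#' by the `<5%` / `>5%` convention).
#'
#' @param contamination A [estimate_contamination()] result or a bare
#'   contamination fraction.
#' @param threshold Decision threshold (default 0.05).
#' @return `"all_fragments"` or `"deaminated_only"`.
#' @export
select_mode <- function(contamination, threshold = 0.05) {
  point <- if (inherits(contamination, "contamination_estimate")) {
    contamination$point
  } else {
    contamination
  }
  stopifnot_scalar_number(point, "contamination", lower = 0, upper = 1)
  if (point < threshold) "all_fragments" else "deaminated_only"
}

#' Terminal C->T masking predicate
#'
#' TRUE for observations that are read-orientation C->T substitutions
#' (reference C read T on the + strand; reference G read A on the -
#' strand) within `window` positions of either read end. Masking is
#' unconditional on whether the T could be true variation: a genuine T
#' allele at a C reference site near a fragment end is masked too.
#'
#' @param fragments Observation-level fragments tibble.
#' @param ref A [reference_genome()].
#' @param window Terminal window in read positions (default 7).
#' @return Logical vector, one element per observation row.
#' @export
mask_terminal_damage <- function(fragments, ref, window = 7) {
  fl <- damage_flags(fragments, ref)
  fl$ct & (fl$dist5 < window | fl$dist3 < window)
}

#' Call a consensus mtDNA genome
#'
#' Applies terminal damage masking, tallies the remaining observations
#' per site, and calls the top base wherever masked coverage reaches
#' `min_coverage` and top-base support reaches `min_support`; every
#' other site (including top-base ties) is N. In `deaminated_only` mode
#' only fragments flagged by [classify_deaminated()] contribute.
#'
#' @param fragments Observation-level fragments tibble (filtered and
#'   deduplicated).
#' @param ref A [reference_genome()].
#' @param params A [consensus_params()]; its `mode` is overridden when
#'   `contamination` is supplied.
#' @param deaminated Optional precomputed [classify_deaminated()] tibble
#'   (computed on demand in `deaminated_only` mode).
#' @param contamination Optional [estimate_contamination()] result used
#'   to resolve the mode via [select_mode()].
#' @param name Sequence name for the called genome.
#' @return An object of class `consensus_genome`: `sequence` (string of
#'   reference length over A/C/G/T/N), `sites` (per-site tibble: `pos`,
#'   `coverage_masked`, `top_base`, `support`, `called`), `mode_used`,
#'   `params`.
#' @export
call_consensus <- function(fragments, ref, params = consensus_params(),
                           deaminated = NULL, contamination = NULL,
                           name = paste0(ref$name, "_consensus")) {
  mode <- params$mode
  if (!is.null(contamination)) {
    mode <- select_mode(contamination, params$contamination_threshold)
  }
  frag_used <- fragments
  if (mode == "deaminated_only") {
    if (is.null(deaminated)) deaminated <- classify_deaminated(fragments, ref)
    keep <- deaminated$fragment_id[deaminated$deaminated]
    frag_used <- dplyr::filter(fragments, .data$fragment_id %in% keep)
    frag_used <- keep_frag_attrs(frag_used, fragments)
  }
  mask <- mask_terminal_damage(frag_used, ref, window = params$mask_window)
  pu <- pileup(frag_used, ref, mask = mask, zero_fill = TRUE)

  m <- as.matrix(pu[, paste0(DNA_BASES, "_masked")])
  cov <- pu$coverage_masked
  top_count <- do.call(pmax, as.data.frame(m))
  tie <- rowSums(m == top_count & m > 0) > 1L
  top_base <- DNA_BASES[max.col(m, ties.method = "first")]
  top_base[cov == 0L] <- NA_character_
  support <- ifelse(cov > 0L, top_count / cov, NA_real_)
  called <- cov >= params$min_coverage & !tie &
    !is.na(support) & support >= params$min_support
  seq_out <- ifelse(called, top_base, "N")

  sites <- tibble(
    pos = pu$pos, coverage_masked = cov,
    top_base = ifelse(tie, "N", top_base),
    support = support, called = called
  )
  structure(
    list(name = name, sequence = paste(seq_out, collapse = ""),
         length = ref$length, sites = sites, mode_used = mode,
         params = params),
    class = "consensus_genome"
  )
}

#' @export
print.consensus_genome <- function(x, ...) {
  cat(sprintf("<consensus_genome> %s: %d bp, %d called (%.1f%%), mode %s\n",
              x$name, x$length, sum(x$sites$called),
              100 * mean(x$sites$called), x$mode_used))
  invisible(x)
}

#' Write a consensus genome (FASTA + per-site TSV)
#'
#' @param genome A [call_consensus()] result.
#' @param fasta_path FASTA output path.
#' @param tsv_path Optional per-site TSV output path (1-based positions).
#' @return `fasta_path`, invisibly.
#' @export
write_consensus <- function(genome, fasta_path, tsv_path = NULL) {
  write_fasta(setNames(genome$sequence, genome$name), fasta_path)
  if (!is.null(tsv_path)) readr::write_tsv(genome$sites, tsv_path)
  invisible(fasta_path)
}
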