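# Strand-aware deamination flags per observation row.
# In read orientation, a deamination opportunity is a template C (reference
# C on +, reference G on -) and a C->T substitution reads T (base T on +,
# base A on - in reference orientation).
damage_flags <- function(fragments, ref) {
  rb <- ref_base_at(ref, fragments$ref_pos)
  minus <- fragments$strand == "-"
  opportunity <- rb == "C"
  opportunity[minus] <- rb[minus] == "G"
  ct <- opportunity & fragments$base == "T"
  ct[minus] <- opportunity[minus] & fragments$base[minus] == "A"
  tibble(
    opportunity = opportunity,
    ct = ct,
    dist5 = fragments$read_pos,
    dist3 = fragments$read_length - 1L - fragments$read_pos
  )
}

#' Terminal C->T substitution profile
#'
#' Computes the position-wise frequency of read-orientation C->T
#' substitutions within `window` positions of each read end — the
#' classic ancient-DNA deamination profile. Frequencies are
#' substitutions / opportunities exactly, with 95% Wilson intervals;
#' positions with zero opportunities report NA (undefined), not 0.
#'
#' @param fragments Observation-level fragments tibble.
#' @param ref A [reference_genome()].
#' @param window Positions per read end (default 15).
#' @return A tibble of class `damage_profile` with columns `end`
#'   ("5p"/"3p"), `position` (1-based from that end), `substitutions`,
#'   `opportunities`, `frequency`, `ci_low`, `ci_high`.
#' @export
damage_profile <- function(fragments, ref, window = 15) {
  fl <- damage_flags(fragments, ref)
  one_end <- function(dist, end_label) {
    d <- tibble(pos = dist + 1L, opportunity = fl$opportunity, ct = fl$ct) |>
      dplyr::filter(.data$pos <= window, .data$opportunity) |>
      dplyr::summarise(substitutions = sum(.data$ct),
                       opportunities = dplyr::n(), .by = "pos")
    tibble(position = seq_len(window)) |>
      dplyr::left_join(d, by = c(position = "pos")) |>
      dplyr::mutate(
        end = end_label,
        substitutions = dplyr::coalesce(.data$substitutions, 0L),
        opportunities = dplyr::coalesce(.data$opportunities, 0L)
      )
  }
  out <- dplyr::bind_rows(one_end(fl$dist5, "5p"), one_end(fl$dist3, "3p")) |>
    dplyr::mutate(
      frequency = ifelse(.data$opportunities > 0,
                         .data$substitutions / .data$opportunities, NA_real_)
    )
  ci <- wilson_interval(out$substitutions, out$opportunities)
  out$ci_low <- ci$low
  out$ci_high <- ci$high
  out <- out[, c("end", "position", "substitutions", "opportunities",
                 "frequency", "ci_low", "ci_high")]
  class(out) <- c("damage_profile", class(out))
  attr(out, "window") <- as.integer(window)
  attr(out, "n_fragments") <- dplyr::n_distinct(fragments$fragment_id)
  out
}

#' Write a damage profile as TSV
#'
#' @param profile A [damage_profile()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_damage_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}

#' Classify fragments as deaminated
#'
#' A fragment is deaminated when it carries at least one read-orientation
#' C->T substitution within `terminal_window` positions of either read
#' end. Deaminated-only consensus calling uses this flag for libraries
#' with substantial present-day contamination.
#'
#' @param fragments Observation-level fragments tibble.
#' @param ref A [reference_genome()].
#' @param terminal_window Terminal positions inspected at each end
#'   (default 3).
#' @return A tibble (`fragment_id`, `deaminated`) with one row per
#'   fragment.
#' @export
classify_deaminated <- function(fragments, ref, terminal_window = 3) {
  fl <- damage_flags(fragments, ref)
  terminal_ct <- fl$ct & (fl$dist5 < terminal_window |
                            fl$dist3 < terminal_window)
  tibble(fragment_id = fragments$fragment_id, hit = terminal_ct) |>
    dplyr::summarise(deaminated = any(.data$hit), .by = "fragment_id")
}

#' Estimate present-day contamination from the conditional damage signal
#'
#' A transparent mixture estimator for single-stranded libraries:
#' contaminant fragments are assumed undamaged, and terminal deamination
#' is assumed independent between the two ends of an endogenous fragment.
#' Then the 5' terminal C->T rate over all fragments is
#' `p_terminal = (1-c) * d + eps`, while the same rate over fragments
#' carrying at least one 3' terminal C->T (an almost purely endogenous
#' subset) is `p_conditional = d + eps`, with `eps = error_rate / 3` the
#' rate at which sequencing error mimics C->T. The contamination
#' fraction is estimated as
#' `c = 1 - (p_terminal - eps) / (p_conditional - eps)`,
#' clipped to [0, 1], with a bootstrap over fragments for the 95%
#' percentile interval.
#'
#' @param fragments Observation-level fragments tibble.
#' @param ref A [reference_genome()].
#' @param error_rate Per-base sequencing error rate; defaults to the
#'   value recorded on simulated fragments, else 0.
#' @param terminal_window Terminal positions defining "terminal" damage
#'   (default 3).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `contamination_estimate` with fields
#'   `point`, `ci_low`, `ci_high`, `p_terminal`, `p_conditional`,
#'   `n_conditioning`, `n_fragments`, `n_boot`, `seed`.
#' @export
estimate_contamination <- function(fragments, ref,
                                   error_rate = attr(fragments, "error_rate"),
                                   terminal_window = 3, n_boot = 200,
                                   seed = NULL) {
  if (is.null(error_rate)) error_rate <- 0
  eps <- error_rate / 3

  fl <- damage_flags(fragments, ref)
  fid <- fragments$fragment_id
  uf <- unique(fid)
  gi <- match(fid, uf)
  sums <- rowsum(cbind(opp5 = as.numeric(fl$opportunity & fl$dist5 < terminal_window),
                       ct5 = as.numeric(fl$ct & fl$dist5 < terminal_window),
                       ct3 = as.numeric(fl$ct & fl$dist3 < terminal_window)),
                 gi)
  per_frag <- tibble(fragment_id = uf[as.integer(rownames(sums))],
                     opp5 = sums[, "opp5"], ct5 = sums[, "ct5"],
                     has3 = sums[, "ct3"] > 0)
  n <- nrow(per_frag)
  if (n < 500) {
    warn(sprintf("estimate_contamination: only %d fragments; estimate may be unstable", n))
  }

  point_from <- function(w) {
    opp_all <- sum(per_frag$opp5 * w)
    ct_all <- sum(per_frag$ct5 * w)
    opp_c <- sum(per_frag$opp5 * w * per_frag$has3)
    ct_c <- sum(per_frag$ct5 * w * per_frag$has3)
    if (opp_all == 0 || opp_c == 0) return(NA_real_)
    p_t <- ct_all / opp_all
    p_c <- ct_c / opp_c
    if (p_c <= eps) return(NA_real_)
    min(1, max(0, 1 - (p_t - eps) / (p_c - eps)))
  }

  p_terminal <- if (sum(per_frag$opp5) > 0) sum(per_frag$ct5) / sum(per_frag$opp5) else NA_real_
  cond <- per_frag$has3
  p_conditional <- if (sum(per_frag$opp5[cond]) > 0) {
    sum(per_frag$ct5[cond]) / sum(per_frag$opp5[cond])
  } else NA_real_
  point <- point_from(rep(1, n))
  if (is.na(point)) {
    abort(paste0("contamination estimate undefined: conditional damage rate ",
                 "does not exceed the error floor (signal too weak)"),
          class = "ancientmt_weak_signal")
  }

  boots <- with_seed_or_not(seed, {
    vapply(seq_len(n_boot), function(b) {
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      point_from(w)
    }, numeric(1))
  })
  ok <- !is.na(boots)
  if (mean(ok) < 0.9) {
    warn(sprintf("contamination bootstrap: %d/%d replicates undefined",
                 sum(!ok), n_boot))
  }
  ci <- if (any(ok)) stats::quantile(boots[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)

  structure(
    list(point = point,
         ci_low = min(ci[1], point), ci_high = max(ci[2], point),
         p_terminal = p_terminal, p_conditional = p_conditional,
         n_conditioning = sum(cond), n_fragments = n,
         terminal_window = terminal_window, error_rate = error_rate,
         n_boot = n_boot, seed = seed),
    class = "contamination_estimate"
  )
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "<contamination_estimate> point = %.3f [%.3f, %.3f]\n  p_terminal = %.4f, p_conditional = %.4f (n_conditioning = %d of %d fragments)\n",
    x$point, x$ci_low, x$ci_high, x$p_terminal, x$p_conditional,
    x$n_conditioning, x$n_fragments))
  invisible(x)
}
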