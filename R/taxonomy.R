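LINEAGES <- c("sapiens", "neanderthal", "denisovan")

diag_pairs <- function() {
  list(c("sapiens", "neanderthal"), c("sapiens", "denisovan"),
       c("neanderthal", "denisovan"))
}

validate_diagnostic_table <- function(tab) {
  need <- c("position", LINEAGES)
  if (!all(need %in% names(tab))) {
    abort(paste0("diagnostic table needs columns: ", paste(need, collapse = ", ")),
          class = "ancientmt_invalid_argument")
  }
  dup <- tab$position[duplicated(tab$position)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate diagnostic position(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "ancientmt_invalid_argument")
  }
  for (l in LINEAGES) {
    tab[[l]] <- toupper(tab[[l]])
    if (any(!tab[[l]] %in% DNA_BASES)) {
      abort(sprintf("column `%s` must contain single A/C/G/T bases", l),
            class = "ancientmt_invalid_argument")
    }
  }
  flat <- tab$sapiens == tab$neanderthal & tab$neanderthal == tab$denisovan
  if (any(flat)) {
    abort(sprintf("non-diagnostic row(s) at position(s): %s (all states equal)",
                  paste(tab$position[flat], collapse = ", ")),
          class = "ancientmt_invalid_argument")
  }
  tab$informative_for <- purrr::pmap(
    tab[LINEAGES],
    function(sapiens, neanderthal, denisovan) {
      st <- c(sapiens = sapiens, neanderthal = neanderthal,
              denisovan = denisovan)
      vapply(Filter(function(p) st[p[1]] != st[p[2]], diag_pairs()),
             paste, character(1), collapse = "-")
    }
  )
  as_tibble(tab)
}

#' Read a hominin diagnostic-position table
#'
#' TSV with a header and columns `position` (1-based mtDNA coordinate),
#' `sapiens`, `neanderthal`, `denisovan` (the lineage base state at that
#' position). Positions where the three states differ allow taxonomic
#' assignment of aligned fragments. Rows whose states are all equal are
#' rejected; duplicate positions are rejected.
#'
#' @param path TSV path.
#' @return A tibble with an added `informative_for` list-column naming
#'   the lineage pairs each position distinguishes.
#' @export
read_diagnostic_table <- function(path) {
  validate_diagnostic_table(
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(position = "i",
                                            .default = "c")))
}

#' Assign a fragment set to a hominin mtDNA lineage
#'
#' Tallies every fragment observation at a diagnostic position to the
#' lineage states it matches and resolves each pairwise lineage contrast
#' separately. With `damage_aware = TRUE` (default) an observation is
#' excluded when it could be a deamination artefact: it reads T in read
#' orientation, lies within `mask_window` positions of a read end, and
#' some lineage state at the site is C in read orientation (so a
#' damaged C-state fragment would mimic the T state). The verdict is the
#' lineage that wins every contrast it participates in at fraction
#' `>= min_margin`, with at least `min_obs` informative observations;
#' otherwise "unassigned".
#'
#' @param fragments Observation-level fragments tibble (filtered and
#'   deduplicated).
#' @param table Diagnostic table from [read_diagnostic_table()].
#' @param damage_aware Exclude deamination-consistent observations.
#' @param min_obs Minimum informative observations for a verdict.
#' @param min_margin Minimum winning fraction per contrast.
#' @param mask_window Terminal window (read positions) for the exclusion
#'   rule; 7 matches the consensus masking convention.
#' @return An object of class `lineage_assignment`: per-lineage summary,
#'   per-contrast counts, verdict, and exclusion diagnostics.
#' @export
assign_lineage <- function(fragments, table, damage_aware = TRUE,
                           min_obs = 10, min_margin = 0.8, mask_window = 7) {
  if (nrow(table) == 0L) {
    abort("empty diagnostic table", class = "ancientmt_invalid_argument")
  }
  table <- validate_diagnostic_table(table)

  obs <- fragments |>
    dplyr::mutate(position = .data$ref_pos + 1L) |>
    dplyr::inner_join(table, by = "position") |>
    dplyr::filter(.data$base %in% DNA_BASES)

  if (nrow(obs) > 0L) {
    minus <- obs$strand == "-"
    # read-orientation views of the observed base and the lineage states
    obs_read <- ifelse(minus, complement_base(obs$base), obs$base)
    terminal <- obs$read_pos < mask_window |
      obs$read_pos >= obs$read_length - mask_window
    c_state <- rep(FALSE, nrow(obs))
    for (l in LINEAGES) {
      st_read <- ifelse(minus, complement_base(obs[[l]]), obs[[l]])
      c_state <- c_state | (st_read == "C" & obs[[l]] != obs$base)
    }
    excluded <- damage_aware & obs_read == "T" & terminal & c_state
  } else {
    excluded <- logical(0)
  }
  n_excluded <- sum(excluded)
  usable <- obs[!excluded, ]

  contrasts <- purrr::map_dfr(diag_pairs(), function(p) {
    d <- usable[usable[[p[1]]] != usable[[p[2]]], ]
    n_a <- sum(d$base == d[[p[1]]])
    n_b <- sum(d$base == d[[p[2]]])
    tibble(lineage_a = p[1], lineage_b = p[2], n_a = n_a, n_b = n_b,
           n_informative = n_a + n_b,
           frac_a = ifelse(n_a + n_b > 0, n_a / (n_a + n_b), NA_real_))
  })

  lineages <- purrr::map_dfr(LINEAGES, function(l) {
    rows <- contrasts[contrasts$lineage_a == l | contrasts$lineage_b == l, ]
    n_support <- sum(ifelse(rows$lineage_a == l, rows$n_a, rows$n_b))
    n_informative <- sum(rows$n_informative)
    fracs <- ifelse(rows$lineage_a == l, rows$frac_a, 1 - rows$frac_a)
    tibble(
      lineage = l, n_support = n_support, n_informative = n_informative,
      support_fraction = ifelse(n_informative > 0,
                                n_support / n_informative, NA_real_),
      wins_all = all(!is.na(fracs) & fracs >= min_margin) &&
        nrow(rows) > 0L
    )
  })

  winners <- lineages$lineage[lineages$wins_all &
                                lineages$n_informative >= min_obs]
  verdict <- if (length(winners) == 1L) winners else "unassigned"

  structure(
    list(
      lineages = dplyr::select(lineages, -"wins_all"),
      contrasts = contrasts,
      verdict = verdict,
      n_sites_covered = dplyr::n_distinct(usable$position),
      n_excluded_damage = n_excluded,
      params = list(damage_aware = damage_aware, min_obs = min_obs,
                    min_margin = min_margin, mask_window = mask_window)
    ),
    class = "lineage_assignment"
  )
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(sprintf("<lineage_assignment> verdict: %s\n", x$verdict))
  cat(sprintf("  %d diagnostic sites covered, %d observations excluded as damage-consistent\n",
              x$n_sites_covered, x$n_excluded_damage))
  print(x$lineages)
  invisible(x)
}
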