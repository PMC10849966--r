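#' Terminal deamination damage model
#'
#' Parameterises the single-stranded-library damage signature: elevated
#' C-to-T substitution rates at both read ends (in read orientation),
#' decaying geometrically into the fragment, plus a uniform per-base
#' sequencing error. On a reverse-strand alignment the same substitutions
#' appear as G-to-A in reference orientation.
#'
#' @param delta5,delta3 Either the terminal (position 1) C->T probability,
#'   expanded geometrically with `lambda`, or a full per-position
#'   probability vector of length `window`.
#' @param lambda Geometric decay per position, `delta[i] = delta[1] * lambda^(i-1)`.
#' @param window Number of positions from each end that carry damage.
#' @param error_rate Per-base probability of a uniform random substitution
#'   (applies to every fragment, ancient or contaminant).
#' @return An object of class `damage_model`.
#' @export
damage_model <- function(delta5 = 0.4, delta3 = 0.4, lambda = 0.5,
                         window = 15, error_rate = 0.001) {
  stopifnot_scalar_number(window, "window", lower = 0)
  stopifnot_scalar_number(error_rate, "error_rate", lower = 0, upper = 1)
  expand <- function(d, nm) {
    if (length(d) == 1L) d <- d * lambda^(seq_len(window) - 1L)
    if (length(d) != window) {
      abort(sprintf("`%s` must have length 1 or `window`", nm),
            class = "ancientmt_invalid_argument")
    }
    if (any(d < 0 | d > 1)) {
      abort(sprintf("`%s` probabilities must lie in [0, 1]", nm),
            class = "ancientmt_invalid_argument")
    }
    d
  }
  structure(
    list(delta5 = expand(delta5, "delta5"), delta3 = expand(delta3, "delta3"),
         window = as.integer(window), error_rate = error_rate),
    class = "damage_model"
  )
}

#' Library construction parameters for the fragment simulator
#'
#' @param n_fragments Number of fragments to draw.
#' @param length_mean Median fragment length in bp (lognormal: meanlog =
#'   log(length_mean)). Default 55 bp, a typical ancient-DNA fragment size.
#' @param length_sd Lognormal sd on the log scale.
#' @param length_min,length_max Hard clamps on sampled lengths (bp).
#' @param contamination_fraction Probability that a fragment derives from
#'   the undamaged present-day contaminant genome.
#' @param duplicate_rate Probability that a fragment receives a PCR
#'   duplicate copy when passed to [inject_duplicates()].
#' @param mapq_min,mapq_max Mapping qualities are drawn uniformly from
#'   this integer range (defaults give a constant MQ 37).
#' @param seed Integer seed governing all randomness of the simulation.
#' @return An object of class `library_config`.
#' @export
library_config <- function(n_fragments, length_mean = 55, length_sd = 0.35,
                           length_min = 20, length_max = 150,
                           contamination_fraction = 0, duplicate_rate = 0,
                           mapq_min = 37, mapq_max = 37, seed = NULL) {
  stopifnot_scalar_number(n_fragments, "n_fragments", lower = 1)
  stopifnot_scalar_number(length_min, "length_min", lower = 20)
  stopifnot_scalar_number(contamination_fraction, "contamination_fraction",
                          lower = 0, upper = 1 - 1e-12)
  stopifnot_scalar_number(duplicate_rate, "duplicate_rate",
                          lower = 0, upper = 1 - 1e-12)
  if (mapq_max < mapq_min) {
    abort("`mapq_max` must be >= `mapq_min`",
          class = "ancientmt_invalid_argument")
  }
  structure(
    list(n_fragments = as.integer(n_fragments), length_mean = length_mean,
         length_sd = length_sd, length_min = as.integer(length_min),
         length_max = as.integer(length_max),
         contamination_fraction = contamination_fraction,
         duplicate_rate = duplicate_rate,
         mapq_min = as.integer(mapq_min), mapq_max = as.integer(mapq_max),
         seed = seed),
    class = "library_config"
  )
}

# per-observation damage probability lookup: d[k+1] for k in the window,
# 0 outside
delta_at <- function(delta, k) {
  out <- numeric(length(k))
  inside <- k >= 0L & k < length(delta)
  out[inside] <- delta[k[inside] + 1L]
  out
}

#' Simulate aligned ancient mtDNA fragments with a truth table
#'
#' Draws fragments uniformly on the circular reference (wrapping across
#' the origin), injects terminal C->T deamination into endogenous
#' fragments per the damage model, adds uniform sequencing error to every
#' fragment, and mixes in undamaged present-day contaminant fragments at
#' the configured fraction. Every per-fragment decision is recorded in the
#' returned truth table, so downstream estimators can be validated
#' against ground truth.
#'
#' @param ref A [reference_genome()].
#' @param damage A [damage_model()].
#' @param lib A [library_config()].
#' @param contaminant Either `NULL` (derive the contaminant genome by
#'   placing `contaminant_sites` random substitutions on the reference),
#'   or a single sequence string of reference length.
#' @param contaminant_sites Number of substitutions separating the
#'   default contaminant genome from the reference.
#' @return A list with elements:
#' \describe{
#'   \item{fragments}{tibble with one row per aligned base observation:
#'     `fragment_id`, `ref_start` (0-based), `strand`, `mapq`,
#'     `read_length`, `ref_pos` (0-based, wrapped), `read_pos` (0-based
#'     from the 5' read end, read orientation), `base` (reference
#'     orientation).}
#'   \item{truth}{tibble with one row per fragment: `fragment_id`,
#'     `origin`, `duplicate_set`, `source_genome`, `damage_positions`
#'     (comma-separated 0-based read positions of injected C->T),
#'     `n_damage`, and `template` (post-damage, pre-error read-orientation
#'     sequence, used to re-sequence PCR duplicates).}
#'   \item{contaminant}{the contaminant genome sequence (named).}
#' }
#' @export
simulate_fragments <- function(ref, damage = damage_model(),
                               lib = library_config(1000),
                               contaminant = NULL, contaminant_sites = 20) {
  if (!inherits(ref, "ref_genome")) {
    abort("`ref` must be a ref_genome", class = "ancientmt_invalid_argument")
  }
  if (ref$length < 1L) {
    abort("empty reference", class = "ancientmt_invalid_argument")
  }
  with_seed_or_not(lib$seed, {
    L <- ref$length
    ref_chars <- seq_chars(ref$sequence)

    cont_chars <- ref_chars
    if (is.null(contaminant)) {
      sites <- sample.int(L, min(contaminant_sites, L))
      for (s in sites) {
        cont_chars[s] <- sample(setdiff(DNA_BASES, ref_chars[s]), 1L)
      }
    } else {
      if (nchar(contaminant) != L) {
        abort("`contaminant` must match the reference length",
              class = "ancientmt_invalid_argument")
      }
      cont_chars <- seq_chars(toupper(contaminant))
    }

    n <- lib$n_fragments
    starts <- sample.int(L, n, replace = TRUE) - 1L
    lens <- as.integer(round(rlnorm(n, log(lib$length_mean), lib$length_sd)))
    lens <- pmin(pmax(lens, lib$length_min), lib$length_max)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    mapq <- if (lib$mapq_min == lib$mapq_max) rep(lib$mapq_min, n) else
      sample(seq.int(lib$mapq_min, lib$mapq_max), n, replace = TRUE)
    is_cont <- runif(n) < lib$contamination_fraction

    idx <- rep.int(seq_len(n), lens)          # fragment index per observation
    j1 <- sequence(lens)                      # 1-based offset along ref segment
    ref_pos <- (starts[idx] + j1 - 1L) %% L
    src <- ref_chars[ref_pos + 1L]
    cont_obs <- is_cont[idx]
    src[cont_obs] <- cont_chars[ref_pos[cont_obs] + 1L]

    minus <- strand[idx] == "-"
    read_pos <- j1 - 1L
    read_pos[minus] <- lens[idx][minus] - j1[minus]
    tmpl <- src                               # read orientation
    tmpl[minus] <- complement_base(src[minus])

    d5 <- delta_at(damage$delta5, read_pos)
    d3 <- delta_at(damage$delta3, lens[idx] - 1L - read_pos)
    p_dam <- 1 - (1 - d5) * (1 - d3)
    damaged <- !cont_obs & tmpl == "C" & runif(length(tmpl)) < p_dam
    read_base <- tmpl                         # post-damage, pre-error
    read_base[damaged] <- "T"

    # read-orientation template strings per fragment (for duplicates/tests):
    # one big collapsed string sliced by cumulative fragment lengths
    ord <- order(idx, read_pos)
    ends <- cumsum(lens)
    template <- substring(paste(read_base[ord], collapse = ""),
                          ends - lens + 1L, ends)

    err <- runif(length(read_base)) < damage$error_rate
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      b <- match(read_base[err], DNA_BASES)
      read_base[err] <- DNA_BASES[((b - 1L + shift) %% 4L) + 1L]
    }

    obs_base <- read_base
    obs_base[minus] <- complement_base(read_base[minus])

    fragments <- tibble(
      fragment_id = idx,
      ref_start = starts[idx],
      strand = strand[idx],
      mapq = as.integer(mapq[idx]),
      read_length = lens[idx],
      ref_pos = as.integer(ref_pos),
      read_pos = as.integer(read_pos),
      base = obs_base
    )
    attr(fragments, "error_rate") <- damage$error_rate
    attr(fragments, "ref_name") <- ref$name

    dam_pos <- rep("", n)
    if (any(damaged)) {
      dd <- tibble(id = idx[damaged], pos = read_pos[damaged]) |>
        dplyr::arrange(.data$id, .data$pos) |>
        dplyr::summarise(s = paste(.data$pos, collapse = ","), .by = "id")
      dam_pos[dd$id] <- dd$s
    }
    n_dam <- tabulate(idx[damaged], nbins = n)

    truth <- tibble(
      fragment_id = seq_len(n),
      origin = ifelse(is_cont, "contaminant", "endogenous"),
      duplicate_set = seq_len(n),
      source_genome = ifelse(is_cont, "contaminant", ref$name),
      damage_positions = dam_pos,
      n_damage = as.integer(n_dam),
      template = template
    )

    list(fragments = fragments, truth = truth,
         contaminant = setNames(paste(cont_chars, collapse = ""), "contaminant"))
  })
}

#' Inject PCR duplicates into a simulated fragment set
#'
#' Each fragment independently receives one extra copy with probability
#' `duplicate_rate`, so the total number of injected copies is
#' Binomial(n, rate). A copy shares start, end and strand with its
#' original and is re-sequenced from the original's post-damage template
#' with independent sequencing error. Applying the function repeatedly
#' can duplicate a duplicate; such copies join the original's duplicate
#' set in the truth table.
#'
#' @param fragments,truth Output of [simulate_fragments()].
#' @param duplicate_rate Per-fragment duplication probability in [0, 1).
#' @param seed Integer seed.
#' @param error_rate Per-base sequencing error applied to copies; defaults
#'   to the rate recorded on `fragments` by the simulator.
#' @return A list with updated `fragments` and `truth`.
#' @export
inject_duplicates <- function(fragments, truth, duplicate_rate, seed = NULL,
                              error_rate = attr(fragments, "error_rate")) {
  stopifnot_scalar_number(duplicate_rate, "duplicate_rate",
                          lower = 0, upper = 1 - 1e-12)
  if (is.null(error_rate)) error_rate <- 0
  if (duplicate_rate == 0) {
    return(list(fragments = fragments, truth = truth))
  }
  with_seed_or_not(seed, {
    ids <- truth$fragment_id
    sel <- ids[runif(length(ids)) < duplicate_rate]
    if (length(sel) == 0L) {
      return(list(fragments = fragments, truth = truth))
    }
    new_ids <- max(ids) + seq_along(sel)

    # re-sequence each copy from the stored template with fresh error
    tmpl_chars <- strsplit(truth$template[match(sel, ids)], "", fixed = TRUE)
    lens <- lengths(tmpl_chars)
    rb <- unlist(tmpl_chars, use.names = FALSE)
    err <- runif(length(rb)) < error_rate
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      b <- match(rb[err], DNA_BASES)
      rb[err] <- DNA_BASES[((b - 1L + shift) %% 4L) + 1L]
    }
    lookup <- tibble(
      fragment_id = rep.int(sel, lens),
      new_id = rep.int(new_ids, lens),
      read_pos = as.integer(sequence(lens) - 1L),
      read_base_new = rb
    )

    copies <- fragments |>
      dplyr::inner_join(lookup, by = c("fragment_id", "read_pos")) |>
      dplyr::mutate(
        base = ifelse(.data$strand == "-",
                      complement_base(.data$read_base_new),
                      .data$read_base_new),
        fragment_id = .data$new_id
      ) |>
      dplyr::select(-"new_id", -"read_base_new")

    orig <- truth[match(sel, ids), ]
    new_truth <- orig |>
      dplyr::mutate(fragment_id = new_ids)

    out_frag <- dplyr::bind_rows(fragments, copies)
    attr(out_frag, "error_rate") <- attr(fragments, "error_rate")
    attr(out_frag, "ref_name") <- attr(fragments, "ref_name")
    list(fragments = out_frag, truth = dplyr::bind_rows(truth, new_truth))
  })
}

#' Write / read the simulation truth table as TSV
#'
#' @param truth Truth tibble from [simulate_fragments()].
#' @param path File path.
#' @param keep_template Include the internal `template` column (default
#'   drops it: it is simulator state, not ground-truth metadata).
#' @return The path (write) or a tibble (read).
#' @export
write_truth <- function(truth, path, keep_template = FALSE) {
  out <- truth
  if (!keep_template) out$template <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(damage_positions = "c")) |>
    dplyr::mutate(damage_positions = dplyr::coalesce(.data$damage_positions, ""))
}
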