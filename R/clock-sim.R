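#' Simulate a serially sampled (dated-tip) coalescent tree
#'
#' Generates a random binary tree whose tips are sampled at the given
#' ages (years before present) and whose branch lengths are in years,
#' consistent with those ages (ultrametric in time). Coalescence waiting
#' times are exponential with mean `theta / (k choose 2)` for `k` active
#' lineages — a simple serial coalescent, adequate as substrate for
#' strict-clock simulations.
#'
#' @param tip_ages Named numeric vector of tip ages in years BP.
#' @param theta Coalescent time-scale parameter in years (default
#'   20000).
#' @param seed Integer seed.
#' @return A rooted `phylo` with branch lengths in years.
#' @export
simulate_dated_tree <- function(tip_ages, theta = 20000, seed = NULL) {
  if (length(tip_ages) < 2L || is.null(names(tip_ages))) {
    abort("`tip_ages` must be a named vector of length >= 2",
          class = "ancientmt_invalid_argument")
  }
  with_seed_or_not(seed, {
    pend <- sort(tip_ages)                 # youngest first
    active_lab <- character(0)             # newick fragments
    active_age <- numeric(0)
    t <- pend[1]
    repeat {
      ready <- names(pend)[pend <= t + 1e-9]
      if (length(ready) > 0L) {
        active_lab <- c(active_lab, ready)
        active_age <- c(active_age, pend[ready])
        pend <- pend[setdiff(names(pend), ready)]
      }
      if (length(active_lab) == 1L && length(pend) == 0L) break
      if (length(active_lab) < 2L) {
        t <- pend[1]
        next
      }
      k <- length(active_lab)
      wait <- stats::rexp(1, rate = choose(k, 2) / theta)
      if (length(pend) > 0L && pend[1] < t + wait) {
        t <- pend[1]
        next
      }
      t <- t + wait
      pair <- sample.int(k, 2L)
      lab <- sprintf("(%s:%.6f,%s:%.6f)",
                     active_lab[pair[1]], t - active_age[pair[1]],
                     active_lab[pair[2]], t - active_age[pair[2]])
      active_lab <- c(active_lab[-pair], lab)
      active_age <- c(active_age[-pair], t)
    }
    ape::read.tree(text = paste0(active_lab, ";"))
  })
}

check_tree_dates <- function(tree, dates, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(depths) <- tree$tip.label
  if (!all(tree$tip.label %in% names(dates))) {
    abort("every tip needs a date", class = "ancientmt_invalid_argument")
  }
  total <- depths + dates[tree$tip.label]
  if (diff(range(total)) > tol * max(1, max(total))) {
    abort(paste0("tree is not ultrametric in time: root-to-tip duration plus ",
                 "tip age differs across tips"),
          class = "ancientmt_invalid_argument")
  }
  invisible(total[1])
}

#' Evolve sequences along a dated tree under a strict Jukes-Cantor clock
#'
#' The root sequence is uniform random; along each branch of duration
#' `t` years every site keeps its base with probability
#' `1/4 + (3/4) exp(-(4/3) rate t)` and otherwise changes uniformly to
#' one of the other three bases (the exact Jukes-Cantor transition
#' kernel, so expected substitutions per site equal `rate * t`).
#'
#' @param tree A rooted `phylo` with branch lengths in years (e.g. from
#'   [simulate_dated_tree()]), ultrametric in time with respect to
#'   `tip_dates`.
#' @param rate Substitution rate in substitutions/site/year (>= 0).
#' @param seq_length Alignment length in bp.
#' @param tip_dates Named numeric vector of tip ages in years BP; used
#'   to validate the tree's time consistency.
#' @param seed Integer seed; identical seeds give identical alignments.
#' @return A list: `alignment` (named character vector over the tips),
#'   `tip_dates`, `root_sequence`.
#' @export
simulate_clock_alignment <- function(tree, rate, seq_length, tip_dates,
                                     seed = NULL) {
  stopifnot_scalar_number(rate, "rate", lower = 0)
  stopifnot_scalar_number(seq_length, "seq_length", lower = 1)
  check_tree_dates(tree, tip_dates_to_vector(tip_dates))
  with_seed_or_not(seed, {
    nt <- ape::Ntip(tree)
    nn <- nt + tree$Nnode
    seqs <- matrix(NA_integer_, nn, seq_length)
    root <- nt + 1L
    seqs[root, ] <- sample.int(4L, seq_length, replace = TRUE)
    tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      p_stay <- 0.25 + 0.75 * exp(-4 / 3 * rate * tr$edge.length[e])
      x <- seqs[par, ]
      change <- runif(seq_length) < 1 - p_stay
      nc <- sum(change)
      if (nc > 0L) {
        x[change] <- ((x[change] - 1L + sample.int(3L, nc, replace = TRUE)) %% 4L) + 1L
      }
      seqs[ch, ] <- x
    }
    alignment <- setNames(
      vapply(seq_len(nt), function(i) paste(DNA_BASES[seqs[i, ]], collapse = ""),
             character(1)),
      tree$tip.label
    )
    list(alignment = alignment,
         tip_dates = tip_dates_to_vector(tip_dates)[tree$tip.label],
         root_sequence = paste(DNA_BASES[seqs[root, ]], collapse = ""))
  })
}
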