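#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) log(1 - (4/3) p)` with `p` the mismatch fraction over
#' sites that are A/C/G/T in both sequences. Undefined (error) when
#' `p >= 0.75` or no sites are comparable.
#'
#' @param a,b Equal-length sequence strings (N allowed, excluded).
#' @return The corrected distance (substitutions/site).
#' @export
jc_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("sequences must have equal length",
          class = "ancientmt_invalid_argument")
  }
  x <- seq_chars(toupper(a))
  y <- seq_chars(toupper(b))
  both <- x %in% DNA_BASES & y %in% DNA_BASES
  if (!any(both)) {
    abort("no comparable (non-N) sites", class = "ancientmt_undefined_distance")
  }
  p <- mean(x[both] != y[both])
  if (p >= 0.75) {
    abort(sprintf("Jukes-Cantor distance undefined for p = %.3f >= 0.75", p),
          class = "ancientmt_undefined_distance")
  }
  -0.75 * log(1 - 4 / 3 * p)
}

jc_transform <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

# site-by-pair mismatch/comparable indicator matrices for fast
# column-bootstrap distance computation
pairwise_site_matrices <- function(alignment) {
  m <- vapply(alignment, seq_chars, character(nchar(alignment[1])))
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  k <- ncol(m)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  D <- matrix(0, nrow(m), nrow(pairs))
  V <- matrix(0, nrow(m), nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    v <- valid[, i] & valid[, j]
    V[, q] <- v
    D[, q] <- v & (m[, i] != m[, j])
  }
  list(D = D, V = V, pairs = pairs, ids = colnames(m), k = k)
}

# distance matrix from column weights (w = site multiplicities)
dist_from_weights <- function(ps, w) {
  diffs <- as.numeric(crossprod(ps$D, w))
  valids <- as.numeric(crossprod(ps$V, w))
  p <- ifelse(valids > 0, diffs / valids, NA_real_)
  d <- jc_transform(p)
  if (any(is.na(d))) return(NULL)
  out <- matrix(0, ps$k, ps$k, dimnames = list(ps$ids, ps$ids))
  out[ps$pairs] <- d
  out[ps$pairs[, c(2, 1), drop = FALSE]] <- d
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via ape), deterministic in taxon order.
#'
#' @param distance_matrix Symmetric numeric matrix with taxon dimnames
#'   (or a `dist`).
#' @return An unrooted `phylo`.
#' @export
build_nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3L) {
    abort("neighbour joining needs at least 3 taxa",
          class = "ancientmt_invalid_argument")
  }
  ape::nj(stats::as.dist(d))
}

#' Root a tree on an outgroup, midpoint of the separating branch
#'
#' Places the root at the midpoint of the branch separating the
#' outgroup tips from the ingroup. Errors if the outgroup is not
#' monophyletic under any rooting. Pairwise tip-to-tip path lengths are
#' preserved.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup_ids Tip labels of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup_ids) {
  missing_tips <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing_tips) > 0L) {
    abort(sprintf("outgroup tip(s) not in tree: %s",
                  paste(missing_tips, collapse = ", ")),
          class = "ancientmt_invalid_argument")
  }
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE),
    error = function(e) {
      abort(paste0("cannot root: ", conditionMessage(e)),
            class = "ancientmt_invalid_argument")
    }
  )
  if (!ape::is.monophyletic(rooted, outgroup_ids)) {
    abort("outgroup is not monophyletic in the rooted tree",
          class = "ancientmt_invalid_argument")
  }
  root_node <- ape::Ntip(rooted) + 1L
  idx <- which(rooted$edge[, 1] == root_node)
  if (length(idx) == 2L) {
    total <- sum(rooted$edge.length[idx])
    rooted$edge.length[idx] <- total / 2
  }
  rooted
}

tip_dates_to_vector <- function(tip_dates) {
  if (is.data.frame(tip_dates)) {
    setNames(tip_dates$age_bp, tip_dates$id)
  } else {
    tip_dates
  }
}

#' Least-squares strict-clock fit from root-to-tip distances
#'
#' Under a strict clock on a tree rooted with an outgroup, the
#' root-to-tip distance of a tip sampled `t` years before present is
#' `y = intercept - rate * t` (older tips are closer to the root).
#' Ordinary least squares over the dated calibration tips estimates the
#' substitution rate and the intercept; an undated query's age is then
#' obtained by inverting the regression at its own root-to-tip distance
#' (see [estimate_tip_date()]).
#'
#' @param rooted_tree A rooted `phylo` with branch lengths in
#'   substitutions/site.
#' @param tip_dates Named numeric vector (or tibble with `id`,
#'   `age_bp`) of calibration ages in years before present; only tips
#'   present in the tree are used.
#' @return An object of class `clock_fit`: `rate`
#'   (substitutions/site/year), `intercept`, `r_squared`, `residuals`,
#'   `n_calibration`, and the underlying `lm` as `model`.
#' @export
fit_strict_clock <- function(rooted_tree, tip_dates) {
  dates <- tip_dates_to_vector(tip_dates)
  depths <- ape::node.depth.edgelength(rooted_tree)[seq_len(ape::Ntip(rooted_tree))]
  names(depths) <- rooted_tree$tip.label
  cal <- intersect(names(dates), rooted_tree$tip.label)
  if (length(cal) < 3L) {
    abort("need at least 3 dated calibration tips",
          class = "ancientmt_invalid_argument")
  }
  age <- dates[cal]
  if (isTRUE(all.equal(var(age), 0)) || var(age) == 0) {
    abort("calibration tips must span a nonzero date range",
          class = "ancientmt_invalid_argument")
  }
  df <- data.frame(y = depths[cal], age = age)
  fit <- lm(y ~ age, data = df)
  rate <- -unname(coef(fit)[2])
  structure(
    list(rate = rate, intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         residuals = setNames(stats::residuals(fit), cal),
         n_calibration = length(cal), model = fit,
         tip_depths = depths),
    class = "clock_fit"
  )
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf(
    "<clock_fit> rate = %.3g subs/site/yr, intercept = %.4g, R^2 = %.3f (n = %d)\n",
    x$rate, x$intercept, x$r_squared, x$n_calibration))
  if (x$rate <= 0) cat("  rate <= 0: inversion for dating refused\n")
  invisible(x)
}

invert_clock <- function(fit, y_query) {
  if (!is.finite(fit$rate) || fit$rate <= 0) return(NA_real_)
  unname(fit$intercept - y_query) / fit$rate
}

#' Estimate a query genome's age by tip-calibrated strict-clock dating
#'
#' Runs the full least-squares dating chain: Jukes-Cantor distances
#' over the alignment, neighbour joining, rooting on the outgroup,
#' root-to-tip regression over the dated calibration tips, and
#' inversion of the regression at the query's root-to-tip distance.
#' Uncertainty comes from a bootstrap over alignment columns,
#' re-running the whole chain per replicate (95% percentile interval).
#' This is a transparent approximation to full Bayesian tip dating:
#' no coalescent prior and no posterior — point estimate and bootstrap
#' interval only.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (query, calibration tips, outgroup).
#' @param tip_dates Named numeric vector (or tibble `id`, `age_bp`) of
#'   ages in years BP for the calibration tips.
#' @param query_id Name of the sequence to date.
#' @param outgroup_ids Names of the outgroup sequences used for rooting
#'   (excluded from the regression).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `date_estimate`: `point`, `ci_low`,
#'   `ci_high` (years BP), `n_boot`, `n_failed`, `rate`, `r_squared`,
#'   `fit` (the full-data [fit_strict_clock()]), `query_id`, `seed`.
#' @export
estimate_tip_date <- function(alignment, tip_dates, query_id, outgroup_ids,
                              n_boot = 200, seed = NULL) {
  dates <- tip_dates_to_vector(tip_dates)
  if (!query_id %in% names(alignment)) {
    abort("query not present in alignment",
          class = "ancientmt_invalid_argument")
  }
  if (!all(outgroup_ids %in% names(alignment))) {
    abort("outgroup not present in alignment",
          class = "ancientmt_invalid_argument")
  }
  cal_ids <- setdiff(intersect(names(dates), names(alignment)),
                     c(query_id, outgroup_ids))
  dates <- dates[cal_ids]
  ps <- pairwise_site_matrices(alignment)
  L <- nrow(ps$D)

  chain <- function(w) {
    d <- dist_from_weights(ps, w)
    if (is.null(d)) return(list(date = NA_real_, fit = NULL))
    tree <- build_nj_tree(d)
    tree$edge.length[tree$edge.length < 0] <- 0  # NJ can emit tiny negatives
    rooted <- tryCatch(root_on_outgroup(tree, outgroup_ids),
                       error = function(e) NULL)
    if (is.null(rooted)) return(list(date = NA_real_, fit = NULL))
    fit <- tryCatch(fit_strict_clock(rooted, dates),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(date = NA_real_, fit = NULL))
    list(date = invert_clock(fit, fit$tip_depths[query_id]), fit = fit)
  }

  full <- chain(rep(1, L))
  if (is.null(full$fit) || is.na(full$date)) {
    abort(paste0("tip dating failed: non-positive clock rate or undefined ",
                 "distances on the full alignment"),
          class = "ancientmt_clock_failure")
  }

  boots <- with_seed_or_not(seed, {
    W <- stats::rmultinom(n_boot, L, rep(1 / L, L))
    vapply(seq_len(n_boot), function(b) chain(W[, b])$date, numeric(1))
  })
  ok <- is.finite(boots)
  n_failed <- sum(!ok)
  ci <- if (any(ok)) stats::quantile(boots[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)

  structure(
    list(point = full$date,
         ci_low = min(ci[1], full$date), ci_high = max(ci[2], full$date),
         n_boot = n_boot, n_failed = n_failed,
         rate = full$fit$rate, r_squared = full$fit$r_squared,
         fit = full$fit, query_id = query_id, seed = seed),
    class = "date_estimate"
  )
}

#' @export
print.date_estimate <- function(x, ...) {
  cat(sprintf(
    "<date_estimate> %s: %.0f yr BP [%.0f, %.0f] (least-squares strict clock, %d bootstrap replicates, %d failed)\n",
    x$query_id, x$point, x$ci_low, x$ci_high, x$n_boot, x$n_failed))
  invisible(x)
}
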