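#' Tidiers for ancientmt result objects
#'
#' broom-style `tidy()` / `glance()` methods: `tidy()` returns the
#' per-unit table of a result (per position, per lineage, per site,
#' per term), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name ancientmt-tidiers
NULL

#' @rdname ancientmt-tidiers
#' @export
tidy.damage_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "damage_profile")
  as_tibble(out)
}

#' @rdname ancientmt-tidiers
#' @export
glance.damage_profile <- function(x, ...) {
  first <- function(end) x$frequency[x$end == end & x$position == 1L]
  tibble(
    ct5_terminal = first("5p"), ct3_terminal = first("3p"),
    window = attr(x, "window"), n_fragments = attr(x, "n_fragments")
  )
}

#' @rdname ancientmt-tidiers
#' @export
tidy.contamination_estimate <- function(x, ...) {
  tibble(estimate = x$point, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname ancientmt-tidiers
#' @export
glance.contamination_estimate <- function(x, ...) {
  tibble(
    point = x$point, ci_low = x$ci_low, ci_high = x$ci_high,
    p_terminal = x$p_terminal, p_conditional = x$p_conditional,
    n_conditioning = x$n_conditioning, n_fragments = x$n_fragments,
    n_boot = x$n_boot
  )
}

#' @rdname ancientmt-tidiers
#' @export
tidy.lineage_assignment <- function(x, ...) x$lineages

#' @rdname ancientmt-tidiers
#' @export
glance.lineage_assignment <- function(x, ...) {
  tibble(
    verdict = x$verdict, n_sites_covered = x$n_sites_covered,
    n_excluded_damage = x$n_excluded_damage,
    damage_aware = x$params$damage_aware
  )
}

#' @rdname ancientmt-tidiers
#' @export
tidy.consensus_genome <- function(x, ...) x$sites

#' @rdname ancientmt-tidiers
#' @export
glance.consensus_genome <- function(x, ...) {
  tibble(
    name = x$name, length = x$length, n_called = sum(x$sites$called),
    n_missing = sum(!x$sites$called),
    fraction_called = mean(x$sites$called), mode = x$mode_used
  )
}

#' @rdname ancientmt-tidiers
#' @export
tidy.clock_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname ancientmt-tidiers
#' @export
glance.clock_fit <- function(x, ...) {
  tibble(rate = x$rate, intercept = x$intercept, r.squared = x$r_squared,
         n_calibration = x$n_calibration)
}

#' @rdname ancientmt-tidiers
#' @export
tidy.date_estimate <- function(x, ...) {
  tibble(query = x$query_id, estimate = x$point,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname ancientmt-tidiers
#' @export
glance.date_estimate <- function(x, ...) {
  tibble(
    query = x$query_id, point = x$point, ci_low = x$ci_low,
    ci_high = x$ci_high, rate = x$rate, r_squared = x$r_squared,
    n_boot = x$n_boot, n_failed = x$n_failed
  )
}
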