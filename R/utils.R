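DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_base(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Wilson score interval for a binomial proportion
#'
#' Small-count-safe interval used for per-position damage frequencies.
#' Returns NA bounds where `n` is zero (the frequency is undefined there,
#' not zero).
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials (vectorised).
#' @param conf Confidence level, default 0.95.
#' @return A tibble with columns `low` and `high`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(
    low  = ifelse(n > 0, pmax(0, centre - half), NA_real_),
    high = ifelse(n > 0, pmin(1, centre + half), NA_real_)
  )
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses the current stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "ancientmt_invalid_argument")
  }
  invisible(x)
}
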