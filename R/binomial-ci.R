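#' Binomial proportion with confidence interval
#'
#' Wilson score interval by default (well-behaved at proportions near 0 and
#' 1, as seen at habituated tap-30 levels); Clopper-Pearson (exact) by flag.
#' The method used is always recorded in the result.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return a `proportion_ci`: list with `numerator`, `denominator`,
#'   `proportion`, `ci_low`, `ci_high`, `method`, `level`.
#' @examples
#' binomial_ci(8, 10)
#' @export
binomial_ci <- function(k, n, level = 0.95,
                        method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(is.numeric(k), is.numeric(n), length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("undefined proportion: n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("require 0 <= k <= n", call. = FALSE)
  p <- k / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    denom <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / denom
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, ctr - hw)
    hi <- min(1, ctr + hw)
  } else {
    a <- 1 - level
    lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  }
  structure(list(numerator = k, denominator = n, proportion = p,
                 ci_low = lo, ci_high = hi, method = method, level = level),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f  [%0.*f%% CI: %.3f, %.3f] (%s)\n",
              x$numerator, x$denominator, x$proportion,
              0, 100 * x$level, x$ci_low, x$ci_high, x$method))
  invisible(x)
}
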