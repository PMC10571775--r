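#' Hill regulation factor
#'
#' Dimensionless saturating factor used throughout the Hippo module for
#' non-stoichiometric regulation: the inhibition of Dachs membrane binding by
#' membrane Fat (decreasing) and the promotion of Riquiqui membrane binding by
#' membrane Dachsous (increasing).
#'
#' @param x Regulator concentration (>= 0).
#' @param K Half-saturation constant (> 0), same units as `x`.
#' @param n Hill exponent (>= 1).
#' @param direction `"increasing"` gives `x^n / (K^n + x^n)`, `"decreasing"`
#'   gives `K^n / (K^n + x^n)`.
#' @return A value in `[0, 1]`; vectorized over `x`.
#' @examples
#' hill_factor(0, 1, 2, "decreasing")  # 1
#' hill_factor(2, 1, 2, "increasing")  # 0.8
#' @export
hill_factor <- function(x, K, n, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0)
    stop("`K` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a single number >= 1", call. = FALSE)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  # compute on the ratio scale for numerical safety at large x
  r <- (x / K)^n
  if (direction == "increasing") r / (1 + r) else 1 / (1 + r)
}
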