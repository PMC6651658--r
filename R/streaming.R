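# Streaming scalar statistics shared by the walking detector and the
# attitude estimator's adaptive gain.

#' Sliding-window unbiased sample variance
#'
#' One-pass sliding variance with the unbiased (N-1) denominator. The first
#' \code{window - 1} samples are a warm-up period and are returned as
#' \code{NA} (the variance is undefined before the window first fills).
#' Rolling sums are accumulated by direct convolution, so the result matches
#' a two-pass recomputation over each window to floating-point accuracy.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 2).
#' @return Numeric vector the same length as \code{x}; element k is the
#'   unbiased variance of \code{x[(k - window + 1):k]}, \code{NA} during
#'   warm-up.
#' @examples
#' running_variance(c(1, 2, 3, 4), 4)  # ..., 5/3
#' @export
running_variance <- function(x, window) {
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  n <- length(x)
  if (n == 0) return(numeric(0))
  kernel <- rep(1, window)
  s1 <- stats::filter(x, kernel, sides = 1)
  s2 <- stats::filter(x^2, kernel, sides = 1)
  v <- (s2 - s1^2 / window) / (window - 1)
  v <- as.numeric(v)
  # guard tiny negative values from cancellation on near-constant input
  v[!is.na(v) & v < 0] <- 0
  v
}

# Rolling mean with NA warm-up, same alignment as running_variance.
running_mean <- function(x, window) {
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
}
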