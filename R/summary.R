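#' Shortest (highest posterior density) interval
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.95).
#' @return length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  k <- n - m
  if (k < 1L) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1L:k]
  j <- which.min(widths)
  c(x[j], x[j + m])
}

#' Posterior mode by kernel density
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth; the mode
#' is the density argmax.
#'
#' @param x numeric draws.
#' @return scalar mode estimate.
#' @export
posterior_mode <- function(x) {
  if (sd(x) == 0) return(x[1L])
  d <- density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Summarize posterior draws
#'
#' Per parameter: posterior mean, kernel-density mode, 95% highest posterior
#' density interval, and the percentage of draws that are negative.
#'
#' @param x an \code{epp_fit}, \code{epp_derived}, or a numeric matrix of
#'   draws (columns = parameters).
#' @param prob HPD mass.
#' @return data frame with one row per parameter.
#' @export
summarize_posterior <- function(x, prob = 0.95) {
  draws <- if (is.matrix(x)) x else x$draws
  stopifnot(is.matrix(draws), nrow(draws) >= 2L)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    mode = apply(draws, 2, posterior_mode),
    hpd_lower = apply(draws, 2, function(v) hpd_interval(v, prob)[1L]),
    hpd_upper = apply(draws, 2, function(v) hpd_interval(v, prob)[2L]),
    pct_negative = 100 * colMeans(draws < 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
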