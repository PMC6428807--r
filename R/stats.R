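# Nonparametric inference: exact paired signed-rank test and Spearman
# correlation.

#' Paired Wilcoxon signed-rank test
#'
#' Tests paired differences (by convention control minus blocked) with the
#' Wilcoxon signed-rank statistic. Exact zeros are dropped first. For
#' n <= 25 the null distribution of W+ is computed exactly by dynamic
#' programming over all 2^n sign assignments of the (possibly tied,
#' average-ranked) absolute ranks, so ties do not force an approximation;
#' above that a normal approximation with tie correction and continuity
#' correction is used. The right tail asks whether the differences are
#' systematically positive.
#'
#' @param d numeric vector of paired differences.
#' @param tail \code{"right"}, \code{"left"} or \code{"two"}.
#' @param exact_max largest n for which the exact distribution is used
#'   (default 25).
#' @return List with \code{p_value}, \code{statistic} (W+), \code{n} (after
#'   zero-dropping), \code{method} and \code{all_zero}.
#' @export
paired_signed_rank <- function(d, tail = c("right", "left", "two"),
                               exact_max = 25L) {
  tail <- match.arg(tail)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, statistic = 0, n = 0L, method = "degenerate",
                all_zero = TRUE))
  r <- rank(abs(d), ties.method = "average")
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    # work with doubled ranks: average ranks over ties are multiples of 1/2
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)   # f[s + 1] = P(2 W+ = s)
    f[1L] <- 1
    for (v in r2) {
      g <- f / 2
      g[(v + 1L):(total + 1L)] <- g[(v + 1L):(total + 1L)] +
        f[1L:(total + 1L - v)] / 2
      f <- g
    }
    w2 <- as.integer(round(2 * w_pos))
    p_right <- sum(f[(w2 + 1L):(total + 1L)])
    p_left <- sum(f[1L:(w2 + 1L)])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    p_right <- stats::pnorm((w_pos - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_left <- stats::pnorm((w_pos + 0.5 - mu) / sigma)
    method <- "normal"
  }
  p <- switch(tail,
              right = p_right,
              left = p_left,
              two = min(1, 2 * min(p_right, p_left)))
  list(p_value = min(1, p), statistic = w_pos, n = n, method = method,
       all_zero = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average fractional ranks; constant input yields an
#' undefined (NA) correlation, flagged rather than raised.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with \code{rho} and \code{defined}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, defined = FALSE))
  list(rho = stats::cor(x, y, method = "spearman"), defined = TRUE)
}
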