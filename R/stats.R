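#' Bland-Altman agreement analysis of paired measurements
#'
#' Differences `d = a - b` are summarized by their mean (bias), sample
#' standard deviation and the 95% limits of agreement `bias +/- 1.96 sd`
#' (the fixed 1.96 multiplier, not a t quantile). The bias is tested for
#' difference from zero with a two-sided one-sample t-test.
#'
#' @param a,b paired measurements (method A and method B), length >= 2.
#' @return object of class `bland_altman`: `bias`, `sd`, `limits`
#'   (length-2 vector), `bias_p`, `differences`, `means`, `n`.
#' @examples
#' ba <- bland_altman(c(10, 12, 11), c(11, 12, 13))
#' ba$limits
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) NA_real_ else stats::t.test(d, mu = 0)$p.value
  structure(list(bias = bias, sd = s,
                 limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 bias_p = p, differences = d, means = (a + b) / 2,
                 n = length(d)),
            class = "bland_altman")
}

#' Bland-Altman limits from a printed bias and SD
#'
#' Convenience for reproducing published agreement tables:
#' `bias +/- 1.96 sd`, rounded half-up to `digits` decimals.
#'
#' @param bias mean difference.
#' @param sd standard deviation of the differences.
#' @param digits decimals of the printed table.
#' @return length-2 vector `c(lower, upper)`.
#' @examples
#' bland_altman_limits(-1.6, 3.8)  # -9.0  5.8
#' @export
bland_altman_limits <- function(bias, sd, digits = 1) {
  round_half_up(c(lower = bias - 1.96 * sd, upper = bias + 1.96 * sd), digits)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g (SD %.3g), 95%% limits [%.3g, %.3g], n = %d\n",
              x$bias, x$sd, x$limits[1], x$limits[2], x$n))
  if (!is.na(x$bias_p)) cat(sprintf("  bias vs 0: p = %.3g\n", x$bias_p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference (A - B)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::abline(h = x$bias, lwd = 2, col = "grey40")
  graphics::abline(h = x$limits, lty = 2, col = "grey40")
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance (and unequal-size) two-sample t-test with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; a thin
#' wrapper over [stats::t.test()] returning the three quantities directly.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("Welch's t-test is undefined when both samples have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# exact null distribution of the positive-rank sum for (possibly tied)
# absolute-difference ranks, via the generating-polynomial convolution on
# doubled (hence integer) mid-ranks
signed_rank_exact_cdf <- function(ranks2) {
  total <- sum(ranks2)
  coef <- numeric(total + 1)  # index = doubled rank sum + 1
  coef[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), coef[seq_len(total + 1 - r)])
    coef <- coef + shifted
  }
  coef / sum(coef)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are discarded (the classical treatment; an alternative
#' keeps them, which this package does not implement), tied absolute
#' differences receive mid-ranks, and the statistic `W` is the sum of the
#' ranks of the positive differences. For `n <= exact_max` nonzero
#' differences the two-sided p-value is exact, computed from the full
#' distribution of `W` over all sign assignments (mid-rank ties included);
#' beyond that a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param d paired differences.
#' @param exact_max largest n for which the exact distribution is
#'   enumerated.
#' @return list with `w`, `p`, `n` (nonzero differences), `exact`.
#' @examples
#' wilcoxon_signed_rank(c(-1, -2, -0.5, -3, -1.5))  # all negative: W = 0
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("signed-rank test undefined: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    cdf <- signed_rank_exact_cdf(as.integer(round(2 * r)))
    w2 <- as.integer(round(2 * w))
    p_le <- sum(cdf[seq_len(w2 + 1)])
    p_ge <- sum(cdf[seq(w2 + 1, length(cdf))])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(w = w, p = p, n = n, exact = exact)
}
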