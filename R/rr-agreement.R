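#' Paired RR-interval series from two devices
#'
#' Two aligned sequences of RR intervals (seconds), e.g. a prototype monitor
#' against a reference bedside monitor; alignment is positional and must be
#' done upstream.
#'
#' @param rr_a,rr_b numeric vectors of equal length, all values > 0.
#' @return An object of class `rr_paired`.
#' @export
rr_paired <- function(rr_a, rr_b) {
  rr_a <- as.numeric(rr_a)
  rr_b <- as.numeric(rr_b)
  if (length(rr_a) != length(rr_b)) {
    stop("paired RR series must have equal lengths", call. = FALSE)
  }
  if (length(rr_a) < 1L) stop("need at least one pair", call. = FALSE)
  if (any(rr_a <= 0) || any(rr_b <= 0)) {
    stop("RR intervals must be positive", call. = FALSE)
  }
  structure(list(rr_a = rr_a, rr_b = rr_b), class = "rr_paired")
}

#' Wilcoxon signed-rank test for paired RR intervals
#'
#' Tests whether the paired differences `a - b` are symmetric about zero.
#' Zero differences are dropped before ranking (the classic convention;
#' `zero_method = "pratt"` ranks them first and drops them after). Ties in
#' the absolute differences receive midranks. For `n <= exact_limit`
#' non-zero pairs the exact two-sided p-value is computed from the full null
#' distribution of the positive-rank sum over all sign assignments
#' (evaluated by convolution, identical to explicit enumeration); for larger
#' `n` a normal approximation with continuity and tie correction is used.
#'
#' If every difference is zero the devices agree exactly and `p = 1` by
#' convention.
#'
#' @param pairs an [rr_paired()] (or numeric vector `rr_a` with `rr_b`
#'   supplied).
#' @param rr_b second series when `pairs` is a plain numeric vector.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_limit largest number of non-zero pairs for which the exact
#'   distribution is used (default 25).
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n_pairs`,
#'   `n_zero_diffs`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(rr_paired(c(1.1, 1.2, 1.3, 1.4, 1.5), rep(1, 5)))$p_value
#' # 0.0625: all five differences positive, 2/2^5
wilcoxon_signed_rank <- function(pairs, rr_b = NULL,
                                 zero_method = c("drop", "pratt"),
                                 exact_limit = 25L) {
  zero_method <- match.arg(zero_method)
  if (!inherits(pairs, "rr_paired")) pairs <- rr_paired(pairs, rr_b)
  d <- pairs$rr_a - pairs$rr_b
  n_all <- length(d)
  zero <- d == 0
  n_zero <- sum(zero)

  if (zero_method == "drop") {
    d <- d[!zero]
    if (length(d) == 0L) {
      return(list(statistic = 0, p_value = 1, n_pairs = n_all,
                  n_zero_diffs = n_zero, method = "all differences zero"))
    }
    r <- rank(abs(d))
  } else {
    if (all(zero)) {
      return(list(statistic = 0, p_value = 1, n_pairs = n_all,
                  n_zero_diffs = n_zero, method = "all differences zero"))
    }
    r_all <- rank(abs(d))       # zeros included in the ranking (Pratt)
    r <- r_all[!zero]
    d <- d[!zero]
  }

  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    p <- signed_rank_normal_p(r, v)
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_pairs = n_all,
       n_zero_diffs = n_zero, method = method)
}

# Exact two-sided p for the positive-rank sum. Ranks are midranks, so 2*r is
# integer; the null distribution of 2*V is built by convolving the
# generating polynomials (1 + z^(2*r_i))/2 — the same distribution explicit
# enumeration of all 2^n sign vectors yields.
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1L)   # dist[w + 1] = P(2V = w)
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1L - ri)])
    dist <- (dist + shifted) / 2
  }
  v2 <- as.integer(round(2 * v))
  p_ge <- sum(dist[(v2 + 1L):(total + 1L)])
  p_le <- sum(dist[1:(v2 + 1L)])
  min(1, 2 * min(p_ge, p_le))
}

# Normal approximation with continuity correction and tie correction.
signed_rank_normal_p <- function(r, v) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(1)
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' MA-plot coordinates for paired RR intervals
#'
#' For each pair `(a, b)` the plot point is `(mean, difference) =
#' ((a + b) / 2, a - b)`; order is preserved.
#'
#' @param pairs an [rr_paired()].
#' @return data.frame with columns `mean` and `difference` (seconds).
#' @export
ma_points <- function(pairs) {
  stopifnot(inherits(pairs, "rr_paired"))
  data.frame(mean = (pairs$rr_a + pairs$rr_b) / 2,
             difference = pairs$rr_a - pairs$rr_b)
}

#' Fraction of pairs inside an agreement band
#'
#' The fraction of pairs whose absolute difference `|a - b|` is at most
#' `band` seconds (default 0.1 s, the band used to judge prototype/reference
#' agreement).
#'
#' @param pairs an [rr_paired()].
#' @param band half-width of the agreement band (s), > 0.
#' @return Fraction in `[0, 1]`.
#' @export
band_fraction <- function(pairs, band = 0.1) {
  stopifnot(inherits(pairs, "rr_paired"))
  if (band <= 0) stop("band must be positive", call. = FALSE)
  mean(abs(pairs$rr_a - pairs$rr_b) <= band)
}

#' Full agreement report for two RR series
#'
#' Combines the Wilcoxon signed-rank test, MA-plot coordinates and the
#' agreement-band fraction into one object.
#'
#' @param pairs an [rr_paired()].
#' @param band agreement band half-width (s).
#' @param alpha significance threshold reported alongside the p-value.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return An object of class `rr_agreement`.
#' @export
rr_agreement <- function(pairs, band = 0.1, alpha = 0.05, ...) {
  stopifnot(inherits(pairs, "rr_paired"))
  w <- wilcoxon_signed_rank(pairs, ...)
  structure(list(wilcoxon_statistic = w$statistic, p_value = w$p_value,
                 method = w$method, alpha = alpha,
                 significant = w$p_value < alpha,
                 n_pairs = w$n_pairs, n_zero_diffs = w$n_zero_diffs,
                 ma_points = ma_points(pairs),
                 band = band, band_fraction = band_fraction(pairs, band)),
            class = "rr_agreement")
}

#' @export
print.rr_agreement <- function(x, ...) {
  cat(sprintf("<rr_agreement> %d pairs (%d zero diffs)\n", x$n_pairs,
              x$n_zero_diffs))
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.3f (%s) -> %s at alpha = %g\n",
              x$wilcoxon_statistic, x$p_value, x$method,
              if (x$significant) "significantly different"
              else "not significantly different", x$alpha))
  cat(sprintf("within +/-%g s band: %.1f%% of pairs\n", x$band,
              100 * x$band_fraction))
  invisible(x)
}

#' @export
plot.rr_agreement <- function(x, ...) {
  plot(x$ma_points$mean, x$ma_points$difference,
       xlab = "mean RR (s)", ylab = "difference (s)",
       main = "RR interval MA plot", pch = 20, ...)
  graphics::abline(h = c(-x$band, 0, x$band), lty = c(2, 1, 2))
  invisible(x)
}
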