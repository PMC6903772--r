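#' Bland-Altman comparison of two paired measurement methods
#'
#' For paired values from two methods measuring the same samples, computes
#' per-pair means and differences, the bias (mean difference), the standard
#' deviation of the differences and the limits of agreement
#' bias +/- k * sd (k = 1.96 for nominal 95% limits under normality).
#'
#' @param x,y Numeric vectors of paired measurements (method A, method B),
#'   equal length >= 2.
#' @param k Multiplier for the limits of agreement (default 1.96).
#' @param shapiro If TRUE, also run a Shapiro-Wilk normality test on the
#'   differences (delegated to [stats::shapiro.test()]; requires
#'   3 <= n <= 5000).
#' @return Object of class `bland_altman`: list with `means`, `diffs`,
#'   `bias`, `sd`, `loa` (length-2), `k`, `n` and optionally `shapiro_p`.
#' @export
bland_altman <- function(x, y, k = 1.96, shapiro = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("pairing error: x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  stopifnot(all(is.finite(x)), all(is.finite(y)), k > 0)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  res <- list(means = (x + y) / 2, diffs = d, bias = bias, sd = s,
              loa = c(lower = bias - k * s, upper = bias + k * s),
              k = k, n = length(x))
  if (shapiro) res$shapiro_p <- stats::shapiro.test(d)$p.value
  structure(res, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman comparison (n = %d pairs)\n", x$n))
  cat(sprintf("  bias                %.6g\n", x$bias))
  cat(sprintf("  sd of differences   %.6g\n", x$sd))
  cat(sprintf("  limits of agreement [%.6g, %.6g]  (bias +/- %.3g sd)\n",
              x$loa[1], x$loa[2], x$k))
  if (!is.null(x$shapiro_p))
    cat(sprintf("  Shapiro-Wilk p      %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-pair mean against per-pair difference with the bias (dotted) and the
#' limits of agreement (dashed).
#'
#' @param x A [bland_altman()] result.
#' @param xlab,ylab,... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference (A - B)", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, lty = 3)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Error as a percentage of the measured range
#'
#' Expresses an absolute error (e.g. a Bland-Altman bias or limit of
#' agreement in ratio units) relative to the span of values actually
#' measured.
#'
#' @param value The error, in measurement units (sign ignored).
#' @param range_lo,range_hi Lower and upper end of the measured range.
#' @return 100 * |value| / (range_hi - range_lo).
#' @export
relative_error <- function(value, range_lo, range_hi) {
  stopifnot(is.numeric(value), range_hi > range_lo)
  100 * abs(value) / (range_hi - range_lo)
}

#' Pairwise paired t-tests with Bonferroni adjustment
#'
#' One paired t-test per named comparison; p-values multiplied by the number
#' of comparisons and capped at 1. Comparisons whose adjusted p is below
#' `alpha` get distinct significance letters for their two members ("a" vs
#' "b"); non-significant comparisons share the letter "a".
#'
#' If the paired differences have zero variance, the classical t statistic
#' is undefined: a nonzero mean difference is then reported as p = 0 with a
#' `degenerate` flag (the methods differ by an exact constant); a zero mean
#' difference as p = 1.
#'
#' @param groups Named list; each element a list or data.frame with two
#'   equal-length numeric components (the paired samples).
#' @param alpha Significance level for the letters (default 0.05).
#' @return data.frame with columns `comparison`, `n`, `mean_diff`, `t`,
#'   `df`, `p_raw`, `p_adj`, `degenerate`, `letters`.
#' @export
paired_t_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  m <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("pair", seq_len(m))
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    x <- as.numeric(g[[1]]); y <- as.numeric(g[[2]])
    if (length(x) != length(y)) stop("pairing error in '", nm, "'")
    if (length(x) < 2L) stop("need n >= 2 pairs in '", nm, "'")
    d <- x - y
    degen <- stats::sd(d) == 0
    if (degen) {
      p <- if (mean(d) == 0) 1 else 0
      tt <- if (mean(d) == 0) 0 else Inf
    } else {
      ht <- stats::t.test(x, y, paired = TRUE)
      p <- ht$p.value; tt <- unname(ht$statistic)
    }
    data.frame(comparison = nm, n = length(x), mean_diff = mean(d),
               t = tt, df = length(x) - 1L, p_raw = p,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$letters <- ifelse(out$p_adj < alpha, "a|b", "a|a")
  out[, c("comparison", "n", "mean_diff", "t", "df",
          "p_raw", "p_adj", "degenerate", "letters")]
}

#' Simulated instrument-agreement distribution
#'
#' Repeatedly measures the same set of true compositions under two
#' instrument profiles (replicate means as the per-sample value, no
#' systematic offset modeled) and collects the Bland-Altman summary of each
#' simulated comparison. With profiles at realistic settings the bias
#' distribution is centered on zero and the limits' width is dominated by
#' the noisier (Q) profile.
#'
#' @param true_avs List of true [abundance_vector()]s (the samples).
#' @param profile_a,profile_b Two [instrument_profile()]s.
#' @param n_sims Number of simulated paired comparisons.
#' @param seed Base seed (deterministic output).
#' @return data.frame with one row per simulation: `bias`, `sd`,
#'   `loa_lower`, `loa_upper`, `n_pairs`.
#' @export
simulate_instrument_agreement <- function(true_avs, profile_a, profile_b,
                                          n_sims = 100L, seed = 1L) {
  stopifnot(is.list(true_avs), length(true_avs) >= 2L)
  rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    va <- vapply(seq_along(true_avs), function(i) {
      run <- simulate_measurement(true_avs[[i]], profile_a, t = 0,
                                  seed = derive_seed(seed, s, i, 1L))
      mean(run$R66)
    }, numeric(1))
    vb <- vapply(seq_along(true_avs), function(i) {
      run <- simulate_measurement(true_avs[[i]], profile_b, t = 0,
                                  seed = derive_seed(seed, s, i, 2L))
      mean(run$R66)
    }, numeric(1))
    ba <- bland_altman(va, vb)
    rows[[s]] <- data.frame(bias = ba$bias, sd = ba$sd,
                            loa_lower = ba$loa[1], loa_upper = ba$loa[2],
                            n_pairs = ba$n)
  }
  do.call(rbind, rows)
}
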