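#' Paired DIBH-minus-FB delta
#'
#' The delta convention is DIBH minus FB; the relative delta is normalized
#' to the FB value and expressed in percent.  With `fb = 0` the relative
#' delta is undefined and returned as `NA` (flagged via
#' `relative_defined`).
#'
#' @param fb,dibh finite numeric values (vectorized).
#' @return list with `delta`, `delta_relative_pct`, `relative_defined`.
#' @export
paired_delta <- function(fb, dibh) {
  if (any(!is.finite(fb)) || any(!is.finite(dibh)))
    stop("paired_delta needs finite values")
  delta <- dibh - fb
  defined <- fb != 0
  rel <- ifelse(defined, delta * 100 / fb, NA_real_)
  list(delta = delta, delta_relative_pct = rel, relative_defined = defined)
}

## exact null distribution of the positive-rank sum W+ for midranks r
## (convolution on a half-unit grid so tied midranks stay exact)
signed_rank_distribution <- function(r) {
  units <- as.integer(round(2 * r))          # midranks on a .5 grid
  total <- sum(units)
  f <- numeric(total + 1L)                   # index k <-> W+ = k/2
  f[1] <- 1
  for (u in units) {
    g <- f
    g[(u + 1L):(total + 1L)] <- g[(u + 1L):(total + 1L)] + f[1:(total + 1L - u)]
    f <- g
  }
  f / 2^length(units)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Two-sided test of the paired differences.  Zero differences are dropped
#' (Wilcoxon convention); ties receive midranks.  For n <= `exact_limit`
#' remaining pairs the exact null distribution of the rank sum is used
#' (valid with ties via midrank convolution); beyond that the normal
#' approximation with tie correction.
#'
#' @param fb,dibh paired vectors, or a single vector of differences in `fb`.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return list with `p_value`, `statistic` (W+), `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(fb, dibh = NULL, exact_limit = 25L) {
  d <- if (is.null(dibh)) as.numeric(fb) else as.numeric(dibh) - as.numeric(fb)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop(errorCondition("all pairs tied; Wilcoxon test undefined",
                        class = c("dosemass_stat_error", "error")))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    f <- signed_rank_distribution(r)
    k <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(k + 1L)])
    p_ge <- sum(f[(k + 1L):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(p_value = p, statistic = w, n_effective = n, method = method)
}

#' Linear regression with zero-crossing threshold
#'
#' Ordinary least squares of y on x with the x value at which the fitted
#' line crosses y = 0 (`x_at_y0 = -intercept / slope`).  Applied to paired
#' relative DVH and DMH deltas, the crossing estimates the volumetric
#' benefit below which no mass benefit is expected.
#'
#' @param x,y numeric vectors (>= 3 points; x not constant).
#' @return list with `slope`, `intercept`, `r_squared`, `x_at_y0`,
#'   `crossing_defined`.
#' @export
regression_zero_crossing <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("regression needs at least 3 points")
  if (max(x) - min(x) < 1e-12) stop("x is constant; regression undefined")
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  defined <- abs(b[2]) > 1e-12
  list(slope = b[2], intercept = b[1], r_squared = r2,
       x_at_y0 = if (defined) -b[1] / b[2] else NA_real_,
       crossing_defined = defined)
}

## Spearman rank correlation with midranks and t-approximation p-value
spearman_one <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L || max(x) - min(x) < 1e-15 || max(y) - min(y) < 1e-15)
    return(c(r = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  c(r = r, p = p, n = n)
}

#' Spearman correlation table
#'
#' Spearman's rank correlation (midranks for ties, two-sided p from the
#' t approximation) for every factor x delta pair, shaped factors in rows,
#' deltas in columns, with significance stars (`*` p < 0.05, `**` p < 0.01).
#' Constant columns yield `NA` (flagged, not an error).
#'
#' @param factors data frame of anatomical factors (rows = patients).
#' @param deltas data frame of delta metrics (same rows).
#' @return data frame with columns `factor`, `delta`, `r`, `p`, `n`,
#'   `stars`.
#' @export
spearman_correlations <- function(factors, deltas) {
  factors <- as.data.frame(factors)
  deltas <- as.data.frame(deltas)
  if (nrow(factors) != nrow(deltas)) stop("row mismatch")
  if (nrow(factors) < 5L) stop("need n >= 5 per correlation")
  out <- expand.grid(factor = names(factors), delta = names(deltas),
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(f, d) spearman_one(factors[[f]], deltas[[d]]),
                  out$factor, out$delta))
  out$r <- res[, "r"]; out$p <- res[, "p"]; out$n <- as.integer(res[, "n"])
  out$stars <- ifelse(is.na(out$p), "",
                      ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", "")))
  out
}
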