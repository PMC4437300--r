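#' @name stats_tests
#' @title Exact small-sample nonparametric tests
#' @description
#' The rank tests used throughout the analysis chain, implemented with
#' exact permutation/enumeration nulls at small sample sizes (verifiable
#' by hand) and tie-corrected normal / chi-squared approximations
#' otherwise. Midranks are used for ties everywhere; exact enumeration
#' declines to the approximation when ties are present. Two-sided exact p
#' values double the smaller one-sided tail, capped at 1.
#'
#' Every test returns a `test_result`: `method`, `statistic`, `p`,
#' `sided`, `exact` (TRUE only when the full enumerated null was used),
#' `n` (per-group sizes).
NULL

.test_result <- function(method, statistic, p, sided, exact, n) {
  structure(list(method = method, statistic = statistic,
                 p = min(max(p, .Machine$double.xmin), 1),
                 sided = sided, exact = exact, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p %s (%s, %s)\n",
              x$method, x$statistic,
              format.pval(x$p, digits = 4), x$sided,
              if (x$exact) "exact" else "approximate"))
  invisible(x)
}

.midranks <- function(v) rank(v, ties.method = "average")

#' Wilcoxon rank-sum test
#'
#' Statistic: sum of (mid)ranks of `x` in the pooled sample. Exact p by
#' enumeration of all `choose(n+m, n)` rank assignments when
#' `n + m <= 16` and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param sided `"two"`, `"greater"` (x tends larger) or `"less"`.
#' @return A `test_result` (see [stats_tests]).
#' @export
rank_sum <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (!length(x) || !length(y)) .stopf("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- .midranks(pooled)
  w <- sum(r[seq_len(n)])
  ties <- anyDuplicated(pooled) > 0
  if (N <= 16 && !ties) {
    sums <- utils::combn(N, n, FUN = sum)
    p_low <- mean(sums <= w + 1e-9)
    p_high <- mean(sums >= w - 1e-9)
    p <- switch(sided, two = min(1, 2 * min(p_low, p_high)),
                greater = p_high, less = p_low)
    return(.test_result("Wilcoxon rank-sum", w, p, sided, TRUE, c(n, m)))
  }
  mu <- n * (N + 1) / 2
  tt <- table(pooled)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  v <- n * m / 12 * ((N + 1) - tie_term)
  z_hi <- (w - mu - 0.5) / sqrt(v)
  z_lo <- (w - mu + 0.5) / sqrt(v)
  p_high <- stats::pnorm(z_hi, lower.tail = FALSE)
  p_low <- stats::pnorm(z_lo)
  p <- switch(sided, two = min(1, 2 * min(p_low, p_high)),
              greater = p_high, less = p_low)
  .test_result("Wilcoxon rank-sum", w, p, sided, FALSE, c(n, m))
}

# exact null distribution of the signed-rank statistic via subset-sum
# convolution over integer ranks (equivalent to enumerating all 2^n signs)
.signed_rank_null <- function(ranks) {
  total <- sum(ranks)
  counts <- c(1, rep(0, total))     # counts[v + 1] = #assignments with V = v
  for (r in ranks) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks)
}

#' Wilcoxon signed-rank test
#'
#' Paired test on `x - y`. Zero differences are dropped (classical
#' Wilcoxon convention). Statistic: sum of ranks of `|d|` over positive
#' differences. Exact p over all `2^n` sign assignments for `n <= 20` and
#' tie-free `|d|`; normal approximation with tie and continuity
#' corrections otherwise.
#'
#' @param x,y paired numeric samples of equal length (>= 2 usable pairs).
#' @param sided `"two"`, `"greater"` (x tends larger) or `"less"`.
#' @return A `test_result` (see [stats_tests]).
#' @export
signed_rank <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (length(x) != length(y)) .stopf("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) .stopf("fewer than 2 nonzero differences: test degenerate")
  r <- .midranks(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 20 && !ties) {
    null <- .signed_rank_null(as.integer(round(r)))
    vals <- seq_along(null) - 1
    p_low <- sum(null[vals <= v + 1e-9])
    p_high <- sum(null[vals >= v - 1e-9])
    p <- switch(sided, two = min(1, 2 * min(p_low, p_high)),
                greater = p_high, less = p_low)
    return(.test_result("Wilcoxon signed-rank", v, p, sided, TRUE, n))
  }
  mu <- n * (n + 1) / 4
  tt <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  p_high <- stats::pnorm((v - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  p_low <- stats::pnorm((v - mu + 0.5) / sqrt(sig2))
  p <- switch(sided, two = min(1, 2 * min(p_low, p_high)),
              greater = p_high, less = p_low)
  .test_result("Wilcoxon signed-rank", v, p, sided, FALSE, n)
}

.kw_statistic <- function(ranks, sizes) {
  N <- sum(sizes)
  idx <- rep(seq_along(sizes), sizes)
  rbar <- tapply(ranks, idx, mean)
  h <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  h
}

# recursive enumeration of all distinct assignments of positions to groups
.kw_enumerate <- function(ranks, sizes, h_obs, tie_c) {
  N <- length(ranks)
  count_ge <- 0; count_all <- 0
  recurse <- function(avail, gi, chosen_ranks) {
    if (gi == length(sizes)) {
      r <- c(chosen_ranks, list(ranks[avail]))
      rr <- unlist(r)
      sz <- sizes
      h <- .kw_statistic(rr, sz) / tie_c
      count_all <<- count_all + 1
      if (h >= h_obs - 1e-9) count_ge <<- count_ge + 1
      return(invisible())
    }
    picks <- utils::combn(length(avail), sizes[gi], simplify = FALSE)
    for (pk in picks) {
      recurse(avail[-pk], gi + 1L,
              c(chosen_ranks, list(ranks[avail[pk]])))
    }
  }
  recurse(seq_len(N), 1L, list())
  c(count_ge, count_all)
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction; p from the chi-squared law with
#' `k - 1` df, or by exact enumeration of all distinct rank assignments
#' when the total sample size is at most 10.
#'
#' @param groups a list of >= 2 non-empty numeric samples.
#' @return A `test_result` (see [stats_tests]).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    .stopf("need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) .stopf("all groups must be non-empty")
  N <- sum(sizes)
  if (N < 3) .stopf("need a total of at least 3 observations")
  pooled <- unlist(groups)
  r <- .midranks(pooled)
  tt <- table(pooled)
  tie_c <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (tie_c <= 0) .stopf("all observations identical: test degenerate")
  h <- .kw_statistic(r, sizes) / tie_c
  if (N <= 10) {
    cnt <- .kw_enumerate(r, sizes, h, tie_c)
    return(.test_result("Kruskal-Wallis", h, cnt[1] / cnt[2], "two",
                        TRUE, sizes))
  }
  p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  .test_result("Kruskal-Wallis", h, p, "two", FALSE, sizes)
}

#' Pearson correlation with regression F-test
#'
#' Product-moment correlation, ordinary least-squares line, and the
#' regression F statistic `F = (n - 2) r^2 / (1 - r^2)` with p from
#' `F(1, n - 2)`. On exactly collinear data F is infinite and the p value
#' is reported as the smallest positive double (a bound, not an estimate).
#'
#' @param x,y numeric samples of equal length >= 3 with positive variance.
#' @return A list: `r`, `slope`, `intercept`, `f`, `p`, `n`.
#' @export
pearson_regression <- function(x, y) {
  n <- length(x)
  if (n != length(y)) .stopf("x and y must have equal length")
  if (n < 3) .stopf("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    .stopf("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  if (1 - r^2 < 1e-12) {
    f <- Inf; p <- .Machine$double.xmin
  } else {
    f <- (n - 2) * r^2 / (1 - r^2)
    p <- max(stats::pf(f, 1, n - 2, lower.tail = FALSE), .Machine$double.xmin)
  }
  list(r = r, slope = slope, intercept = intercept, f = f, p = p, n = n)
}
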