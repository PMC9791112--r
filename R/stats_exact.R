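#' Exact Wilcoxon rank-sum test by full enumeration
#'
#' Two-sample rank-sum (Mann-Whitney) test tailored to very small sequencing
#' cohorts (e.g. 3 vs 6 samples), where the exact null distribution of the
#' U statistic is obtained by enumerating every assignment of ranks to the
#' first group. For `n1 + n2 <= max_exact_n` and tie-free data the two-sided
#' p-value is exact; otherwise a normal approximation with tie correction
#' (and continuity correction) is used.
#'
#' The U statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j`,
#' ties counting one half. The exact two-sided p-value doubles the smaller
#' tail, `2 * min(P(U <= u), P(U >= u))`, capped at 1; an alternative that
#' sums the probability of all U values at least as extreme in absolute
#' deviation from the null mean is available via `two_sided = "deviation"`.
#'
#' @param x,y Numeric vectors, one per group; no missing values.
#' @param max_exact_n Largest combined sample size for which the exact
#'   enumeration path is used (default 12; `choose(12, 6) = 924` subsets).
#' @param two_sided How the two-sided exact p-value is formed:
#'   `"doubling"` (default) or `"deviation"`.
#' @return An object of class `ranksum_result`: a list with elements `U`,
#'   `p_two_sided`, and `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' exact_rank_sum(c(10, 11, 12), c(1, 2, 3, 4, 5, 6))  # p = 2/84
#' @export
exact_rank_sum <- function(x, y, max_exact_n = 12L,
                           two_sided = c("doubling", "deviation")) {
  two_sided <- match.arg(two_sided)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L

  ## U with half-credit for cross-group ties
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

  if (!ties && n <= max_exact_n) {
    ## exact null distribution of U over all C(n, n1) rank assignments
    offset <- n1 * (n1 + 1) / 2
    u_all <- utils::combn(n, n1, function(r) sum(r) - offset)
    n_assign <- length(u_all)
    if (two_sided == "doubling") {
      p <- 2 * min(sum(u_all <= u), sum(u_all >= u)) / n_assign
    } else {
      dev <- abs(u_all - n1 * n2 / 2)
      p <- sum(dev >= abs(u - n1 * n2 / 2)) / n_assign
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    ## normal approximation with tie and continuity corrections
    nties <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) stop("degenerate data: all values tied")
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(U = u, p_two_sided = p, method = method),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %g, two-sided p = %.4g\n",
              x$method, x$U, x$p_two_sided))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Correlation of average ranks, with the usual two-sided p-value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1. Errors on a zero marginal.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return List with `statistic`, `p`, `df`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value, df = 1L)
}
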