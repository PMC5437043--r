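#' Statistical kernels
#'
#' Self-contained implementations of the three procedures the pipeline's
#' downstream analyses rely on: tie-corrected Spearman rank correlation,
#' the two-sided Mann-Whitney U test, and an ordinary least-squares line.
#' Each returns a one-row tibble so results bind directly into result tables.
#'
#' @name stats_core
NULL

# Midranks, identical to rank(x, ties.method = "average") but kept explicit
# because the U statistic and the tie correction both consume it.
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected Spearman correlation: Pearson correlation of midranks, with
#' a two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return A one-row tibble with columns `statistic` (rho), `p_value`,
#'   `method`, `n`.
#' @examples
#' spearman(1:10, (1:10)^2)
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  rx <- midrank(x)
  ry <- midrank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(statistic = r, p_value = p, method = "spearman", n = n)
}

# U statistic of sample a against b with midranks: wins + half-ties.
mw_u <- function(a, b) {
  ra <- midrank(c(a, b))[seq_along(a)]
  sum(ra) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed with midranks. For pooled sample sizes up to `exact_max` the
#' two-sided p-value is exact by full enumeration of group assignments,
#' defined as P(|U - E(U)| >= |u_obs - E(U)|) under the permutation null;
#' above that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Largest pooled size for which enumeration is used.
#' @return A one-row tibble: `statistic` (U of `a`), `p_value`, `method`, `n`.
#' @export
mann_whitney_two_sided <- function(a, b, exact_max = 12) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  u <- mw_u(a, b)
  mu <- na * nb / 2
  if (n <= exact_max) {
    pool <- c(a, b)
    idx <- combn(n, na)
    us <- apply(idx, 2, function(i) mw_u(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "mann-whitney exact"
  } else {
    pool <- c(a, b)
    tie_tab <- table(pool)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- 2 * pnorm(-z)
    }
    method <- "mann-whitney normal"
  }
  tibble::tibble(statistic = u, p_value = min(p, 1), method = method, n = n)
}

#' Ordinary least-squares line
#'
#' Fits y = slope * x + intercept by least squares and reports
#' R^2 = 1 - SSE/SST. A constant y gives slope 0 and R^2 = 0 by convention.
#'
#' @param x,y Numeric vectors, length >= 2; `x` must not be constant.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
ols_line <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2) abort("need at least 2 points")
  if (sd(x) == 0) abort("x is constant; line undefined")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- 0
  } else {
    sse <- sum((y - slope * x - intercept)^2)
    r2 <- 1 - sse / sst
  }
  tibble::tibble(slope = slope, intercept = intercept, r_squared = r2, n = n)
}
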