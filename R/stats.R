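# Null distribution of the Mann-Whitney U statistic by the classic
# count-of-partitions recursion N(m, n, u) = N(m-1, n, u-n) +
# N(m, n-1, u): number of the choose(m+n, m) equally likely rank
# labelings giving U = u. Returns counts for u = 0..m*n.
mwu_null_counts <- function(m, n) {
  umax <- m * n
  # dp[mm+1, u+1] = N(mm, nn, u) for the current nn, swept nn = 0..n
  dp <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
  dp[, 1L] <- 1  # nn = 0: U = 0 for every mm
  for (nn in seq_len(n)) {
    new <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
    new[1L, 1L] <- 1  # mm = 0: U = 0
    for (mm in seq_len(m)) {
      u <- 0:(mm * nn)
      from_m <- numeric(length(u))
      ok <- u - nn >= 0
      from_m[ok] <- new[mm, u[ok] - nn + 1L]
      new[mm + 1L, u + 1L] <- from_m + dp[mm + 1L, u + 1L]
    }
    dp <- new
  }
  dp[m + 1L, ]
}

#' Exact one-tailed Mann-Whitney U test
#'
#' U counts the pairs `(x_i, y_j)` in which `y_j` beats `x_i` in the
#' direction of the alternative (`"greater"`: `y_j > x_i`; `"less"`:
#' `y_j < x_i`). The one-tailed p-value `P(U* >= U)` is computed from
#' the full exact null distribution of U, obtained by the
#' count-of-partitions recursion over all `choose(n1+n2, n1)` labelings
#' (supported up to `n1 + n2 <= 40`). Ties fall back to midranks with a
#' tie-corrected normal approximation, flagged in `method`.
#'
#' @param x,y numeric samples (x = reference group)
#' @param alternative `"greater"` (y tends larger than x) or `"less"`
#' @return object of classes `mwu_test` and `htest` with fields
#'   `statistic` (U), `p.value` (full precision; `p_rounded` gives the
#'   3-decimal table form), `alternative`, `method`, `n1`, `n2`
#' @export
mann_whitney_exact <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  cmp <- if (alternative == "greater") outer(x, y, "<") else outer(x, y, ">")
  U <- sum(cmp) + 0.5 * sum(outer(x, y, "=="))
  if (!ties && n1 + n2 <= 40L) {
    counts <- mwu_null_counts(n1, n2)
    p <- sum(counts[(U + 1L):(n1 * n2 + 1L)]) / choose(n1 + n2, n1)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    allr <- rank(c(x, y))
    nties <- table(allr)
    sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                              sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - 0.5) / sqrt(sig2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_approx (ties present or n too large)"
  }
  structure(list(statistic = c(U = U), p.value = p,
                 p_rounded = round(p, 3L),
                 alternative = alternative,
                 method = paste("One-tailed Mann-Whitney U test,", method),
                 n1 = n1, n2 = n2,
                 data.name = "x and y"),
            class = c("mwu_test", "htest"))
}

#' Summary statistics over replicate values
#'
#' @param values numeric vector of per-replicate values (n >= 2)
#' @return object of class `replicate_summary`: `values`, `mean`, `sd`
#'   (n-1 denominator), `rounded_mean` (1 decimal), `n`
#' @export
replicate_summary <- function(values) {
  if (length(values) < 2L) stop("sd undefined: need at least 2 values")
  structure(list(values = values, mean = mean(values),
                 sd = stats::sd(values), rounded_mean = round1(mean(values)),
                 n = length(values)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate_summary: mean %.1f +/- %.1f (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Difference between two state summaries
#'
#' @param summary_a,summary_b [replicate_summary()] objects
#'   (a = reference); the delta is `b - a`
#' @param convention `"rounded"` differences the means after rounding
#'   to one decimal (reproduces printed table deltas); `"raw"`
#'   differences the raw means
#' @return numeric delta in the inputs' units
#' @export
state_delta <- function(summary_a, summary_b,
                        convention = c("rounded", "raw")) {
  convention <- match.arg(convention)
  if (convention == "rounded") {
    summary_b$rounded_mean - summary_a$rounded_mean
  } else {
    summary_b$mean - summary_a$mean
  }
}

#' Percent contribution of one component to a total difference
#'
#' Used for per-residue shares of a state-level binding-energy change:
#' the focal residue's share of the total delta, and the residual
#' attributed to the remaining (allosteric) contributions.
#'
#' @param part component delta (same units as `total`)
#' @param total total delta
#' @return list with `percent` (100 * part / total), `residual`
#'   (total - part) and `residual_percent`
#' @export
percent_contribution <- function(part, total) {
  if (total == 0) stop("total delta is zero")
  list(percent = 100 * part / total,
       residual = total - part,
       residual_percent = 100 * (total - part) / total)
}
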