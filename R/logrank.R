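#' Conditional K-group log-rank test with asymptotic p-value
#'
#' Computes the conditional (hypergeometric-variance) log-rank statistic
#' for `K >= 2` groups and its asymptotic p-value (AP) from the chi-square
#' distribution with `K - 1` degrees of freedom.
#'
#' At each distinct event time \eqn{t_i} with \eqn{d_i} events out of
#' \eqn{n_i} at risk (\eqn{d_{ij}}, \eqn{n_{ij}} per group), the observed
#' and expected counts are \eqn{O_j = \sum_i d_{ij}} and
#' \eqn{E_j = \sum_i d_i n_{ij} / n_i}, and the covariance of
#' \eqn{O - E} is
#' \deqn{V_{jl} = \sum_i \frac{d_i (n_i - d_i)}{n_i - 1}
#'   \frac{n_{ij}}{n_i}\left(\delta_{jl} - \frac{n_{il}}{n_i}\right),}
#' with a term of zero whenever \eqn{n_i = 1}.  The statistic is
#' \eqn{T = z^\top \hat V^{-1} z} where \eqn{z} and \eqn{\hat V} restrict
#' to the first \eqn{K - 1} groups.  When \eqn{\hat V} is singular (for
#' example a group whose at-risk period never overlaps an event), a
#' Moore-Penrose pseudo-inverse is used, the degrees of freedom drop to
#' the rank of \eqn{\hat V}, and a warning is issued.
#'
#' The chi-square p-value is accurate when every group has many events and
#' the group sizes are balanced; with few events per group or strongly
#' imbalanced groups it is anti-conservative.  In those regimes use
#' [logrank_permutation_test()] and report the exact p-value.
#'
#' @param data a [survival_dataset()].
#' @return An object of class `logrank_test`: a list with elements
#'   `statistic` (T), `df`, `p.value` (the AP), `observed`, `expected`
#'   (named per-group vectors), `var` (the full K x K covariance of
#'   O - E) and `singular`.
#' @examples
#' d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' logrank_test(d)
#' @seealso [logrank_permutation_test()] for the exact permutation p-value.
#' @export
logrank_test <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  ord <- order(data$time, method = "radix")
  res <- .lr_stat_cpp(data$time[ord], as.integer(data$event[ord]),
                      data$group[ord], data$k)
  df <- data$k - 1L
  if (res$singular) {
    df <- max(1L, as.integer(res$rank))
    warning("log-rank covariance matrix is singular; using pseudo-inverse, df = ",
            df)
  }
  names(res$observed) <- names(res$expected) <- data$levels
  dimnames(res$var) <- list(data$levels, data$levels)
  structure(
    list(statistic = res$statistic, df = df,
         p.value = chisq_pvalue(res$statistic, df),
         observed = res$observed, expected = res$expected,
         var = res$var, singular = res$singular,
         n = data$n, k = data$k),
    class = "logrank_test"
  )
}

#' Upper-tail chi-square p-value
#'
#' @param statistic non-negative test statistic.
#' @param df degrees of freedom (positive integer).
#' @return The upper-tail probability `P(X >= statistic)` for
#'   `X ~ chi-square(df)`.
#' @examples
#' chisq_pvalue(3.8415, 1)  # ~0.05
#' @export
chisq_pvalue <- function(statistic, df) {
  stopifnot(statistic >= 0)
  if (any(df < 1)) stop("df must be >= 1")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' @export
print.logrank_test <- function(x, digits = 4, ...) {
  cat("Conditional log-rank test (", x$k, " groups, n = ", x$n, ")\n",
      sep = "")
  tab <- data.frame(observed = x$observed, expected = x$expected,
                    `O-E` = x$observed - x$expected, check.names = FALSE)
  print(round(tab, digits))
  cat(sprintf("Chi-square = %.*g on %d df, asymptotic p-value (AP) = %.*g\n",
              digits, x$statistic, x$df, digits, x$p.value))
  if (isTRUE(x$singular))
    cat("(covariance singular: pseudo-inverse used, df reduced)\n")
  invisible(x)
}

# Statistic only, for permutation loops: data already sorted by time.
# labels is an n x B integer matrix of group assignments in sorted order.
lr_stat_batch <- function(time_sorted, event_sorted, labels, k) {
  .lr_stat_batch_cpp(time_sorted, as.integer(event_sorted),
                     labels, as.integer(k))
}
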