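# Shared fixtures, built in code.

# Four-patient worked example: group A events at times 1 and 2, group B at
# 3 and 4, no censoring.  Hand-computed over its risk table:
#   O_A = 2, E_A = 5/6, Vhat = 17/36, T = (7/6)^2 / (17/36) = 49/17.
d1 <- function() {
  survival_dataset(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                   group = c("A", "A", "B", "B"))
}

# Random valid dataset: K groups all present, at least one event; optional
# ties (times rounded to a coarse grid) and censoring.
random_dataset <- function(n, K = 2, ties = FALSE, cens_prob = 0.3) {
  repeat {
    g <- sample.int(K, n, replace = TRUE)
    t <- rexp(n)
    if (ties) t <- ceiling(t * 4) / 4
    e <- as.numeric(runif(n) > cens_prob)
    if (length(unique(g)) == K && sum(e) >= 1) {
      return(survival_dataset(t, e, g))
    }
  }
}

# Monte Carlo standard error of a proportion.
mc_se_prop <- function(p, n) sqrt(p * (1 - p) / n)

# Pure-R log-rank statistic computed from risk_table(), an independent
# route from the compiled core (shares only the risk-table code).
logrank_reference <- function(data) {
  rt <- risk_table(data)
  K <- data$k
  nr <- as.matrix(rt[, paste0("n_risk_", data$levels)])
  ne <- as.matrix(rt[, paste0("n_event_", data$levels)])
  d <- rt$n_event; nn <- rt$n_risk
  O <- colSums(ne)
  E <- colSums(d * nr / nn)
  V <- matrix(0, K, K)
  for (i in seq_len(nrow(rt))) {
    if (nn[i] <= 1) next
    c_i <- d[i] * (nn[i] - d[i]) / (nn[i] - 1)
    p <- nr[i, ] / nn[i]
    V <- V + c_i * (diag(p, K) - outer(p, p))
  }
  z <- (O - E)[seq_len(K - 1)]
  Vh <- V[seq_len(K - 1), seq_len(K - 1), drop = FALSE]
  Tstat <- drop(t(z) %*% solve(Vh, z))
  list(observed = O, expected = E, var = V, statistic = Tstat)
}
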