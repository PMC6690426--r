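#' Exact permutation p-value (EP) for the log-rank test
#'
#' Estimates the permutation p-value of the conditional log-rank statistic
#' by Monte Carlo resampling.  The observed statistic \eqn{T_{obs}} is
#' computed once; each of `B` resamples recomputes the statistic, and the
#' p-value uses the add-one estimator \eqn{EP = (b + 1)/(B + 1)} where
#' \eqn{b} counts resamples with \eqn{T \ge T_{obs}} (ties count as
#' extreme).  The estimator can never report zero, so the test is valid at
#' any `B`.  A Clopper-Pearson confidence interval for the exceedance
#' probability is attached.
#'
#' Two resampling schemes are available:
#' \describe{
#'   \item{`"label"`}{plain permutation of the group labels.  Exact when
#'     the censoring distribution is the same in every group.}
#'   \item{`"conditional"`}{the follow-up-conditioned scheme of Heinze and
#'     co-workers, which conditions on the observed follow-up in each
#'     group.  Latent event times are imputed for censored patients (from
#'     the pooled Kaplan-Meier estimate, conditional on exceeding the
#'     observed time) and latent follow-up times for event patients (from
#'     the reverse Kaplan-Meier estimate, conditional on at least the
#'     observed time); each resample permutes the latent event times
#'     across patient slots while every slot keeps its group and latent
#'     follow-up time, then re-censors.  This keeps each group's follow-up
#'     structure intact and remains valid when censoring differs between
#'     groups.  The imputation is repeated `imputations` times and the
#'     exceedance counts are pooled over all `imputations * B` resamples.}
#' }
#' With no censored observations the conditional scheme reduces to plain
#' label permutation.
#'
#' @param data a [survival_dataset()].
#' @param B number of permutations per imputation (>= 1).
#' @param scheme `"label"` or `"conditional"`.
#' @param seed integer seed; the result is fully reproducible given
#'   `(data, B, scheme, seed, imputations)`.
#' @param imputations number of independent imputations M for the
#'   conditional scheme (ignored for `"label"`).
#' @param level confidence level for the EP interval.
#' @return An object of class `permutation_test`: a list with elements
#'   `p.value` (EP), `b` (exceedance count), `B` (total resamples),
#'   `conf.int`, `statistic` (observed T), `df`, `ap` (the asymptotic
#'   p-value, for comparison), `scheme`, `imputations`, `seed`.
#' @examples
#' d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' logrank_permutation_test(d, B = 999, seed = 1)
#' @seealso [logrank_enumeration()] for full enumeration on small samples,
#'   [ep_confidence_interval()] for the interval alone.
#' @export
logrank_permutation_test <- function(data, B = 10000,
                                     scheme = c("label", "conditional"),
                                     seed = NULL, imputations = 10,
                                     level = 0.95) {
  stopifnot(inherits(data, "survival_dataset"))
  scheme <- match.arg(scheme)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  M <- if (scheme == "conditional") as.integer(imputations) else 1L
  if (M < 1L) stop("imputations must be >= 1")

  obs <- suppressWarnings(logrank_test(data))
  t_obs <- obs$statistic

  b <- with_rng(seed, {
    if (scheme == "label") {
      ord <- order(data$time, method = "radix")
      tt <- data$time[ord]; ev <- data$event[ord]; gg <- data$group[ord]
      perms <- vapply(seq_len(B), function(i) sample(gg), integer(data$n))
      t_perm <- lr_stat_batch(tt, ev, perms, data$k)
      sum(stat_ge(t_perm, t_obs))
    } else {
      total <- 0L
      for (m in seq_len(M)) {
        lat <- impute_latent_times(data)
        for (i in seq_len(B)) {
          e_perm <- lat$event_time[sample.int(data$n)]
          tt <- pmin(e_perm, lat$followup)
          ev <- e_perm <= lat$followup
          ordp <- order(tt, method = "radix")
          res <- .lr_stat_cpp(tt[ordp], as.integer(ev[ordp]),
                              data$group[ordp], data$k)
          if (stat_ge(res$statistic, t_obs)) total <- total + 1L
        }
      }
      total
    }
  })

  B_total <- M * B
  ep <- (b + 1) / (B_total + 1)
  structure(
    list(p.value = ep, b = b, B = B_total,
         conf.int = ep_confidence_interval(b, B_total, level),
         statistic = t_obs, df = obs$df, ap = obs$p.value,
         scheme = scheme, imputations = M, seed = seed, level = level),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, digits = 4, ...) {
  cat(sprintf("Permutation log-rank test (scheme = %s)\n", x$scheme))
  cat(sprintf("  T = %.*g on %d df; asymptotic p-value (AP) = %.*g\n",
              digits, x$statistic, x$df, digits, x$ap))
  cat(sprintf("  exact p-value (EP) = %.*g  [b = %d of B = %d resamples]\n",
              digits, x$p.value, x$b, x$B))
  cat(sprintf("  %d%% CI for EP: (%.*g, %.*g)\n", round(100 * x$level),
              digits, x$conf.int[1], digits, x$conf.int[2]))
  invisible(x)
}

#' Exact p-value by full enumeration of label assignments
#'
#' Evaluates the log-rank statistic for every distinct assignment of the
#' observed group sizes to patients (distinct multiset permutations of the
#' label vector, not all `n!` orderings) and returns the exact proportion
#' with \eqn{T \ge T_{obs}}.  This is the gold standard that the sampled
#' EP of [logrank_permutation_test()] converges to; it is only feasible
#' for small samples, so the number of assignments is capped.
#'
#' @param data a [survival_dataset()].
#' @param cap maximum number of distinct assignments (default `1e6`).
#' @return A list with `p.value` (exact), `n_assignments`, `statistic`
#'   (observed T).
#' @examples
#' d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' logrank_enumeration(d)  # 6 assignments
#' @export
logrank_enumeration <- function(data, cap = 1e6) {
  stopifnot(inherits(data, "survival_dataset"))
  counts <- tabulate(data$group, data$k)
  n_assign <- multinomial_count(counts)
  if (n_assign > cap)
    stop("number of distinct label assignments (", n_assign,
         ") exceeds cap (", cap, ")")

  obs <- suppressWarnings(logrank_test(data))
  ord <- order(data$time, method = "radix")
  assigns <- multiset_assignments(counts)          # n x M, patient order
  t_all <- lr_stat_batch(data$time[ord], data$event[ord],
                         assigns[ord, , drop = FALSE], data$k)
  list(p.value = mean(stat_ge(t_all, obs$statistic)),
       n_assignments = ncol(assigns),
       statistic = obs$statistic)
}

# Number of distinct label assignments: multinomial(n; n_1..n_K).
multinomial_count <- function(counts) {
  n <- sum(counts)
  out <- 1
  left <- n
  for (c_j in counts) {
    out <- out * choose(left, c_j)
    left <- left - c_j
  }
  out
}

# All distinct assignments of groups 1..K with the given sizes to
# sum(counts) slots; returns an n x M integer matrix.
multiset_assignments <- function(counts) {
  K <- length(counts)
  n <- sum(counts)
  rec <- function(avail, g) {
    if (g == K) {
      m <- matrix(0L, n, 1L)
      m[avail, 1L] <- K
      return(m)
    }
    cs <- utils::combn(length(avail), counts[g])
    blocks <- vector("list", ncol(cs))
    for (ci in seq_len(ncol(cs))) {
      chosen <- avail[cs[, ci]]
      sub <- rec(setdiff(avail, chosen), g + 1L)
      sub[chosen, ] <- g
      blocks[[ci]] <- sub
    }
    do.call(cbind, blocks)
  }
  rec(seq_len(n), 1L)
}

#' Clopper-Pearson confidence interval for the permutation p-value
#'
#' Exact binomial interval for the exceedance probability underlying the
#' EP, from `b` exceedances in `B` resamples:
#' `low = qbeta(alpha/2, b, B - b + 1)` (0 when `b = 0`) and
#' `high = qbeta(1 - alpha/2, b + 1, B - b)` (1 when `b = B`).
#'
#' @param b exceedance count, `0 <= b <= B`.
#' @param B number of resamples.
#' @param level confidence level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' ep_confidence_interval(0, 1000)   # (0, ~0.00368)
#' @export
ep_confidence_interval <- function(b, B, level = 0.95) {
  clopper_pearson(b, B, level)
}

# --- Follow-up-conditioned (Heinze-style) resampling ---------------------

# Discrete probability mass of a Kaplan-Meier estimate: jumps at the event
# times plus any leftover tail mass placed at the largest observed time
# (the simplest proper distribution; isolated here so an alternative tail
# model can be swapped in).  `flip = TRUE` gives the reverse-KM follow-up
# distribution; if the flipped indicator has no "events" (i.e. no censored
# patients) all mass sits at the largest observed time.
km_mass <- function(time, event, flip = FALSE) {
  ev <- if (flip) !event else as.logical(event)
  tmax <- max(time)
  if (!any(ev)) return(list(support = tmax, mass = 1))
  km <- kaplan_meier(time, ev)
  p <- -diff(c(1, km$survival))
  support <- km$time
  tail <- km$survival[nrow(km)]
  if (tail > 0) {
    if (tmax > support[length(support)]) {
      support <- c(support, tmax)
      p <- c(p, tail)
    } else {
      p[length(p)] <- p[length(p)] + tail
    }
  }
  list(support = support, mass = p)
}

# One draw from a km_mass distribution conditional on the support being
# > lower (strict = TRUE) or >= lower.  If no mass satisfies the
# constraint the largest support point is returned.
sample_km_conditional <- function(dist, lower, strict) {
  keep <- if (strict) dist$support > lower else dist$support >= lower
  if (!any(keep)) return(dist$support[length(dist$support)])
  s <- dist$support[keep]
  p <- dist$mass[keep]
  if (length(s) == 1L) return(s)
  sample(s, 1L, prob = p)
}

#' Impute latent event and follow-up times for conditional resampling
#'
#' One multiple-imputation draw for the follow-up-conditioned permutation
#' scheme: the pooled event-time distribution is estimated by
#' Kaplan-Meier and the pooled follow-up (censoring) distribution by
#' reverse Kaplan-Meier; each censored patient receives a latent event
#' time drawn conditional on exceeding the observed time, and each event
#' patient a latent follow-up time drawn conditional on being at least the
#' observed time.  Observed quantities are kept as-is.
#'
#' @param data a [survival_dataset()].
#' @return A list with numeric vectors `event_time` and `followup`, one
#'   entry per patient (slot).
#' @export
impute_latent_times <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  S_hat <- km_mass(data$time, data$event, flip = FALSE)
  G_hat <- km_mass(data$time, data$event, flip = TRUE)
  e <- f <- numeric(data$n)
  for (i in seq_len(data$n)) {
    if (data$event[i]) {
      e[i] <- data$time[i]
      f[i] <- sample_km_conditional(G_hat, data$time[i], strict = FALSE)
    } else {
      e[i] <- sample_km_conditional(S_hat, data$time[i], strict = TRUE)
      f[i] <- data$time[i]
    }
  }
  list(event_time = e, followup = f)
}

#' One resample under the follow-up-conditioned scheme
#'
#' Permutes the latent event times across patient slots while each slot
#' keeps its group label and latent follow-up time, then re-censors:
#' observed time is the minimum of the permuted latent event time and the
#' slot's follow-up time; the event flag records whether the event came
#' first.  The multiset of follow-up times within each group is therefore
#' identical in every resample built from the same imputation.
#'
#' @param data a [survival_dataset()].
#' @param latent optional latent times from [impute_latent_times()]; drawn
#'   fresh when `NULL`.
#' @return A `survival_dataset` with the same groups; the latent structure
#'   used is attached as attribute `"latent"`.
#' @export
conditional_resample <- function(data, latent = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(latent)) latent <- impute_latent_times(data)
  e_perm <- latent$event_time[sample.int(data$n)]
  out <- replace_times(data, pmin(e_perm, latent$followup),
                       e_perm <= latent$followup)
  attr(out, "latent") <- latent
  out
}
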