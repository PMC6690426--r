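#' Compare asymptotic and exact p-values across clustering solutions
#'
#' For each clustering solution of a cohort, computes the asymptotic
#' p-value (AP), the exact permutation p-value (EP) with its confidence
#' interval, and the disagreement diagnostics: whether the AP falls inside
#' the EP confidence interval, the fold gap `max(AP, EP) / min(AP, EP)`,
#' and whether the two disagree about significance at `alpha`
#' (discordance is judged against the EP confidence interval, not the EP
#' point estimate, so Monte Carlo noise cannot flip the call).
#'
#' @param data a [survival_dataset()] for the cohort.
#' @param solutions a list (ideally named) of group-label vectors, each
#'   aligned with the patients of `data`; when `data` has ids and a
#'   solution has names, the solution is joined on id instead of row
#'   order.
#' @param B permutations per solution.
#' @param alpha significance threshold for the discordance flags.
#' @param scheme permutation scheme, see [logrank_permutation_test()].
#' @param imputations imputations for the conditional scheme.
#' @param seed integer seed.
#' @return A list with `records` (a data frame with one row per solution:
#'   `solution`, `ap`, `ep`, `ci_low`, `ci_high`, `ap_in_ci`, `fold_gap`,
#'   `discordant_at_alpha`) and `summary` (counts of solutions, APs
#'   outside the EP CI, at-least-2-fold gaps among significant APs, and
#'   discordant significance calls).
#' @export
compare_solutions <- function(data, solutions, B = 10000, alpha = 0.05,
                              scheme = c("label", "conditional"),
                              imputations = 10, seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  scheme <- match.arg(scheme)
  if (!is.list(solutions)) solutions <- list(solutions)
  ids <- names(solutions)
  if (is.null(ids)) ids <- paste0("solution", seq_along(solutions))

  records <- with_rng(seed, {
    do.call(rbind, lapply(seq_along(solutions), function(s) {
      lab <- solutions[[s]]
      if (!is.null(data$id) && !is.null(names(lab))) {
        idx <- match(data$id, names(lab))
        if (anyNA(idx))
          stop("solution '", ids[s], "': missing labels for some patient ids")
        lab <- lab[idx]
      }
      if (length(lab) != data$n)
        stop("solution '", ids[s], "': ", length(lab),
             " labels for ", data$n, " patients")
      d <- survival_dataset(data$time, data$event, lab)
      pt <- logrank_permutation_test(d, B = B, scheme = scheme,
                                     imputations = imputations)
      fold <- max(pt$ap, pt$p.value) / min(pt$ap, pt$p.value)
      ci <- pt$conf.int
      data.frame(
        solution = ids[s], ap = pt$ap, ep = pt$p.value,
        ci_low = ci[1], ci_high = ci[2],
        ap_in_ci = ci[1] <= pt$ap && pt$ap <= ci[2],
        fold_gap = fold,
        discordant_at_alpha =
          (pt$ap <= alpha && ci[1] > alpha) ||
          (pt$ap > alpha && ci[2] <= alpha),
        stringsAsFactors = FALSE)
    }))
  })
  sig <- records$ap <= alpha
  summary <- list(
    n_solutions = nrow(records),
    n_ap_outside_ci = sum(!records$ap_in_ci),
    n_fold_ge_2_among_significant = sum(sig & records$fold_gap >= 2),
    n_significant_ap = sum(sig),
    n_discordant = sum(records$discordant_at_alpha),
    alpha = alpha)
  list(records = records, summary = summary)
}

#' Null distribution of the asymptotic p-value under label permutation
#'
#' Permutes a clustering solution's label vector uniformly at random
#' `n_perm` times and computes the asymptotic log-rank p-value of each
#' permuted solution on the same survival data.  Under the null this
#' distribution should be uniform; an excess of small APs quantifies the
#' anti-conservatism of the chi-square approximation for that cohort and
#' group-size profile.  Setting `alpha` to an observed AP turns this into
#' the label-permutation significance diagnostic for a reported p-value
#' (the fraction of permutations with an AP at least as small).
#'
#' @param data a [survival_dataset()] for the cohort.
#' @param labels a group-label vector aligned with the patients.
#' @param n_perm number of label permutations (>= 1).
#' @param alpha threshold for the summary fraction.
#' @param seed integer seed.
#' @return A list with `ap` (vector of length `n_perm`),
#'   `fraction_le_alpha`, `alpha`, `n_perm`.
#' @export
ap_null_distribution <- function(data, labels, n_perm = 10000,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(labels) != data$n)
    stop("labels (", length(labels), ") do not align with patients (",
         data$n, ")")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  d <- survival_dataset(data$time, data$event, labels)
  ord <- order(d$time, method = "radix")
  gg <- d$group[ord]
  ap <- with_rng(seed, {
    perms <- vapply(seq_len(n_perm), function(i) sample(gg), integer(d$n))
    t_perm <- lr_stat_batch(d$time[ord], d$event[ord], perms, d$k)
    chisq_pvalue(t_perm, d$k - 1L)
  })
  list(ap = ap, fraction_le_alpha = mean(ap <= alpha), alpha = alpha,
       n_perm = n_perm)
}

#' Random small-cluster partition labels
#'
#' Partitions `n` patients uniformly at random into `k - 1` clusters of
#' exactly `small_size` patients and one large cluster holding everyone
#' else -- the partition family used to probe how the false-positive rate
#' of the asymptotic test grows with the number of clusters.
#'
#' @param n number of patients.
#' @param k total number of clusters (>= 2).
#' @param small_size size of each small cluster.
#' @return An integer label vector of length `n` with values `1 .. k`;
#'   cluster `k` is the large one.
#' @examples
#' table(random_clustering_labels(621, k = 4))  # 10, 10, 10, 591
#' @export
random_clustering_labels <- function(n, k, small_size = 10) {
  k <- as.integer(k); n <- as.integer(n); small_size <- as.integer(small_size)
  if (k < 2L) stop("k must be >= 2")
  if (n <= (k - 1L) * small_size)
    stop("infeasible sizes: (k - 1) * small_size = ", (k - 1L) * small_size,
         " must be < n = ", n)
  labels <- rep.int(k, n)
  picked <- sample.int(n, (k - 1L) * small_size)
  labels[picked] <- rep(seq_len(k - 1L), each = small_size)
  labels
}

#' False-positive-rate curve over random small-cluster partitions
#'
#' For each cluster count `k`, draws `n_reps` random partitions of the
#' cohort into `k - 1` clusters of `small_size` and one large cluster
#' (see [random_clustering_labels()]), tests each partition against the
#' cohort's survival, and records the fraction of partitions declared
#' significant at `alpha`.  Because the partitions are independent of
#' survival, that fraction estimates the test's false-positive rate; for
#' the asymptotic p-value it rises well above `alpha` as `k` grows, while
#' an exact permutation p-value stays at or below `alpha` up to Monte
#' Carlo noise.
#'
#' @param data a [survival_dataset()] (groups in `data` are ignored; only
#'   times and events are used).
#' @param k_range integer vector of cluster counts to evaluate.
#' @param small_size small-cluster size.
#' @param n_reps random partitions per `k`.
#' @param alpha significance threshold.
#' @param method `"AP"`, `"EP-label"` or `"EP-conditional"`.
#' @param B,imputations permutation settings for the EP methods.
#' @param seed integer seed.
#' @param level confidence level for the binomial interval.
#' @return A data frame with one row per `k`: `k`, `fraction_le_alpha`,
#'   `ci_low`, `ci_high`, `n_reps`, `mc_se`.
#' @export
fpr_curve <- function(data, k_range = 2:20, small_size = 10,
                      n_reps = 10000, alpha = 0.05,
                      method = c("AP", "EP-label", "EP-conditional"),
                      B = 999, imputations = 2, seed = NULL,
                      level = 0.95) {
  stopifnot(inherits(data, "survival_dataset"))
  method <- match.arg(method)
  k_range <- as.integer(k_range)
  if (any(data$n <= (k_range - 1L) * small_size))
    stop("infeasible k in k_range for n = ", data$n)
  ord <- order(data$time, method = "radix")
  tt <- data$time[ord]; ev <- data$event[ord]

  rows <- with_rng(seed, {
    lapply(k_range, function(k) {
      if (method == "AP") {
        labs <- vapply(seq_len(n_reps),
                       function(r) random_clustering_labels(data$n, k,
                                                            small_size)[ord],
                       integer(data$n))
        t_stat <- lr_stat_batch(tt, ev, labs, k)
        p <- chisq_pvalue(t_stat, k - 1L)
      } else {
        p <- vapply(seq_len(n_reps), function(r) {
          lab <- random_clustering_labels(data$n, k, small_size)
          d <- survival_dataset(data$time, data$event, lab)
          logrank_permutation_test(
            d, B = B,
            scheme = if (method == "EP-label") "label" else "conditional",
            imputations = imputations)$p.value
        }, numeric(1))
      }
      hits <- sum(p <= alpha)
      ci <- clopper_pearson(hits, n_reps, level)
      data.frame(k = k, fraction_le_alpha = hits / n_reps,
                 ci_low = ci[1], ci_high = ci[2], n_reps = n_reps,
                 mc_se = mc_se(alpha, n_reps))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}
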