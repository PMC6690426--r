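test_that("EP uses the add-one estimator and respects its bounds", {
  pt <- logrank_permutation_test(d1(), B = 499, seed = 3)
  expect_equal(pt$p.value, (pt$b + 1) / (pt$B + 1))
  expect_gte(pt$p.value, 1 / (pt$B + 1))
  expect_lte(pt$p.value, 1)
  expect_true(pt$conf.int[1] <= pt$conf.int[2])
  expect_error(logrank_permutation_test(d1(), B = 0), "B must be")
  expect_error(logrank_permutation_test(d1(), scheme = "bootstrap"))
})

test_that("identical seeds reproduce the permutation result exactly", {
  d <- random_dataset(n = 25, K = 3)
  for (scheme in c("label", "conditional")) {
    a <- logrank_permutation_test(d, B = 299, scheme = scheme, seed = 11,
                                  imputations = 2)
    b <- logrank_permutation_test(d, B = 299, scheme = scheme, seed = 11,
                                  imputations = 2)
    expect_identical(a, b)
  }
})

test_that("enumeration evaluates every distinct label assignment", {
  en <- logrank_enumeration(d1())
  expect_equal(en$n_assignments, choose(4, 2))   # 6 assignments for sizes (2,2)
  # only the observed split and its mirror reach T = 49/17
  expect_equal(en$p.value, 2/6)
  expect_equal(en$statistic, 49/17)
})

test_that("complete degeneracy gives exact p = 1", {
  d <- survival_dataset(rep(2, 5), rep(1, 5), c("A", "A", "B", "B", "B"))
  en <- logrank_enumeration(d)
  expect_equal(en$p.value, 1)
  expect_equal(en$statistic, 0)
})

test_that("the enumeration cap is enforced", {
  d <- random_dataset(n = 30, K = 3)
  expect_error(logrank_enumeration(d, cap = 100), "cap")
})

test_that("sampled EP converges to the enumerated exact value", {
  set.seed(41)
  for (rep in 1:4) {
    d <- random_dataset(n = sample(5:8, 1), K = 2, ties = rep %% 2 == 0,
                        cens_prob = 0.2)
    exact <- logrank_enumeration(d)$p.value
    B <- 20000
    ep <- logrank_permutation_test(d, B = B, seed = 50 + rep)$p.value
    expect_lt(abs(ep - exact), 4 * sqrt(exact * (1 - exact) / B) + 2 / B)
  }
})

test_that("Clopper-Pearson interval matches its closed forms", {
  ci <- ep_confidence_interval(0, 1000)
  expect_equal(ci[1], 0)
  expect_equal(ci[2], 1 - 0.025^(1 / 1000), tolerance = 1e-10)
  ci_hi <- ep_confidence_interval(1000, 1000)
  expect_equal(ci_hi[1], 0.025^(1 / 1000), tolerance = 1e-10)
  expect_equal(ci_hi[2], 1)
  ci_mid <- ep_confidence_interval(50, 1000)
  expect_true(ci_mid[1] < 0.05 && 0.05 < ci_mid[2])
  expect_error(ep_confidence_interval(10, 100, level = 1.2), "level")
})

test_that("conditional resampling preserves follow-up structure", {
  # unequal administrative cutoffs: group g1 truncated at 0.4, g2 at 2
  cfg <- scenario_config(c(25, 25), censoring = list(
    censoring_model("administrative", tau = 0.4),
    censoring_model("administrative", tau = 2)))
  d <- generate_dataset(cfg, seed = 61)
  set.seed(62)
  lat <- impute_latent_times(d)
  expect_length(lat$event_time, d$n)
  expect_true(all(lat$followup[d$event] >= d$time[d$event]))
  expect_true(all(lat$event_time[!d$event] >= d$time[!d$event]))
  for (r in 1:5) {
    rs <- conditional_resample(d, latent = lat)
    expect_identical(rs$group, d$group)
    fu <- attr(rs, "latent")$followup
    # per-group follow-up multiset invariant across resamples
    expect_equal(sort(fu[rs$group == 1]), sort(lat$followup[d$group == 1]))
    expect_true(all(rs$time <= fu + 1e-12))
  }
})

test_that("with zero censoring the conditional scheme is label permutation", {
  d <- random_dataset(n = 20, K = 2, cens_prob = 0)
  set.seed(63)
  lat <- impute_latent_times(d)
  expect_equal(lat$event_time, d$time)           # nothing to impute
  expect_true(all(lat$followup == max(d$time)))  # degenerate follow-up law
  rs <- conditional_resample(d, latent = lat)
  expect_equal(sort(rs$time), sort(d$time))      # times merely permuted
  expect_true(all(rs$event))
})

test_that("EP is valid under the null for both schemes", {
  set.seed(64)
  cfg <- scenario_config(c(12, 12), censoring =
                           censoring_model("exponential", rate = 0.4),
                         n_reps = 1)
  n_reps <- 150
  for (scheme in c("label", "conditional")) {
    rej <- mean(vapply(seq_len(n_reps), function(r) {
      d <- generate_dataset(cfg)
      logrank_permutation_test(d, B = 99, scheme = scheme,
                               imputations = 2)$p.value
    }, numeric(1)) <= 0.05)
    expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / n_reps))
  }
})

test_that("AP and EP agree in the large balanced, event-rich regime", {
  set.seed(65)
  cfg <- scenario_config(c(250, 250), n_reps = 1)   # no censoring
  gaps <- vapply(1:10, function(r) {
    d <- generate_dataset(cfg)
    pt <- logrank_permutation_test(d, B = 2000)
    abs(pt$ap - pt$p.value)
  }, numeric(1))
  expect_lt(median(gaps), 0.01)
})
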