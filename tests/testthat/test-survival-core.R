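test_that("validation rejects malformed inputs", {
  expect_error(survival_dataset(c(1, 2), c(1, 1), c("A", "A")), "K < 2")
  expect_error(survival_dataset(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_error(survival_dataset(c(-1, 2), c(1, 1), c("A", "B")), "negative time")
  expect_error(survival_dataset(c(1, 2), c(1, 2), c("A", "B")), "0/1")
  expect_error(survival_dataset(c(1, Inf), c(1, 1), c("A", "B")), "non-finite")
  expect_error(survival_dataset(1, 1, "A"), "at least 2")
  expect_error(survival_dataset(c(1, 2), c(1, 1, 1), c("A", "B")), "equal length")
})

test_that("a well-formed table passes through with first-appearance coding", {
  d <- survival_dataset(c(5, 1, 3, 2), c(1, 0, 1, 1), c("b", "a", "b", "a"))
  expect_s3_class(d, "survival_dataset")
  expect_equal(d$n, 4)
  expect_equal(d$k, 2)
  expect_equal(d$levels, c("b", "a"))       # first-appearance order
  expect_equal(d$group, c(1L, 2L, 1L, 2L))
  expect_equal(as.data.frame(d)$group, c("b", "a", "b", "a"))
})

test_that("time zero is allowed and enters the first risk set", {
  d <- survival_dataset(c(0, 1, 2), c(1, 1, 0), c("A", "B", "B"))
  rt <- risk_table(d)
  expect_equal(rt$time[1], 0)
  expect_equal(rt$n_risk[1], 3)
})

test_that("risk table matches hand enumeration on the worked example", {
  rt <- risk_table(d1())
  expect_equal(rt$time, c(1, 2, 3, 4))
  expect_equal(rt$n_risk, c(4, 3, 2, 1))
  expect_equal(rt$n_event, rep(1L, 4))
  expect_equal(rt$n_risk_A, c(2, 1, 0, 0))
  expect_equal(rt$n_event_A, c(1L, 1L, 0L, 0L))
})

test_that("censoring at an event time counts as at risk (events first at ties)", {
  d <- survival_dataset(c(5, 5, 1), c(1, 0, 1), c("A", "B", "B"))
  rt <- risk_table(d)
  i <- which(rt$time == 5)
  expect_equal(rt$n_risk[i], 2)       # both the event and the censored patient
  expect_equal(rt$n_event[i], 1)
})

test_that("single event among censored gives a one-row risk table", {
  d <- survival_dataset(c(2, 1, 3, 4), c(1, 0, 0, 0), c("A", "A", "B", "B"))
  rt <- risk_table(d)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$n_event, 1L)
  expect_equal(rt$n_risk, 3L)          # patients with time >= 2
})

test_that("risk table counts conserve and are order/transform invariant", {
  set.seed(101)
  for (rep in 1:10) {
    d <- random_dataset(n = sample(10:40, 1), K = sample(2:4, 1),
                        ties = rep %% 2 == 0)
    rt <- risk_table(d)
    nr <- as.matrix(rt[, paste0("n_risk_", d$levels)])
    ne <- as.matrix(rt[, paste0("n_event_", d$levels)])
    expect_equal(unname(rowSums(nr)), as.numeric(rt$n_risk))
    expect_equal(unname(rowSums(ne)), as.numeric(rt$n_event))
    expect_true(all(diff(rt$n_risk) <= 0))
    expect_true(all(rt$n_event >= 1 & rt$n_event <= rt$n_risk))

    # row order invariance
    perm <- sample.int(d$n)
    d2 <- survival_dataset(d$time[perm], d$event[perm],
                           d$levels[d$group][perm])
    rt2 <- risk_table(d2)
    expect_equal(rt2$time, rt$time)
    expect_equal(rt2$n_risk, rt$n_risk)
    expect_equal(unname(as.matrix(rt2[, paste0("n_risk_", d$levels)])),
                 unname(nr))

    # strictly monotone transform of time preserves all counts
    d3 <- survival_dataset(d$time^3 + d$time, d$event, d$levels[d$group])
    rt3 <- risk_table(d3)
    expect_equal(rt3$n_risk, rt$n_risk)
    expect_equal(rt3$n_event, rt$n_event)
  }
})

test_that("Kaplan-Meier matches the product-limit hand calculation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(7)
  t <- rexp(40)
  km <- kaplan_meier(t, rep(1, 40))
  expect_equal(km$survival, 1 - ecdf(t)(km$time), tolerance = 1e-12)
})

test_that("KM with one event among censored has a single 1/n step", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(nrow(km), 1L)
  expect_equal(km$survival, 1 - 1/4)
})

test_that("KM is non-increasing and errors without events", {
  set.seed(8)
  km <- kaplan_meier(rexp(30), rbinom(30, 1, 0.6))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival <= 1))
  expect_error(kaplan_meier(c(1, 2), c(0, 0)), "no events")
})
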