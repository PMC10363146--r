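test_that("spearman matches the rank-difference formula and symmetry", {
  expect_equal(spearmanTest(1:5, c(2, 4, 6, 8, 10))$rs, 1)
  expect_equal(spearmanTest(1:5, 5:1)$rs, -1)
  # perfect correlation: p floored at smallest positive double, not 0
  expect_gt(spearmanTest(1:5, 1:5 * 2)$p_value, 0)

  # no-tie oracle: rs = 1 - 6*sum(d^2)/(n*(n^2-1))
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  d <- rank(x) - rank(y)
  expect_equal(spearmanTest(x, y)$rs, 1 - 6 * sum(d^2) / (4 * 15))
  expect_equal(spearmanTest(x, y)$rs, 0.6)

  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r1 <- spearmanTest(x, y); r2 <- spearmanTest(y, x)
    expect_equal(r1$rs, r2$rs)
    expect_equal(r1$p_value, r2$p_value)
    d <- rank(x) - rank(y)
    expect_equal(r1$rs, 1 - 6 * sum(d^2) / (8 * 63))
    # invariance under strictly increasing transforms
    expect_equal(spearmanTest(exp(x), y)$rs, r1$rs)
    expect_equal(spearmanTest(x, 3 * y + 7)$p_value, r1$p_value)
  }

  expect_error(spearmanTest(rep(1, 5), 1:5), "constant")
  expect_error(spearmanTest(1:3, 1:3), "n >= 4")
})

test_that("spearman t-approximation tracks the exact permutation null at small n", {
  set.seed(102)
  mx <- 0
  for (i in 1:15) {
    n <- sample(5:7, 1)
    x <- rnorm(n); y <- rnorm(n)
    p_exact <- spearmanPermP(x, y)
    p_t <- spearmanTest(x, y)$p_value
    mx <- max(mx, abs(p_exact - p_t))
  }
  # measured deviation of the documented approximation at n = 5..7
  expect_lt(mx, 0.1)
})

test_that("mann-whitney agrees with label-enumeration and self-comparison is null", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)  # 2 of 6 assignments as extreme
  expect_equal(r$p_value, mwEnumP(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_equal(r$direction, "group2_higher")

  x <- c(5, 1, 9, 4)
  same <- mannWhitney(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  set.seed(103)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(4, 1)
    expect_equal(mannWhitney(x, y, "exact")$p_value, mwEnumP(x, y),
                 tolerance = 1e-12)
  }

  # large separated groups are decisively significant
  set.seed(104)
  big <- mannWhitney(rnorm(50), rnorm(50, 3))
  expect_lt(big$p_value, 0.001)
  expect_equal(big$direction, "group2_higher")

  expect_error(mannWhitney(numeric(0), 1:3), "empty group")
})

test_that("mann-whitney normal approximation stays close to exact", {
  set.seed(105)
  for (i in 1:15) {
    n1 <- sample(10:20, 1); n2 <- sample(10:20, 1)  # n1*n2 in [100, 400]
    x <- rnorm(n1); y <- rnorm(n2, 0.3)
    pe <- mannWhitney(x, y, "exact")$p_value
    pn <- mannWhitney(x, y, "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
  # auto mode picks exact for small tie-free inputs, normal with ties
  expect_equal(mannWhitney(rnorm(5), rnorm(5), "auto")$mode_used, "exact")
  expect_equal(mannWhitney(c(1, 2, 2), c(2, 3, 4), "auto")$mode_used, "normal")
  expect_equal(mannWhitney(rnorm(25), rnorm(25), "auto")$mode_used, "normal")
})

test_that("km fit reproduces hand product-limit computations", {
  k <- kmFit(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(k@times, c(1, 3))
  expect_equal(k@surv, c(1 - 1/3, (1 - 1/3) * (1 - 1/1)))
  expect_equal(kmSurvAt(k, c(0.5, 1.5, 5)), c(1, 2/3, 0))

  # all censored: flat at 1
  flat <- kmFit(c(5, 6, 7), c(FALSE, FALSE, FALSE))
  expect_equal(kmSurvAt(flat, c(0, 10)), c(1, 1))

  # distinct event times telescope d_i/n_i
  tele <- kmFit(1:4, rep(TRUE, 4))
  expect_equal(tele@surv, c(0.75, 0.5, 0.25, 0))

  # with no censoring the curve equals 1 - ECDF at event times
  set.seed(106)
  tms <- round(rexp(40, 1 / 50), 3)
  k2 <- kmFit(tms, rep(TRUE, 40))
  ec <- stats::ecdf(tms)
  expect_equal(k2@surv, 1 - ec(k2@times), tolerance = 1e-12)

  # hand oracle with censoring interleaved
  set.seed(107)
  tms <- sample(1:30, 20, replace = TRUE)
  evs <- runif(20) < 0.7
  if (any(evs)) {
    h <- handKM(tms, evs)
    k3 <- kmFit(tms, evs)
    expect_equal(k3@times, h$times)
    expect_equal(k3@surv, h$surv, tolerance = 1e-12)
  }

  expect_error(kmFit(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("log-rank test is symmetric, shift-invariant and null on identical groups", {
  t1 <- c(5, 10, 15, 20, 25); e1 <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  same <- logrankTest(t1, e1, t1, e1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  set.seed(108)
  t2 <- rexp(30, 1 / 20); e2 <- runif(30) < 0.8
  t3 <- rexp(25, 1 / 10); e3 <- runif(25) < 0.8
  a <- logrankTest(t2, e2, t3, e3)
  b <- logrankTest(t3, e3, t2, e2)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  # direction flips with the labels
  expect_true(setequal(c(a$direction, b$direction),
                       c("group1_worse", "group2_worse")))
  # adding a constant to all times changes nothing
  shifted <- logrankTest(t2 + 100, e2, t3 + 100, e3)
  expect_equal(shifted$statistic, a$statistic)

  # no events anywhere: p = 1, no direction
  none <- logrankTest(c(1, 2), c(FALSE, FALSE), c(3, 4), c(FALSE, FALSE))
  expect_equal(none$p_value, 1)
  expect_equal(none$direction, "none")
})

test_that("log-rank detects a threefold hazard ratio with high power", {
  set.seed(109)
  reject <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    d1 <- rexp(100, 1); c1 <- rexp(100, 0.25)   # ~20% censoring
    d2 <- rexp(100, 3); c2 <- rexp(100, 0.25)
    r <- logrankTest(pmin(d1, c1), d1 <= c1, pmin(d2, c2), d2 <= c2)
    if (r$p_value < 0.05) reject <- reject + 1
  }
  expect_gt(reject / reps, 0.9)
})
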