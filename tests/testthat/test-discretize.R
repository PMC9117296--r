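test_that("discretize applies the two-threshold sign rule with boundary -> 0", {
  expect_identical(discretize(c(1, 5, 10), 3, 8), c(-1L, 0L, 1L))
  expect_identical(discretize(c(9, 10, 11), 3, 8), c(1L, 1L, 1L))
  expect_identical(discretize(c(3, 8), 3, 8), c(0L, 0L))
  expect_error(discretize(c(1, NA), 0, 1), "finite")
  expect_error(discretize(c(1, Inf), 0, 1), "finite")
  expect_error(discretize(1:3, 2, 1), "k1 <= k2")
})

test_that("confusion matrix counts co-occurring signs and carries exact marginals", {
  cm <- confusion_matrix(c(1, 1, -1), c(-1, 0, 1))
  expect_equal(cm["+", "-"], 1L)
  expect_equal(cm["+", "0"], 1L)
  expect_equal(cm["-", "+"], 1L)
  expect_equal(sum(cm), 3L)
  expect_equal(sum(cm) - cm["+", "-"] - cm["+", "0"] - cm["-", "+"], 0L)

  cm2 <- confusion_matrix(c(1, -1, 0), c(1, -1, 0))
  expect_equal(diag(cm2), c("+" = 1L, "-" = 1L, "0" = 1L))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0L)

  # marginal identities hold for random sign vectors
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    vh <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    vd <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    cm <- confusion_matrix(vh, vd)
    expect_equal(unname(rowSums(cm)),
                 c(sum(vh == 1), sum(vh == -1), sum(vh == 0)))
    expect_equal(unname(colSums(cm)),
                 c(sum(vd == 1), sum(vd == -1), sum(vd == 0)))
  }
  expect_error(confusion_matrix(c(1, 0), c(1, 0, -1)), "equal length")
  expect_error(confusion_matrix(c(2, 0), c(1, 0)), "values in")
})

test_that("discordance statistic is n_{+,-} + n_{-,+}", {
  expect_equal(discordance(confusion_matrix(c(1, 1, -1), c(-1, 0, 1))), 2L)
  expect_equal(discordance(confusion_matrix(c(1, -1, 0), c(1, -1, 0))), 0L)
  expect_equal(discordance(confusion_matrix(rep(1, 5), rep(-1, 5))), 5L)
})

test_that("exhaustive threshold search attains the brute-force maximum", {
  # perfectly separated profile
  opt <- optimize_thresholds(rep(1, 4) + 1e-3 * (0:3), rep(10, 4) + 1e-3 * (0:3))
  expect_equal(opt$h_max, 4L)
  # constant profile: no cut separates anything
  opt0 <- optimize_thresholds(rep(2, 4), rep(2, 4))
  expect_equal(opt0$h_max, 0L)
  # derived example, checked against the direct scan
  expect_equal(optimize_thresholds(c(1, 2, 6, 7), c(5, 8, 3, 4))$h_max,
               brute_force_hmax(c(1, 2, 6, 7), c(5, 8, 3, 4)))

  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    h <- rnorm(n); d <- rnorm(n)
    opt <- optimize_thresholds(h, d)
    expect_equal(opt$h_max, brute_force_hmax(h, d))
    expect_true(opt$h_max >= 0 && opt$h_max <= n)
    expect_true(opt$k1 <= opt$k2)
  }
})

test_that("h_max is invariant under strictly increasing transforms", {
  set.seed(5)
  for (i in 1:10) {
    h <- rnorm(8); d <- rnorm(8)
    base <- optimize_thresholds(h, d)$h_max
    expect_equal(optimize_thresholds(exp(h), exp(d))$h_max, base)
    expect_equal(optimize_thresholds(atan(h), atan(d))$h_max, base)
    expect_equal(optimize_thresholds(2 * h + 5, 2 * d + 5)$h_max, base)
  }
})

test_that("genetic search reaches the exhaustive maximum on small inputs", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:14, 1)   # <= 30 unique pooled values
    h <- rnorm(n); d <- rnorm(n)
    ex <- optimize_thresholds(h, d)$h_max
    ga <- optimize_thresholds(h, d, method = "genetic", seed = i)$h_max
    expect_lte(ga, ex)
    expect_equal(ga, ex)
  }
})

test_that("threshold tie-breaking prefers the widest no-change band", {
  # values placed so several candidate pairs attain h_max: pooled values
  # 0, 1, 2, 3 give candidates 0.5, 1.5, 2.5; pairs (h=0, d=3) and
  # (h=1, d=2) are fully discordant for k1 = k2 = 1.5 but the first pair
  # alone admits the wider band (0.5, 2.5) -- h_max decides first
  h <- c(0, 1); d <- c(3, 2)
  opt <- optimize_thresholds(h, d)
  expect_equal(opt$h_max, 2L)
  expect_equal(c(opt$k1, opt$k2), c(1.5, 1.5))
  # single maximizing pair with slack on k1 only: widest band chosen
  h2 <- c(0, 0.1, 0.2); d2 <- c(10, 10.1, 10.2)
  opt2 <- optimize_thresholds(h2, d2)
  expect_equal(opt2$h_max, 3L)
  expect_equal(c(opt2$k1, opt2$k2), c(5.1, 5.1))
  # constant profile resolves to the infinite band
  opt0 <- optimize_thresholds(rep(1, 3), rep(1, 3))
  expect_identical(c(opt0$k1, opt0$k2), c(-Inf, Inf))
})
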