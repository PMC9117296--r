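test_that("split probabilities are multivariate hypergeometric and normalize", {
  # only one split possible when every sign is 0
  expect_equal(split_probability(c(0, 0, 3), c(0, 0, 3)), 1)
  # direct binomial evaluation: C(2,1) C(2,1) / C(4,2)
  expect_equal(split_probability(c(1, 1, 0), c(1, 1, 0)), 4 / 6)
  expect_error(split_probability(c(1, 1, 0), c(1, 1, 0), pooled = c(2, 2, 1)),
               "inconsistent")
  expect_error(split_probability(c(1, 1, 1), c(1, 1, 0)), "sum to n")

  # normalization over all feasible splits, several pooled configurations
  for (pooled in list(c(2, 2, 0), c(3, 2, 3), c(5, 0, 3), c(1, 1, 4))) {
    n <- sum(pooled) / 2
    tot <- 0
    for (kd in split_triples(n)) {
      kh <- pooled - kd
      if (any(kh < 0)) next
      tot <- tot + split_probability(kd, kh)
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("confusion-matrix probabilities multiply the two hypergeometric factors", {
  # forced configuration: all healthy and diseased signs positive
  expect_equal(confusion_probability(3, 0, 0, 0, c(3, 0, 0), c(3, 0, 0)), 1)
  # derived: two equally likely pairings
  expect_equal(confusion_probability(0, 1, 1, 0, c(1, 1, 0), c(1, 1, 0)), 1 / 2)
  # infeasible configurations return 0, not an error
  expect_equal(confusion_probability(2, 0, 0, 0, c(1, 1, 0), c(1, 1, 0)), 0)

  # normalization over all free entries for random splits
  set.seed(8)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    kh <- as.vector(rmultinom(1, n, c(1, 1, 1)))
    kd <- as.vector(rmultinom(1, n, c(1, 1, 1)))
    tot <- 0
    for (npp in 0:n) for (npm in 0:n) for (nmp in 0:n) for (nmm in 0:n)
      tot <- tot + confusion_probability(npp, npm, nmp, nmm, kh, kd)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("conditional distribution of the discordance matches pairing enumeration", {
  # derived two-pairing example
  expect_equal(conditional_distribution(c(1, 1, 0), c(1, 1, 0)),
               c(1 / 2, 0, 1 / 2))
  # all-zero healthy signs force x = 0
  expect_equal(conditional_distribution(c(0, 0, 3), c(1, 1, 1)),
               c(1, 0, 0, 0))
  # full agreement with the n! enumeration for every split with n <= 4
  for (n in 2:4) {
    for (kh in split_triples(n)) for (kd in split_triples(n)) {
      pmf <- conditional_distribution(kh, kd)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      expect_equal(pmf, enumerate_pairing_pmf(kh, kd), tolerance = 1e-12)
    }
  }
})

test_that("conditional p-value is the exact upper tail", {
  expect_equal(conditional_pvalue(0, c(2, 1, 0), c(0, 1, 2)), 1)
  expect_equal(conditional_pvalue(2, c(1, 1, 0), c(1, 1, 0)), 1 / 2)
  expect_equal(conditional_pvalue(7, c(1, 1, 0), c(1, 1, 0)), 0)
})

test_that("Hy-test p-value: worked values, tails, and the two evaluation paths agree", {
  expect_equal(hy_pvalue(2, 2, 2, 0), 2 / 3, tolerance = 1e-12)
  expect_equal(hy_pvalue(2, 2, 2, 0, method = "split"), 2 / 3, tolerance = 1e-12)
  expect_equal(hy_pvalue(0, 3, 4, 1), 1)
  expect_equal(hy_pvalue(1, 0, 0, 8), 0)    # all signs zero: x is always 0

  # pairing and split mixtures agree well beyond the enumeration range
  for (pooled in list(c(10, 8, 6), c(20, 15, 15), c(7, 0, 9), c(12, 12, 0))) {
    p1 <- hy_null_pmf(pooled[1], pooled[2], pooled[3])
    p2 <- hy_null_pmf(pooled[1], pooled[2], pooled[3], method = "split")
    expect_equal(p1, p2, tolerance = 1e-11)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
  }
})

test_that("exact null matches the enumeration oracle for all configurations (2n <= 8)", {
  for (two_n in seq(2, 8, 2)) {
    for (pooled in pooled_configs(two_n)) {
      o <- enumerate_null_oracle(pooled[1], pooled[2], pooled[3])
      expect_equal(hy_null_pmf(pooled[1], pooled[2], pooled[3]), o,
                   tolerance = 1e-10)
    }
  }
  expect_error(enumerate_null_oracle(8, 8, 0), "2n <= 14")
  expect_equal(enumerate_null_oracle(0, 0, 6), c(1, 0, 0, 0))
})

test_that("p-value is monotone in x_hat and symmetric in labels and signs", {
  for (pooled in list(c(5, 3, 2), c(10, 10, 0), c(4, 4, 8))) {
    n <- sum(pooled) / 2
    p <- vapply(0:n, hy_pvalue, numeric(1),
                k_plus = pooled[1], k_minus = pooled[2], k_zero = pooled[3])
    expect_true(all(diff(p) <= 1e-14))
    # sign symmetry: K+ <-> K-
    p_swap <- vapply(0:n, hy_pvalue, numeric(1),
                     k_plus = pooled[2], k_minus = pooled[1], k_zero = pooled[3])
    expect_equal(p, p_swap, tolerance = 1e-12)
  }
})

test_that("single-gene Hy-test composes thresholding and the exact null", {
  g <- hy_test_gene(c(1, 1.1), c(8, 9))
  expect_equal(g$x_hat, 2L)
  expect_equal(g$p_value, 2 / 3, tolerance = 1e-12)

  const <- hy_test_gene(rep(2, 5), rep(2, 5))
  expect_equal(const$x_hat, 0L)
  expect_equal(const$p_value, 1)

  set.seed(13)
  for (i in 1:10) {
    h <- rnorm(9); d <- rnorm(9, mean = 0.8)
    g <- hy_test_gene(h, d)
    # composition contract
    expect_equal(g$p_value,
                 hy_pvalue(g$x_hat, g$k_plus, g$k_minus, g$k_zero))
    expect_true(g$p_value >= 0 && g$p_value <= 1)
    # monotone-transform invariance of (x_hat, p)
    g2 <- hy_test_gene(2^h, 2^d)
    expect_equal(g2$x_hat, g$x_hat)
    expect_equal(g2$p_value, g$p_value)
    # healthy/diseased label symmetry
    g3 <- hy_test_gene(d, h)
    expect_equal(g3$x_hat, g$x_hat)
    expect_equal(g3$p_value, g$p_value)
  }
})

test_that("p-value depends on the data only through pooled counts and x_hat", {
  # two very different profiles engineered to share (K+, K-, K0, x_hat)
  a <- hy_test_gene(c(-5, -4, 10, 11), c(6, 7, -8, -9))
  b <- hy_test_gene(c(-50, -40, 100, 110) / 7, c(60, 70, -80, -90) / 7)
  expect_equal(a[c("x_hat", "k_plus", "k_minus", "k_zero")],
               b[c("x_hat", "k_plus", "k_minus", "k_zero")])
  expect_identical(a$p_value, b$p_value)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(0.001, m = 1000), 1.0)
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m")
})
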