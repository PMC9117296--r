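test_that("scenario constructor validates its parameters", {
  expect_s3_class(sim_scenario(), "hy_scenario")
  expect_error(sim_scenario(n = 1), "n")
  expect_error(sim_scenario(rho = 1), "rho")
  expect_error(sim_scenario(variance = 0), "variance")
  expect_error(sim_scenario(pl_alpha = 2), "pl_alpha")
})

test_that("simulation is reproducible and leaves the global RNG untouched", {
  s <- sim_scenario("powerlaw", n = 10, n_genes = 20, seed = 99)
  a <- simulate_paired_matrix(s)
  set.seed(1234); before <- .Random.seed
  b <- simulate_paired_matrix(s)
  expect_identical(before, .Random.seed)
  expect_identical(a$y1, b$y1)
  expect_identical(a$y2, b$y2)
})

test_that("log-normal generator honours the stated moments", {
  s_null <- sim_scenario("lognormal", n = 50, rho = 0, n_genes = 250,
                         seed = 5, hypothesis = "null")
  sim <- simulate_paired_matrix(s_null)
  d <- log2(sim$y2) - log2(sim$y1)
  se <- sqrt(0.5 / length(d))           # var of a difference = 2 * 0.25
  expect_lt(abs(mean(d)), 4 * se)

  s_alt <- sim_scenario("lognormal", n = 50, rho = 0, n_genes = 250, seed = 6)
  sim <- simulate_paired_matrix(s_alt)
  d <- log2(sim$y2) - log2(sim$y1)
  expect_lt(abs(mean(d) - 1), 4 * se)
  v <- var(as.vector(log2(sim$y1)))
  expect_lt(abs(v - 0.25), 4 * 0.25 * sqrt(2 / length(d)))
})

test_that("power-law generator has log2 mean shift 1 and the printed parameters", {
  s <- sim_scenario("powerlaw", n = 50, rho = 0.1, n_genes = 250, seed = 7)
  sim <- simulate_paired_matrix(s)
  expect_gte(min(sim$y1), 20)           # Pareto support starts at x_min
  expect_gte(min(sim$y2), 40)
  d <- log2(sim$y2) - log2(sim$y1)
  sd_d <- sd(as.vector(d))
  expect_lt(abs(mean(d) - 1), 4 * sd_d / sqrt(length(d)))
  # log2 values are affine in Exp(1)/shape: variance 1/(2.5 ln 2)^2
  v_theo <- 1 / (2.5 * log(2))^2
  expect_lt(abs(var(as.vector(log2(sim$y1))) - v_theo), 0.03)
  # rescale flag forces the stated 0.25
  s2 <- sim_scenario("powerlaw", n = 50, rho = 0.1, n_genes = 250, seed = 7,
                     rescale_variance = TRUE)
  sim2 <- simulate_paired_matrix(s2)
  expect_lt(abs(var(as.vector(log2(sim2$y1))) - 0.25), 0.03)
})

test_that("within-pair correlation tracks the scenario rho for both marginals", {
  for (marg in c("lognormal", "powerlaw")) {
    for (rho in c(0.1, 0.4)) {
      s <- sim_scenario(marg, n = 50, rho = rho, n_genes = 250, seed = 31)
      sim <- simulate_paired_matrix(s)
      r <- cor(as.vector(log2(sim$y1)), as.vector(log2(sim$y2)))
      expect_lt(abs(r - rho), 0.05)
    }
  }
})

test_that("Hy-test results are identical on raw and log2 simulated scales", {
  s <- sim_scenario("powerlaw", n = 20, n_genes = 5, seed = 17)
  sim <- simulate_paired_matrix(s)
  for (g in 1:5) {
    raw <- hy_test_gene(sim$y1[g, ], sim$y2[g, ])
    lg <- hy_test_gene(log2(sim$y1[g, ]), log2(sim$y2[g, ]))
    expect_equal(raw$x_hat, lg$x_hat)
    expect_equal(raw$p_value, lg$p_value)
  }
})

test_that("rejection rate counts Bonferroni-significant fractions", {
  expect_equal(rejection_rate(rep(1, 10)), 0)
  expect_equal(rejection_rate(rep(0, 10)), 1)
  expect_equal(rejection_rate(c(0.0001, 0.5), m = 2), 0.5)
})

test_that("power study runs both methods deterministically", {
  s <- sim_scenario("lognormal", n = 20, rho = 0.1, n_genes = 40, seed = 3)
  r1 <- run_power_study(s)
  r2 <- run_power_study(list(s))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$method, c("hytest", "modt"))
  expect_true(all(r1$rejection_rate >= 0 & r1$rejection_rate <= 1))
})

test_that("fixture generator plants labelled shifts and round-trips scenarios", {
  fx <- simulate_fixture(n_genes = 12, n_pairs = 8, frac_de = 0.5, seed = 4)
  expect_equal(dim(fx$expr), c(12L, 16L))
  expect_equal(sum(fx$truth$is_de), 6L)
  expect_identical(fx$expr, simulate_fixture(n_genes = 12, n_pairs = 8,
                                             frac_de = 0.5, seed = 4)$expr)
  # planted genes really are shifted on the log2 scale
  lg <- log2(fx$expr)
  shift <- rowMeans(lg[, 9:16]) - rowMeans(lg[, 1:8])
  expect_gt(min(shift[fx$truth$is_de]), 1)
  expect_lt(max(abs(shift[!fx$truth$is_de])), 1)
})

test_that("scenario YAML configs round-trip through the reader", {
  cfg <- list(scenarios = list(
    list(marginal = "lognormal", n = 10L, rho = 0.2, n_genes = 5L, seed = 2L),
    list(marginal = "powerlaw", n = 12L, hypothesis = "null", seed = 3L)))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  sc <- read_scenarios(f)
  expect_length(sc, 2)
  expect_equal(sc[[1]]$rho, 0.2)
  expect_equal(sc[[2]]$hypothesis, "null")
  unlink(f)
})
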