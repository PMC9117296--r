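# Monte Carlo power study: Hy-test vs moderated paired t, rejection rates
# after Bonferroni correction across the replicate genes.

#' Bonferroni-corrected rejection rate
#'
#' Fraction of p-values significant at `alpha` after multiplying by `m`
#' (capped at 1).
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param alpha Significance level.
#' @param m Bonferroni multiplier, at least `length(p_values)`.
#' @return Proportion in \[0, 1\].
#' @export
rejection_rate <- function(p_values, alpha = 0.05, m = length(p_values)) {
  mean(bonferroni_adjust(p_values, m) < alpha)
}

#' Scenario grid of the power study (alternative hypothesis)
#'
#' All combinations of marginal family (log-normal, power-law), sample size
#' n in \{50, 75\} and copula correlation rho in \{0.1, 0.2, 0.4\}, each
#' with 250 replicate genes, log2 shift 1 and log2 variance 0.25.
#'
#' @param seed Base seed; each scenario derives its own stream.
#' @param n_genes Replicates per scenario.
#' @param n_values,rho_values Grid values.
#' @return List of `"hy_scenario"` objects.
#' @export
power_study_scenarios <- function(seed = 1L, n_genes = 250L,
                                  n_values = c(50L, 75L),
                                  rho_values = c(0.1, 0.2, 0.4)) {
  grid <- expand.grid(marginal = c("lognormal", "powerlaw"),
                      n = n_values, rho = rho_values,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    sim_scenario(marginal = grid$marginal[i], n = grid$n[i],
                 rho = grid$rho[i], n_genes = n_genes,
                 seed = (seed * 1009L + i) %% .Machine$integer.max,
                 hypothesis = "alternative"))
}

#' Null-hypothesis scenarios of the power study
#'
#' No mean shift and independent samples (rho = 0), for both marginal
#' families and both sample sizes.
#'
#' @inheritParams power_study_scenarios
#' @return List of `"hy_scenario"` objects.
#' @export
null_study_scenarios <- function(seed = 1L, n_genes = 250L,
                                 n_values = c(50L, 75L)) {
  grid <- expand.grid(marginal = c("lognormal", "powerlaw"),
                      n = n_values, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    sim_scenario(marginal = grid$marginal[i], n = grid$n[i], rho = 0,
                 n_genes = n_genes,
                 seed = (seed * 2003L + i) %% .Machine$integer.max,
                 hypothesis = "null"))
}

#' Run the Monte Carlo power study
#'
#' For each scenario: simulate the replicate genes, apply the Hy-test and
#' the moderated paired t-test to every gene (the t-test on the log2
#' scale; the Hy-test is invariant to it), Bonferroni-correct across the
#' replicate genes, and record the mean rejection rate.
#'
#' @param scenarios List of `"hy_scenario"` objects.
#' @param alpha Significance level.
#' @param methods Subset of `c("hytest", "modt")`.
#' @return A data frame of class `"hy_power_study"` with one row per
#'   scenario x method: `marginal`, `n`, `rho`, `hypothesis`, `method`,
#'   `rejection_rate`, `n_genes`, `seed`.
#' @export
run_power_study <- function(scenarios, alpha = 0.05,
                            methods = c("hytest", "modt")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (inherits(scenarios, "hy_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (s in scenarios) {
    sim <- simulate_paired_matrix(s)
    l1 <- log2(sim$y1); l2 <- log2(sim$y2)
    rates <- c()
    if ("hytest" %in% methods) {
      p_hy <- vapply(seq_len(s$n_genes), function(g)
        hy_test_gene(l1[g, ], l2[g, ])$p_value, numeric(1))
      rates["hytest"] <- rejection_rate(p_hy, alpha, s$n_genes)
    }
    if ("modt" %in% methods) {
      p_t <- moderated_t_paired(l1, l2)
      rates["modt"] <- rejection_rate(p_t, alpha, s$n_genes)
    }
    for (m in names(rates))
      rows[[length(rows) + 1L]] <- data.frame(
        marginal = s$marginal, n = s$n, rho = s$rho,
        hypothesis = s$hypothesis, method = m,
        rejection_rate = unname(rates[m]), n_genes = s$n_genes,
        seed = s$seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hy_power_study", "data.frame")
  out
}

#' @export
print.hy_power_study <- function(x, ...) {
  cat("Monte Carlo rejection rates (Bonferroni-corrected)\n\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
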