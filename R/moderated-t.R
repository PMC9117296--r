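# Empirical-Bayes moderated paired t-test (the comparator in the power
# study), implemented from the published formulas: gene-wise variances of
# the paired differences are assumed scaled chi-square given a gene-level
# variance drawn from a scaled inverse chi-square prior; the prior degrees
# of freedom d0 and scale s0^2 are estimated by matching moments of
# log(s^2) (digamma/trigamma identities), variances are squeezed towards
# s0^2, and the t statistic gains d0 extra degrees of freedom.

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0`; used to estimate the prior degrees
#' of freedom from the excess spread of log sample variances.
#'
#' @param x Positive numeric vector.
#' @return Numeric vector `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  if (any(x <= 0)) stop_input("'x' must be positive")
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  y
}

# Moment-matching fit of the log-variance hierarchy: returns the prior df
# and prior variance. s2 ~ s_g^2 chi^2_d / d with 1/s_g^2 ~ chi^2_{d0}
# scaled so E = 1/s0^2.
fit_variance_prior <- function(s2, df) {
  G <- length(s2)
  z <- log(pmax(s2, .Machine$double.xmin))
  e <- z - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  excess <- mean((e - e_bar)^2 * G / (G - 1)) - trigamma(df / 2)
  if (excess > 0) {
    df_prior <- 2 * trigamma_inverse(excess)
    s2_prior <- exp(e_bar + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(e_bar)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Moderated paired t-test
#'
#' Per-gene paired differences `y2 - y1` are tested against zero mean with
#' an empirical-Bayes moderated variance: each gene's sample variance is
#' shrunk towards a common prior variance estimated from the whole ensemble,
#' and the t statistic is referred to a t distribution with
#' `(n - 1) + df_prior` degrees of freedom. With `prior_df = 0` this is the
#' ordinary paired t-test.
#'
#' @param y1,y2 Numeric matrices, genes x pairs, of (log-scale) expression;
#'   equal dimensions, at least 2 genes and 2 pairs.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (0 disables shrinkage; `Inf` fully pools variances).
#' @return Numeric vector of two-sided p-values, one per gene, with
#'   attributes `t` (moderated t statistics), `df_total`, `df_prior` and
#'   `s2_prior`.
#' @export
moderated_t_paired <- function(y1, y2, prior_df = NULL) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  if (!all(dim(y1) == dim(y2))) stop_input("'y1' and 'y2' must have equal dimensions")
  if (nrow(y1) < 2L) stop_input("shrinkage needs at least 2 genes")
  n <- ncol(y1)
  if (n < 2L) stop_input("need at least 2 pairs")
  d <- y2 - y1
  dbar <- rowMeans(d)
  s2 <- rowSums((d - dbar)^2) / (n - 1)
  df <- n - 1
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df)
  } else {
    if (prior_df < 0) stop_input("'prior_df' must be >= 0")
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0) fit_variance_prior(s2, df)$s2_prior else NA_real_)
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) rep(prior$s2_prior, length(s2))
             else if (d0 == 0) s2
             else (d0 * prior$s2_prior + df * s2) / (d0 + df)
  tstat <- dbar / sqrt(s2_post / n)
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  attributes(p) <- NULL
  structure(p, t = tstat, df_total = df_total,
            df_prior = d0, s2_prior = prior$s2_prior)
}
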