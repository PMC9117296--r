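# Exact null distributions for the discordance statistic.
#
# Constrained null: the per-condition sign counts K_H = (K_H+, K_H-, K_H0)
# and K_D = (K_D+, K_D-, K_D0) are fixed and the pairing between healthy and
# diseased tissues is uniformly random; the confusion matrix then follows a
# product of multivariate hypergeometric laws.
#
# Relaxed null (the Hy-test proper): only the pooled counts (K+, K-, K0)
# over the 2n samples are fixed; n samples are chosen uniformly at random to
# be "diseased" (a multivariate hypergeometric split) and paired uniformly
# with the rest. This two-stage draw is distributionally identical to a
# single uniform random perfect matching of the 2n pooled signs, which gives
# a closed-form pmf used as the fast default evaluation path; the explicit
# split-mixture form is retained as `method = "split"` and the two are
# checked against each other (and against brute-force enumeration) in the
# test suite.

validate_triple <- function(k, what) {
  if (length(k) != 3L || anyNA(k) || any(k < 0) || any(k != round(k)))
    stop_input(what, " must be three non-negative integers (+, -, 0)")
  as.integer(k)
}

#' Probability of a healthy/diseased sign split under the relaxed null
#'
#' With pooled sign counts (K+, K-, K0) over the 2n samples and n samples
#' chosen uniformly at random to be diseased, the diseased sign counts K_D
#' follow a multivariate hypergeometric law:
#' `C(K+, K_D+) C(K-, K_D-) C(K0, K_D0) / C(2n, n)`.
#'
#' @param kd,kh Integer triples (+, -, 0) of diseased and healthy sign
#'   counts; each must sum to n and their sum defines the pooled counts.
#' @param pooled Optional pooled counts (K+, K-, K0); defaults to `kd + kh`
#'   and is validated against it.
#' @return Probability in \[0, 1\].
#' @export
split_probability <- function(kd, kh, pooled = kd + kh) {
  kd <- validate_triple(kd, "kd"); kh <- validate_triple(kh, "kh")
  pooled <- validate_triple(pooled, "pooled")
  if (sum(kd) != sum(kh))
    stop_input("kd and kh must each sum to n")
  if (!all(kd + kh == pooled))
    stop_input("split inconsistent with pooled counts: kd + kh != pooled")
  n <- sum(kd)
  exp(lchoose(pooled[1L], kd[1L]) + lchoose(pooled[2L], kd[2L]) +
        lchoose(pooled[3L], kd[3L]) - lchoose(2L * n, n))
}

#' Probability of a confusion matrix under the constrained null
#'
#' Given the per-condition sign counts, the four free entries
#' (n_++, n_+-, n_-+, n_--) determine the full 3x3 confusion matrix through
#' the marginal constraint system; this returns the product of the two
#' multivariate hypergeometric factors describing a uniformly random pairing
#' (first the row of healthy "+" tissues, then the row of healthy "-"
#' tissues drawn from the remaining diseased signs). Infeasible
#' configurations (any implied entry negative) have probability 0.
#'
#' @param n_pp,n_pm,n_mp,n_mm Free confusion-matrix entries
#'   n_\{+,+\}, n_\{+,-\}, n_\{-,+\}, n_\{-,-\}.
#' @param kh,kd Integer triples (+, -, 0) of healthy and diseased sign
#'   counts, each summing to n.
#' @return Probability in \[0, 1\].
#' @export
confusion_probability <- function(n_pp, n_pm, n_mp, n_mm, kh, kd) {
  kh <- validate_triple(kh, "kh"); kd <- validate_triple(kd, "kd")
  n <- sum(kh)
  if (sum(kd) != n) stop_input("kh and kd must sum to the same n")
  free <- c(n_pp, n_pm, n_mp, n_mm)
  if (anyNA(free) || any(free != round(free))) stop_input("entries must be integers")
  if (any(free < 0)) return(0)
  # dependent entries from the marginal system
  n_p0 <- kh[1L] - n_pp - n_pm
  n_m0 <- kh[2L] - n_mp - n_mm
  n_0p <- kd[1L] - n_pp - n_mp
  n_0m <- kd[2L] - n_pm - n_mm
  n_00 <- kh[3L] - n_0p - n_0m
  if (any(c(n_p0, n_m0, n_0p, n_0m, n_00) < 0)) return(0)
  lp <- lchoose(kd[1L], n_pp) + lchoose(kd[2L], n_pm) + lchoose(kd[3L], n_p0) -
    lchoose(n, kh[1L]) +
    lchoose(kd[1L] - n_pp, n_mp) + lchoose(kd[2L] - n_pm, n_mm) +
    lchoose(kd[3L] - n_p0, n_m0) - lchoose(n - kh[1L], kh[2L])
  exp(lp)
}

#' Exact distribution of the discordance statistic for a fixed split
#'
#' Probability mass function of `x = n_{+,-} + n_{-,+}` over 0..n under a
#' uniformly random pairing of healthy and diseased tissues with fixed sign
#' counts. Computed by summing the confusion-matrix law over its free
#' entries: the joint law of (n_+-, n_-+) is accumulated as a matrix product
#' of the first-row multivariate hypergeometric factor and the second-row
#' factor marginalized over n_-- (a univariate hypergeometric), then folded
#' along anti-diagonals.
#'
#' @inheritParams confusion_probability
#' @return Numeric vector of length n + 1; `[x + 1]` is P(H = x).
#' @export
conditional_distribution <- function(kh, kd) {
  kh <- validate_triple(kh, "kh"); kd <- validate_triple(kd, "kd")
  n <- sum(kh)
  if (sum(kd) != n) stop_input("kh and kd must sum to the same n")
  a_max <- min(kh[1L], kd[2L])          # a = n_{+,-}
  npp_max <- min(kh[1L], kd[1L])
  b_max <- min(kh[2L], kd[1L])          # b = n_{-,+}
  A <- matrix(0, a_max + 1L, npp_max + 1L)
  for (npp in 0:npp_max) {
    a <- 0:a_max
    np0 <- kh[1L] - npp - a
    ok <- np0 >= 0L & np0 <= kd[3L]
    if (any(ok))
      A[ok, npp + 1L] <- exp(lchoose(kd[1L], npp) + lchoose(kd[2L], a[ok]) +
                               lchoose(kd[3L], np0[ok]) - lchoose(n, kh[1L]))
  }
  B <- matrix(0, b_max + 1L, npp_max + 1L)
  pool <- n - kh[1L]
  for (npp in 0:npp_max) {
    w <- kd[1L] - npp                   # diseased "+" left for the "-" row
    if (w < 0L || w > pool) next
    B[, npp + 1L] <- stats::dhyper(0:b_max, w, pool - w, kh[2L])
  }
  joint <- A %*% t(B)                   # (a, b) joint law
  pmf <- numeric(n + 1L)
  for (a in 0:a_max)
    for (b in 0:b_max)
      pmf[a + b + 1L] <- pmf[a + b + 1L] + joint[a + 1L, b + 1L]
  pmf
}

#' Conditional p-value of an observed discordance for a fixed split
#'
#' Upper tail `P(H >= x_hat)` of [conditional_distribution()]; equals 1 for
#' `x_hat = 0` and 0 beyond the support.
#'
#' @param x_hat Observed discordance, integer >= 0.
#' @inheritParams confusion_probability
#' @return Probability in \[0, 1\].
#' @export
conditional_pvalue <- function(x_hat, kh, kd) {
  if (!is_count(x_hat)) stop_input("'x_hat' must be a non-negative integer")
  if (x_hat == 0) return(1)
  pmf <- conditional_distribution(kh, kd)
  if (x_hat + 1 > length(pmf)) return(0)
  min(1, rev(cumsum(rev(pmf)))[x_hat + 1L])
}

# pmf of the discordance count under a uniform random perfect matching of
# K+ pluses, K- minuses and K0 zeros (the closed form of the relaxed null):
# sum matching counts over pair-type multiplicities (m_++, m_--) with
# m_+- = x fixed and the remaining types implied.
pairing_null_pmf <- function(k_plus, k_minus, k_zero) {
  N <- k_plus + k_minus + k_zero
  n <- N %/% 2L
  log_total <- lgamma(N + 1) - n * log(2) - lgamma(n + 1)
  const <- lgamma(k_plus + 1) + lgamma(k_minus + 1) + lgamma(k_zero + 1)
  pmf <- numeric(n + 1L)
  for (x in 0:min(k_plus, k_minus)) {
    mpp <- 0:((k_plus - x) %/% 2L)
    mmm <- 0:((k_minus - x) %/% 2L)
    mp0 <- k_plus - 2L * mpp - x
    mm0 <- k_minus - 2L * mmm - x
    rem <- k_zero - outer(mp0, mm0, "+")
    ok <- rem >= 0L & rem %% 2L == 0L
    if (!any(ok)) next
    m00 <- rem / 2
    lw <- const - lgamma(x + 1) -
      outer(mpp * log(2) + lgamma(mpp + 1) + lgamma(mp0 + 1),
            mmm * log(2) + lgamma(mmm + 1) + lgamma(mm0 + 1), "+") -
      (m00 * log(2) + lgamma(m00 + 1))
    pmf[x + 1L] <- exp(logsumexp(lw[ok]) - log_total)
  }
  pmf
}

# Relaxed-null pmf as the explicit mixture over all feasible splits
# (the literal two-stage structure).
split_null_pmf <- function(k_plus, k_minus, k_zero) {
  n <- (k_plus + k_minus + k_zero) %/% 2L
  pooled <- c(k_plus, k_minus, k_zero)
  pmf <- numeric(n + 1L)
  l2n <- lchoose(2L * n, n)
  for (kdp in 0:min(k_plus, n)) {
    for (kdm in 0:min(k_minus, n - kdp)) {
      kd0 <- n - kdp - kdm
      if (kd0 > k_zero) next
      kd <- c(kdp, kdm, kd0)
      kh <- pooled - kd
      if (any(kh < 0L)) next
      w <- exp(lchoose(k_plus, kdp) + lchoose(k_minus, kdm) +
                 lchoose(k_zero, kd0) - l2n)
      pmf <- pmf + w * conditional_distribution(kh, kd)
    }
  }
  pmf
}

#' Exact null pmf of the discordance statistic under the relaxed null
#'
#' Distribution of `H` when only the pooled sign counts (K+, K-, K0) over
#' the 2n samples are fixed, n samples are uniformly chosen to be diseased,
#' and the pairing is uniformly random. `method = "pairing"` (default)
#' evaluates the equivalent closed form under a uniform random perfect
#' matching of the pooled signs; `method = "split"` evaluates the explicit
#' mixture of conditional pairing distributions over all multivariate
#' hypergeometric splits. The two agree to floating-point accuracy; the
#' pairing form is much faster at large n. Results are memoized per
#' configuration.
#'
#' @param k_plus,k_minus,k_zero Pooled sign counts; their sum 2n must be
#'   even.
#' @param method `"pairing"` or `"split"`.
#' @return Numeric vector of length n + 1 summing to 1.
#' @export
hy_null_pmf <- function(k_plus, k_minus, k_zero,
                        method = c("pairing", "split")) {
  method <- match.arg(method)
  if (!is_count(k_plus) || !is_count(k_minus) || !is_count(k_zero))
    stop_input("pooled counts must be non-negative integers")
  N <- k_plus + k_minus + k_zero
  if (N < 2L || N %% 2L != 0L)
    stop_input("pooled counts must sum to 2n for some n >= 1")
  key <- sprintf("%d_%d_%d_%s", k_plus, k_minus, k_zero, method)
  if (!is.null(.hy_cache[[key]])) return(.hy_cache[[key]])
  pmf <- switch(method,
                pairing = pairing_null_pmf(k_plus, k_minus, k_zero),
                split = split_null_pmf(k_plus, k_minus, k_zero))
  .hy_cache[[key]] <- pmf
  pmf
}

#' Hy-test p-value
#'
#' Exact upper-tail probability `P(H >= x_hat)` under the relaxed null with
#' pooled sign counts (K+, K-, K0). This is the Hy-test p-value for an
#' observed discordance `x_hat`; it depends on the data only through the
#' pooled counts and `x_hat`.
#'
#' @inheritParams hy_null_pmf
#' @param x_hat Observed discordance statistic, integer in 0..n.
#' @return Probability in \[0, 1\]; exactly 1 when `x_hat = 0`.
#' @examples
#' hy_pvalue(2, k_plus = 2, k_minus = 2, k_zero = 0)  # 2/3
#' @export
hy_pvalue <- function(x_hat, k_plus, k_minus, k_zero,
                      method = c("pairing", "split")) {
  if (!is_count(x_hat)) stop_input("'x_hat' must be a non-negative integer")
  if (x_hat == 0) return(1)
  pmf <- hy_null_pmf(k_plus, k_minus, k_zero, method = method)
  if (x_hat + 1 > length(pmf)) return(0)
  min(1, rev(cumsum(rev(pmf)))[x_hat + 1L])
}

#' Brute-force enumeration oracle for the relaxed null
#'
#' Enumerates every way to choose n of the 2n pooled signs as diseased and
#' every pairing (permutation) against the remaining n, all equally likely,
#' and tabulates the discordance count. Exponential cost; refuses 2n > 14.
#' Exists as an independent check of [hy_null_pmf()].
#'
#' @inheritParams hy_null_pmf
#' @return Numeric vector of length n + 1: the exact pmf of H.
#' @export
enumerate_null_oracle <- function(k_plus, k_minus, k_zero) {
  if (!is_count(k_plus) || !is_count(k_minus) || !is_count(k_zero))
    stop_input("pooled counts must be non-negative integers")
  N <- k_plus + k_minus + k_zero
  if (N %% 2L != 0L || N < 2L) stop_input("pooled counts must sum to 2n")
  if (N > 14L) stop_input("enumeration oracle limited to 2n <= 14")
  n <- N %/% 2L
  signs <- rep(c(1L, -1L, 0L), c(k_plus, k_minus, k_zero))
  subsets <- utils::combn(N, n)
  pm <- all_permutations(n)
  counts <- numeric(n + 1L)
  for (j in seq_len(ncol(subsets))) {
    S <- subsets[, j]
    h <- signs[-S]
    d <- signs[S]
    D <- matrix(d[pm], nrow(pm), n)
    H <- matrix(h, nrow(pm), n, byrow = TRUE)
    x <- rowSums((H == 1L & D == -1L) | (H == -1L & D == 1L))
    counts <- counts + tabulate(x + 1L, n + 1L)
  }
  counts / sum(counts)
}

# All permutations of 1..n as an n!-row matrix (n small).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p + (p >= i)
    out[[i]] <- cbind(rep(i, nrow(p)), q)
  }
  do.call(rbind, out)
}

#' Bonferroni multiple-testing correction
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  check_prob_vector(p_values)
  if (!is_count(m) || m < length(p_values))
    stop_input("'m' must be an integer >= length(p_values)")
  pmin(p_values * m, 1)
}
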