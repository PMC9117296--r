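# Independent brute-force oracles used across the suite. Kept deliberately
# dumb and separate from the package's evaluation paths.

# all permutations of 1..n as a matrix (n small)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

# exact pmf of the discordance count for a FIXED split, by enumerating all
# n! pairings of the healthy signs against the diseased signs
enumerate_pairing_pmf <- function(kh, kd) {
  n <- sum(kh)
  h <- rep(c(1L, -1L, 0L), kh)
  d <- rep(c(1L, -1L, 0L), kd)
  pm <- perm_matrix(n)
  D <- matrix(d[pm], nrow(pm), n)
  H <- matrix(h, nrow(pm), n, byrow = TRUE)
  x <- rowSums((H == 1L & D == -1L) | (H == -1L & D == 1L))
  tabulate(x + 1L, n + 1L) / nrow(pm)
}

# maximum attainable discordance by direct scan over all candidate pairs
brute_force_hmax <- function(h, d) {
  cands <- threshold_candidates(c(h, d))
  best <- -1L
  for (a in seq_along(cands))
    for (b in a:length(cands))
      best <- max(best, sum(h > cands[b] & d < cands[a]) +
                        sum(h < cands[a] & d > cands[b]))
  best
}

# all (K+, K-, K0) compositions of 2n
pooled_configs <- function(two_n) {
  out <- list()
  for (kp in 0:two_n)
    for (km in 0:(two_n - kp))
      out[[length(out) + 1L]] <- c(kp, km, two_n - kp - km)
  out
}

# all sign-count triples summing to n
split_triples <- function(n) pooled_configs(n)
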