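#' Discretize expression values into signs with a two-threshold cut
#'
#' Maps each value to -1 ("downregulated") below `k1`, +1 ("upregulated")
#' above `k2`, and 0 ("no-changed") otherwise. Values exactly equal to a
#' threshold map to 0; with the default midpoint candidate thresholds (see
#' [optimize_thresholds()]) ties against a threshold never occur, so the
#' boundary convention only matters for user-supplied thresholds.
#'
#' @param values Numeric vector of (log2) expression values; must be finite.
#' @param k1,k2 Thresholds with `k1 <= k2`.
#' @return Integer vector of the same length with entries in \{-1, 0, 1\}.
#' @examples
#' discretize(c(1, 5, 10), k1 = 3, k2 = 8)
#' @export
discretize <- function(values, k1, k2) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop_input("'values' must be finite numeric")
  if (length(k1) != 1L || length(k2) != 1L || is.na(k1) || is.na(k2) || k1 > k2)
    stop_input("thresholds must satisfy k1 <= k2")
  out <- integer(length(values))
  out[values < k1] <- -1L
  out[values > k2] <- 1L
  out
}

#' Sign co-occurrence (confusion) matrix of two paired sign vectors
#'
#' Entry (i, j) counts the tissue pairs whose healthy member has sign i and
#' whose diseased member has sign j, in the index order (+, -, 0). Row sums
#' are the healthy sign counts K_H and column sums the diseased sign counts
#' K_D, by construction.
#'
#' @param v_h,v_d Integer vectors of equal length with entries in \{-1,0,1\}
#'   (healthy and diseased signs, pairing by position).
#' @return A 3x3 integer matrix with dimnames `c("+", "-", "0")`.
#' @examples
#' confusion_matrix(c(1, 1, -1), c(-1, 0, 1))
#' @export
confusion_matrix <- function(v_h, v_d) {
  if (length(v_h) != length(v_d))
    stop_input("sign vectors must have equal length")
  if (!all(v_h %in% c(-1L, 0L, 1L)) || !all(v_d %in% c(-1L, 0L, 1L)))
    stop_input("sign vectors must take values in {-1, 0, 1}")
  lv <- c(1L, -1L, 0L)
  lab <- c("+", "-", "0")
  counts <- table(factor(v_h, levels = lv), factor(v_d, levels = lv))
  m <- matrix(as.integer(counts), 3L, 3L,
              dimnames = list(healthy = lab, diseased = lab))
  m
}

#' Discordance statistic H of a confusion matrix
#'
#' `H = n_{+,-} + n_{-,+}`: the number of pairs with opposite non-zero signs
#' in the two conditions.
#'
#' @param cm A 3x3 confusion matrix as returned by [confusion_matrix()].
#' @return Non-negative integer, at most the number of pairs.
#' @export
discordance <- function(cm) {
  if (!is.matrix(cm) || !all(dim(cm) == 3L))
    stop_input("'cm' must be a 3x3 confusion matrix")
  as.integer(cm[1L, 2L] + cm[2L, 1L])
}

#' Candidate thresholds for the two-threshold cut
#'
#' The discordance statistic is piecewise constant in (k1, k2), changing only
#' when a threshold crosses a data value; midpoints between consecutive
#' sorted unique pooled values, plus -Inf/+Inf sentinels, therefore cover
#' every attainable discretization.
#'
#' @param values Numeric vector (typically the pooled 2n expression values).
#' @return Sorted numeric vector of candidate thresholds.
#' @export
threshold_candidates <- function(values) {
  sv <- sort(unique(as.numeric(values)))
  if (length(sv) < 2L) return(c(-Inf, Inf))
  c(-Inf, (sv[-1L] + sv[-length(sv)]) / 2, Inf)
}

# Full H surface over the candidate grid, O(m^2 + n) via 2-d cumulated
# counts. Returns list(H = m x m matrix over (a = k1 index, b = k2 index),
# candidates). Only a <= b is meaningful.
h_surface <- function(expr_h, expr_d, candidates) {
  m <- length(candidates)
  # pos = number of candidates strictly below the value (candidates never
  # coincide with data values): value > candidates[b] iff b <= pos,
  # value < candidates[a] iff pos <= a - 1.
  pos_h <- findInterval(expr_h, candidates)
  pos_d <- findInterval(expr_d, candidates)
  # F1[p, q] = #{i : pos_d[i] <= p - 1, pos_h[i] >= q}  (p, q in 1..m)
  count_grid <- function(prow, pcol) {
    g <- matrix(0L, m, m)
    idx <- cbind(prow + 1L, pcol)      # rows shifted so row p holds pos <= p-1
    keep <- idx[, 1L] <= m & idx[, 2L] >= 1L
    idx <- idx[keep, , drop = FALSE]
    for (r in seq_len(nrow(idx))) g[idx[r, 1L], idx[r, 2L]] <- g[idx[r, 1L], idx[r, 2L]] + 1L
    g <- apply(g, 2L, cumsum)                       # pos_row <= p - 1
    t(apply(g, 1L, function(z) rev(cumsum(rev(z))))) # pos_col >= q
  }
  n_pm <- count_grid(pos_d, pos_h)  # healthy up (> k2), diseased down (< k1)
  n_mp <- count_grid(pos_h, pos_d)  # healthy down, diseased up
  list(H = n_pm + n_mp, candidates = candidates)
}

# Deterministic tie-break among candidate index pairs attaining the maximum:
# widest no-change band, then smallest k1, then largest k2.
pick_threshold_pair <- function(a, b, candidates) {
  width <- ifelse(a == b, 0, candidates[b] - candidates[a])
  keep <- which(width == max(width))
  a <- a[keep]; b <- b[keep]
  keep <- which(candidates[a] == min(candidates[a]))
  a <- a[keep]; b <- b[keep]
  j <- which.max(candidates[b])
  c(a[j], b[j])
}

#' Optimal discretization thresholds for a paired profile
#'
#' Finds the threshold pair (k1, k2), k1 <= k2, maximizing the discordance
#' statistic H between the discretized healthy and diseased vectors. The
#' candidate set consists of midpoints between consecutive sorted unique
#' pooled values plus -Inf/+Inf sentinels, which covers all attainable sign
#' patterns. `method = "exhaustive"` (default) scans all candidate pairs and
#' is deterministic; `method = "genetic"` runs a small genetic algorithm over
#' the same candidate set, useful only when the number of candidates is very
#' large. Ties are broken towards the widest no-change band, then the
#' smallest k1 (a conservative choice: fewest forced sign calls).
#'
#' @param expr_h,expr_d Numeric vectors of paired (log2) expression values.
#' @param method `"exhaustive"` or `"genetic"`.
#' @param seed Integer seed for `method = "genetic"`.
#' @param pop_size,generations Genetic-algorithm controls.
#' @return List with elements `k1`, `k2`, `h_max`, `method`.
#' @examples
#' optimize_thresholds(c(1, 2, 6, 7), c(5, 8, 3, 4))
#' @export
optimize_thresholds <- function(expr_h, expr_d,
                                method = c("exhaustive", "genetic"),
                                seed = NULL, pop_size = 40L,
                                generations = 80L) {
  method <- match.arg(method)
  if (length(expr_h) != length(expr_d))
    stop_input("paired vectors must have equal length")
  if (length(expr_h) < 2L) stop_input("need at least 2 pairs")
  if (anyNA(expr_h) || anyNA(expr_d) ||
      any(!is.finite(expr_h)) || any(!is.finite(expr_d)))
    stop_input("expression values must be finite")
  cands <- threshold_candidates(c(expr_h, expr_d))
  if (method == "exhaustive") {
    surf <- h_surface(expr_h, expr_d, cands)
    H <- surf$H
    H[lower.tri(H)] <- -1L   # enforce a <= b
    h_max <- max(H)
    hit <- which(H == h_max, arr.ind = TRUE)
    ab <- pick_threshold_pair(hit[, 1L], hit[, 2L], cands)
  } else {
    ab <- ga_search(expr_h, expr_d, cands, seed = seed,
                    pop_size = pop_size, generations = generations)
    h_max <- h_eval(expr_h, expr_d, cands[ab[1L]], cands[ab[2L]])
  }
  list(k1 = cands[ab[1L]], k2 = cands[ab[2L]],
       h_max = as.integer(h_max), method = method)
}

# Direct O(n) evaluation of H for one threshold pair.
h_eval <- function(expr_h, expr_d, k1, k2) {
  sum(expr_h > k2 & expr_d < k1) + sum(expr_h < k1 & expr_d > k2)
}

# Small steady-state genetic algorithm over candidate index pairs. Kept
# simple: tournament selection, coordinate crossover, geometric-step index
# mutation, elitism. Deterministic given `seed`.
ga_search <- function(expr_h, expr_d, cands, seed = NULL,
                      pop_size = 40L, generations = 80L) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  m <- length(cands)
  fitness <- function(a, b) h_eval(expr_h, expr_d, cands[a], cands[b])
  clamp <- function(i) pmin(pmax(i, 1L), m)
  pa <- sample.int(m, pop_size, replace = TRUE)
  pb <- clamp(pa + sample.int(m, pop_size, replace = TRUE) %/% 2L)
  swap <- pa > pb; tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  fit <- mapply(fitness, pa, pb)
  best <- list(a = pa[which.max(fit)], b = pb[which.max(fit)], f = max(fit))
  for (g in seq_len(generations)) {
    i1 <- sample.int(pop_size, pop_size, replace = TRUE)
    i2 <- sample.int(pop_size, pop_size, replace = TRUE)
    parents <- ifelse(fit[i1] >= fit[i2], i1, i2)
    cross <- sample.int(pop_size, pop_size, replace = TRUE)
    ca <- ifelse(stats::runif(pop_size) < 0.5, pa[parents], pa[cross])
    cb <- ifelse(stats::runif(pop_size) < 0.5, pb[parents], pb[cross])
    step <- stats::rgeom(pop_size, prob = 0.4) + 1L
    mut <- stats::runif(pop_size) < 0.3
    ca[mut] <- clamp(ca[mut] + sample(c(-1L, 1L), sum(mut), TRUE) * step[mut])
    mut <- stats::runif(pop_size) < 0.3
    cb[mut] <- clamp(cb[mut] + sample(c(-1L, 1L), sum(mut), TRUE) * step[mut])
    swap <- ca > cb; tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
    cfit <- mapply(fitness, ca, cb)
    # elitism: keep the best-so-far individual alive
    worst <- which.min(cfit)
    ca[worst] <- best$a; cb[worst] <- best$b; cfit[worst] <- best$f
    pa <- ca; pb <- cb; fit <- cfit
    if (max(fit) > best$f) {
      j <- which.max(fit)
      best <- list(a = pa[j], b = pb[j], f = fit[j])
    }
  }
  # apply the deterministic tie-break among final-population maximizers
  top <- which(fit == best$f)
  ab <- pick_threshold_pair(c(pa[top], best$a), c(pb[top], best$b), cands)
  ab
}
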