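# Hypergeometric association tests: literature co-occurrence of two
# keywords (disease x GO term) across PubMed article counts, and gene-set
# over-representation of a query list against a universe. Both use the same
# upper-tail hypergeometric kernel, evaluated on the log scale so that
# p-values below the double-precision floor (~1.11e-16) are still reported
# exactly in log10 units and flagged as underflowed.

# log upper tail P(X >= q) with X ~ Hypergeometric(white, black, draws)
hyper_log_tail <- function(q, white, black, draws) {
  stats::phyper(q - 1, white, black, draws, lower.tail = FALSE, log.p = TRUE)
}

validate_counts <- function(n_total, n_c, n_t, n_ct) {
  for (v in c(n_total, n_c, n_t, n_ct))
    if (!is_count(v)) stop_input("counts must be non-negative integers")
  if (n_c > n_total || n_t > n_total || n_ct > min(n_c, n_t))
    stop_input("inconsistent counts: need n_ct <= min(n_c, n_t) <= n_total")
}

#' Hypergeometric pmf of a keyword co-occurrence count
#'
#' Probability of observing exactly `x` articles carrying both keywords,
#' given `n_total` articles of which `n_c` carry the disease keyword and
#' `n_t` the term keyword, under random independent tagging:
#' `C(n_c, x) C(n_total - n_c, n_t - x) / C(n_total, n_t)`.
#'
#' @param x Co-occurrence count(s).
#' @param n_total,n_c,n_t Article counts (all, with disease keyword, with
#'   term keyword).
#' @return Probability vector.
#' @export
literature_association_pmf <- function(x, n_total, n_c, n_t) {
  validate_counts(n_total, n_c, n_t, 0L)
  stats::dhyper(x, n_c, n_total - n_c, n_t)
}

#' Literature association p-value
#'
#' Upper-tail hypergeometric probability of at least `n_ct` articles
#' carrying both keywords. The value is computed on the log scale; the
#' returned number carries attributes `log10_p` and `underflow` (whether p
#' fell below the double-precision floor 1.11e-16, the level at which
#' printed p-values degenerate to "< 1.11E-16").
#'
#' @inheritParams literature_association_pmf
#' @param n_ct Observed co-occurrence count.
#' @return P-value in \[0, 1\] with attributes `log10_p`, `underflow`.
#' @examples
#' literature_association_pvalue(10, 4, 5, 3)   # 66/252
#' @export
literature_association_pvalue <- function(n_total, n_c, n_t, n_ct) {
  validate_counts(n_total, n_c, n_t, n_ct)
  lp <- hyper_log_tail(n_ct, n_c, n_total - n_c, n_t)
  p <- exp(lp)
  structure(p, log10_p = lp / log(10), underflow = p < 1.11e-16)
}

#' Batch literature association tests from a counts table
#'
#' @param counts Data frame (or TSV path) with columns `term`, `n_total`,
#'   `n_c`, `n_t`, `n_ct`.
#' @param alpha Significance level after Bonferroni correction.
#' @return Data frame with `p_value`, `log10_p`, `underflow`, `p_adjusted`,
#'   `significant` per term.
#' @export
literature_association_table <- function(counts, alpha = 0.05) {
  if (is.character(counts))
    counts <- utils::read.table(counts, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  need <- c("term", "n_total", "n_c", "n_t", "n_ct")
  if (!all(need %in% names(counts)))
    stop_input("counts table needs columns: ", paste(need, collapse = ", "))
  res <- lapply(seq_len(nrow(counts)), function(i)
    literature_association_pvalue(counts$n_total[i], counts$n_c[i],
                                  counts$n_t[i], counts$n_ct[i]))
  p <- vapply(res, as.numeric, numeric(1))
  out <- data.frame(term = counts$term, n_total = counts$n_total,
                    n_c = counts$n_c, n_t = counts$n_t, n_ct = counts$n_ct,
                    p_value = p,
                    log10_p = vapply(res, attr, numeric(1), "log10_p"),
                    underflow = vapply(res, attr, logical(1), "underflow"),
                    stringsAsFactors = FALSE)
  out$p_adjusted <- bonferroni_adjust(out$p_value)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Read gene sets in GMT format
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param file Path to a `.gmt` file.
#' @return Named list of character vectors of gene IDs.
#' @export
read_gmt <- function(file) fgsea::gmtPathways(file)

#' Hypergeometric gene-set over-representation test
#'
#' For each set, the overlap with the query list is referred to the upper
#' tail of a hypergeometric distribution with the universe as population,
#' the set as successes and the query as draws -- the same kernel as
#' [literature_association_pvalue()] under the mapping universe <-> all
#' articles, set <-> disease-keyword articles, query <-> term-keyword
#' articles, overlap <-> co-occurrence. Sets are intersected with the
#' universe first; p-values are Bonferroni-corrected across sets.
#'
#' @param query Character vector of gene IDs (must lie in the universe).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all assayed gene IDs.
#' @param alpha Significance level after correction.
#' @return Data frame: `set`, `set_size`, `overlap`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
gene_set_enrichment <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_input("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop_input("query genes outside the universe: ",
               paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  if (!length(sets)) stop_input("no gene sets supplied")
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  U <- length(universe); q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- length(intersect(s, query))
    p <- exp(hyper_log_tail(ov, length(s), U - length(s), q))
    data.frame(set = nm, set_size = length(s), overlap = ov,
               p_value = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value)
  out$significant <- out$p_adjusted < alpha
  out
}
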