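# Internal numerical helpers.

# log(sum(exp(x))) with the usual max shift; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_input <- function(...) stop(..., call. = FALSE)

check_prob_vector <- function(p, what = "p_values") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_input(what, " must be numeric in [0, 1]")
  invisible(p)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
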