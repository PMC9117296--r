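# Plain-text I/O: expression matrices as TSV/CSV with a gene-ID first
# column and sample-ID header; pairing tables as two-column TSV.

guess_sep <- function(file) if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs
#' (duplicates allowed; see [collapse_duplicates()]).
#'
#' @param file Path; `.csv` is comma-separated, anything else tab-separated.
#' @param sep Field separator override.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(file, sep = guess_sep(file)) {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("expression file needs a gene column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric expression values in ", file)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read a pairing table
#'
#' Two-column tab-separated file mapping each healthy sample to its diseased
#' partner. A header line naming the columns `healthy` and `diseased` is
#' recognized; otherwise the first two columns are used in that order.
#'
#' @param file Path to the pairing TSV.
#' @param sep Field separator override.
#' @return Data frame with character columns `healthy` and `diseased`.
#' @export
read_pairing <- function(file, sep = guess_sep(file)) {
  first <- strsplit(readLines(file, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- all(c("healthy", "diseased") %in% tolower(first))
  df <- utils::read.table(file, header = has_header, sep = sep,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("healthy", "diseased")
  names(df) <- tolower(names(df))
  data.frame(healthy = as.character(df$healthy),
             diseased = as.character(df$diseased),
             stringsAsFactors = FALSE)
}

#' Write Hy-test DEA results to a TSV file
#'
#' @param x An `"hy_dea"` object from [hy_test()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hy_results <- function(x, file) {
  if (!inherits(x, "hy_dea")) stop_input("'x' must be an 'hy_dea' object")
  utils::write.table(x$results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
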