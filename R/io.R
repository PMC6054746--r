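#' Read a gene-set file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("gene-set file '", path, "' contains no genes")
  unique(x)
}

#' Read a per-gene control count table
#'
#' @param path TSV with header columns `gene`, `x_control` (and optionally
#'   `x_control_syn`).
#' @return A `data.frame`.
#' @export
read_control_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "x_control") %in% names(df)))
  if (any(df$x_control < 0)) stop("control counts must be non-negative")
  df
}

#' Read an expression table
#'
#' @param path TSV with header columns `gene`, `value`.
#' @return A `data.frame`.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "value") %in% names(df)))
  df
}

# deterministic TSV writer used for all pipeline outputs
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
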