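#' Expression matrix with measure and scale tags
#'
#' A `quant_matrix` is a genes x samples numeric matrix carrying two tags:
#' the quantification `measure` (`"count"`, `"tpm"`, `"fpkm"`, `"normcount"`
#' or `"zscore"`) and the `scale` it lives on (`"linear"` or `"log2p1"`).
#' Row names are gene identifiers, column names sample identifiers; every
#' downstream operation keys on these names, so they are mandatory.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   row and column names.
#' @param measure One of `"count"`, `"tpm"`, `"fpkm"`, `"normcount"`,
#'   `"zscore"`.
#' @param scale One of `"linear"`, `"log2p1"`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values,
                         measure = c("count", "tpm", "fpkm", "normcount", "zscore"),
                         scale = c("linear", "log2p1")) {
  measure <- match.arg(measure)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicated sample identifiers")
  if (scale == "linear" && measure != "zscore" && any(values < 0, na.rm = TRUE)) {
    stop("negative entries are not allowed for linear-scale measure '", measure, "'")
  }
  structure(list(values = values, measure = measure, scale = scale),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d genes x %d samples [measure=%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$measure, x$scale))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of a quant_matrix
#' @param x A [quant_matrix].
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Log-transform an expression matrix
#'
#' Replaces every entry by `log2(x + 1)`. The pseudocount of 1 is used
#' uniformly for all measures so that zeros map to zero.
#'
#' @param x A linear-scale [quant_matrix].
#' @return A [quant_matrix] with `scale = "log2p1"` and the same measure.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$scale != "linear") {
    stop("matrix is already on the log2(x+1) scale; refusing to transform twice")
  }
  out <- x
  out$values <- log2(x$values + 1)
  out$scale <- "log2p1"
  out
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, samples in columns; the first column is `gene_id` and the
#' header row holds the sample identifiers.
#'
#' @param x A [quant_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "quant_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
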