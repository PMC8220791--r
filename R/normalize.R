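#' Median-of-ratios (virtual reference sample) size factors
#'
#' Builds a virtual reference sample as the per-gene geometric mean of
#' counts over all samples, then takes each sample's scaling factor as the
#' median, over genes with a positive reference value (i.e. genes with a
#' positive count in every sample), of the ratio count / reference. Counts
#' are rounded to the nearest integer first, mirroring the usual route by
#' which fractional RSEM expected counts enter integer-count normalization
#' frameworks; the effect on factors is negligible and tested.
#'
#' @param counts A [quant_matrix] with `measure = "count"`, >= 2 samples.
#' @param round_counts Round counts to integers first (default `TRUE`).
#' @return A `norm_factors` object: data frame with columns `sample_id`,
#'   `factor`, `library_size`, and attribute `method = "median_ratio"`.
#' @export
size_factors_median_ratio <- function(counts, round_counts = TRUE) {
  stopifnot(inherits(counts, "quant_matrix"))
  if (counts$measure != "count") stop("expected a count matrix")
  q <- counts$values
  if (ncol(q) < 2) stop("median-of-ratios requires >= 2 samples")
  if (round_counts) q <- round(q)
  pos <- rowSums(q > 0) == ncol(q)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "cannot form a virtual reference")
  }
  ref <- exp(rowMeans(log(q[pos, , drop = FALSE])))
  f <- apply(q[pos, , drop = FALSE] / ref, 2, stats::median)
  new_norm_factors(colnames(q), f, colSums(counts$values), "median_ratio")
}

new_norm_factors <- function(sample_ids, factor, library_size, method) {
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    stop("non-positive or non-finite normalization factor computed")
  }
  out <- data.frame(sample_id = sample_ids, factor = unname(factor),
                    library_size = unname(library_size),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Weighted trimmed mean of M-values (TMM) scaling factors
#'
#' For each sample \eqn{s} against a reference sample \eqn{r}, using only
#' genes positive in both, with library sizes \eqn{N}:
#' \deqn{M_g = \log_2\frac{q_{gs}/N_s}{q_{gr}/N_r}, \qquad
#'       A_g = \tfrac12 \log_2\Big(\frac{q_{gs}}{N_s}\cdot\frac{q_{gr}}{N_r}\Big).}
#' Genes in the upper and lower `logratio_trim` tails of M and the upper
#' and lower `abs_trim` tails of A are dropped (rank-based inclusion, ties
#' kept), and the factor is \eqn{2^{\sum w_g M_g / \sum w_g}} over the
#' remaining genes, with inverse asymptotic (delta-method binomial)
#' variances as weights when `weighted`:
#' \deqn{1/w_g = \frac{N_s - q_{gs}}{N_s q_{gs}} + \frac{N_r - q_{gr}}{N_r q_{gr}}.}
#' Factors are rescaled to have geometric mean 1. When `reference` is not
#' given it is chosen as the sample whose 75th-percentile count fraction is
#' closest to the mean of those quantiles across samples.
#'
#' The function accepts count matrices and also TPM matrices, in which case
#' TPM values are treated as abundances with library size \eqn{10^6}.
#'
#' @param x A [quant_matrix] (`count` or `tpm`), linear scale, >= 2 samples.
#' @param reference Sample id to use as reference, or `NULL` for automatic
#'   selection.
#' @param logratio_trim Two-sided trim fraction on M (default 0.30).
#' @param abs_trim Two-sided trim fraction on A (default 0.05).
#' @param weighted Use inverse-variance weights (default `TRUE`).
#' @return A `norm_factors` object with attribute `method = "tmm"` and
#'   attribute `reference` (the reference sample id).
#' @export
tmm_factors <- function(x, reference = NULL, logratio_trim = 0.30,
                        abs_trim = 0.05, weighted = TRUE) {
  stopifnot(inherits(x, "quant_matrix"))
  if (!x$measure %in% c("count", "tpm") || x$scale != "linear") {
    stop("TMM expects a linear-scale count or TPM matrix")
  }
  q <- x$values
  if (ncol(q) < 2) stop("TMM requires >= 2 samples")
  N <- colSums(q)
  if (any(N <= 0)) stop("sample(s) with zero library size")
  if (is.null(reference)) {
    f75 <- apply(q, 2, function(col) stats::quantile(col / sum(col), 0.75))
    reference <- colnames(q)[which.min(abs(f75 - mean(f75)))]
  } else if (!reference %in% colnames(q)) {
    stop("reference sample '", reference, "' not found")
  }
  r_idx <- match(reference, colnames(q))
  f <- vapply(seq_len(ncol(q)), function(s) {
    if (s == r_idx) return(1)
    tmm_pair_factor(q[, s], q[, r_idx], N[s], N[r_idx],
                    logratio_trim, abs_trim, weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- new_norm_factors(colnames(q), f, N, "tmm")
  attr(out, "reference") <- reference
  out
}

# One sample against the reference; q, r are count vectors, N their totals.
tmm_pair_factor <- function(q, r, Nq, Nr, logratio_trim, abs_trim, weighted) {
  keep <- q > 0 & r > 0
  if (!any(keep)) stop("no gene is positive in both sample and reference")
  q <- q[keep]; r <- r[keep]
  M <- log2((q / Nq) / (r / Nr))
  A <- 0.5 * log2((q / Nq) * (r / Nr))
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n - floor(n * logratio_trim)
  loA <- floor(n * abs_trim) + 1
  hiA <- n - floor(n * abs_trim)
  rkM <- rank(M)
  rkA <- rank(A)
  use <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
  if (!any(use)) {
    stop("TMM trimming removed every gene; reduce 'logratio_trim'/'abs_trim'")
  }
  w <- if (weighted) 1 / ((Nq - q) / (Nq * q) + (Nr - r) / (Nr * r)) else rep(1, n)
  2^(sum(w[use] * M[use]) / sum(w[use]))
}

#' Apply normalization factors to an expression matrix
#'
#' Median-of-ratios factors divide each column directly. TMM factors scale
#' each column by its effective library size \eqn{N_s \cdot factor_s},
#' rescaled to the mean library size, giving normalized counts
#' \eqn{q_{gs} / (N_s \cdot factor_s) \cdot \overline{N}}.
#'
#' @param x A linear-scale [quant_matrix].
#' @param f A `norm_factors` object covering exactly the samples of `x`.
#' @return A [quant_matrix] with `measure = "normcount"`.
#' @export
apply_factors <- function(x, f) {
  stopifnot(inherits(x, "quant_matrix"), inherits(f, "norm_factors"))
  if (x$scale != "linear") stop("factors apply to linear-scale matrices")
  if (!identical(sort(colnames(x$values)), sort(f$sample_id))) {
    stop("sample sets of matrix and factors differ")
  }
  fac <- f$factor[match(colnames(x$values), f$sample_id)]
  if (attr(f, "method") == "tmm") {
    N <- f$library_size[match(colnames(x$values), f$sample_id)]
    scl <- N * fac / mean(N)
  } else {
    scl <- fac
  }
  vals <- x$values / rep(scl, each = nrow(x$values))
  quant_matrix(vals, measure = "normcount", scale = "linear")
}

#' TMM normalization applied directly to TPM values
#'
#' Treats TPM values as abundances with library size \eqn{10^6} per sample,
#' computes TMM factors, and divides each column by its factor. Because all
#' TPM library sizes are equal, effective-library-size scaling reduces to
#' division by the factor.
#'
#' @inheritParams tmm_factors
#' @param tpm A [quant_matrix] with `measure = "tpm"`, linear scale.
#' @return A [quant_matrix] with `measure = "tpm"` whose columns have been
#'   rescaled by the TMM factors (attribute `norm_factors` holds them).
#' @export
tmm_on_tpm <- function(tpm, reference = NULL, logratio_trim = 0.30,
                       abs_trim = 0.05, weighted = TRUE) {
  stopifnot(inherits(tpm, "quant_matrix"))
  if (tpm$measure != "tpm" || tpm$scale != "linear") {
    stop("expected a linear-scale TPM matrix")
  }
  f <- tmm_factors(tpm, reference = reference, logratio_trim = logratio_trim,
                   abs_trim = abs_trim, weighted = weighted)
  fac <- f$factor[match(colnames(tpm$values), f$sample_id)]
  out <- quant_matrix(tpm$values / rep(fac, each = nrow(tpm$values)),
                      measure = "tpm", scale = "linear")
  attr(out, "norm_factors") <- f
  out
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors [%s] for %d samples\n", attr(x, "method"), nrow(x)))
  NextMethod()
}
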