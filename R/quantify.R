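#' TPM and FPKM from counts and effective lengths
#'
#' Computes the two length-normalized within-sample abundance measures from
#' fragment counts \eqn{q_i} and effective gene lengths \eqn{l_i}:
#' \deqn{FPKM_i = \frac{q_i}{l_i \cdot \sum_j q_j} \cdot 10^9, \qquad
#'       TPM_i  = \frac{q_i / l_i}{\sum_j (q_j / l_j)} \cdot 10^6.}
#' Effective length (gene length adjusted for the fragment-length
#' distribution) is used as \eqn{l_i}, the convention under which RSEM's own
#' TPM/FPKM columns are reproduced from its `expected_count` and
#' `effective_length` columns. Genes with effective length 0 (shorter than
#' the fragment length) must have zero counts; they receive TPM = FPKM = 0
#' and are excluded from denominators.
#'
#' @param counts A [quant_matrix] with `measure = "count"`, linear scale.
#' @param lengths Named numeric vector of effective lengths covering all
#'   genes of `counts`.
#' @return A [quant_matrix] with measure `"fpkm"` or `"tpm"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  ql <- check_counts_lengths(counts, lengths)
  q <- counts$values
  l <- ql$l
  tot <- colSums(q)
  fpkm <- q / l * rep(1e9 / tot, each = nrow(q))
  fpkm[l == 0, ] <- 0
  quant_matrix(fpkm, measure = "fpkm", scale = "linear")
}

#' @rdname compute_fpkm
#' @export
compute_tpm <- function(counts, lengths) {
  ql <- check_counts_lengths(counts, lengths)
  q <- counts$values
  l <- ql$l
  rate <- q / l
  rate[l == 0, ] <- 0
  denom <- colSums(rate)
  if (any(denom <= 0)) {
    stop("degenerate sample(s) with no length-normalized signal: ",
         paste(colnames(q)[denom <= 0], collapse = ", "))
  }
  tpm <- rate * rep(1e6 / denom, each = nrow(q))
  quant_matrix(tpm, measure = "tpm", scale = "linear")
}

check_counts_lengths <- function(counts, lengths) {
  stopifnot(inherits(counts, "quant_matrix"))
  if (counts$measure != "count" || counts$scale != "linear") {
    stop("expected a linear-scale count matrix, got measure=", counts$measure,
         ", scale=", counts$scale)
  }
  if (is.null(names(lengths))) stop("'lengths' must be named by gene_id")
  missing <- setdiff(rownames(counts$values), names(lengths))
  if (length(missing) > 0) {
    stop("no effective length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  l <- lengths[rownames(counts$values)]
  tot <- colSums(counts$values)
  if (any(tot <= 0)) {
    stop("degenerate sample(s) with all-zero counts: ",
         paste(colnames(counts$values)[tot <= 0], collapse = ", "))
  }
  bad <- l == 0 & rowSums(counts$values > 0) > 0
  if (any(bad)) {
    stop("gene(s) with positive counts but zero effective length: ",
         paste(utils::head(rownames(counts$values)[bad], 5), collapse = ", "))
  }
  list(l = l)
}

#' Convert FPKM to TPM
#'
#' TPM is FPKM rescaled so every sample sums to one million:
#' \eqn{TPM_i = FPKM_i / \sum_j FPKM_j \cdot 10^6}.
#'
#' @param fpkm A [quant_matrix] with `measure = "fpkm"`, linear scale.
#' @return A [quant_matrix] with `measure = "tpm"`.
#' @export
fpkm_to_tpm <- function(fpkm) {
  stopifnot(inherits(fpkm, "quant_matrix"))
  if (fpkm$measure != "fpkm" || fpkm$scale != "linear") {
    stop("expected a linear-scale FPKM matrix")
  }
  tot <- colSums(fpkm$values)
  if (any(tot <= 0)) {
    stop("degenerate sample(s) with all-zero FPKM: ",
         paste(colnames(fpkm$values)[tot <= 0], collapse = ", "))
  }
  quant_matrix(fpkm$values * rep(1e6 / tot, each = nrow(fpkm$values)),
               measure = "tpm", scale = "linear")
}

#' Z-score transform of a TPM matrix
#'
#' Per gene \eqn{i} and sample \eqn{j}:
#' \deqn{Z_{ij} = \frac{\log_2(TPM_{ij}+1) - \mathrm{median}_j \log_2(TPM_{ij}+1)}
#'                     {SD_j(\log_2(TPM_{ij}+1))}}
#' with the sample standard deviation (\eqn{n-1} denominator) taken about
#' the mean. The pairing of a median-centered numerator with an SD
#' denominator is deliberate: the formula is applied literally rather than
#' replaced by a fully robust variant; `center = "mean"` switches to
#' conventional mean centering. Genes with zero SD across samples get all
#' Z set to 0 and are flagged in the `"zero_sd_genes"` attribute.
#'
#' @param tpm A [quant_matrix] with `measure = "tpm"`, linear scale, at
#'   least 2 samples.
#' @param center `"median"` (default) or `"mean"`.
#' @return A [quant_matrix] with `measure = "zscore"`, carrying attribute
#'   `zero_sd_genes` (character vector).
#' @export
zscore_tpm <- function(tpm, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(inherits(tpm, "quant_matrix"))
  if (tpm$measure != "tpm" || tpm$scale != "linear") {
    stop("expected a linear-scale TPM matrix")
  }
  if (ncol(tpm$values) < 2) stop("Z-score requires at least 2 samples")
  lx <- log2(tpm$values + 1)
  ctr <- if (center == "median") apply(lx, 1, stats::median) else rowMeans(lx)
  sds <- sqrt(rowSums((lx - rowMeans(lx))^2) / (ncol(lx) - 1))
  zero <- sds == 0
  z <- (lx - ctr) / sds
  z[zero, ] <- 0
  out <- quant_matrix(z, measure = "zscore", scale = "linear")
  attr(out, "zero_sd_genes") <- rownames(lx)[zero]
  out
}
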