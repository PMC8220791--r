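#' Coefficient of variation of one gene across replicates
#'
#' CV is the sample standard deviation (n-1 denominator) divided by the
#' mean, on the linear (untransformed) scale of the measure.
#'
#' @param values Numeric vector of length >= 2 with positive mean.
#' @return Non-negative numeric scalar.
#' @export
gene_cv <- function(values) {
  if (length(values) < 2) stop("CV needs >= 2 replicates")
  m <- mean(values)
  if (m <= 0) stop("CV undefined for non-positive mean")
  stats::sd(values) / m
}

#' Per-model CV summaries
#'
#' For each model, computes the CV of every gene across that model's
#' replicate samples, restricted to genes whose mean within the model is
#' positive, and reports the median and interquartile range (quartiles by
#' linear interpolation, type 7).
#'
#' @param x A linear-scale [quant_matrix].
#' @param groups Data frame with columns `sample_id`, `model_id`; every
#'   model must have >= 2 samples present in `x`.
#' @return Data frame with columns `model_id`, `median_cv`, `iqr_cv`,
#'   `n_genes_used`.
#' @export
model_cv_summary <- function(x, groups) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$scale != "linear") stop("CV is computed on the linear scale")
  groups <- as_grouping(groups)
  models <- unique(groups$model_id)
  rows <- lapply(models, function(m) {
    samps <- intersect(groups$sample_id[groups$model_id == m], colnames(x$values))
    if (length(samps) < 2) {
      stop("model '", m, "' has fewer than 2 replicate samples in the matrix")
    }
    sub <- x$values[, samps, drop = FALSE]
    mu <- rowMeans(sub)
    keep <- mu > 0
    cv <- sqrt(rowSums((sub[keep, , drop = FALSE] - mu[keep])^2) /
                 (length(samps) - 1)) / mu[keep]
    qs <- stats::quantile(cv, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(model_id = m, median_cv = qs[2], iqr_cv = qs[3] - qs[1],
               n_genes_used = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way random-effects intraclass correlation
#'
#' Fits the components-of-variance model \eqn{Y_{ij} = u_i + e_{ij}}
#' (units i = rows, replicates j = columns) and estimates the ICC by the
#' Shrout-Fleiss one-way formula
#' \deqn{ICC = \frac{MS_b - MS_e}{MS_b + (k-1) MS_e}}
#' where \eqn{MS_b} is the between-unit mean square, \eqn{MS_e} the
#' residual (within-unit) mean square, and k the number of replicates.
#' Negative raw estimates, which this estimator can produce when the true
#' ICC is near zero, are clamped to 0 in `icc` while `icc_raw` is kept.
#'
#' @param m Numeric matrix, units x replicates, >= 2 rows and >= 2 columns,
#'   complete (no NA).
#' @return List with `ms_between`, `ms_error`, `k`, `n_units`, `icc_raw`,
#'   `icc`.
#' @export
icc_oneway <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2) {
    stop("ICC needs a complete matrix with >= 2 units and >= 2 replicates")
  }
  if (anyNA(m)) stop("ICC input must be complete (no NA)")
  k <- ncol(m)
  n <- nrow(m)
  rm_ <- rowMeans(m)
  gm <- mean(m)
  ms_b <- k * sum((rm_ - gm)^2) / (n - 1)
  ms_e <- sum((m - rm_)^2) / (n * (k - 1))
  if (ms_b == 0 && ms_e == 0) {
    stop("ICC undefined: all values identical")
  }
  raw <- (ms_b - ms_e) / (ms_b + (k - 1) * ms_e)
  list(ms_between = ms_b, ms_error = ms_e, k = k, n_units = n,
       icc_raw = raw, icc = max(raw, 0))
}

#' Per-model gene-wise ICC (ICC_g)
#'
#' For each model, the genes x replicates matrix of log-transformed values
#' is fed to [icc_oneway()]; a high ICC_g means between-gene variation
#' dominates replicate noise, i.e. the measure is reproducible within the
#' model while preserving gene-to-gene differences. All replicates of a
#' model are used (k = 3 or 4 in the emulated design).
#'
#' @param x A [quant_matrix] on the `log2p1` scale.
#' @param groups Data frame with columns `sample_id`, `model_id`.
#' @return Data frame with columns `model_id`, `k`, `ms_between`,
#'   `ms_error`, `icc_raw`, `icc`.
#' @export
icc_g_per_model <- function(x, groups) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$scale != "log2p1") stop("ICC_g expects a log2(x+1)-scale matrix")
  groups <- as_grouping(groups)
  models <- unique(groups$model_id)
  rows <- lapply(models, function(m) {
    samps <- intersect(groups$sample_id[groups$model_id == m], colnames(x$values))
    if (length(samps) < 2) stop("model '", m, "' has fewer than 2 replicates")
    res <- tryCatch(icc_oneway(x$values[, samps, drop = FALSE]),
                    error = function(e) stop("model '", m, "': ",
                                             conditionMessage(e)))
    data.frame(model_id = m, k = res$k, ms_between = res$ms_between,
               ms_error = res$ms_error, icc_raw = res$icc_raw, icc = res$icc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene model-wise ICC (ICC_m)
#'
#' For each gene, a models x r matrix (r = the minimum replicate count over
#' models; each model contributes its first r replicates in sample-sheet
#' order) is analyzed with the one-way ICC. In the emulated design 19
#' models have 3 replicates and one has 4, so r = 3 and the four-replicate
#' model is truncated to its first three replicates, giving a uniform
#' 20 x 3 matrix per gene. Genes whose matrix is constant have undefined
#' ICC; they are excluded from the median and counted.
#'
#' @param x A [quant_matrix] on the `log2p1` scale.
#' @param groups Data frame with columns `sample_id`, `model_id`; row order
#'   defines replicate order.
#' @return List with `per_gene` (data frame: `gene_id`, `icc_raw`, `icc`,
#'   `defined`), `median_icc` (median over defined genes of clamped ICC),
#'   `n_undefined`, `k` (replicates used per model).
#' @export
icc_m_per_gene <- function(x, groups) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$scale != "log2p1") stop("ICC_m expects a log2(x+1)-scale matrix")
  groups <- as_grouping(groups)
  models <- unique(groups$model_id)
  if (length(models) < 2) stop("ICC_m needs >= 2 models")
  per_model <- lapply(models, function(m) {
    intersect(groups$sample_id[groups$model_id == m], colnames(x$values))
  })
  r <- min(lengths(per_model))
  if (r < 2) stop("every model needs >= 2 replicates for ICC_m")
  chosen <- lapply(per_model, function(s) s[seq_len(r)])

  n_genes <- nrow(x$values)
  n_models <- length(models)
  # genes x (models*r) layout, replicates within model contiguous
  y <- x$values[, unlist(chosen), drop = FALSE]
  model_of_col <- rep(seq_len(n_models), each = r)
  # per-gene per-model means
  mu <- vapply(seq_len(n_models), function(mi) {
    rowMeans(y[, model_of_col == mi, drop = FALSE])
  }, numeric(n_genes))
  mu <- matrix(mu, nrow = n_genes)
  grand <- rowMeans(y)
  ms_b <- r * rowSums((mu - grand)^2) / (n_models - 1)
  ms_e <- rowSums((y - mu[, model_of_col, drop = FALSE])^2) /
    (n_models * (r - 1))
  defined <- !(ms_b == 0 & ms_e == 0)
  raw <- rep(NA_real_, n_genes)
  raw[defined] <- (ms_b[defined] - ms_e[defined]) /
    (ms_b[defined] + (r - 1) * ms_e[defined])
  clamped <- pmax(raw, 0)
  per_gene <- data.frame(gene_id = rownames(x$values), icc_raw = raw,
                         icc = clamped, defined = defined,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       median_icc = stats::median(clamped[defined]),
       n_undefined = sum(!defined), k = r)
}

#' TPM fraction of the top-k most abundant genes
#'
#' Per model, genes are ranked by the sum of TPM over that model's
#' replicate samples (ties broken lexicographically by gene id); for each
#' replicate the fraction is the sum of the top-k genes' TPM divided by
#' \eqn{10^6}. Variable fractions across replicates flag dominant-transcript
#' (typically rRNA/mitochondrial) contamination that skews the whole TPM
#' distribution of a sample.
#'
#' @param tpm A [quant_matrix] with `measure = "tpm"`, linear scale.
#' @param groups Data frame with columns `sample_id`, `model_id`.
#' @param k Number of top genes (default 5).
#' @return Data frame with columns `model_id`, `sample_id`, `fraction`,
#'   plus attribute `top_genes` (named list of the k gene ids per model).
#' @export
top_k_abundance <- function(tpm, groups, k = 5) {
  stopifnot(inherits(tpm, "quant_matrix"))
  if (tpm$measure != "tpm" || tpm$scale != "linear") {
    stop("expected a linear-scale TPM matrix")
  }
  if (k > nrow(tpm$values)) stop("k exceeds the number of genes")
  groups <- as_grouping(groups)
  models <- unique(groups$model_id)
  top_genes <- list()
  rows <- lapply(models, function(m) {
    samps <- intersect(groups$sample_id[groups$model_id == m], colnames(tpm$values))
    sub <- tpm$values[, samps, drop = FALSE]
    sums <- rowSums(sub)
    ord <- order(-sums, rownames(sub))
    top <- rownames(sub)[ord[seq_len(k)]]
    top_genes[[m]] <<- top
    data.frame(model_id = m, sample_id = samps,
               fraction = colSums(sub[top, , drop = FALSE]) / 1e6,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "top_genes") <- top_genes
  out
}
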