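two_sample_counts <- function(a, b, genes = paste0("g", seq_along(a))) {
  quant_matrix(matrix(c(a, b), ncol = 2,
                      dimnames = list(genes, c("A", "B"))), measure = "count")
}

test_that("median-of-ratios factors match hand computations and DESeq2", {
  m <- two_sample_counts(c(2, 4), c(4, 8))
  f <- size_factors_median_ratio(m)
  expect_equal(f$factor, c(sqrt(0.5), sqrt(2)), tolerance = 1e-10)
  norm <- apply_factors(m, f)
  expect_equal(norm$values[, "A"], norm$values[, "B"])
  expect_equal(unname(norm$values[, "A"]), c(2 * sqrt(2), 4 * sqrt(2)),
               tolerance = 1e-10)

  # identical samples give unit factors
  k <- quant_matrix(matrix(rep(c(3, 9, 27), 4), ncol = 4,
                           dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
                    measure = "count")
  expect_equal(size_factors_median_ratio(k)$factor, rep(1, 4))

  # genes absent from any sample are excluded from the reference
  mz <- two_sample_counts(c(0, 4), c(0, 8))
  expect_equal(size_factors_median_ratio(mz)$factor, c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-10)
  expect_error(size_factors_median_ratio(two_sample_counts(c(0, 4), c(8, 0))),
               "virtual reference")

  # per-sample scaling of a common base vector is recovered up to a constant
  base <- c(10, 55, 200, 1000, 40)
  scl <- c(0.5, 1, 2, 4)
  msv <- outer(base, scl)
  dimnames(msv) <- list(paste0("g", 1:5), paste0("s", 1:4))
  ms <- quant_matrix(msv, measure = "count", scale = "linear")
  fs <- size_factors_median_ratio(ms, round_counts = FALSE)
  expect_equal(fs$factor / fs$factor[2], scl, tolerance = 1e-10)

  skip_if_not_installed("DESeq2")
  mm <- random_count_matrix(41, 4, seed = 11)  # odd gene count: medians agree
  mm$values <- round(mm$values)
  ours <- size_factors_median_ratio(mm)$factor
  deseq <- DESeq2::estimateSizeFactorsForMatrix(mm$values)
  expect_equal(ours, unname(deseq), tolerance = 1e-10)
})

test_that("TMM factors reproduce hand-computed and library-implemented values", {
  # identical samples
  k <- quant_matrix(matrix(rep(c(30, 90, 270), 3), ncol = 3,
                           dimnames = list(paste0("g", 1:3), paste0("s", 1:3))),
                    measure = "count")
  expect_equal(tmm_factors(k)$factor, rep(1, 3))

  # depth-only difference: B = 3A elementwise
  a <- c(50, 100, 200, 400)
  md <- two_sample_counts(a, 3 * a)
  expect_equal(tmm_factors(md)$factor, c(1, 1), tolerance = 1e-12)

  # untrimmed unweighted toy: factor ratio B/A = 2^((3 log2(0.4) + log2(2.8))/4)
  mt <- two_sample_counts(c(100, 100, 100, 100), c(100, 100, 100, 700))
  ft <- tmm_factors(mt, reference = "A", logratio_trim = 0, abs_trim = 0,
                    weighted = FALSE)
  expect_equal(ft$factor[2] / ft$factor[1],
               2^((3 * log2(0.4) + log2(2.8)) / 4), tolerance = 1e-10)
  expect_equal(exp(mean(log(ft$factor))), 1, tolerance = 1e-12)

  # symmetry: swapping roles inverts the factor (untrimmed, unweighted)
  m <- random_count_matrix(80, 2, seed = 3)
  fab <- tmm_factors(m, reference = "s01", logratio_trim = 0, abs_trim = 0,
                     weighted = FALSE)
  fba <- tmm_factors(m, reference = "s02", logratio_trim = 0, abs_trim = 0,
                     weighted = FALSE)
  expect_equal(fab$factor[2] / fab$factor[1], fba$factor[2] / fba$factor[1],
               tolerance = 1e-10)

  # gene reordering leaves factors unchanged
  mp <- m
  perm <- sample(seq_len(nrow(m$values)))
  mp$values <- mp$values[perm, ]
  expect_equal(tmm_factors(mp)$factor, tmm_factors(m)$factor)

  # over-trimming every gene is an explicit error
  expect_error(tmm_factors(mt, reference = "A", logratio_trim = 0.5),
               "trimming removed every gene")
})

test_that("default trimmed weighted TMM matches independent oracles", {
  m <- random_count_matrix(150, 5, seed = 21)
  m$values <- round(m$values)
  f <- tmm_factors(m, reference = "s01")
  # naive sort-based oracle, pre-rescaling pairwise factors
  raw <- vapply(1:5, function(s) {
    if (s == 1) return(1)
    oracle_tmm_pair(m$values[, s], m$values[, 1])
  }, numeric(1))
  expect_equal(f$factor, raw / exp(mean(log(raw))), tolerance = 1e-10)

  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(m$values, method = "TMM", refColumn = 1)
  expect_equal(f$factor, unname(fe), tolerance = 1e-10)
})

test_that("factor application respects method semantics and inverts scalings", {
  m <- random_count_matrix(30, 3, seed = 5)
  f1 <- size_factors_median_ratio(m)
  f1$factor <- rep(1, 3)
  expect_equal(apply_factors(m, f1)$values, m$values)
  expect_equal(apply_factors(m, f1)$measure, "normcount")

  # scaling a column by c with factor c restores the original column
  m2 <- m
  m2$values[, 2] <- m2$values[, 2] * 2.5
  f2 <- f1
  f2$factor <- c(1, 2.5, 1)
  expect_equal(apply_factors(m2, f2)$values, m$values)

  # TMM uses effective library sizes rescaled to the mean library size
  ft <- tmm_factors(m)
  nrm <- apply_factors(m, ft)
  N <- colSums(m$values)
  expect_equal(nrm$values,
               sweep(m$values, 2, N * ft$factor / mean(N), "/"))

  f3 <- f1[c(2, 1, 3), ]
  class(f3) <- class(f1)
  attr(f3, "method") <- "median_ratio"
  expect_equal(apply_factors(m, f3)$values, m$values) # order-insensitive match
})

test_that("TMM on TPM realigns non-dominant genes under contamination", {
  # identical TPM columns pass through unchanged
  tpmv <- matrix(rep(c(2e5, 3e5, 5e5), 3), ncol = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  tpm <- quant_matrix(tpmv, measure = "tpm")
  expect_equal(tmm_on_tpm(tpm)$values, tpmv)

  # contamination fixture: sample B loses 40% of its pool to a dominant gene
  set.seed(9)
  base <- stats::rgamma(200, 2, 0.5) + 0.5
  pa <- c(0.10, base / sum(base) * 0.90)
  pb <- c(0.50, base / sum(base) * 0.50)
  tv <- cbind(A = pa, B = pb) * 1e6
  rownames(tv) <- c("dom", sprintf("g%03d", 1:200))
  tpm2 <- quant_matrix(tv, measure = "tpm")
  fixed <- tmm_on_tpm(tpm2)
  nd <- rownames(tv)[-1]
  shift_before <- median(abs(log2(tv[nd, "A"] / tv[nd, "B"])))
  shift_after <- median(abs(log2(fixed$values[nd, "A"] / fixed$values[nd, "B"])))
  expect_lt(shift_after, 0.05)          # non-dominant genes realigned
  expect_gt(shift_before, 0.8)
  # the dominant gene remains discrepant after rescaling
  expect_gt(abs(log2(fixed$values["dom", "A"] / fixed$values["dom", "B"])), 1.5)
  f <- attr(fixed, "norm_factors")
  expect_equal(exp(mean(log(f$factor))), 1, tolerance = 1e-12)
})
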