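test_that("gene CV is SD/mean with scale invariance", {
  expect_equal(gene_cv(c(1, 2, 3)), 0.5)
  expect_equal(gene_cv(c(4, 4, 4)), 0)
  x <- c(2, 5, 9, 4)
  expect_equal(gene_cv(17 * x), gene_cv(x))
  expect_error(gene_cv(3), ">= 2")
  expect_error(gene_cv(c(-2, 2)), "non-positive mean")
})

test_that("per-model CV summaries restrict to expressed genes and use type-7 quartiles", {
  v <- rbind(g1 = c(10, 10, 14, 14),   # model A CV != 0, model B CV 0
             g2 = c(8, 12, 7, 13),
             g3 = c(0, 0, 5, 5))       # zero-mean in model A: excluded there
  colnames(v) <- c("A1", "A2", "B1", "B2")
  m <- quant_matrix(v, measure = "normcount", scale = "linear")
  groups <- data.frame(sample_id = colnames(v),
                       model_id = c("A", "A", "B", "B"))
  s <- model_cv_summary(m, groups)
  expect_equal(s$n_genes_used, c(2, 3))
  # model A gene CVs: g1 = 0, g2 = sd(8,12)/10
  cvA <- c(0, stats::sd(c(8, 12)) / 10)
  expect_equal(s$median_cv[1], stats::median(cvA))

  # identical replicates: median and IQR both zero
  ident <- quant_matrix(matrix(rep(c(3, 8), 2), 2, 2,
                               dimnames = list(c("g1", "g2"), c("A1", "A2"))),
                        measure = "normcount")
  sA <- model_cv_summary(ident, data.frame(sample_id = c("A1", "A2"),
                                           model_id = "A"))
  expect_equal(sA$median_cv, 0)
  expect_equal(sA$iqr_cv, 0)

  # two genes with CVs 0.2 and 0.4 -> median 0.3 (midpoint interpolation)
  v2 <- rbind(g1 = 10 * c(1 - 0.2 / sqrt(2), 1 + 0.2 / sqrt(2)),
              g2 = 10 * c(1 - 0.4 / sqrt(2), 1 + 0.4 / sqrt(2)))
  colnames(v2) <- c("A1", "A2")
  s2 <- model_cv_summary(quant_matrix(v2, measure = "normcount"),
                         data.frame(sample_id = c("A1", "A2"), model_id = "A"))
  expect_equal(s2$median_cv, 0.3, tolerance = 1e-12)

  # per-model column rescaling leaves that model's summary unchanged
  v3 <- v
  v3[, c("B1", "B2")] <- v3[, c("B1", "B2")] * 7
  s3 <- model_cv_summary(quant_matrix(v3, measure = "normcount"), groups)
  expect_equal(s3[s3$model_id == "B", -1], s[s$model_id == "B", -1])

  expect_error(model_cv_summary(m, data.frame(sample_id = "A1",
                                              model_id = "A")), "fewer than 2")
})

test_that("one-way ICC matches worked examples and clamps negatives", {
  r <- icc_oneway(rbind(c(0, 2), c(4, 6)))
  expect_equal(r$ms_between, 16)
  expect_equal(r$ms_error, 2)
  expect_equal(r$icc_raw, 14 / 18, tolerance = 1e-12)

  perfect <- icc_oneway(rbind(c(1, 1), c(3, 3)))
  expect_equal(perfect$ms_error, 0)
  expect_equal(perfect$icc, 1)

  neg <- icc_oneway(rbind(c(1, 3), c(3, 1)))
  expect_equal(neg$icc_raw, -1)
  expect_equal(neg$icc, 0)

  expect_error(icc_oneway(matrix(5, 3, 3)), "identical")
  expect_error(icc_oneway(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("one-way ICC agrees with a brute-force ANOVA oracle on 200 matrices", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    k <- sample(2:5, 1)
    m <- matrix(stats::rnorm(n * k, sd = sample(c(0.5, 1, 3), 1)), n, k)
    expect_equal(icc_oneway(m)$icc_raw, oracle_icc_oneway(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC_g is computed per model on all replicates and ignores gene order", {
  sim <- small_sim(seed = 55)
  mats <- sim_matrices(sim)
  lt <- log_transform(mats$counts)
  g <- icc_g_per_model(lt, sim$annotation)
  expect_equal(nrow(g), 6)
  expect_equal(sort(unique(g$k)), c(3, 4))   # last model keeps its 4 replicates
  expect_true(all(g$icc >= 0 & g$icc <= 1))

  ltp <- lt
  perm <- sample(seq_len(nrow(lt$values)))
  ltp$values <- ltp$values[perm, ]
  expect_equal(icc_g_per_model(ltp, sim$annotation)$icc, g$icc)

  expect_error(icc_g_per_model(mats$counts, sim$annotation), "log2")
})

test_that("ICC_m truncates to the minimum replicate count and excludes constants", {
  # 2 models x 2 replicates, one informative gene matching the ANOVA toy
  v <- rbind(g1 = c(0, 2, 4, 6),
             g2 = c(5, 5, 5, 5))
  colnames(v) <- c("A1", "A2", "B1", "B2")
  m <- quant_matrix(v, measure = "normcount", scale = "linear")
  lt <- log_transform(m)
  lt$values <- v  # inject raw values to keep the hand computation exact
  groups <- data.frame(sample_id = colnames(v),
                       model_id = c("A", "A", "B", "B"))
  res <- icc_m_per_gene(lt, groups)
  expect_equal(res$per_gene$icc_raw[1], 14 / 18, tolerance = 1e-12)
  expect_false(res$per_gene$defined[2])
  expect_equal(res$n_undefined, 1)
  expect_equal(res$median_icc, 14 / 18, tolerance = 1e-12)

  # four-replicate models are truncated to their first r replicates
  sim <- small_sim(seed = 31)
  lt2 <- log_transform(sim_matrices(sim)$counts)
  res2 <- icc_m_per_gene(lt2, sim$annotation)
  expect_equal(res2$k, 3)
  dropped <- tail(sim$annotation$sample_id, 1)  # 4th replicate, sheet order
  lt3 <- lt2
  lt3$values <- lt3$values[, setdiff(colnames(lt3$values), dropped)]
  res3 <- icc_m_per_gene(lt3, sim$annotation[sim$annotation$sample_id != dropped, ])
  expect_equal(res3$per_gene$icc, res2$per_gene$icc)
})

test_that("top-k TPM fractions rank by within-model totals with lexicographic ties", {
  tv <- matrix(c(5e5, 2e5, 1e5, 1e5, 5e4, 5e4), ncol = 1,
               dimnames = list(c("g1", "g2", "g3", "g4", "ga", "gb"), "A1"))
  tv <- cbind(A1 = tv[, 1], A2 = tv[, 1])
  tpm <- quant_matrix(tv, measure = "tpm")
  groups <- data.frame(sample_id = c("A1", "A2"), model_id = "A")
  res <- top_k_abundance(tpm, groups, k = 5)
  expect_equal(res$fraction, c(0.95, 0.95))
  expect_equal(attr(res, "top_genes")$A, c("g1", "g2", "g3", "g4", "ga"))

  # ten equally expressed genes: any five give one half
  tv10 <- matrix(rep(1e5, 20), ncol = 2,
                 dimnames = list(sprintf("g%02d", 1:10), c("A1", "A2")))
  res10 <- top_k_abundance(quant_matrix(tv10, measure = "tpm"), groups, k = 5)
  expect_equal(res10$fraction, c(0.5, 0.5))

  # exactly k expressed genes: fraction 1; and monotone non-decreasing in k
  resall <- top_k_abundance(quant_matrix(tv10, measure = "tpm"), groups, k = 10)
  expect_equal(resall$fraction, c(1, 1))
  fr <- vapply(1:10, function(k) {
    top_k_abundance(quant_matrix(tv10, measure = "tpm"), groups, k)$fraction[1]
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))

  expect_error(top_k_abundance(quant_matrix(tv10, measure = "tpm"), groups,
                               k = 11), "exceeds")
})
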