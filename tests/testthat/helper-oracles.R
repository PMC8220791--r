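# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately written in the most naive style available
# (explicit loops, closed forms) so it shares no code path with the
# implementation it checks.

# One-way ANOVA variance components by explicit double loops.
oracle_icc_oneway <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) grand <- grand + m[i, j]
  grand <- grand / (n * k)
  ssb <- 0
  sse <- 0
  for (i in seq_len(n)) {
    mi <- 0
    for (j in seq_len(k)) mi <- mi + m[i, j]
    mi <- mi / k
    ssb <- ssb + k * (mi - grand)^2
    for (j in seq_len(k)) sse <- sse + (m[i, j] - mi)^2
  }
  ms_b <- ssb / (n - 1)
  ms_e <- sse / (n * (k - 1))
  (ms_b - ms_e) / (ms_b + (k - 1) * ms_e)
}

# Ward.D2 on Euclidean point configurations via the closed-form cluster
# criterion d(A,B)^2 = 2 nA nB / (nA + nB) * ||centroid_A - centroid_B||^2,
# recomputed from the raw points at every step (O(n^3) re-scan).
# Returns merge heights and the leaf set of every internal node.
oracle_ward_points <- function(pts) {
  clusters <- lapply(seq_len(nrow(pts)), identity)
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(pts[a, , drop = FALSE])
        cb <- colMeans(pts[b, , drop = FALSE])
        d2 <- 2 * length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (d2 < best - 1e-12) { best <- d2; bi <- i; bj <- j }
      }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    heights <- c(heights, sqrt(best))
    clades <- c(clades, list(sort(merged)))
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  list(heights = heights, clades = clades)
}

# Brute-force TMM factor of column s against column r, written with
# sort-based trimming and explicit accumulation, no shared helpers.
oracle_tmm_pair <- function(q, r, logratio_trim = 0.30, abs_trim = 0.05,
                            weighted = TRUE) {
  Nq <- sum(q); Nr <- sum(r)
  keep <- which(q > 0 & r > 0)
  M <- numeric(0); A <- numeric(0); w <- numeric(0)
  for (g in keep) {
    pg <- q[g] / Nq; pr <- r[g] / Nr
    M <- c(M, log2(pg / pr))
    A <- c(A, 0.5 * log2(pg * pr))
    w <- c(w, if (weighted) {
      1 / ((Nq - q[g]) / (Nq * q[g]) + (Nr - r[g]) / (Nr * r[g]))
    } else 1)
  }
  n <- length(M)
  cutM <- floor(n * logratio_trim)
  cutA <- floor(n * abs_trim)
  okM <- rank(M) > cutM & rank(M) <= n - cutM
  okA <- rank(A) > cutA & rank(A) <= n - cutA
  use <- which(okM & okA)
  2^(sum(w[use] * M[use]) / sum(w[use]))
}

# Random positive count-matrix fixture without ties in M or A (generic
# continuous draws; ties have probability zero).
random_count_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  v <- matrix(stats::rgamma(n_genes * n_samples, shape = 2, rate = 0.01) + 1,
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  quant_matrix(v, measure = "count", scale = "linear")
}

# Small-but-structured simulated dataset for fast pipeline tests.
small_sim <- function(seed = 101, contaminated = NULL) {
  cfg <- synthetic_config(n_genes = 400, n_models = 6,
                          contaminated_model_ids = contaminated,
                          seed = seed)
  simulate_dataset(cfg)
}

sim_matrices <- function(sim) {
  list(counts = assemble_matrix(sim$samples, "expected_count"),
       tpm = assemble_matrix(sim$samples, "tpm"),
       fpkm = assemble_matrix(sim$samples, "fpkm"))
}

# Minimal hand-written RSEM file for parser tests.
write_toy_rsem <- function(path,
                           header = "gene_id\ttranscript_id(s)\tlength\teffective_length\texpected_count\tTPM\tFPKM",
                           rows = c("g1\tt1\t1000\t800\t10\t600000\t500000",
                                    "g2\tt2\t2000\t1800\t5\t300000\t250000",
                                    "g3\tt3\t1500\t1300\t2\t100000\t83333.3")) {
  writeLines(c(header, rows), path)
  path
}
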