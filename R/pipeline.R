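MEASURE_SET <- c("tpm", "fpkm", "count_medratio", "count_tmm",
                 "tpm_zscore", "tpm_tmm")
METRIC_SET <- c("one_minus_pearson", "euclidean")

#' Build the six benchmark measure matrices
#'
#' From a count matrix, its TPM/FPKM companions and effective lengths,
#' derives the full scenario set: TPM, FPKM, median-of-ratios normalized
#' counts, TMM normalized counts, Z-score on TPM, and TMM-rescaled TPM.
#'
#' @param counts,tpm,fpkm [quant_matrix] objects sharing genes and samples.
#' @return Named list of [quant_matrix] objects.
#' @export
build_measure_matrices <- function(counts, tpm, fpkm) {
  mr <- size_factors_median_ratio(counts)
  tf <- tmm_factors(counts)
  list(
    tpm = tpm,
    fpkm = fpkm,
    count_medratio = apply_factors(counts, mr),
    count_tmm = apply_factors(counts, tf),
    tpm_zscore = zscore_tpm(tpm),
    tpm_tmm = tmm_on_tpm(tpm)
  )
}

#' Run the full quantification-measure comparison
#'
#' Orchestrates the whole benchmark: assembles the six measure matrices,
#' clusters the samples under 1-Pearson and Euclidean dissimilarities with
#' Ward.D2 (or complete) linkage, counts discordant models and maximum
#' merge heights, and computes per-model CV summaries, per-model ICC_g,
#' per-gene ICC_m medians and top-k TPM abundance fractions. Clustering
#' and ICC are computed on the log2(x+1) scale (Z-score matrices are used
#' as-is); CV on the linear scale.
#'
#' @param sample_sheet Path to a sample sheet CSV
#'   (`sample_id,model_id,passage,file_path`).
#' @param out_dir Optional output directory for report tables; `NULL`
#'   (default) skips writing.
#' @param cluster_scale `"log2p1"` (default) or `"linear"`.
#' @param linkage `"ward"` (default) or `"complete"`.
#' @param top_k Number of top-abundance genes to track (default 5).
#' @param verbose Emit one log line per stage (default `TRUE`).
#' @return A `comparison_report` list with elements `discordance`,
#'   `max_height`, `cv`, `icc_g`, `icc_m_summary`, `icc_m_per_gene`,
#'   `top_fractions`, `dendrograms`, `options`.
#' @export
run_comparison <- function(sample_sheet, out_dir = NULL,
                           cluster_scale = c("log2p1", "linear"),
                           linkage = c("ward", "complete"),
                           top_k = 5, verbose = TRUE) {
  cluster_scale <- match.arg(cluster_scale)
  linkage <- match.arg(linkage)
  sheet <- read_sample_sheet(sample_sheet)
  if (length(unique(sheet$model_id)) < 2) stop("need >= 2 models")
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage=read samples=%d models=%d", nrow(sheet),
      length(unique(sheet$model_id)))
  recs <- read_rsem_cohort(sheet)
  counts <- assemble_matrix(recs, "expected_count")
  tpm <- assemble_matrix(recs, "tpm")
  fpkm <- assemble_matrix(recs, "fpkm")
  say("stage=assemble genes=%d samples=%d", nrow(counts$values),
      ncol(counts$values))
  report <- compare_measures(counts, tpm, fpkm, sheet,
                             cluster_scale = cluster_scale, linkage = linkage,
                             top_k = top_k, verbose = verbose)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Compare measures from pre-assembled matrices
#'
#' In-memory core of [run_comparison()]; useful when the matrices come
#' from [simulate_dataset()] rather than files.
#'
#' @inheritParams run_comparison
#' @param counts,tpm,fpkm [quant_matrix] objects sharing genes and samples.
#' @param groups Data frame with columns `sample_id`, `model_id`.
#' @return A `comparison_report` list; see [run_comparison()].
#' @export
compare_measures <- function(counts, tpm, fpkm, groups,
                             cluster_scale = c("log2p1", "linear"),
                             linkage = c("ward", "complete"),
                             top_k = 5, verbose = FALSE) {
  cluster_scale <- match.arg(cluster_scale)
  linkage <- match.arg(linkage)
  groups <- as_grouping(groups)
  say <- function(...) if (verbose) message(sprintf(...))

  measures <- build_measure_matrices(counts, tpm, fpkm)
  say("stage=measures built=%s", paste(names(measures), collapse = ","))

  dendrograms <- list()
  disc_rows <- list()
  height_rows <- list()
  for (meas in names(measures)) {
    m <- measures[[meas]]
    cl_input <- if (m$measure == "zscore" || cluster_scale == "linear") m
                else log_transform(m)
    for (metric in METRIC_SET) {
      dis <- if (metric == "one_minus_pearson") pearson_dissimilarity(cl_input)
             else euclidean_dissimilarity(cl_input)
      dend <- ward_linkage(dis, linkage = linkage)
      key <- paste(meas, metric, sep = ".")
      dendrograms[[key]] <- dend
      dm <- discordant_models(dend, groups)
      disc_rows[[key]] <- data.frame(
        measure = meas, metric = metric, n_discordant = dm$count,
        n_models = length(unique(groups$model_id)),
        discordant_ids = paste(dm$discordant_ids, collapse = ";"),
        stringsAsFactors = FALSE)
      height_rows[[key]] <- data.frame(
        measure = meas, metric = metric, max_height = max_height(dend),
        stringsAsFactors = FALSE)
      say("stage=cluster measure=%s metric=%s discordant=%d max_height=%.4g",
          meas, metric, dm$count, max_height(dend))
    }
  }

  linear_measures <- setdiff(names(measures), "tpm_zscore")
  cv <- do.call(rbind, lapply(linear_measures, function(meas) {
    s <- model_cv_summary(measures[[meas]], groups)
    cbind(measure = meas, s, stringsAsFactors = FALSE)
  }))
  say("stage=cv measures=%d", length(linear_measures))

  icc_g <- do.call(rbind, lapply(linear_measures, function(meas) {
    s <- icc_g_per_model(log_transform(measures[[meas]]), groups)
    cbind(measure = meas, s, stringsAsFactors = FALSE)
  }))
  icc_m_per_gene <- list()
  icc_m_summary <- do.call(rbind, lapply(linear_measures, function(meas) {
    s <- icc_m_per_gene(log_transform(measures[[meas]]), groups)
    icc_m_per_gene[[meas]] <<- s$per_gene
    data.frame(measure = meas, median_icc_m = s$median_icc,
               n_undefined = s$n_undefined, k = s$k, stringsAsFactors = FALSE)
  }))
  say("stage=icc done")

  top_fractions <- top_k_abundance(tpm, groups, k = top_k)
  say("stage=topk k=%d", top_k)

  structure(list(
    discordance = do.call(rbind, c(disc_rows, list(make.row.names = FALSE))),
    max_height = do.call(rbind, c(height_rows, list(make.row.names = FALSE))),
    cv = cv,
    icc_g = icc_g,
    icc_m_summary = icc_m_summary,
    icc_m_per_gene = icc_m_per_gene,
    top_fractions = top_fractions,
    dendrograms = dendrograms,
    options = list(cluster_scale = cluster_scale, linkage = linkage,
                   top_k = top_k)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  cat(" discordant models by measure/metric:\n")
  print(x$discordance[, c("measure", "metric", "n_discordant", "n_models")],
        row.names = FALSE)
  cat(" median ICC_m by measure:\n")
  print(x$icc_m_summary[, c("measure", "median_icc_m")], row.names = FALSE)
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits `table1_discordance.tsv`, `table2_maxheight.tsv`,
#' `cv_by_model.tsv`, `icc_g.tsv`, `icc_m_summary.tsv`,
#' `top_fractions.tsv` and one Newick file per dendrogram (when the `ape`
#' package is available). Numeric cells are rounded to 3 decimals; a
#' full-precision sidecar (`*_full.tsv`) accompanies each rounded table.
#'
#' @param report A `comparison_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tables <- list(
    table1_discordance = report$discordance,
    table2_maxheight = report$max_height,
    cv_by_model = report$cv,
    icc_g = report$icc_g,
    icc_m_summary = report$icc_m_summary,
    top_fractions = report$top_fractions
  )
  for (nm in names(tables)) {
    df <- tables[[nm]]
    write_tsv_det(round_numeric(df, 3), file.path(out_dir, paste0(nm, ".tsv")))
    write_tsv_det(df, file.path(out_dir, paste0(nm, "_full.tsv")))
  }
  if (requireNamespace("ape", quietly = TRUE)) {
    for (key in names(report$dendrograms)) {
      export_newick(report$dendrograms[[key]],
                    file.path(out_dir, paste0("dendrogram_", key, ".nwk")))
    }
  }
  invisible(out_dir)
}

round_numeric <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_tsv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
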