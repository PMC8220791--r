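#' Configuration for the synthetic PDX replicate generator
#'
#' The generator emulates a replicate RNA-seq design of the kind found in
#' patient-derived xenograft (PDX) repositories: `n_models` tumor models,
#' each with a few biological replicates quantified at the gene level, plus
#' a small set of very short, very highly expressed "dominant" genes
#' (rRNA/mitochondrial-like) whose share of the sequenced pool varies
#' between replicates of selected models. Because TPM is compositional,
#' that variable share mechanically shifts the TPM of every other gene,
#' while count-based normalizations remain robust.
#'
#' Gene expression propensities combine a baseline profile shared by all
#' models (log-normal, `baseline_log_mean`/`baseline_log_sd`) with sparse
#' model-specific effects: each model differentially expresses a random
#' subset of genes (`model_de_fraction`) with log-normal effect sizes
#' (`model_effect_log_sd`). Tumors share most of the transcriptome and are
#' separated by a minority of subtype-marker genes, so between-model
#' differences are moderate relative to the overall dynamic range.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param n_models Number of PDX-like models (default 20).
#' @param replicates_per_model Integer, or integer vector of length
#'   `n_models`. Default: 3 everywhere except the last model, which gets 4,
#'   mirroring a 19x3 + 1x4 design.
#' @param mean_library_size Mean library size in fragments (default 2e6).
#' @param library_size_cv CV of the log-normal library sizes (default 0.2).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of the
#'   shared baseline expression propensities (defaults 4.0, 2.0).
#' @param model_de_fraction Fraction of genes differentially expressed in
#'   any one model relative to the shared baseline (default 0.15).
#' @param model_effect_log_sd Natural-log sd of model-specific expression
#'   effects on those genes (default 0.5, i.e. typical ~1.4-fold subtype
#'   shifts).
#' @param nb_dispersion Negative-binomial dispersion of replicate count
#'   noise (default 0.01, placing the replicate CV floor at 0.1, the
#'   middle of the range reported for well-normalized PDX replicate
#'   counts); 0 gives Poisson noise.
#' @param n_dominant_genes Number of dominant rRNA/mito-like genes
#'   (default 5).
#' @param dominant_length Length range (bases) for the short dominant
#'   genes (default c(120, 1500)).
#' @param contaminated_model_ids Models whose replicates have strongly
#'   variable dominant-gene fractions. Default: the first 4 models. Use
#'   `character(0)` for a fully clean design.
#' @param dominant_fraction_range_contaminated Range of the molar fraction
#'   of the pool taken by dominant genes in contaminated models
#'   (default c(0.05, 0.5)). Replicates of a contaminated model span this
#'   range on an even grid with uniform jitter — a flagged model is by
#'   definition one whose replicates differ strongly in dominant content —
#'   while clean models draw i.i.d. uniform fractions.
#' @param dominant_fraction_range_clean Same for clean models
#'   (default c(0.08, 0.12)).
#' @param gene_length_log_mean,gene_length_log_sd Natural-log parameters of
#'   ordinary gene lengths (defaults 7.5, 0.7; lengths clamped to
#'   [200, 100000] bases).
#' @param effective_length_offset Bases subtracted from length to get the
#'   effective length, clamped at 1 (default 200, a typical mean fragment
#'   length).
#' @param seed Integer seed (default 20210622).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_models = 20,
                             replicates_per_model = NULL,
                             mean_library_size = 2e6,
                             library_size_cv = 0.2,
                             baseline_log_mean = 4.0,
                             baseline_log_sd = 2.0,
                             model_de_fraction = 0.15,
                             model_effect_log_sd = 0.5,
                             nb_dispersion = 0.01,
                             n_dominant_genes = 5,
                             dominant_length = c(120, 1500),
                             contaminated_model_ids = NULL,
                             dominant_fraction_range_contaminated = c(0.05, 0.5),
                             dominant_fraction_range_clean = c(0.08, 0.12),
                             gene_length_log_mean = 7.5,
                             gene_length_log_sd = 0.7,
                             effective_length_offset = 200,
                             seed = 20210622) {
  model_ids <- sprintf("SYN-%03d-R", seq_len(n_models))
  if (is.null(replicates_per_model)) {
    replicates_per_model <- rep(3L, n_models)
    replicates_per_model[n_models] <- 4L
  } else if (length(replicates_per_model) == 1) {
    replicates_per_model <- rep(as.integer(replicates_per_model), n_models)
  }
  if (length(replicates_per_model) != n_models) {
    stop("'replicates_per_model' must have length 1 or n_models")
  }
  if (is.null(contaminated_model_ids)) {
    contaminated_model_ids <- model_ids[seq_len(min(4, n_models))]
  }
  if (!all(contaminated_model_ids %in% model_ids)) {
    stop("contaminated_model_ids must be a subset of the model ids (",
         paste(utils::head(model_ids, 3), collapse = ", "), ", ...)")
  }
  cfg <- list(
    n_genes = n_genes, n_models = n_models, model_ids = model_ids,
    replicates_per_model = replicates_per_model,
    mean_library_size = mean_library_size, library_size_cv = library_size_cv,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    model_de_fraction = model_de_fraction,
    model_effect_log_sd = model_effect_log_sd,
    nb_dispersion = nb_dispersion,
    n_dominant_genes = n_dominant_genes, dominant_length = dominant_length,
    contaminated_model_ids = contaminated_model_ids,
    dominant_fraction_range_contaminated = dominant_fraction_range_contaminated,
    dominant_fraction_range_clean = dominant_fraction_range_clean,
    gene_length_log_mean = gene_length_log_mean,
    gene_length_log_sd = gene_length_log_sd,
    effective_length_offset = effective_length_offset,
    seed = seed
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_dominant_genes >= n_genes) stop("all genes dominant: invalid config")
    if (mean_library_size <= 0) stop("mean_library_size must be positive")
    if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    rng <- c(dominant_fraction_range_contaminated, dominant_fraction_range_clean)
    if (any(rng < 0) || any(rng >= 1)) {
      stop("dominant fractions must lie in [0, 1)")
    }
    if (any(replicates_per_model < 2)) {
      stop("every model needs >= 2 replicates")
    }
    if (model_de_fraction < 0 || model_de_fraction > 1) {
      stop("model_de_fraction must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

#' Generate a synthetic replicate RNA-seq dataset
#'
#' All randomness is drawn from a single stream seeded with `config$seed`,
#' in a fixed documented order (gene lengths, baseline profile, model
#' effects, then per sample: dominant fraction, library size, counts), so
#' the output is bit-identical for identical `(config, seed)`.
#'
#' Per model, non-dominant expression propensities are
#' \eqn{\theta_{mg} = \exp(b_g + \delta_{mg})}. Per replicate, a dominant
#' molar fraction f is drawn from the model's range; the dominant genes
#' split f evenly and the rest of the pool is allocated proportionally to
#' \eqn{\theta}. Expected read shares are molar fraction times effective
#' length (short dominant genes therefore consume far fewer reads than
#' their molar share, which is why TPM is hit harder than FPKM), counts
#' are negative-binomial around library size times share, and the TPM/FPKM
#' fields are filled by [compute_tpm()]/[compute_fpkm()] on the generated
#' counts.
#'
#' @param config A [synthetic_config()] object.
#' @return List with `samples` (named list of RSEM-style record data
#'   frames), `annotation` (sample sheet data frame), and `truth`
#'   (generator ground truth: `theta`, `dominant_gene_ids`,
#'   `dominant_fraction`, `library_size`, `contaminated`, `config`).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_dom <- cfg$n_dominant_genes
  n_nd <- cfg$n_genes - n_dom
  dom_ids <- sprintf("rRNA-like-%02d", seq_len(n_dom))
  nd_ids <- sprintf("gene_%05d", seq_len(n_nd))
  gene_id <- c(dom_ids, nd_ids)

  # 1. gene lengths
  dom_len <- round(stats::runif(n_dom, cfg$dominant_length[1], cfg$dominant_length[2]))
  nd_len <- round(pmin(pmax(stats::rlnorm(n_nd, cfg$gene_length_log_mean,
                                          cfg$gene_length_log_sd), 200), 1e5))
  len <- c(dom_len, nd_len)
  eff_len <- pmax(len - cfg$effective_length_offset, 1)

  # 2. shared baseline profile, 3. sparse model effects (DE indicator, then
  # effect sizes; non-DE effects are zeroed so the stream layout is fixed)
  base <- stats::rnorm(n_nd, cfg$baseline_log_mean, cfg$baseline_log_sd)
  is_de <- matrix(stats::rbinom(n_nd * cfg$n_models, 1, cfg$model_de_fraction),
                  nrow = n_nd)
  delta <- matrix(stats::rnorm(n_nd * cfg$n_models, 0, cfg$model_effect_log_sd),
                  nrow = n_nd) * is_de
  theta <- exp(base + delta)   # genes x models
  dimnames(theta) <- list(nd_ids, cfg$model_ids)

  contaminated <- stats::setNames(cfg$model_ids %in% cfg$contaminated_model_ids,
                                  cfg$model_ids)
  ls_sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  ls_meanlog <- log(cfg$mean_library_size) - ls_sdlog^2 / 2

  sample_id <- character(0)
  model_of <- character(0)
  frac <- numeric(0)
  libsize <- numeric(0)
  counts <- NULL

  for (mi in seq_len(cfg$n_models)) {
    m <- cfg$model_ids[mi]
    rng <- if (contaminated[[m]]) cfg$dominant_fraction_range_contaminated
           else cfg$dominant_fraction_range_clean
    nd_molar <- theta[, mi] / sum(theta[, mi])
    k_rep <- cfg$replicates_per_model[mi]
    for (ri in seq_len(k_rep)) {
      sid <- sprintf("%s-rep%d", m, ri)
      f <- if (contaminated[[m]]) {
        # even grid over the range with +/- quarter-cell jitter
        w <- (rng[2] - rng[1]) / k_rep
        rng[1] + (ri - 0.5) * w + stats::runif(1, -w / 4, w / 4)
      } else {
        stats::runif(1, rng[1], rng[2])
      }
      N <- stats::rlnorm(1, ls_meanlog, ls_sdlog)
      molar <- c(rep(f / n_dom, n_dom), (1 - f) * nd_molar)
      share <- molar * eff_len
      share <- share / sum(share)
      mu <- N * share
      cts <- if (cfg$nb_dispersion > 0) {
        stats::rnbinom(cfg$n_genes, size = 1 / cfg$nb_dispersion, mu = mu)
      } else {
        stats::rpois(cfg$n_genes, mu)
      }
      sample_id <- c(sample_id, sid)
      model_of <- c(model_of, m)
      frac <- c(frac, f)
      libsize <- c(libsize, N)
      counts <- cbind(counts, cts)
    }
  }
  dimnames(counts) <- list(gene_id, sample_id)
  counts <- counts[, , drop = FALSE]
  storage.mode(counts) <- "double"

  cmat <- quant_matrix(counts, measure = "count", scale = "linear")
  lens <- stats::setNames(eff_len, gene_id)
  tpm <- compute_tpm(cmat, lens)
  fpkm <- compute_fpkm(cmat, lens)

  samples <- lapply(seq_along(sample_id), function(si) {
    data.frame(gene_id = gene_id,
               transcript_ids = paste0("t_", gene_id),
               length = len,
               effective_length = eff_len,
               expected_count = counts[, si],
               tpm = tpm$values[, si],
               fpkm = fpkm$values[, si],
               stringsAsFactors = FALSE)
  })
  names(samples) <- sample_id

  annotation <- data.frame(sample_id = sample_id, model_id = model_of,
                           passage = "P0",
                           file_path = paste0(sample_id, ".genes.results"),
                           stringsAsFactors = FALSE)
  truth <- list(theta = theta,
                dominant_gene_ids = dom_ids,
                dominant_fraction = stats::setNames(frac, sample_id),
                library_size = stats::setNames(libsize, sample_id),
                contaminated = contaminated,
                config = cfg)
  list(samples = samples, annotation = annotation, truth = truth)
}

#' Write a simulated dataset as RSEM files plus a sample sheet
#'
#' One `<sample_id>.genes.results` TSV per sample with the standard RSEM
#' gene-level header, and a `samples.csv` sample sheet. Numeric values are
#' written with 17 significant digits so that reading the files back
#' reproduces the generated values exactly.
#'
#' @param samples Named list of record data frames
#'   (from [simulate_dataset()]).
#' @param annotation Sample sheet data frame (from [simulate_dataset()]).
#' @param out_dir Output directory (created if needed).
#' @return Path to the written sample sheet, invisibly.
#' @export
write_rsem_files <- function(samples, annotation, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  header <- paste("gene_id", "transcript_id(s)", "length", "effective_length",
                  "expected_count", "TPM", "FPKM", sep = "\t")
  for (sid in annotation$sample_id) {
    rec <- samples[[sid]]
    if (is.null(rec)) stop("no records for sample '", sid, "'")
    lines <- paste(rec$gene_id, rec$transcript_ids,
                   fmt_num(rec$length), fmt_num(rec$effective_length),
                   fmt_num(rec$expected_count),
                   fmt_num(rec$tpm), fmt_num(rec$fpkm), sep = "\t")
    path <- file.path(out_dir, paste0(sid, ".genes.results"))
    con <- file(path, open = "wb")
    writeLines(c(header, lines), con)
    close(con)
  }
  sheet <- file.path(out_dir, "samples.csv")
  con <- file(sheet, open = "wb")
  writeLines(c("sample_id,model_id,passage,file_path",
               paste(annotation$sample_id, annotation$model_id,
                     annotation$passage,
                     paste0(annotation$sample_id, ".genes.results"),
                     sep = ",")), con)
  close(con)
  invisible(sheet)
}

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         sprintf("%.0f", x),
         sprintf("%.17g", x))
}
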