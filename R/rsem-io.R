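#' Read an RSEM gene-level results file
#'
#' Parses a tab-separated `*.genes.results` file as produced by RSEM. The
#' required columns are `gene_id`, `length`, `effective_length`,
#' `expected_count`, `TPM` and `FPKM`; a transcript column may be named
#' either `transcript_id(s)` or `transcript_id` and unknown extra columns
#' are ignored. Rows are returned in file order.
#'
#' @param path Path to a `*.genes.results` file.
#' @return A data frame with one row per gene and columns `gene_id`,
#'   `transcript_ids`, `length`, `effective_length`, `expected_count`,
#'   `tpm`, `fpkm`. A header-only file yields a zero-row data frame.
#' @export
read_rsem_genes <- function(path) {
  if (!file.exists(path)) stop("RSEM file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_id", "length", "effective_length",
                "expected_count", "TPM", "FPKM")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("RSEM file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tid_col <- intersect(c("transcript_id(s)", "transcript_id"), names(raw))
  tids <- if (length(tid_col) > 0) raw[[tid_col[1]]] else rep(NA_character_, nrow(raw))

  numify <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' of ", path,
           " at data row ", bad[1], ": '", raw[[col]][bad[1]], "'")
    }
    x
  }
  rec <- data.frame(
    gene_id = raw[["gene_id"]],
    transcript_ids = tids,
    length = numify("length"),
    effective_length = numify("effective_length"),
    expected_count = numify("expected_count"),
    tpm = numify("TPM"),
    fpkm = numify("FPKM"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rec$gene_id)) {
    stop("duplicated gene_id in ", path, ": ",
         rec$gene_id[anyDuplicated(rec$gene_id)])
  }
  if (nrow(rec) > 0) {
    if (any(rec$expected_count < 0)) stop("negative expected_count in ", path)
    if (any(rec$effective_length < 0)) stop("negative effective_length in ", path)
    if (any(rec$effective_length > rec$length + 1e-8)) {
      stop("effective_length exceeds length in ", path)
    }
  }
  rec
}

#' Read a sample sheet
#'
#' The sample sheet is a CSV with header
#' `sample_id,model_id,passage,file_path` mapping each sample to its model
#' (replicate group) and to its RSEM file. Relative `file_path` entries are
#' resolved against the directory containing the sheet. Row order defines
#' the replicate order used wherever "first k replicates" matters.
#'
#' @param path Path to the sample sheet CSV.
#' @return A data frame with columns `sample_id`, `model_id`, `passage`,
#'   `file_path` (absolute or sheet-relative paths resolved).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "model_id", "passage", "file_path")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         sheet$sample_id[anyDuplicated(sheet$sample_id)])
  }
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$file_path)
  sheet$file_path[rel] <- file.path(dirname(path), sheet$file_path[rel])
  sheet[, required]
}

#' Assemble a per-measure expression matrix from RSEM records
#'
#' All samples must share an identical gene set; the gene order of the first
#' sample is canonical and no sorting is applied.
#'
#' @param records_by_sample Named list of data frames as returned by
#'   [read_rsem_genes()], one per sample.
#' @param measure Which RSEM column to extract: `"expected_count"`, `"tpm"`
#'   or `"fpkm"`.
#' @return A [quant_matrix] on the linear scale whose measure is `"count"`,
#'   `"tpm"` or `"fpkm"` respectively.
#' @export
assemble_matrix <- function(records_by_sample,
                            measure = c("expected_count", "tpm", "fpkm")) {
  measure <- match.arg(measure)
  if (length(records_by_sample) == 0) stop("no samples supplied")
  if (is.null(names(records_by_sample)) || any(!nzchar(names(records_by_sample)))) {
    stop("'records_by_sample' must be a named list (names = sample ids)")
  }
  genes <- records_by_sample[[1]]$gene_id
  for (s in names(records_by_sample)) {
    g <- records_by_sample[[s]]$gene_id
    if (!setequal(g, genes)) {
      diff <- c(setdiff(genes, g), setdiff(g, genes))
      stop("sample '", s, "' has a different gene set; symmetric difference: ",
           paste(utils::head(diff, 10), collapse = ", "),
           if (length(diff) > 10) " ..." else "")
    }
  }
  vals <- vapply(records_by_sample, function(rec) {
    rec[[measure]][match(genes, rec$gene_id)]
  }, numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, names(records_by_sample)))
  out_measure <- c(expected_count = "count", tpm = "tpm", fpkm = "fpkm")[[measure]]
  quant_matrix(vals, measure = out_measure, scale = "linear")
}

#' Effective-length vector from RSEM records
#'
#' @param records A data frame from [read_rsem_genes()].
#' @return Named numeric vector of effective lengths (bases), named by
#'   gene_id.
#' @export
effective_lengths <- function(records) {
  stats::setNames(records$effective_length, records$gene_id)
}

#' Load all RSEM files referenced by a sample sheet
#'
#' @param sheet Data frame from [read_sample_sheet()].
#' @return Named list of record data frames, in sheet order.
#' @export
read_rsem_cohort <- function(sheet) {
  recs <- lapply(sheet$file_path, read_rsem_genes)
  names(recs) <- sheet$sample_id
  recs
}
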