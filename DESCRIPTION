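Package: quantbench
Title: Benchmarking RNA-Seq Quantification Measures on Replicate Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well RNA-seq quantification measures (TPM,
    FPKM, median-of-ratios normalized counts, TMM normalized counts, and
    Z-scores of TPM) preserve agreement among replicate samples. Reads RSEM
    gene-level result files, recomputes TPM/FPKM from expected counts and
    effective lengths, implements median-of-ratios and weighted trimmed mean
    of M-values (TMM) scaling factors from first principles, performs
    Ward-linkage hierarchical clustering of samples under 1-Pearson and
    Euclidean dissimilarities, and summarizes replicate concordance via
    discordant-model counts, maximum dendrogram heights, per-model coefficient
    of variation, and one-way intraclass correlation coefficients (per model
    across genes and per gene across models). A synthetic-data generator
    emulates the replicate structure of patient-derived xenograft RNA-seq
    experiments, including dominant ribosomal/mitochondrial-like transcripts
    whose variable abundance skews compositional measures, so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    edgeR,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
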