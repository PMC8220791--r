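#' Sample-sample dissimilarity matrices
#'
#' `pearson_dissimilarity` computes \eqn{d_{ij} = 1 - r_{ij}} where
#' \eqn{r_{ij}} is the Pearson correlation between sample columns over all
#' genes (range [0, 2]). `euclidean_dissimilarity` computes the Euclidean
#' distance between sample columns.
#'
#' @param x A [quant_matrix] with >= 2 samples.
#' @return A `quant_dissim` object: list with `d` (symmetric matrix with
#'   zero diagonal, sample ids as dimnames) and `metric`.
#' @export
pearson_dissimilarity <- function(x) {
  v <- dissim_input(x)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  new_quant_dissim(d, "one_minus_pearson")
}

#' @rdname pearson_dissimilarity
#' @export
euclidean_dissimilarity <- function(x) {
  v <- dissim_input(x)
  d <- as.matrix(stats::dist(t(v), method = "euclidean"))
  new_quant_dissim(d, "euclidean")
}

dissim_input <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (ncol(x$values) < 2) stop("need >= 2 samples")
  x$values
}

new_quant_dissim <- function(d, metric) {
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(d = d, metric = metric), class = "quant_dissim")
}

#' @export
print.quant_dissim <- function(x, ...) {
  cat(sprintf("quant_dissim [%s] over %d samples\n", x$metric, nrow(x$d)))
  invisible(x)
}

#' Agglomerative clustering with Ward.D2 or complete linkage
#'
#' Under the Ward.D2 convention the algorithm operates on squared
#' dissimilarities: at each step the pair of clusters with the smallest
#' current criterion is merged and the criterion is updated by the
#' Lance-Williams recurrence
#' \deqn{d^2(k, i \cup j) = \frac{(n_i + n_k) d_{ki}^2 + (n_j + n_k) d_{kj}^2
#'       - n_k d_{ij}^2}{n_i + n_j + n_k},}
#' with merge heights reported on the unsquared scale. Ties are broken
#' deterministically by the smallest (row, column) index pair in the
#' current sample ordering. Heights need not be monotone when the input
#' dissimilarity is not Euclidean (e.g. 1-Pearson), and no monotonicity is
#' enforced.
#'
#' @param d A `quant_dissim` object or a symmetric numeric matrix with
#'   sample-id dimnames.
#' @param linkage `"ward"` (Ward.D2) or `"complete"`.
#' @return A `quant_dendrogram`: list with `merge` (hclust-style signed
#'   matrix), `height`, `labels`, `order`, `method`, `metric`.
#' @export
ward_linkage <- function(d, linkage = c("ward", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "quant_dissim")) {
    metric <- d$metric
    d <- d$d
  } else {
    metric <- "unknown"
  }
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("'d' must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("'d' must be symmetric")
  n <- nrow(d)
  if (n < 2) stop("need >= 2 samples to cluster")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  work <- if (linkage == "ward") d^2 else d
  diag(work) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)            # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- lapply(seq_len(n), identity)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- idx[hit[1, 1]]
    j <- idx[hit[1, 2]]
    height[step] <- if (linkage == "ward") sqrt(best) else best
    merge[step, ] <- order_merge_pair(code[i], code[j])
    for (k in idx) {
      if (k == i || k == j) next
      work[k, i] <- work[i, k] <- if (linkage == "ward") {
        ((sizes[i] + sizes[k]) * work[k, i] + (sizes[j] + sizes[k]) * work[k, j] -
           sizes[k] * best) / (sizes[i] + sizes[j] + sizes[k])
      } else {
        max(work[k, i], work[k, j])
      }
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    code[i] <- step
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
  }

  ord <- dendrogram_leaf_order(merge)
  structure(list(merge = merge, height = height, labels = labels, order = ord,
                 method = if (linkage == "ward") "ward.D2" else "complete",
                 metric = metric),
            class = "quant_dendrogram")
}

# hclust merge rows list leaves (negative) before internal nodes (positive);
# two leaves ascending by index, two nodes ascending by step.
order_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
  else if (a > 0 && b > 0) sort(c(a, b))
  else c(min(a, b), max(a, b))
}

dendrogram_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.quant_dendrogram <- function(x, ...) {
  cat(sprintf("quant_dendrogram [%s, %s]: %d leaves, max height %.4g\n",
              x$method, x$metric, length(x$labels), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.quant_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$metric),
            class = "hclust")
}

#' Leaf sets of every internal node
#'
#' @param dend A `quant_dendrogram`.
#' @return List (one element per merge) of character vectors of leaf labels.
#' @export
clade_leaf_sets <- function(dend) {
  stopifnot(inherits(dend, "quant_dendrogram"))
  sets <- vector("list", nrow(dend$merge))
  for (s in seq_len(nrow(dend$merge))) {
    get_side <- function(v) if (v < 0) dend$labels[-v] else sets[[v]]
    sets[[s]] <- c(get_side(dend$merge[s, 1]), get_side(dend$merge[s, 2]))
  }
  sets
}

#' Discordant models in a dendrogram
#'
#' A model (replicate group) is concordant iff some internal node's leaf
#' set equals exactly that model's replicate set (an exclusive clade); a
#' single-replicate model is trivially concordant. The discordant-model
#' count is the number of models failing this.
#'
#' @param dend A `quant_dendrogram` whose leaves are sample ids.
#' @param groups Data frame with columns `sample_id` and `model_id`.
#' @return List with `count` (integer) and `discordant_ids` (character).
#' @export
discordant_models <- function(dend, groups) {
  stopifnot(inherits(dend, "quant_dendrogram"))
  groups <- as_grouping(groups)
  unassigned <- setdiff(dend$labels, groups$sample_id)
  if (length(unassigned) > 0) {
    stop("leaf/leaves without model assignment: ",
         paste(unassigned, collapse = ", "))
  }
  sets <- clade_leaf_sets(dend)
  models <- unique(groups$model_id)
  disc <- vapply(models, function(m) {
    reps <- groups$sample_id[groups$model_id == m]
    reps <- intersect(reps, dend$labels)
    if (length(reps) <= 1) return(FALSE)
    !any(vapply(sets, function(s) {
      length(s) == length(reps) && setequal(s, reps)
    }, logical(1)))
  }, logical(1))
  list(count = sum(disc), discordant_ids = models[disc])
}

as_grouping <- function(groups) {
  if (!is.data.frame(groups) || !all(c("sample_id", "model_id") %in% names(groups))) {
    stop("'groups' must be a data frame with columns sample_id and model_id")
  }
  groups
}

#' Maximum merge height of a dendrogram
#'
#' Under Ward linkage this is the height of the root merge; for 1-Pearson
#' input it is not bounded by 2.
#'
#' @param dend A `quant_dendrogram`.
#' @return Numeric scalar.
#' @export
max_height <- function(dend) {
  stopifnot(inherits(dend, "quant_dendrogram"))
  max(dend$height)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights via [ape::as.phylo()].
#'
#' @param dend A `quant_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(dend, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export requires the 'ape' package")
  }
  phy <- ape::as.phylo(as.hclust.quant_dendrogram(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Merge table of a dendrogram as a data frame
#'
#' @param dend A `quant_dendrogram`.
#' @return Data frame with columns `cluster_a`, `cluster_b`, `height`,
#'   `size` (leaves in the merged cluster).
#' @export
merge_table <- function(dend) {
  stopifnot(inherits(dend, "quant_dendrogram"))
  sizes <- vapply(clade_leaf_sets(dend), length, integer(1))
  data.frame(cluster_a = dend$merge[, 1], cluster_b = dend$merge[, 2],
             height = dend$height, size = sizes)
}
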