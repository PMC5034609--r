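#' Merge nearby CpGs into regions
#'
#' Single-linkage chaining per chromosome: consecutive CpGs whose positions
#' differ by less than `cfg$merge_gap` bp (strictly) join one region; a gap
#' equal to `merge_gap` splits. The region value per sample is the
#' unweighted mean of its member CpGs' methylation fractions.
#'
#' @param m A filtered [methylome()].
#' @param cfg [analysis_config()].
#' @return A list of class `region_matrix`: `regions` (tibble `chrom`,
#'   `start`, `end`, `n_cpgs`) and `values` (regions x samples numeric
#'   matrix of mean methylation fractions).
#' @export
merge_cpg_regions <- function(m, cfg = analysis_config()) {
  cfg <- as_config(cfg)
  ord <- order(m$sites$chrom, m$sites$pos)
  chrom <- m$sites$chrom[ord]
  pos <- m$sites$pos[ord]
  frac <- meth_fractions(m)[ord, , drop = FALSE]

  new_chrom <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  gap_split <- c(TRUE, diff(pos) >= cfg$merge_gap)
  region_id <- cumsum(new_chrom | gap_split)

  regions <- tibble(chrom = chrom, pos = pos, region = region_id) %>%
    group_by(.data$region) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$pos),
              end = max(.data$pos), n_cpgs = n(), .groups = "drop") %>%
    select("chrom", "start", "end", "n_cpgs")

  values <- rowsum(frac, region_id, reorder = TRUE) / regions$n_cpgs
  rownames(values) <- NULL
  colnames(values) <- m$samples$sample_id
  structure(list(regions = regions, values = values),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("<region_matrix> %d regions x %d samples (%d CpGs merged)\n",
              nrow(x$regions), ncol(x$values), sum(x$regions$n_cpgs)))
  invisible(x)
}

#' Principal component embedding of samples
#'
#' Centers features (rows) without scaling — methylation fractions share a
#' scale — and decomposes the feature x sample matrix, returning per-sample
#' coordinates. Zero-variance features are dropped first.
#'
#' @param values Numeric features x samples matrix.
#' @param n_components Number of components to keep (at most samples - 1).
#' @return A list of class `sample_pca`: `scores` (tibble `sample_id`,
#'   `PC1`, ...) and `explained` (variance fractions, non-increasing).
#' @export
pca_embed <- function(values, n_components = 2L) {
  if (ncol(values) < 2) abort("need >= 2 samples")
  if (n_components > ncol(values) - 1) {
    abort("n_components must be <= samples - 1")
  }
  keep <- apply(values, 1, function(r) stats::var(r) > 0)
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0) {
    abort("all features have zero variance across samples")
  }
  fit <- prcomp(t(values), center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  if (total_var == 0) abort("no variance among samples")
  explained <- (fit$sdev^2 / total_var)[seq_len(n_components)]
  scores <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble(sample_id = colnames(values) %||% paste0("S", seq_len(ncol(values)))),
    scores
  )
  structure(list(scores = scores, explained = explained),
            class = "sample_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("<sample_pca> %d samples, variance explained: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.sample_pca <- function(x, ...) x$scores

#' Hierarchically cluster samples
#'
#' Average-linkage agglomerative clustering of the columns of a feature x
#' sample matrix, under euclidean distance or one minus Pearson correlation.
#' The tree is deterministic given the input column order.
#'
#' @param values Numeric features x samples matrix.
#' @param k Number of flat clusters to cut (optional).
#' @param distance `"euclidean"` or `"correlation"`.
#' @return A list of class `sample_clustering`: `tree` (an
#'   [stats::hclust()] object) and, when `k` is given, `labels` (tibble
#'   `sample_id`, `cluster`).
#' @export
hierarchical_cluster <- function(values, k = NULL,
                                 distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  if (ncol(values) < 2) abort("need >= 2 samples")
  d <- if (distance == "euclidean") {
    dist(t(values))
  } else {
    stats::as.dist(1 - cor(values))
  }
  tree <- hclust(d, method = "average")
  out <- list(tree = tree, distance = distance)
  if (!is.null(k)) {
    if (k < 1 || k > ncol(values)) abort("k must be in 1..n_samples")
    cl <- cutree(tree, k = k)
    out$labels <- tibble(
      sample_id = colnames(values) %||% paste0("S", seq_len(ncol(values))),
      cluster = unname(cl)
    )
  }
  structure(out, class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("<sample_clustering> %d samples, average linkage, %s distance\n",
              length(x$tree$order), x$distance))
  if (!is.null(x$labels)) {
    cat("  clusters:", paste(x$labels$cluster, collapse = " "), "\n")
  }
  invisible(x)
}

#' Agreement between a clustering and known groups
#'
#' Adjusted Rand index between two partitions of the same samples; 1 for
#' identical partitions up to relabeling, around 0 for random agreement.
#'
#' @param labels Vector of cluster assignments.
#' @param truth_groups Vector of reference group labels, same length.
#' @return The adjusted Rand index (numeric scalar in \[-1, 1\]).
#' @export
grouping_agreement <- function(labels, truth_groups) {
  if (length(labels) != length(truth_groups)) {
    abort("labels and truth_groups must have equal length")
  }
  mclust::adjustedRandIndex(labels, truth_groups)
}
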