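#' Genes consistently differentially methylated across timepoints
#'
#' Intersects per-timepoint DMP calls: a gene is retained only when it is a
#' called DMP at every supplied timepoint with the same direction
#' throughout (the consistently hyper- or hypomethylated gene set).
#'
#' @param dmp_lists Named list of DMP tibbles from [call_dmps()], one per
#'   timepoint (names are the timepoint labels).
#' @return A tibble `gene_id`, `direction`, `mean_delta` (averaged over
#'   timepoints) plus one `delta_<timepoint>` column per input, of class
#'   `consistent_gene_set` with a `timepoints` attribute.
#' @export
consistent_dmps <- function(dmp_lists) {
  if (length(dmp_lists) < 2) abort("need DMP calls from >= 2 timepoints")
  if (is.null(names(dmp_lists)) || any(names(dmp_lists) == "")) {
    names(dmp_lists) <- paste0("t", seq_along(dmp_lists))
  }

  stacked <- purrr::imap_dfr(dmp_lists, function(dmps, tp) {
    mutate(dmps, timepoint = tp)
  })
  out <- stacked %>%
    group_by(.data$gene_id) %>%
    filter(n() == length(dmp_lists),
           dplyr::n_distinct(.data$direction) == 1) %>%
    summarise(
      direction = .data$direction[1],
      mean_delta = mean(.data$mean_delta),
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id)

  deltas <- stacked %>%
    filter(.data$gene_id %in% out$gene_id) %>%
    select("gene_id", "timepoint", "mean_delta") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "mean_delta",
                       names_prefix = "delta_")
  out <- left_join(out, deltas, by = "gene_id")
  attr(out, "timepoints") <- names(dmp_lists)
  class(out) <- c("consistent_gene_set", class(out))
  out
}

#' Hypergeometric gene-family enrichment
#'
#' Upper-tail hypergeometric test for over-representation of a gene family
#' (e.g. Hox transcription factors) inside a gene set, against a stated
#' universe: `p = P(X >= hits)` with
#' `X ~ Hypergeometric(universe, family, set)`.
#'
#' @param set_genes Character vector, the gene set of interest.
#' @param family_genes Character vector, the family being tested.
#' @param universe_genes Character vector, the universe both are drawn from
#'   (conventionally, genes whose promoter has at least one analyzable CpG).
#' @return A one-row tibble of class `enrichment_result`: `universe_size`,
#'   `family_size`, `set_size`, `hits_in_set`, `p`.
#' @export
hypergeometric_enrichment <- function(set_genes, family_genes,
                                      universe_genes) {
  universe_genes <- unique(universe_genes)
  set_genes <- unique(set_genes)
  family_genes <- unique(family_genes)
  if (!all(set_genes %in% universe_genes)) {
    abort("gene set contains genes outside the universe")
  }
  if (!all(family_genes %in% universe_genes)) {
    abort("gene family contains genes outside the universe")
  }
  hits <- length(intersect(set_genes, family_genes))
  res <- tibble(
    universe_size = length(universe_genes),
    family_size = length(family_genes),
    set_size = length(set_genes),
    hits_in_set = hits,
    p = phyper(hits - 1, length(family_genes),
               length(universe_genes) - length(family_genes),
               length(set_genes), lower.tail = FALSE)
  )
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(p.value = x$p, hits = x$hits_in_set,
         expected = x$family_size * x$set_size / x$universe_size)
}

#' Drop genes with negligible expression everywhere
#'
#' A gene is retained when its FPKM reaches `cfg$min_fpkm` in at least one
#' sample (i.e. genes with FPKM below the threshold in all samples are
#' removed). When gene models are supplied, the table is additionally
#' restricted to genes on the configured autosomes.
#'
#' @param expr Wide expression tibble from [read_expression_table()].
#' @param cfg [analysis_config()].
#' @param genes Optional gene-model tibble used to restrict to autosomal
#'   genes.
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(expr, cfg = analysis_config(), genes = NULL) {
  cfg <- as_config(cfg)
  if (nrow(expr) == 0) return(expr)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  keep <- apply(vals, 1, max) >= cfg$min_fpkm
  out <- expr[keep, , drop = FALSE]
  if (!is.null(genes)) {
    autosomal <- genes$gene_id[genes$chrom %in% cfg$autosomes]
    out <- filter(out, .data$gene_id %in% autosomal)
  }
  out
}

#' Log2 fold change of expression between two samples
#'
#' `log2((FPKM_target + 1) / (FPKM_reference + 1))`, with a pseudocount of
#' 1 to tame low-expression genes.
#'
#' @param expr Wide expression tibble.
#' @param target,reference Sample column names.
#' @return A tibble `gene_id`, `lfc`.
#' @export
expression_lfc <- function(expr, target, reference) {
  if (!all(c(target, reference) %in% names(expr))) {
    abort("target/reference sample not in the expression table")
  }
  tibble(
    gene_id = expr$gene_id,
    lfc = log2((expr[[target]] + 1) / (expr[[reference]] + 1))
  )
}

#' Correlate promoter methylation change with expression change
#'
#' Spearman rank correlation between per-gene promoter methylation
#' differences and expression log2 fold changes, over the genes present in
#' both inputs, with a permutation p-value (expression labels permuted, a
#' fixed seed, two-sided on |rho|).
#'
#' @param promoter_deltas Tibble `gene_id`, `delta` (promoter methylation
#'   difference, fraction).
#' @param expression_lfc Tibble `gene_id`, `lfc` (log2 fold change).
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Seed for the permutation draw.
#' @return A list of class `meth_expr_cor`: `rho`, `p`, `n`, `n_ties`, and
#'   the joined `genes` tibble.
#' @export
methylation_expression_correlation <- function(promoter_deltas,
                                               expression_lfc,
                                               n_perm = 10000L,
                                               seed = 1L) {
  joined <- inner_join(promoter_deltas, expression_lfc, by = "gene_id")
  if (nrow(joined) < 3) abort("need >= 3 genes shared between inputs")

  rx <- rank(joined$delta)
  ry <- rank(joined$lfc)
  rho <- cor(rx, ry)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- matrix(0, nrow(joined), n_perm)
  for (k in seq_len(n_perm)) perm[, k] <- sample(ry)
  rho_perm <- as.numeric(cor(rx, perm))
  p <- (1 + sum(abs(rho_perm) >= abs(rho))) / (n_perm + 1)

  ties <- joined$gene_id[duplicated(joined$delta) | duplicated(joined$lfc)]
  structure(
    list(rho = rho, p = p, n = nrow(joined),
         n_ties = length(unique(ties)), n_perm = n_perm, genes = joined),
    class = "meth_expr_cor"
  )
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  cat(sprintf(
    "<meth_expr_cor> Spearman rho = %.3f, permutation p = %.2g (n = %d genes, %d permutations)\n",
    x$rho, x$p, x$n, x$n_perm))
  invisible(x)
}

#' @export
tidy.meth_expr_cor <- function(x, ...) x$genes

#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble(rho = x$rho, p.value = x$p, n = x$n, n_perm = x$n_perm)
}

# keep user RNG state untouched by seeded internals
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
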