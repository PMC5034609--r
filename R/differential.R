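#' Vectorized two-sided Fisher exact test for 2x2 count tables
#'
#' For each table `[[a, b], [c, d]]` (methylated/unmethylated reads in the
#' target and reference sample), the two-sided p-value is the sum of
#' hypergeometric probabilities, over all tables with the same margins, of
#' every table whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7, the same two-sidedness rule as
#' [stats::fisher.test()]). Tables with an all-zero margin give p = 1.
#'
#' The routine is vectorized over tables: per-CpG testing runs over tens of
#' thousands of sites, where one `fisher.test()` call per site would
#' dominate the pipeline's runtime.
#'
#' @param a,b,c,d Non-negative integer vectors of equal length.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)     # symmetric table -> 1
#' fisher_exact_two_sided(10, 0, 0, 10)   # extreme table
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) abort("counts must be non-negative")
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (n == 0) return(numeric(0))

  n1 <- a + b            # target depth
  K <- a + c             # methylated margin
  N <- a + b + c + d
  lo <- pmax(0L, K - (c + d))
  hi <- pmin(K, n1)

  degenerate <- K == 0 | K == N | n1 == 0 | n1 == N
  p <- rep(1, n)
  idx <- which(!degenerate)
  if (length(idx) == 0) return(p)

  len <- hi[idx] - lo[idx] + 1L
  tab <- rep(idx, len)
  ks <- sequence(len) - 1L + lo[tab]
  dens <- dhyper(ks, K[tab], N[tab] - K[tab], n1[tab])
  p_obs <- dhyper(a[idx], K[idx], N[idx] - K[idx], n1[idx])
  keep <- dens <= rep(p_obs, len) * (1 + 1e-7)
  sums <- rowsum(dens * keep, group = tab, reorder = FALSE)
  p[unique(tab)] <- pmin(as.numeric(sums), 1)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up rule
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} (capped at 1), returned in
#' input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Call differentially methylated CpGs between two samples
#'
#' Implements the per-CpG differential recipe: only CpGs whose methylation
#' difference between the pair is at least `cfg$min_diff` enter a two-sided
#' Fisher exact test on the read counts; p-values are BH-adjusted over
#' exactly that tested set; a CpG is significant when additionally
#' `q < cfg$alpha`. Delta is `fraction(target) - fraction(reference)` on the
#' aggregate counts, and `hyper` means delta > 0 for the named target.
#'
#' @param m A filtered [methylome()] containing both samples.
#' @param target,reference Sample identifiers.
#' @param cfg [analysis_config()].
#' @param label Optional comparison label carried into the result.
#' @return A tibble of tested CpGs: `chrom`, `pos`, `frac_target`,
#'   `frac_reference`, `delta`, `p`, `q`, `direction`, `significant`
#'   (and `label` when given).
#' @export
call_dmcs <- function(m, target, reference, cfg = analysis_config(),
                      label = NULL) {
  cfg <- as_config(cfg)
  if (identical(target, reference)) abort("target and reference must differ")
  jt <- match(target, m$samples$sample_id)
  jr <- match(reference, m$samples$sample_id)
  if (is.na(jt) || is.na(jr)) {
    abort(sprintf("sample '%s' not in the methylome",
                  if (is.na(jt)) target else reference))
  }

  ft <- m$meth[, jt] / m$depth[, jt]
  fr <- m$meth[, jr] / m$depth[, jr]
  delta <- ft - fr
  tested <- which(abs(delta) >= cfg$min_diff)

  out <- tibble(
    chrom = m$sites$chrom[tested],
    pos = m$sites$pos[tested],
    frac_target = ft[tested],
    frac_reference = fr[tested],
    delta = delta[tested]
  )
  out$p <- fisher_exact_two_sided(
    m$meth[tested, jt], m$depth[tested, jt] - m$meth[tested, jt],
    m$meth[tested, jr], m$depth[tested, jr] - m$meth[tested, jr]
  )
  out$q <- bh_adjust(out$p)
  out$direction <- dplyr::case_when(
    out$delta > 0 ~ "hyper",
    out$delta < 0 ~ "hypo",
    TRUE ~ NA_character_
  )
  out$significant <- abs(out$delta) >= cfg$min_diff & out$q < cfg$alpha &
    !is.na(out$direction)
  if (!is.null(label)) out$label <- label
  out
}

#' Call differentially methylated promoters from DMC records
#'
#' A promoter is a DMP when it contains at least `cfg$min_dmcs_per_dmp`
#' significant CpGs that all share one direction (all hypermethylated or
#' all hypomethylated). With `cfg$dmp_mode = "majority"` the majority
#' direction is called instead, provided it alone reaches the count
#' threshold. A CpG inside two genes' promoters contributes to both.
#'
#' @param dmcs DMC tibble from [call_dmcs()] for one comparison.
#' @param catalog [build_feature_catalog()] (its `promoters` table is used).
#' @param cfg [analysis_config()].
#' @return A tibble of called DMPs: `gene_id`, `n_sig_cpgs`, `direction`,
#'   `mean_delta` (over the direction's significant CpGs), `covered_cpgs`
#'   (tested CpGs inside the promoter).
#' @export
call_dmps <- function(dmcs, catalog, cfg = analysis_config()) {
  cfg <- as_config(cfg)
  stopifnot(inherits(catalog, "feature_catalog"))
  empty <- tibble(gene_id = character(), n_sig_cpgs = integer(),
                  direction = character(), mean_delta = double(),
                  covered_cpgs = integer())
  if (nrow(dmcs) == 0 || nrow(catalog$promoters) == 0) return(empty)

  hits <- quiet_overlaps(GenomicRanges::findOverlaps,
                         gr_positions(dmcs), gr_intervals(catalog$promoters))
  if (length(hits) == 0) return(empty)
  per <- tibble(
    gene_id = catalog$promoters$gene_id[S4Vectors::subjectHits(hits)],
    delta = dmcs$delta[S4Vectors::queryHits(hits)],
    direction = dmcs$direction[S4Vectors::queryHits(hits)],
    significant = dmcs$significant[S4Vectors::queryHits(hits)]
  )

  stats_tb <- per %>%
    group_by(.data$gene_id) %>%
    summarise(
      covered_cpgs = n(),
      n_hyper = sum(.data$significant & .data$direction == "hyper"),
      n_hypo = sum(.data$significant & .data$direction == "hypo"),
      mean_delta_hyper = mean(.data$delta[.data$significant &
                                            .data$direction == "hyper"]),
      mean_delta_hypo = mean(.data$delta[.data$significant &
                                           .data$direction == "hypo"]),
      .groups = "drop"
    )

  if (cfg$dmp_mode == "strict") {
    called <- stats_tb %>%
      filter((.data$n_hyper >= cfg$min_dmcs_per_dmp & .data$n_hypo == 0) |
               (.data$n_hypo >= cfg$min_dmcs_per_dmp & .data$n_hyper == 0))
  } else {
    called <- stats_tb %>%
      filter(pmax(.data$n_hyper, .data$n_hypo) >= cfg$min_dmcs_per_dmp,
             .data$n_hyper != .data$n_hypo)
  }
  if (nrow(called) == 0) return(empty)

  called %>%
    mutate(
      direction = if_else(.data$n_hyper > .data$n_hypo, "hyper", "hypo"),
      n_sig_cpgs = if_else(.data$direction == "hyper",
                           .data$n_hyper, .data$n_hypo),
      mean_delta = if_else(.data$direction == "hyper",
                           .data$mean_delta_hyper, .data$mean_delta_hypo)
    ) %>%
    select("gene_id", "n_sig_cpgs", "direction", "mean_delta",
           "covered_cpgs") %>%
    arrange(.data$gene_id)
}

#' Two-sided binomial test for hyper/hypo dominance
#'
#' Tests whether hypermethylated CpGs outnumber hypomethylated CpGs (or
#' vice versa) beyond what a fair 50/50 split would produce.
#'
#' @param n_hyper,n_hypo Non-negative counts, not both zero.
#' @return The exact two-sided binomial p-value.
#' @export
direction_dominance_test <- function(n_hyper, n_hypo) {
  stopifnot(n_hyper >= 0, n_hypo >= 0)
  if (n_hyper + n_hypo < 1) abort("need at least one directional CpG")
  binom.test(n_hyper, n_hyper + n_hypo, p = 0.5,
             alternative = "two.sided")$p.value
}

#' Break significant DMCs down by genomic category
#'
#' @param dmcs DMC tibble from [call_dmcs()].
#' @param contexts Context tibble from [assign_genic_context()] covering
#'   every DMC position (`chrom`, `pos`, `genic`).
#' @return A tibble with one row per category (`promoter`, `exon`, `intron`,
#'   `intergenic`): `n_hyper`, `n_hypo` significant DMC counts and their
#'   `ratio` (`Inf` when `n_hypo` is 0 and `n_hyper` > 0).
#' @export
dmc_category_breakdown <- function(dmcs, contexts) {
  sig <- filter(dmcs, .data$significant)
  joined <- left_join(sig, contexts[, c("chrom", "pos", "genic")],
                      by = c("chrom", "pos"))
  if (any(is.na(joined$genic))) {
    abort("missing genic context for some significant DMC positions")
  }
  cats <- c("promoter", "exon", "intron", "intergenic")
  joined %>%
    mutate(genic = factor(.data$genic, levels = cats)) %>%
    group_by(.data$genic, .drop = FALSE) %>%
    summarise(
      n_hyper = sum(.data$direction == "hyper"),
      n_hypo = sum(.data$direction == "hypo"),
      .groups = "drop"
    ) %>%
    mutate(ratio = .data$n_hyper / .data$n_hypo) %>%
    rename(category = "genic")
}
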