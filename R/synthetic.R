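#' Parameters of the synthetic nine-sample study
#'
#' Describes the generative model behind the simulator: a bimodal per-CpG
#' baseline methylation mixture (most CpGs either lowly or highly
#' methylated), beta-binomial read counts over negative-binomial sequencing
#' depths, positive-only methylation drift during differentiation on a
#' subset of non-promoter CpGs, a white-vs-brown lineage signature on
#' non-promoter CpGs (asymmetric towards WAT hypermethylation), a small
#' norepinephrine-treatment wrinkle distinguishing treated white samples,
#' planted differentially methylated promoters shared by the WAT and BWAT
#' lineages, and gene expression responding negatively to promoter
#' methylation on top of a day-of-differentiation program shared across
#' lineages.
#'
#' @param seed Integer master seed; all downstream draws derive from it.
#' @param n_genes Number of genes in the synthetic catalog.
#' @param n_cgis Number of CpG islands.
#' @param genome_length Total genome length in bp, split over `n_chroms`
#'   autosome-named chromosomes.
#' @param n_chroms Number of chromosomes (`chr1`, `chr2`, ...).
#' @param n_cpgs Total number of CpG sites.
#' @param promoter_cpg_min,promoter_cpg_mean Per-promoter CpG count is
#'   `promoter_cpg_min + Poisson(promoter_cpg_mean - promoter_cpg_min)`.
#' @param n_planted Number of planted differentially methylated promoters.
#' @param prop_hyper Fraction of planted genes hypermethylated in WAT.
#' @param effect_size Methylation difference (fraction) planted at every
#'   promoter CpG of a planted gene, WAT/BWAT relative to BAT.
#' @param low_mean,high_mean,low_weight,baseline_conc Two-mode Beta mixture
#'   for baseline methylation: mode means, weight of the low mode, and the
#'   Beta concentration of each mode.
#' @param depth_mean,depth_size Sequencing depth is
#'   `1 + NegBinomial(mu = depth_mean - 1, size = depth_size)`.
#' @param bb_rho Beta-binomial overdispersion (intra-CpG correlation).
#' @param drift_per_day,drift_frac Differentiation adds
#'   `drift_per_day * day` to a random `drift_frac` of non-promoter CpGs in
#'   every lineage (positive-only, reproducing global hypermethylation).
#' @param lineage_frac,lineage_delta,lineage_hyper_frac Fraction of
#'   non-promoter CpGs carrying a WAT/BWAT-vs-BAT offset of size
#'   `lineage_delta`, with `lineage_hyper_frac` of them WAT-hypermethylated.
#' @param bwat_frac,bwat_delta Fraction of non-promoter CpGs with a
#'   sign-symmetric norepinephrine-treatment offset in BWAT samples only.
#' @param expression_link Slope of log2-FPKM response per unit promoter
#'   methylation deviation (negative: methylation represses).
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline log2 FPKM.
#' @param day_effect_sd Spread (log2 FPKM) of the per-gene
#'   day-of-differentiation program: every gene draws an independent effect
#'   for each sampled day, shared across lineages, so each day has its own
#'   expression signature.
#' @param expr_noise_sd Per-cell Gaussian noise on log2 FPKM.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 42L,
                            n_genes = 400L,
                            n_cgis = 200L,
                            genome_length = 60e6,
                            n_chroms = 5L,
                            n_cpgs = 50000L,
                            promoter_cpg_min = 6L,
                            promoter_cpg_mean = 14,
                            n_planted = 50L,
                            prop_hyper = 0.8,
                            effect_size = 0.3,
                            low_mean = 0.08,
                            high_mean = 0.85,
                            low_weight = 0.55,
                            baseline_conc = 8,
                            depth_mean = 30,
                            depth_size = 10,
                            bb_rho = 0.02,
                            drift_per_day = 0.02,
                            drift_frac = 0.20,
                            lineage_frac = 0.15,
                            lineage_delta = 0.40,
                            lineage_hyper_frac = 0.7,
                            bwat_frac = 0.06,
                            bwat_delta = 0.35,
                            expression_link = -4,
                            expr_baseline_mean = 3,
                            expr_baseline_sd = 2,
                            day_effect_sd = 1.0,
                            expr_noise_sd = 0.2) {
  stopifnot(
    n_genes >= 0, n_cpgs > 0, genome_length > 0, n_chroms >= 1,
    n_planted <= n_genes, effect_size >= 0, effect_size < 1,
    bb_rho > 0, bb_rho < 1, depth_mean > 1, drift_per_day >= 0,
    low_weight >= 0, low_weight <= 1,
    promoter_cpg_min >= 3, promoter_cpg_mean >= promoter_cpg_min
  )
  structure(as.list(environment()), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d: %d genes (%d planted DMPs, effect %.2f), %d CpGs, depth ~%g\n",
    x$seed, x$n_genes, x$n_planted, x$effect_size, x$n_cpgs, x$depth_mean))
  invisible(x)
}

#' Generate a synthetic gene/CGI/CpG annotation
#'
#' Places non-overlapping genes (2-8 exons each) on autosome-named
#' chromosomes, CpG islands at a fraction of promoters plus random
#' locations, and unique CpG site positions: every promoter receives at
#' least `promoter_cpg_min` CpGs and the remainder are scattered uniformly.
#' Deterministic given the seed.
#'
#' @param n_genes,n_cgis,genome_length,n_chroms,n_cpgs See
#'   [synthetic_truth()].
#' @param seed Integer seed.
#' @param promoter_cpg_min,promoter_cpg_mean Per-promoter CpG counts.
#' @param cgi_promoter_frac Fraction of islands centered on a promoter TSS.
#' @param cfg [analysis_config()] (promoter geometry).
#' @return A list: `genes` (gene-model tibble as from [read_gene_models()]),
#'   `cgis` (interval tibble), `cpg_sites` (tibble `chrom`, `pos`),
#'   `chrom_lengths` (named vector).
#' @export
generate_annotation <- function(n_genes, n_cgis, genome_length,
                                seed = 42L, n_chroms = 5L,
                                n_cpgs = 50000L,
                                promoter_cpg_min = 6L,
                                promoter_cpg_mean = 14,
                                cgi_promoter_frac = 0.6,
                                cfg = analysis_config()) {
  cfg <- as_config(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  chrom_len <- floor(genome_length / n_chroms)
  chroms <- paste0("chr", seq_len(n_chroms))
  chrom_lengths <- setNames(rep(chrom_len, n_chroms), chroms)

  empty_genes <- tibble(gene_id = character(), symbol = character(),
                        chrom = character(), strand = character(),
                        tx_start = integer(), tx_end = integer(),
                        exons = list())
  genes <- empty_genes
  if (n_genes > 0) {
    per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chroms + 1)))
    margin <- 2L * max(cfg$promoter_up, cfg$promoter_down) # promoter clearance
    gi <- 0L
    chrom_tabs <- list()
    for (ci in seq_len(n_chroms)) {
      k <- per_chrom[ci]
      if (k == 0) next
      lens <- as.integer(round(runif(k, 3000, 15000)))
      free <- chrom_len - sum(lens) - margin * (k + 1L)
      if (free < 0) {
        abort("genome too small to place the requested genes")
      }
      # random extra slack between consecutive genes; leftover stays 3'
      gaps <- diff(c(0, sort(runif(k, 0, free))))
      tx_start <- as.integer(round(
        margin + 1 + cumsum(gaps) + cumsum(c(0, lens[-k] + margin))
      ))
      tx_end <- tx_start + lens - 1L
      ids <- sprintf("G%04d", gi + seq_len(k))
      gi <- gi + k
      chrom_tabs[[ci]] <- tibble(
        gene_id = ids, symbol = ids, chrom = chroms[ci],
        strand = sample(c("+", "-"), k, replace = TRUE),
        tx_start = tx_start, tx_end = tx_end,
        exons = purrr::map2(tx_start, tx_end, make_exons)
      )
    }
    genes <- bind_rows(chrom_tabs)
  }

  # CpG islands: a fraction centered at promoters, the rest uniform
  cgis <- tibble(chrom = character(), start = integer(), end = integer())
  if (n_cgis > 0) {
    n_at_prom <- min(round(cgi_promoter_frac * n_cgis), nrow(genes))
    widths <- as.integer(round(runif(n_cgis, 300, 1500)))
    rows <- list()
    if (n_at_prom > 0) {
      picked <- sample(nrow(genes), n_at_prom)
      tss <- if_else(genes$strand[picked] == "+",
                     genes$tx_start[picked], genes$tx_end[picked])
      rows[[1]] <- tibble(
        chrom = genes$chrom[picked],
        start = pmax(tss - widths[seq_len(n_at_prom)] %/% 2L, 1L)
      ) %>% mutate(end = .data$start + widths[seq_len(n_at_prom)] - 1L)
    }
    n_rand <- n_cgis - n_at_prom
    if (n_rand > 0) {
      w <- widths[n_at_prom + seq_len(n_rand)]
      ch <- sample(chroms, n_rand, replace = TRUE)
      st <- as.integer(floor(runif(n_rand, 1, chrom_len - max(w))))
      rows[[2]] <- tibble(chrom = ch, start = st, end = st + w - 1L)
    }
    cgis <- bind_rows(rows) %>% arrange(.data$chrom, .data$start)
  }

  # CpG sites: seed every promoter, scatter the rest genome-wide
  prom_sites <- tibble(chrom = character(), pos = integer())
  if (nrow(genes) > 0) {
    plus <- genes$strand == "+"
    tss <- if_else(plus, genes$tx_start, genes$tx_end)
    p_start <- if_else(plus, tss - cfg$promoter_up, tss - cfg$promoter_down + 1L)
    p_end <- if_else(plus, tss + cfg$promoter_down - 1L, tss + cfg$promoter_up)
    counts <- promoter_cpg_min +
      rpois(nrow(genes), promoter_cpg_mean - promoter_cpg_min)
    prom_sites <- purrr::map_dfr(seq_len(nrow(genes)), function(g) {
      tibble(chrom = genes$chrom[g],
             pos = sort(sample(seq(p_start[g], p_end[g]), counts[g])))
    })
  }
  n_bg <- n_cpgs - nrow(prom_sites)
  if (n_bg < 0) abort("n_cpgs smaller than the promoter-seeded CpG count")
  sites <- prom_sites
  while (nrow(sites) < n_cpgs) {
    need <- n_cpgs - nrow(sites)
    extra <- tibble(
      chrom = sample(chroms, ceiling(need * 1.05), replace = TRUE),
      pos = as.integer(floor(runif(ceiling(need * 1.05), 1, chrom_len)))
    )
    sites <- distinct(bind_rows(sites, extra), .data$chrom, .data$pos)
    if (nrow(sites) > n_cpgs) {
      sites <- bind_rows(prom_sites,
                         dplyr::anti_join(sites, prom_sites,
                                          by = c("chrom", "pos")) %>%
                           dplyr::slice_head(n = n_cpgs - nrow(prom_sites)))
    }
  }
  sites <- arrange(sites, .data$chrom, .data$pos)

  list(genes = genes, cgis = cgis, cpg_sites = sites,
       chrom_lengths = chrom_lengths)
}

make_exons <- function(tx_start, tx_end) {
  n_ex <- sample(2:8, 1)
  width <- tx_end - tx_start + 1L
  if (width < 2L * n_ex + 2L) n_ex <- 2L
  cuts <- sort(sample(seq(tx_start + 1L, tx_end - 1L), 2L * (n_ex - 1L)))
  starts <- c(tx_start, cuts[seq(2, length(cuts), by = 2)] + 1L)
  ends <- c(cuts[seq(1, length(cuts), by = 2)], tx_end)
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Generate the nine-sample synthetic methylome
#'
#' Draws per-CpG baseline methylation from the two-mode Beta mixture,
#' applies differentiation drift, the white-lineage signature, the
#' norepinephrine wrinkle and the planted promoter effects, then samples
#' beta-binomial read counts over negative-binomial depths for all nine
#' samples of the study design. Planted effects are shared by the WAT and
#' BWAT lineages (treatment does not change lineage identity).
#'
#' @param truth A [synthetic_truth()].
#' @param annotation A [generate_annotation()] result.
#' @return A list: `tables` (named list of nine call tibbles), `metas`
#'   (sample metadata), `methylome` (assembled, unfiltered), `planted`
#'   (tibble `gene_id`, `direction`, `effect_size`), `pi` (true sites x
#'   samples methylation matrix).
#' @export
generate_methylome_design <- function(truth, annotation) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed + 1L)

  metas <- study_design()
  sites <- annotation$cpg_sites
  n <- nrow(sites)

  # baseline: two-mode Beta mixture
  low <- runif(n) < truth$low_weight
  m <- if_else(low, truth$low_mean, truth$high_mean)
  pi0 <- rbeta(n, m * truth$baseline_conc, (1 - m) * truth$baseline_conc)

  # promoter membership
  catalog <- build_feature_catalog(annotation$genes, annotation$cgis)
  hits <- quiet_overlaps(GenomicRanges::findOverlaps, gr_positions(sites),
                         gr_intervals(catalog$promoters))
  prom_cpg <- S4Vectors::queryHits(hits)
  prom_gene <- catalog$promoters$gene_id[S4Vectors::subjectHits(hits)]
  in_promoter <- seq_len(n) %in% prom_cpg
  bg <- which(!in_promoter)

  # planted promoters, headroom-aware baselines
  planted <- tibble(gene_id = character(), direction = character(),
                    effect_size = double())
  if (truth$n_planted > 0 && nrow(annotation$genes) > 0) {
    picked <- sort(sample(annotation$genes$gene_id, truth$n_planted))
    dir <- if_else(runif(truth$n_planted) < truth$prop_hyper, "hyper", "hypo")
    planted <- tibble(gene_id = picked, direction = dir,
                      effect_size = truth$effect_size)
    for (g in seq_len(nrow(planted))) {
      cpgs <- prom_cpg[prom_gene == planted$gene_id[g]]
      if (planted$direction[g] == "hyper") {
        pi0[cpgs] <- runif(length(cpgs), 0.10, 0.95 - truth$effect_size)
      } else {
        pi0[cpgs] <- runif(length(cpgs), 0.05 + truth$effect_size, 0.90)
      }
    }
  }

  # effect assignments on non-promoter CpGs
  drift_set <- sample(bg, round(truth$drift_frac * length(bg)))
  lin_set <- sample(bg, round(truth$lineage_frac * length(bg)))
  lin_sign <- if_else(runif(length(lin_set)) < truth$lineage_hyper_frac, 1, -1)
  bwat_set <- sample(bg, round(truth$bwat_frac * length(bg)))
  bwat_sign <- sample(c(-1, 1), length(bwat_set), replace = TRUE)

  planted_cpgs <- lapply(seq_len(nrow(planted)), function(g) {
    prom_cpg[prom_gene == planted$gene_id[g]]
  })
  planted_sign <- if_else(planted$direction == "hyper", 1, -1)

  pi <- matrix(rep(pi0, nrow(metas)), ncol = nrow(metas))
  colnames(pi) <- metas$sample_id
  for (j in seq_len(nrow(metas))) {
    day <- metas$day[j]
    white <- metas$lineage[j] %in% c("WAT", "BWAT")
    pij <- pi0
    pij[drift_set] <- pij[drift_set] + truth$drift_per_day * day
    if (white) {
      pij[lin_set] <- pij[lin_set] + lin_sign * truth$lineage_delta
      for (g in seq_along(planted_cpgs)) {
        pij[planted_cpgs[[g]]] <- pij[planted_cpgs[[g]]] +
          planted_sign[g] * truth$effect_size
      }
    }
    if (metas$lineage[j] == "BWAT") {
      pij[bwat_set] <- pij[bwat_set] + bwat_sign * truth$bwat_delta
    }
    pi[, j] <- pmin(pmax(pij, 0.01), 0.99)
  }

  # beta-binomial counts over shifted negative-binomial depths
  conc <- 1 / truth$bb_rho - 1
  depth <- matrix(
    1L + rnbinom(n * nrow(metas), size = truth$depth_size,
                 mu = truth$depth_mean - 1),
    ncol = nrow(metas)
  )
  p_cell <- matrix(
    rbeta(n * nrow(metas), as.vector(pi) * conc, (1 - as.vector(pi)) * conc),
    ncol = nrow(metas)
  )
  meth <- matrix(rbinom(n * nrow(metas), as.vector(depth), as.vector(p_cell)),
                 ncol = nrow(metas))

  tables <- lapply(seq_len(nrow(metas)), function(j) {
    mj <- meth[, j]
    dj <- depth[, j]
    t <- tibble(chrom = sites$chrom, pos = sites$pos,
                meth = mj, unmeth = dj - mj)
    attr(t, "sample_id") <- metas$sample_id[j]
    t
  })
  names(tables) <- metas$sample_id

  list(
    tables = tables, metas = metas,
    methylome = methylome(sites, metas, meth, depth),
    planted = planted, pi = pi, catalog = catalog
  )
}

#' Generate synthetic expression anti-correlated with promoter methylation
#'
#' Per gene and sample, log2 FPKM is a gene baseline plus a
#' day-of-differentiation effect shared across lineages (so transcriptomes
#' separate by day), plus `expression_link` times the sample's true promoter
#' methylation deviation from the gene's across-sample mean, plus Gaussian
#' noise; FPKM is `2^x - 1` clipped at zero.
#'
#' @param truth A [synthetic_truth()].
#' @param design A [generate_methylome_design()] result.
#' @param annotation The matching [generate_annotation()] result.
#' @return A wide expression tibble (`gene_id` + one column per sample).
#' @export
generate_expression <- function(truth, design, annotation) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed + 2L)

  genes <- annotation$genes
  metas <- design$metas
  n_g <- nrow(genes)
  if (n_g == 0) {
    return(tibble(gene_id = character()))
  }

  # true mean promoter methylation per gene x sample
  hits <- quiet_overlaps(GenomicRanges::findOverlaps,
                         gr_positions(design$methylome$sites),
                         gr_intervals(design$catalog$promoters))
  prom_meth <- rowsum(
    design$pi[S4Vectors::queryHits(hits), , drop = FALSE],
    group = design$catalog$promoters$gene_id[S4Vectors::subjectHits(hits)]
  )
  counts <- as.vector(table(
    design$catalog$promoters$gene_id[S4Vectors::subjectHits(hits)]
  )[rownames(prom_meth)])
  prom_meth <- prom_meth / counts
  prom_meth <- prom_meth[match(genes$gene_id, rownames(prom_meth)), ,
                         drop = FALSE]
  prom_meth[is.na(prom_meth)] <- 0.5
  prom_dev <- prom_meth - rowMeans(prom_meth)

  baseline <- rnorm(n_g, truth$expr_baseline_mean, truth$expr_baseline_sd)
  days <- sort(unique(metas$day))
  day_effects <- matrix(rnorm(n_g * length(days), 0, truth$day_effect_sd),
                        nrow = n_g)

  log2fpkm <- outer(baseline, rep(1, nrow(metas))) +
    day_effects[, match(metas$day, days), drop = FALSE] +
    truth$expression_link * prom_dev +
    matrix(rnorm(n_g * nrow(metas), 0, truth$expr_noise_sd), nrow = n_g)
  fpkm <- pmax(2^log2fpkm - 1, 0)
  colnames(fpkm) <- metas$sample_id
  bind_cols(tibble(gene_id = genes$gene_id), as_tibble(fpkm))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [generate_methylome_design()] and [generate_expression()] under one
#' seed. Fully deterministic given `truth`.
#'
#' @param truth A [synthetic_truth()].
#' @return A list: `truth`, `annotation`, `design` (tables, metas,
#'   methylome, planted, pi, catalog), `expression`.
#' @export
simulate_study <- function(truth = synthetic_truth()) {
  annotation <- generate_annotation(
    n_genes = truth$n_genes, n_cgis = truth$n_cgis,
    genome_length = truth$genome_length, seed = truth$seed,
    n_chroms = truth$n_chroms, n_cpgs = truth$n_cpgs,
    promoter_cpg_min = truth$promoter_cpg_min,
    promoter_cpg_mean = truth$promoter_cpg_mean
  )
  design <- generate_methylome_design(truth, annotation)
  expression <- generate_expression(truth, design, annotation)
  list(truth = truth, annotation = annotation, design = design,
       expression = expression)
}

#' Write a simulated study to disk
#'
#' Emits one counts-dialect call TSV per sample, a refFlat gene-model file,
#' a CGI BED, an FPKM TSV, a sample metadata TSV and a `truth.json`
#' bookkeeping file — everything [run_full_analysis()] needs.
#'
#' @param sim A [simulate_study()] result.
#' @param out_dir Output directory, created if needed.
#' @return Named list of file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  call_paths <- purrr::imap_chr(sim$design$tables, function(t, id) {
    p <- file.path(out_dir, paste0(id, ".calls.tsv"))
    write_cpg_calls(t, p, dialect = "counts")
    p
  })
  genes_path <- file.path(out_dir, "genes.refflat")
  write_refflat(sim$annotation$genes, genes_path)
  cgi_path <- file.path(out_dir, "cgi.bed")
  write_interval_bed(sim$annotation$cgis, cgi_path)
  expr_path <- file.path(out_dir, "fpkm.tsv")
  readr::write_tsv(sim$expression, expr_path)
  meta_path <- file.path(out_dir, "samples.tsv")
  readr::write_tsv(sim$design$metas, meta_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(
      seed = sim$truth$seed,
      planted = sim$design$planted,
      params = sim$truth[setdiff(names(sim$truth), "seed")]
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  list(calls = call_paths, genes = genes_path, cgi = cgi_path,
       expression = expr_path, samples = meta_path, truth = truth_path)
}

write_refflat <- function(genes, path) {
  lines <- purrr::map_chr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(
      genes$gene_id[i], paste0(genes$gene_id[i], ".1"), genes$chrom[i],
      genes$strand[i], genes$tx_start[i] - 1L, genes$tx_end[i],
      genes$tx_start[i] - 1L, genes$tx_end[i], nrow(ex),
      paste0(paste(ex$start - 1L, collapse = ","), ","),
      paste0(paste(ex$end, collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' Score recovery of planted differentially methylated promoters
#'
#' @param planted Tibble `gene_id`, `direction` of planted DMP genes (from
#'   `simulate_study()$design$planted`).
#' @param called Consistent-gene tibble from [consistent_dmps()] (or any
#'   tibble with `gene_id` and `direction`).
#' @return One-row tibble: `n_planted`, `n_called`, `recall`,
#'   `empirical_fdr` (NA when nothing was called), `direction_accuracy`
#'   over the recovered genes (NA when none recovered).
#' @export
evaluate_recovery <- function(planted, called) {
  recovered <- intersect(called$gene_id, planted$gene_id)
  n_called <- length(unique(called$gene_id))
  dir_ok <- if (length(recovered) > 0) {
    truth_dir <- planted$direction[match(recovered, planted$gene_id)]
    call_dir <- called$direction[match(recovered, called$gene_id)]
    mean(truth_dir == call_dir)
  } else {
    NA_real_
  }
  tibble(
    n_planted = nrow(planted),
    n_called = n_called,
    recall = if (nrow(planted) > 0) length(recovered) / nrow(planted) else NA_real_,
    empirical_fdr = if (n_called > 0) {
      (n_called - length(recovered)) / n_called
    } else {
      NA_real_
    },
    direction_accuracy = dir_ok
  )
}
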