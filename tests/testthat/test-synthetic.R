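test_that("annotation generation is valid, promoter-seeded and deterministic", {
  ann <- generate_annotation(n_genes = 30, n_cgis = 15, genome_length = 6e6,
                             seed = 1, n_chroms = 2, n_cpgs = 3000)
  expect_equal(nrow(ann$genes), 30)
  expect_true(all(ann$genes$tx_start <= ann$genes$tx_end))
  for (i in seq_len(nrow(ann$genes))) {
    ex <- ann$genes$exons[[i]]
    expect_true(all(ex$start <= ex$end))
    expect_gte(min(ex$start), ann$genes$tx_start[i])
    expect_lte(max(ex$end), ann$genes$tx_end[i])
    expect_true(all(diff(ex$start) > 0))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
  # gene bodies do not overlap within a chromosome
  by_chrom <- split(ann$genes, ann$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$tx_start), ]
    if (nrow(g) > 1) expect_true(all(g$tx_start[-1] > g$tx_end[-nrow(g)]))
  }
  expect_equal(nrow(ann$cpg_sites), 3000)
  expect_equal(nrow(dplyr::distinct(ann$cpg_sites)), 3000)

  # every promoter holds at least the minimum CpG count
  cat <- build_feature_catalog(ann$genes, ann$cgis)
  cov <- region_cpg_coverage(ann$cpg_sites, cat$promoters)
  expect_equal(cov$fraction, 1)

  ann2 <- generate_annotation(n_genes = 30, n_cgis = 15, genome_length = 6e6,
                              seed = 1, n_chroms = 2, n_cpgs = 3000)
  expect_identical(ann, ann2)
  expect_equal(nrow(generate_annotation(0, 0, 1e6, seed = 1,
                                        n_cpgs = 100)$genes), 0)
  expect_error(generate_annotation(5000, 10, 1e5, seed = 1, n_cpgs = 100),
               "too small|smaller")
})

test_that("the simulated study is fully deterministic given the seed", {
  s1 <- simulate_study(small_truth(seed = 9))
  s2 <- simulate_study(small_truth(seed = 9))
  expect_identical(s1$design$methylome$meth, s2$design$methylome$meth)
  expect_identical(s1$design$methylome$depth, s2$design$methylome$depth)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$design$planted, s2$design$planted)

  s3 <- simulate_study(small_truth(seed = 10))
  expect_false(identical(s1$design$methylome$meth, s3$design$methylome$meth))
})

test_that("written simulation files are byte-identical across reruns", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  truth <- small_truth(seed = 3, n_cpgs = 1500L, n_genes = 20L)
  write_simulation(simulate_study(truth), d1)
  write_simulation(simulate_study(truth), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # files re-enter through the package's own readers
  back <- read_cpg_calls(file.path(d1, "BAT_d0.calls.tsv"), "counts")
  expect_equal(nrow(back), 1500)
  genes <- read_gene_models(file.path(d1, "genes.refflat"), "refflat")
  expect_equal(nrow(genes), 20)
})

test_that("planted promoters show the planted effect; nulls show none", {
  truth <- small_truth(seed = 21)
  sim <- simulate_study(truth)
  cat <- sim$design$catalog
  pi <- sim$design$pi
  sites <- sim$design$methylome$sites
  wat <- which(sim$design$metas$lineage == "WAT")
  bat <- which(sim$design$metas$lineage == "BAT")

  prom_mean <- function(gid, cols) {
    p <- cat$promoters[cat$promoters$gene_id == gid, ]
    in_p <- sites$chrom == p$chrom & sites$pos >= p$start & sites$pos <= p$end
    mean(pi[in_p, cols])
  }
  for (i in seq_len(nrow(sim$design$planted))) {
    gid <- sim$design$planted$gene_id[i]
    diff <- prom_mean(gid, wat) - prom_mean(gid, bat)
    want <- ifelse(sim$design$planted$direction[i] == "hyper", 1, -1) *
      truth$effect_size
    expect_equal(diff, want, tolerance = 0.02)
  }

  # zero effect size: lineage promoter means agree in truth
  null_sim <- simulate_study(small_truth(seed = 22, effect_size = 0))
  pi0 <- null_sim$design$pi
  w <- which(null_sim$design$metas$lineage == "WAT")
  b <- which(null_sim$design$metas$lineage == "BAT")
  for (gid in null_sim$design$planted$gene_id[1:3]) {
    p <- null_sim$design$catalog$promoters[
      null_sim$design$catalog$promoters$gene_id == gid, ]
    in_p <- null_sim$design$methylome$sites$chrom == p$chrom &
      null_sim$design$methylome$sites$pos >= p$start &
      null_sim$design$methylome$sites$pos <= p$end
    expect_equal(mean(pi0[in_p, w]), mean(pi0[in_p, b]), tolerance = 1e-12)
  }
})

test_that("zero drift leaves day class profiles indistinguishable", {
  sim <- simulate_study(small_truth(seed = 31, drift_per_day = 0,
                                    n_planted = 0L, lineage_frac = 0,
                                    bwat_frac = 0))
  mf <- filter_common_autosomal(sim$design$methylome)
  frac <- meth_fractions(mf)
  bat_cols <- which(mf$samples$lineage == "BAT")
  counts <- sapply(bat_cols, function(j) {
    table(classify_meth_level(frac[, j]))
  })
  expect_gt(suppressWarnings(stats::chisq.test(counts)$p.value), 0.01)
})

test_that("expression responds to the methylation link and the day program", {
  truth <- small_truth(seed = 41)
  sim <- simulate_study(truth)
  expr <- sim$expression
  lfc <- expression_lfc(expr, "WAT_d6", "BAT_d6")
  planted <- dplyr::inner_join(sim$design$planted, lfc, by = "gene_id")
  # negative link: WAT-hypermethylated promoters are WAT-repressed
  expect_lt(mean(planted$lfc[planted$direction == "hyper"]), 0)
  expect_gt(mean(planted$lfc[planted$direction == "hypo"]), 0)

  no_link <- simulate_study(small_truth(seed = 41, expression_link = 0))
  lfc0 <- expression_lfc(no_link$expression, "WAT_d6", "BAT_d6")
  p0 <- dplyr::inner_join(no_link$design$planted, lfc0, by = "gene_id")
  grand <- abs(mean(p0$lfc[p0$direction == "hyper"]) -
                 mean(p0$lfc[p0$direction == "hypo"]))
  linked <- abs(mean(planted$lfc[planted$direction == "hyper"]) -
                  mean(planted$lfc[planted$direction == "hypo"]))
  expect_lt(grand, linked / 2)
})

test_that("recovery scoring handles perfect, empty and random callers", {
  planted <- tibble::tibble(gene_id = c("a", "b", "c"),
                            direction = c("hyper", "hyper", "hypo"))
  perfect <- evaluate_recovery(planted, planted)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$empirical_fdr, 0)
  expect_equal(perfect$direction_accuracy, 1)

  empty <- evaluate_recovery(
    planted, tibble::tibble(gene_id = character(), direction = character())
  )
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$empirical_fdr))

  wrong <- evaluate_recovery(
    planted, tibble::tibble(gene_id = c("a", "zz"),
                            direction = c("hypo", "hyper"))
  )
  expect_equal(wrong$recall, 1 / 3)
  expect_equal(wrong$empirical_fdr, 1 / 2)
  expect_equal(wrong$direction_accuracy, 0)
})

test_that("recall grows with planted effect size", {
  recall_at <- function(effect) {
    truth <- small_truth(seed = 51, effect_size = effect)
    sim <- simulate_study(truth)
    mf <- filter_common_autosomal(sim$design$methylome)
    dmps <- lapply(c(0, 4, 6), function(d) {
      call_dmps(call_dmcs(mf, paste0("WAT_d", d), paste0("BAT_d", d)),
                sim$design$catalog)
    })
    cons <- consistent_dmps(setNames(dmps, c("d0", "d4", "d6")))
    evaluate_recovery(sim$design$planted, cons)$recall
  }
  weak <- recall_at(0.08)
  strong <- recall_at(0.45)
  expect_lte(weak, strong)
  expect_gte(strong, 0.8)
})
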