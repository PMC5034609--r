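test_that("promoter and gene-body geometry follows the region definitions", {
  cat <- build_feature_catalog(toy_genes(), toy_cgis())

  plus <- cat$promoters[cat$promoters$gene_id == "plusG", ]
  expect_equal(c(plus$start, plus$end), c(9000L, 10499L))
  body <- cat$gene_bodies[cat$gene_bodies$gene_id == "plusG", ]
  expect_equal(c(body$start, body$end), c(10500L, 20000L))

  minus <- cat$promoters[cat$promoters$gene_id == "minusG", ]
  expect_equal(c(minus$start, minus$end), c(59501L, 61000L))
  expect_equal(minus$end - minus$start + 1L, 1500L)
  mbody <- cat$gene_bodies[cat$gene_bodies$gene_id == "minusG", ]
  expect_equal(c(mbody$start, mbody$end), c(50000L, 59500L))

  # promoter and body of the same gene never co-assign a position
  for (gid in c("plusG", "minusG")) {
    p <- cat$promoters[cat$promoters$gene_id == gid, ]
    b <- cat$gene_bodies[cat$gene_bodies$gene_id == gid, ]
    expect_true(p$end < b$start || b$end < p$start)
  }
})

test_that("genes shorter than the promoter tail get an empty gene body", {
  short <- tibble::tibble(
    gene_id = "tiny", symbol = "tiny", chrom = "chr1", strand = "+",
    tx_start = 5000L, tx_end = 5300L,
    exons = list(tibble::tibble(start = 5000L, end = 5300L))
  )
  cat <- build_feature_catalog(short, toy_cgis()[0, ])
  expect_equal(nrow(cat$gene_bodies), 0)
  ctx <- assign_genic_context(tibble::tibble(chrom = "chr1", pos = 5200L), cat)
  expect_equal(ctx$genic, "promoter")
})

test_that("multiple transcripts collapse to one 5'-most TSS per gene", {
  two_tx <- tibble::tibble(
    gene_id = c("g", "g"), symbol = c("g", "g"), chrom = "chr1",
    strand = "+", tx_start = c(10000L, 12000L), tx_end = c(20000L, 21000L),
    exons = list(tibble::tibble(start = 10000L, end = 20000L),
                 tibble::tibble(start = 12000L, end = 21000L))
  )
  cat <- build_feature_catalog(two_tx, toy_cgis()[0, ])
  expect_equal(nrow(cat$promoters), 1)
  expect_equal(cat$promoters$start, 9000L)
  expect_equal(cat$gene_bodies$end, 21000L)
})

test_that("CGI shores and shelves are the stated 2 kb bands", {
  cat <- build_feature_catalog(toy_genes()[0, ], toy_cgis())
  # island [10000, 11000] -> shores [8000, 9999] & [11001, 13000],
  # shelves [6000, 7999] & [13001, 15000]
  expect_equal(cat$shores$start, c(8000L, 11001L))
  expect_equal(cat$shores$end, c(9999L, 13000L))
  expect_equal(cat$shelves$start, c(6000L, 13001L))
  expect_equal(cat$shelves$end, c(7999L, 15000L))

  pos <- tibble::tibble(chrom = "chr1",
                        pos = c(10500L, 11500L, 13500L, 16000L))
  ctx <- assign_cgi_context(pos, cat)
  expect_equal(ctx$cgi, c("island", "shore", "shelf", "open_sea"))
})

test_that("island precedence beats another island's shore", {
  cgis <- tibble::tibble(chrom = "chr1", start = c(10000L, 12000L),
                         end = c(11000L, 12400L))
  cat <- build_feature_catalog(toy_genes()[0, ], cgis)
  # 12200 is in island 2 and in the shore band of island 1
  ctx <- assign_cgi_context(tibble::tibble(chrom = "chr1", pos = 12200L), cat)
  expect_equal(ctx$cgi, "island")
  # bands stay mutually disjoint
  all_bands <- dplyr::bind_rows(
    dplyr::mutate(cat$islands, band = "island"),
    dplyr::mutate(cat$shores, band = "shore"),
    dplyr::mutate(cat$shelves, band = "shelf")
  )
  for (p in seq(5000L, 17000L, by = 7L)) {
    hits <- sum(all_bands$start <= p & all_bands$end >= p)
    expect_lte(hits, 1)
  }
})

test_that("genic precedence is promoter > exon > intron > intergenic", {
  genes <- dplyr::bind_rows(
    toy_genes(),
    tibble::tibble(
      gene_id = "B", symbol = "B", chrom = "chr1", strand = "+",
      tx_start = 13000L, tx_end = 30000L,
      exons = list(tibble::tibble(start = 13000L, end = 13100L))
    )
  )
  cat <- build_feature_catalog(genes, toy_cgis())
  # 12500 is in plusG's intron and in B's promoter [12000, 13499]
  ctx <- assign_genic_context(tibble::tibble(chrom = "chr1", pos = 12500L), cat)
  expect_equal(ctx$genic, "promoter")
  expect_equal(ctx$gene_ids[[1]], "B")

  far <- assign_genic_context(tibble::tibble(chrom = "chr1", pos = 99999L), cat)
  expect_equal(far$genic, "intergenic")

  expect_warning(
    unk <- assign_genic_context(tibble::tibble(chrom = "chr99", pos = 1L), cat),
    "no annotated feature"
  )
  expect_equal(unk$genic, "intergenic")
})

test_that("every position gets exactly one genic and one cgi label", {
  cat <- build_feature_catalog(toy_genes(), toy_cgis())
  pos <- tibble::tibble(chrom = "chr1", pos = seq(5000L, 70000L, by = 97L))
  ctx <- annotate_cpgs(pos, cat)
  expect_equal(nrow(ctx), nrow(pos))
  expect_true(all(ctx$genic %in% c("promoter", "exon", "intron", "intergenic")))
  expect_true(all(ctx$cgi %in% c("island", "shore", "shelf", "open_sea")))
  expect_equal(sum(table(ctx$genic)), nrow(pos))
  expect_equal(sum(table(ctx$cgi)), nrow(pos))
})

test_that("interval assignment matches the linear-scan oracle", {
  for (seed in 1:10) {
    cat <- random_toy_catalog(seed)
    set.seed(seed + 1000)
    pos <- tibble::tibble(chrom = "chr1",
                          pos = sort(sample.int(100000L, 150L)))
    ctx <- annotate_cpgs(pos, cat)
    oracle_genic <- vapply(pos$pos, function(p) {
      genic_scan_oracle("chr1", p, cat)
    }, character(1))
    oracle_cgi <- vapply(pos$pos, function(p) {
      cgi_scan_oracle("chr1", p, cat)
    }, character(1))
    expect_equal(ctx$genic, oracle_genic)
    expect_equal(ctx$cgi, oracle_cgi)
  }
})

test_that("region coverage counts features with at least two CpGs", {
  feats <- tibble::tibble(chrom = "chr1",
                          start = c(100L, 1000L, 2000L),
                          end = c(500L, 1500L, 2500L))
  pos <- tibble::tibble(chrom = "chr1",
                        pos = c(1100L, 2100L, 2200L))  # features get 0, 1, 2
  cov <- region_cpg_coverage(pos, feats)
  expect_equal(cov$n_covered, 1L)
  expect_equal(cov$fraction, 1 / 3)

  none <- region_cpg_coverage(tibble::tibble(chrom = "chr9", pos = 1L), feats)
  expect_equal(none$fraction, 0)

  expect_error(region_cpg_coverage(pos, feats[0, ]), "empty")
})
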