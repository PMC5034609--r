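test_that("two-sided Fisher p matches hand-derived tables", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  # margins (10,10;10,10): the two extreme tables each have mass 1/C(20,10)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)  # zero meth margin
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("vectorized Fisher equals enumeration oracle and fisher.test", {
  set.seed(11)
  n_tab <- 500
  tot <- sample(4:60, n_tab, replace = TRUE)
  n1 <- vapply(tot, function(t) sample(1:(t - 1), 1), integer(1))
  a <- vapply(n1, function(x) sample(0:x, 1), integer(1))
  c_ <- vapply(tot - n1, function(x) sample(0:x, 1), integer(1))
  b <- n1 - a
  d <- tot - n1 - c_

  p_vec <- fisher_exact_two_sided(a, b, c_, d)
  p_oracle <- mapply(fisher_oracle, a, b, c_, d)
  expect_equal(p_vec, p_oracle, tolerance = 1e-7)

  p_ft <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }, a[1:100], b[1:100], c_[1:100], d[1:100])
  expect_equal(p_vec[1:100], unname(p_ft), tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("DMC calling tests only the prefiltered CpGs and flags correctly", {
  m <- toy_methylome(
    "chr1", c(100, 200, 300),
    meth = cbind(c(30, 54, 15), c(0, 50, 15)),
    depth = cbind(c(30, 100, 30), c(30, 100, 30)),
    sample_ids = c("t", "r"), lineage = c("WAT", "BAT")
  )
  dmcs <- call_dmcs(m, "t", "r")
  # site 200 has delta 0.04 and site 300 delta 0 -> excluded
  expect_equal(dmcs$pos, 100L)
  expect_equal(dmcs$delta, 1)
  expect_equal(dmcs$direction, "hyper")
  expect_true(dmcs$significant)
  expect_equal(dmcs$p, fisher_oracle(30, 0, 0, 30), tolerance = 1e-9)

  ident <- toy_methylome("chr1", 1:3, cbind(1:3, 1:3), matrix(10L, 3, 2),
                         sample_ids = c("t", "r"))
  expect_equal(nrow(call_dmcs(ident, "t", "r")), 0)
  expect_error(call_dmcs(m, "t", "t"), "differ")
  expect_error(call_dmcs(m, "t", "zz"), "not in the methylome")
})

test_that("swapping target and reference is a clean antisymmetry", {
  set.seed(31)
  n <- 400
  depth <- matrix(10L + rpois(2 * n, 20), n, 2)
  meth <- matrix(rbinom(2 * n, as.vector(depth), rep(runif(n), 2)), n, 2)
  m <- toy_methylome("chr1", seq_len(n), meth, depth,
                     sample_ids = c("t", "r"), lineage = c("WAT", "BAT"))
  fwd <- call_dmcs(m, "t", "r")
  rev <- call_dmcs(m, "r", "t")
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$q, rev$q)
  expect_equal(fwd$significant, rev$significant)
  swapped <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(fwd$direction, unname(swapped[rev$direction]))
})

test_that("DMP calling needs >= 2 significant same-direction promoter CpGs", {
  cat <- build_feature_catalog(toy_genes(), toy_cgis())
  # plusG promoter is [9000, 10499]
  base <- tibble::tibble(
    chrom = "chr1", pos = c(9100L, 9200L, 9300L, 9400L),
    frac_target = 0.8, frac_reference = 0.2, delta = 0.6,
    p = 1e-6, q = 1e-5, direction = "hyper", significant = TRUE
  )
  one_sig <- dplyr::mutate(base, significant = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(call_dmps(one_sig, cat)), 0)

  two_sig <- dplyr::mutate(base, significant = c(TRUE, TRUE, FALSE, FALSE))
  dmp <- call_dmps(two_sig, cat)
  expect_equal(dmp$gene_id, "plusG")
  expect_equal(dmp$direction, "hyper")
  expect_equal(dmp$n_sig_cpgs, 2L)
  expect_equal(dmp$covered_cpgs, 4L)
  expect_equal(dmp$mean_delta, 0.6)

  mixed <- dplyr::mutate(base,
                         delta = c(0.6, 0.6, -0.5, 0.6),
                         direction = c("hyper", "hyper", "hypo", "hyper"),
                         significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(call_dmps(mixed, cat)), 0)  # strict mode: mixed is no DMP
  maj <- call_dmps(mixed, cat, analysis_config(dmp_mode = "majority"))
  expect_equal(maj$direction, "hyper")
  expect_equal(maj$n_sig_cpgs, 2L)

  expect_equal(nrow(call_dmps(base[0, ], cat)), 0)
})

test_that("a CpG in two promoters contributes to both genes", {
  genes <- tibble::tibble(
    gene_id = c("fwd", "rev"), symbol = c("fwd", "rev"), chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 2000L), tx_end = c(20000L, 9600L),
    exons = list(tibble::tibble(start = 10000L, end = 20000L),
                 tibble::tibble(start = 2000L, end = 9600L))
  )
  cat <- build_feature_catalog(genes, toy_cgis()[0, ])
  # fwd promoter [9000, 10499]; rev promoter (TSS 9600, minus) [9101, 10600]
  dmcs <- tibble::tibble(
    chrom = "chr1", pos = c(9200L, 9300L),
    frac_target = 0.1, frac_reference = 0.6, delta = -0.5,
    p = 1e-6, q = 1e-5, direction = "hypo", significant = TRUE
  )
  dmp <- call_dmps(dmcs, cat)
  expect_setequal(dmp$gene_id, c("fwd", "rev"))
  expect_true(all(dmp$direction == "hypo"))
})

test_that("the dominance binomial test is exact and symmetric", {
  expect_equal(direction_dominance_test(5, 5), 1)
  expect_equal(direction_dominance_test(9, 1), 22 / 1024)
  expect_equal(direction_dominance_test(1, 9),
               direction_dominance_test(9, 1))
  expect_error(direction_dominance_test(0, 0), "at least one")
})

test_that("the category breakdown counts significant DMCs per context", {
  dmcs <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L, 3L, 4L, 5L, 6L),
    frac_target = 0.5, frac_reference = 0.2,
    delta = c(0.3, 0.3, 0.3, -0.3, 0.3, -0.3),
    p = 1e-5, q = 1e-4,
    direction = c("hyper", "hyper", "hyper", "hypo", "hyper", "hypo"),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  ctx <- tibble::tibble(
    chrom = "chr1", pos = 1:6,
    genic = c("promoter", "promoter", "promoter", "promoter",
              "intergenic", "intron")
  )
  bd <- dmc_category_breakdown(dmcs, ctx)
  expect_equal(sum(bd$n_hyper + bd$n_hypo), 5L)  # only significant DMCs
  prom <- bd[bd$category == "promoter", ]
  expect_equal(prom$ratio, 3)
  inter <- bd[bd$category == "intergenic", ]
  expect_equal(inter$ratio, Inf)

  expect_error(dmc_category_breakdown(dmcs, ctx[-1, ]), "missing genic")
})
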