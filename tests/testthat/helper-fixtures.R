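# small in-code fixtures shared across test files

# methylome from per-sample count lists: meth/depth are site x sample
toy_methylome <- function(chrom, pos, meth, depth,
                          sample_ids = paste0("S", seq_len(ncol(meth))),
                          lineage = rep("BAT", ncol(meth)),
                          day = rep(0L, ncol(meth))) {
  methylome(
    tibble::tibble(chrom = chrom, pos = as.integer(pos)),
    sample_meta(sample_ids, lineage, day),
    matrix(as.integer(meth), ncol = length(sample_ids)),
    matrix(as.integer(depth), ncol = length(sample_ids))
  )
}

# one plus- and one minus-strand gene with known geometry
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("plusG", "minusG"),
    symbol = c("plusG", "minusG"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    tx_start = c(10000L, 50000L),
    tx_end = c(20000L, 60000L),
    exons = list(
      tibble::tibble(start = c(10000L, 15000L), end = c(11000L, 16000L)),
      tibble::tibble(start = c(50000L, 58000L), end = c(51000L, 60000L))
    )
  )
}

toy_cgis <- function() {
  tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
}

# a random toy genome for oracle-equivalence checks
random_toy_catalog <- function(seed, genome_len = 100000L, max_genes = 20L) {
  set.seed(seed)
  n <- sample(1:max_genes, 1)
  tx_start <- sort(sample(seq(3000L, genome_len - 20000L), n))
  len <- sample(1000:8000, n, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_len(n)), symbol = paste0("g", seq_len(n)),
    chrom = "chr1", strand = sample(c("+", "-"), n, replace = TRUE),
    tx_start = tx_start, tx_end = tx_start + len,
    exons = lapply(seq_len(n), function(i) {
      mid <- tx_start[i] + (len[i] %/% 2)
      tibble::tibble(start = c(tx_start[i], mid + 100L),
                     end = c(mid - 100L, tx_start[i] + len[i]))
    })
  )
  n_cgi <- sample(1:8, 1)
  cgi_start <- sort(sample(seq(5000L, genome_len - 5000L), n_cgi))
  cgis <- tibble::tibble(chrom = "chr1", start = cgi_start,
                         end = cgi_start + sample(200:2000, n_cgi, TRUE))
  build_feature_catalog(genes, cgis)
}

# a small-but-complete synthetic study for fast tests
small_truth <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 80L, n_cgis = 40L, genome_length = 12e6,
         n_chroms = 2L, n_cpgs = 8000L, n_planted = 10L),
    list(...)
  )
  do.call(synthetic_truth, args)
}
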