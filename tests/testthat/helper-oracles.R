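# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and dhyper/p.adjust where the implementation uses them) so
# that implementation and check stay separate routes.

# two-sided Fisher p by direct enumeration with choose()
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c; N <- n1 + n2
  if (K == 0 || K == N || n1 == 0 || n2 == 0) return(1)
  ks <- max(0, K - n2):min(K, n1)
  probs <- choose(K, ks) * choose(N - K, n1 - ks) / choose(N, n1)
  p_obs <- choose(K, a) * choose(N - K, n1 - a) / choose(N, n1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# BH step-up by the textbook formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# upper-tail hypergeometric by pmf summation with choose()
hyper_tail_oracle <- function(hits, family, universe, set) {
  ks <- hits:min(family, set)
  sum(choose(family, ks) * choose(universe - family, set - ks) /
        choose(universe, set))
}

# adjusted Rand index from the contingency-table formula
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(0)
  (sij - expected) / denom
}

# per-position linear scan over all features: the annotation oracle
genic_scan_oracle <- function(chrom, pos, catalog) {
  inside <- function(tb) {
    any(tb$chrom == chrom & tb$start <= pos & tb$end >= pos)
  }
  if (inside(catalog$promoters)) return("promoter")
  if (inside(catalog$exons)) return("exon")
  if (inside(catalog$gene_bodies)) return("intron")
  "intergenic"
}

cgi_scan_oracle <- function(chrom, pos, catalog) {
  inside <- function(tb) {
    any(tb$chrom == chrom & tb$start <= pos & tb$end >= pos)
  }
  if (inside(catalog$islands)) return("island")
  if (inside(catalog$shores)) return("shore")
  if (inside(catalog$shelves)) return("shelf")
  "open_sea"
}
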