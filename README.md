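# methdyn

Differential DNA methylation dynamics for brown and white adipogenesis.

`methdyn` is a tidyverse-native R package for analysing reduced
representation bisulfite sequencing (RRBS) methylomes from a nine-sample
adipogenesis design: brown adipocytes (BAT), white adipocytes (WAT) and
norepinephrine-treated white adipocytes (BWAT), each sampled at
differentiation days 0, 4 and 6. It is aimed at epigenomics analysts who
want the full per-CpG-to-promoter differential methylation recipe as
composable, tested functions rather than a one-off script.

## The method

Starting from per-CpG methylation call tables (bismark-coverage-style),
analysis is restricted to autosomal CpGs with depth ≥ 10 in **all**
samples. Between a pair of samples, a CpG with methylation difference

Δ = m_t/n_t − m_r/n_r,  |Δ| ≥ 0.10

enters a two-sided Fisher exact test on its 2×2 read-count table;
p-values are Benjamini–Hochberg adjusted over the tested set and a CpG is
a significant **DMC** when |Δ| ≥ 0.10 and q < 0.05. A promoter (1 kb
upstream to 500 bp downstream of the TSS) is a **DMP** when it contains
≥ 2 significant DMCs, all in one direction. Genes that are same-direction
DMPs at all three timepoints form the consistent gene set, which can be
tested for gene-family (e.g. Hox) enrichment with an upper-tail
hypergeometric test, and related to expression via Spearman correlation
between promoter Δ methylation and log2((FPKM+1) fold change) with a
permutation p-value. Supporting machinery covers CpG-island
shore/shelf annotation, LM/PM/HM (<30% / 30–70% / >70%) methylation-class
dynamics, merged-CpG-region clustering, PCA, and a fully seeded
beta-binomial simulator of the whole study design with planted ground
truth.

See `vignettes/methylation-dynamics.Rmd` for the models, parameter
meanings and design decisions.

## Worked example

Simulate the default study (50,000 CpGs, 50 planted differentially
methylated promoters at effect size 0.30, depth ≈ 30), run the
differential recipe, and score recovery:

```r
library(methdyn)

sim  <- simulate_study(synthetic_truth(seed = 42))
meth <- filter_common_autosomal(sim$design$methylome)
meth
#> <methylome> 47181 CpG sites x 9 samples
#>   samples: BAT_d0, BAT_d4, BAT_d6, WAT_d0, WAT_d4, WAT_d6, ...

dmcs <- call_dmcs(meth, target = "WAT_d6", reference = "BAT_d6")
c(tested = nrow(dmcs), significant = sum(dmcs$significant))
#>      tested significant
#>       15424        4011

dmps <- call_dmps(dmcs, sim$design$catalog)
head(dmps, 3)
#>   gene_id n_sig_cpgs direction mean_delta covered_cpgs
#> 1 G0005            7 hyper          0.419           17
#> 2 G0006            6 hyper          0.442           17
#> 3 G0007            7 hyper          0.449           14

cons <- consistent_dmps(lapply(
  setNames(c(0, 4, 6), paste0("d", c(0, 4, 6))),
  function(d) call_dmps(
    call_dmcs(meth, paste0("WAT_d", d), paste0("BAT_d", d)),
    sim$design$catalog
  )
))
evaluate_recovery(sim$design$planted, cons)
#>   n_planted n_called recall empirical_fdr direction_accuracy
#> 1        50       49   0.98             0                  1

co <- methylation_expression_correlation(
  dplyr::select(dmps, gene_id, delta = mean_delta),
  expression_lfc(filter_expressed(sim$expression), "WAT_d6", "BAT_d6"),
  seed = 42
)
co
#> <meth_expr_cor> Spearman rho = -0.444, permutation p = 0.0008
#>   (n = 49 genes, 10000 permutations)
```

Of 47,181 retained CpGs, 15,424 pass the 10% prefilter for the day-6
lineage comparison and 4,011 are significant DMCs; 49 genes are
consistent DMPs across all three timepoints, recovering 49/50 planted
promoters with no false calls and every direction correct, and promoter
methylation change anti-correlates with expression change (ρ = −0.44).

The same analysis runs end to end from files via a YAML/list config:

```r
paths  <- write_simulation(sim, "simdir")
report <- run_full_analysis(simulation_config("simdir"))
```

which writes per-comparison DMC BED / DMP TSV tables, the consistent gene
set, CpG context annotation and a JSON run report.

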