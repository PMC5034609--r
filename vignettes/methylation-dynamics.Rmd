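---
title: "Differential methylation dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

## The analysis problem

Brown (BAT) and white (WAT) adipocytes arise from distinct precursor
lineages, and DNA methylation is a candidate carrier of that lineage
identity: it may stay fixed while the transcriptome churns through the
differentiation program. `methdyn` implements an RRBS (reduced
representation bisulfite sequencing) analysis for a nine-sample design —
three lineages (BAT, WAT, and norepinephrine-treated WAT, "BWAT") sampled
at differentiation days 0, 4 and 6 — that asks, per CpG and per promoter,
where methylation differs between lineages and across time, and whether
promoter methylation anti-correlates with expression.

## The statistical recipe

**Common-coverage filter.** Analysis is restricted to autosomal CpGs
(mouse chr1–chr19 by default) with sequencing depth of at least 10 reads
in *every* sample. This makes all per-CpG comparisons use the same site
universe and guarantees no missing cells downstream. The filter is
idempotent.

**Per-CpG testing.** For a pair of samples, a CpG enters testing only when
the methylation difference

$$\Delta = \frac{m_t}{n_t} - \frac{m_r}{n_r}$$

(methylated reads $m$ over depth $n$ in target $t$ and reference $r$)
satisfies $|\Delta| \ge 0.10$. The tested CpGs receive a two-sided Fisher
exact p-value on the 2×2 count table, computed by summing hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed that of the observed table (relative tolerance $10^{-7}$,
matching `stats::fisher.test`; the package routine is vectorized because a
comparison tests tens of thousands of CpGs). Benjamini–Hochberg adjustment
is applied over exactly the tested set of that one comparison, and a CpG
is a significant DMC when $|\Delta| \ge 0.10$ *and* $q < 0.05$. Adjusting
within the prefiltered set, per comparison, is a deliberate reading of the
recipe ("only CpGs … were selected … p-values were then adjusted"); the
pooled alternative would change the q-values but not the test statistics.

**Promoter aggregation.** A promoter spans 1 kb upstream through 500 bp
downstream of the TSS (1500 bp exactly; the TSS base counts as the first
downstream base, so a plus-strand gene with TSS $t$ has promoter
$[t-1000,\,t+499]$ and gene body $[t+500,\,\mathrm{TTS}]$). A promoter is
a differentially methylated promoter (DMP) when it contains at least two
significant DMCs, all sharing one direction. Mixed-direction promoters are
*not* DMPs by default (`dmp_mode = "strict"`); a majority-vote mode exists
for sensitivity analyses. A CpG lying in two genes' promoters contributes
to both, so gene-level results are gene-complete. Genes with several
transcripts are collapsed to the union of exons and the 5'-most TSS.

**Context annotation.** Each CpG receives one genic label (precedence
promoter > exon > intron > intergenic, evaluated across all genes) and one
CpG-island label (island > shore > shelf > open sea; shores are the 2 kb
island flanks, shelves the next 2 kb, with bands from different islands
unioned and clipped where they would overlap an island). Boundary cases at
exactly 30% / 70% methylation fall in the partially methylated (PM) class:
LM $< 0.30 \le$ PM $\le 0.70 <$ HM, reading the stated "30–70%" interval
inclusively.

**Consistency and enrichment.** Genes that are DMPs with the same
direction at all three timepoints of the BAT-vs-WAT comparison form the
consistent gene set. Family enrichment (e.g. Hox transcription factors)
uses the upper-tail hypergeometric test $P(X \ge \text{hits})$ against a
stated universe; the default universe is genes whose promoter contains at
least one analyzable CpG, since genes invisible to RRBS cannot be called
and would deflate the test.

**Methylation–expression correlation.** Genes with FPKM $< 1$ in every
sample are removed first. Expression change is
$\log_2\!\big((\mathrm{FPKM}_t + 1)/(\mathrm{FPKM}_r + 1)\big)$; the
pseudocount tames low-expression genes and is our choice, not dictated by
the recipe. The association with promoter methylation change is Spearman's
$\rho$ with a permutation p-value (10,000 label permutations, fixed seed,
two-sided on $|\rho|$) — rank-based because FPKM fold changes are heavy
tailed, permutation-based because called DMP deltas are far from
exchangeable-normal.

**Clustering.** For the methylome, consecutive CpGs closer than 500 bp
(strictly) merge into regions whose value is the unweighted mean of member
CpG fractions (unweighted, matching an "average methylation percentage"
reading; depth-weighting would let one deep CpG dominate a region).
Samples are clustered by average linkage on euclidean distances over
region means; the transcriptome uses $1 - r$ (Pearson) on
$\log_2(\mathrm{FPKM}+1)$, the conventional choice for expression
profiles. PCA centers features but does not scale them — methylation
fractions already share a scale. Agreement with known groupings is scored
by the adjusted Rand index.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 | per-sample depth for the common filter (reads) |
| `min_diff` | 0.10 | minimum \|Δ\| (fraction) to test a CpG |
| `alpha` | 0.05 | BH FDR level |
| `lm_cut`, `hm_cut` | 0.30, 0.70 | LM/PM/HM class boundaries |
| `promoter_up`, `promoter_down` | 1000, 500 | promoter extent around the TSS (bp) |
| `shore_bp`, `shelf_bp` | 2000, 2000 | CGI band widths (bp) |
| `merge_gap` | 500 | strict CpG-chaining gap (bp) |
| `min_fpkm` | 1 | expression floor (FPKM, any sample) |
| `min_dmcs_per_dmp` | 2 | significant same-direction CpGs per DMP |

All of these travel together in `analysis_config()` and are echoed into
the pipeline's JSON report, so a run is reproducible from the report
alone.

## The synthetic study generator

Real RRBS data for this design are large and external, so the package
ships a generator (`synthetic_truth()`, `simulate_study()`) that emulates
the study's statistical structure with known ground truth:

* **Bimodal baseline.** Per-CpG baseline methylation comes from a
  two-mode Beta mixture (modes 0.08 and 0.85, 55% low, concentration 8),
  mimicking the LM/HM-dominated genome RRBS sees. These are generator
  defaults, not estimates from any dataset.
* **Counts.** Depth is $1 + \mathrm{NB}(\mu = 29, \text{size} = 10)$
  (mean 30); methylated reads are beta-binomial with intra-CpG correlation
  $\rho = 0.02$. The overdispersion is deliberate: purely binomial counts
  would flatter the Fisher test's error control.
* **Differentiation drift.** A random 20% of non-promoter CpGs gain
  $0.02 \cdot \mathrm{day}$ in every lineage — positive-only, reproducing
  global hypermethylation during adipogenesis.
* **Lineage signature.** 15% of non-promoter CpGs carry a ±0.40 offset in
  the white lineages (WAT and BWAT), 70% of them WAT-hypermethylated,
  reproducing both the methylome-clusters-by-lineage observation and the
  WAT-hypermethylation dominance. Offsets sit on non-promoter CpGs because
  lineage DMCs are predominantly intronic/intergenic in this system.
* **Treatment wrinkle.** BWAT samples add a sign-symmetric ±0.35 offset on
  6% of non-promoter CpGs: enough for the treated lineage to be separable,
  while sharing the full white-lineage signature (norepinephrine does not
  change lineage identity).
* **Planted DMPs.** 50 genes (80% WAT-hyper) receive ±0.30 at every
  promoter CpG in the white lineages. Promoters carry on average ~14 CpGs
  (minimum 6), in line with RRBS promoter coverage — roughly 30 CpGs per
  covered promoter is typical — and with per-CpG Fisher power ~0.4 at
  depth 30 and Δ = 0.3, which makes "two significant same-direction CpGs
  at all three timepoints" recoverable without being trivial. Planted
  baselines are drawn with headroom so effects never clip.
* **Expression.** $\log_2 \mathrm{FPKM}$ is a gene baseline
  $\mathcal{N}(3, 2)$ plus a per-gene, per-day effect
  $\mathcal{N}(0, 1)$ shared across lineages, plus
  $-4 \times$ (promoter methylation deviation from the gene's
  across-sample mean), plus $\mathcal{N}(0, 0.2)$ noise;
  $\mathrm{FPKM} = 2^x - 1$ clipped at 0. The day effect is categorical
  per day level rather than a linear slope: a linear-in-day program leaves
  adjacent late days nearly collinear, and the generator's contract is
  that the day program — not lineage — drives transcriptome clustering.
  Differentiation programs are in any case not linear in time.

Everything is deterministic given the master seed (the annotation,
methylome and expression stages use seed, seed+1, seed+2), and
`write_simulation()` emits byte-identical files on reruns.

**What the generator does not emulate:** MspI fragment selection and the
resulting genomic clustering of RRBS CpGs, bisulfite conversion errors,
strand-level calls, chromosome-scale covariates (e.g. CpG density varying
with genic context), repetitive elements, and any correlation between
neighbouring CpGs beyond shared effect assignment. Passing tests on
synthetic data therefore demonstrate that the *statistical machinery* is
correct and well calibrated under a realistic noise model — not that any
particular biological conclusion transfers to a given real dataset.

## Numerical and degenerate-input choices

* Fisher tables with an all-zero margin give $p = 1$ by convention.
* $q$-score output caps $-\log_{10} q$ at 300 (BED score column).
* Hyper:hypo ratios with zero hypomethylated DMCs are reported as `Inf`,
  never clamped.
* Genes shorter than the 500 bp promoter tail get an empty gene body; all
  intragenic positions fall in the promoter, so the definitions compose
  without special cases.
* CpG call tables are assumed plus-strand-collapsed (one record per CpG
  dyad); `collapse_strands = TRUE` greedily sums a record at `pos + 1`
  into the plus-strand cytosine for callers that emit both strands.
  Whether a deposited site count refers to dyads or stranded cytosines is
  often ambiguous, so both readings are one flag apart.
* Readers reject coordinate violations (zero-length BED intervals, exons
  outside transcripts, inconsistent percentage-vs-count rows beyond 0.5
  percentage points) rather than repairing them silently.
* Hierarchical clustering is deterministic given column order; the
  permutation p-value uses `(1 + \#\{|\rho_{perm}| \ge |\rho|\})/(B+1)`
  so it is never exactly zero.

## Problem sizes used by the test suite

The shipped tests exercise the defaults at the design's native scale:
50,000 CpGs × 9 samples for the recovery, clustering, correlation and
(10-seed) null-calibration checks, with smaller 8,000-CpG studies for the
pipeline round-trip tests; the Fisher and BH implementations are checked
against brute-force enumeration oracles on 10,000 random 2×2 tables
(total count ≤ 60) and 1,000 random p-vectors, and interval annotation
against a per-position linear scan on 100 random toy genomes. These sizes
were chosen so the whole suite gives tight statistical checks in a few
minutes on one CPU.

## Known limitations

* Per-CpG Fisher testing ignores biological replication and
  overdispersion; it is faithful to the original recipe, not
  state-of-the-art differential methylation modelling (no beta-binomial
  regression, no smoothing across neighbouring CpGs).
* BH adjustment after the \|Δ\| prefilter conditions on an effect-size
  selection, so q-values are not FDR estimates over all CpGs — only over
  the tested set. The shipped null calibration shows the end-to-end
  consistent-gene calls remain conservative regardless.
* The consistency intersection treats timepoints symmetrically and
  requires presence at every timepoint; a gene missing one DMP call by a
  hair is dropped (no "2 of 3" relaxation is offered).
* Enrichment depends on the declared family list and universe; the
  package deliberately does not guess family membership from gene
  symbols.
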