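# tkiprio

Prioritizing drug-resistance genes by discounted rank aggregation across
paired sensitive/resistant expression experiments.

## What it does, and for whom

Cancer cell lines driven into acquired drug resistance (for example,
EGFR-mutant lung adenocarcinoma lines made resistant to tyrosine kinase
inhibitors by long-term exposure) are routinely profiled against their
drug-sensitive parental lines. Any one sensitive-versus-resistant comparison
is noisy and platform-bound; a collection of K such experiments carries much
stronger evidence, but raw effect sizes are not comparable across platforms.
`tkiprio` is for computational biologists who have K paired expression
experiments (microarray or RNA-seq, as genes × samples TSV matrices) and
want one robust, reproducible candidate-gene list out of them.

The method:

1. **Score** each gene per experiment with the resistance-related score
   *s(g)* = log2 fold change of the resistant over the sensitive group mean
   (pseudocount ε on linear data; a variance-moderated variant is available).
2. **Rank** genes within each experiment in descending score order (ties
   averaged).
3. **Fuse** the K rankings with a discounted rating system: each experiment
   contributes *r(g)* = 1 / log2(1 + rank(g)) — worth 1 at rank 1, decaying
   with rank — and the combined score is the sum

   *S(g)* = Σᵢ 1 / log2(1 + rankᵢ(g)),

   so only genes consistently near the top of many rankings score highly.
   A geometric discount *d*^(rank−1) and a worst-rank missing-gene policy
   are provided as alternatives.
4. **Characterize** the top-n fused genes (default 100) by one-sided
   hypergeometric over-representation against a GMT gene-set collection,
   with Benjamini–Hochberg FDR, and build an enrichment-map graph linking
   terms whose gene-set overlap coefficient exceeds 0.5.

A synthetic-study generator with planted resistance genes (configurable
effect size, penetrance across experiments, Gaussian log-intensity or
negative-binomial count noise) makes the whole pipeline testable end to end
without any external download. Small validation utilities — qPCR 2^(−ΔCt)
relative expression and a summary-statistics Welch/Student t-test — round
out the analysis workflow.

## Worked example

```r
library(tkiprio)

cfg <- study_config(n_genes = 2000, n_experiments = 6, n_replicates = 3,
                    planted_genes = 15, effect_size = 2, penetrance = 0.8,
                    noise_sd = 1, seed = 42)
study <- generate_study(cfg)

rankings <- lapply(study$experiments,
                   function(e) rank_genes(resistance_score(e)))
fused <- discounted_rating(rankings)
fused
#> <prioritization_result> 2000 genes fused over 6 experiments (log discount, param 2, missing=zero)
#> top genes: g00561, g01327, g00356, g01170, g01252

head(as.data.frame(fused)[, c("gene", "combined_score", "n_experiments_observed")])
#>     gene combined_score n_experiments_observed
#> 1 g00561       3.319110                      6
#> 2 g01327       2.637792                      6
#> 3 g00356       1.955751                      6
#> 4 g01170       1.928760                      6
#> 5 g01252       1.835254                      6
#> 6 g00321       1.743397                      6

top <- top_n(fused, 50)
sum(study$truth$planted_gene_ids %in% top)   # 14 of 15 planted genes recovered
```

`combined_score` is the summed discounted rating: the top gene, `g00561`,
averages close to rank 2–3 across the six experiments (six ratings near
1/log2(3) ≈ 0.63 or better), while a gene near rank 1000 everywhere would
score about 6/log2(1000) ≈ 0.6 in total. Fourteen of the fifteen planted
resistance genes land in the fused top-50; the fifteenth was assigned an
effect in too few experiments to stand out (penetrance 0.8).

Over-representation of the top list against a toy annotation whose first
term was seeded with the planted genes:

```r
ann <- generate_annotation(sprintf("g%05d", 1:2000), n_sets = 100,
                           set_size_range = c(10, 60),
                           planted_set = study$truth$planted_gene_ids,
                           seed = 43)
enr <- enrich(top, ann, background = fused$gene_ids)
head(enr[, c("term_id", "term_size", "overlap", "p_value", "q_value")], 3)
#>   term_id term_size overlap      p_value      q_value
#> 1  set001        60      14 4.103710e-11 4.103710e-09
#> 2  set074        48       6 9.910542e-04 4.955271e-02
#> 3  set093        17       3 7.812384e-03 2.604128e-01

map <- build_enrichment_map(enr, q_cutoff = 0.05, overlap_threshold = 0.5)
```

The designated planted term (`set001`) is recovered at q ≈ 4 × 10⁻⁹: 14 of
its 60 genes appear in the 50-gene list against a 2000-gene background.

The whole flow — simulate (or read TSVs), score, fuse, enrich, write all
tables, the GraphML map, and an md5-checksummed run manifest — is one call:

```r
run_pipeline(run_config("simulate", out_dir = "out",
                        study = study_config(seed = 1)))
```

or, from a shell, via the thin CLI (`inst/cli/tkiprio.R`) with subcommands
`run`, `simulate`, `score`, `aggregate`, `enrich`, `qpcr`, and `ttest`.

Summary-statistics group comparison, as printed in published figures
(mean ± SEM with group sizes):

```r
welch_t_from_summary(group_summary(0.114, 0.059, 8),
                     group_summary(1.18, 0.412, 16))
#> t = 2.561, df = 15.6, p = 0.0212
```

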