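# mirintegrate

Integrated miRNA/mRNA expression analysis for case–control tumour cohorts,
built around the inflammatory breast cancer (IBC) versus non-IBC study
design: qPCR arrays profiling a few hundred miRNAs in ~70 tumours, with
genome-wide mRNA profiles available for a subset of samples, and the
question of which miRNAs mark the aggressive subtype, which genes they
regulate, and whether those target genes carry prognostic information in
independent survival cohorts.

The package is aimed at analysts who have (a) a raw threshold-cycle (Ct)
matrix from a TaqMan-array-style miRNA assay, (b) a log-scale mRNA
expression matrix, (c) sample annotations, (d) a TargetScan-style
miRNA→target prediction table, and optionally (e) survival tables. Because
such multi-layer data are rarely public in matched form, the package also
ships a synthetic cohort generator with a planted-effect truth table, so
every stage of the pipeline can be exercised and validated end to end.

## What it computes

1. **qPCR preprocessing** — assays detected at Ct < 35 in ≥ 25 % of samples
   are kept; per-sample global centring turns Ct into relative expression
   `x = −(Ct − c_s)` with `c_s` the sample's mean (or median) detected Ct,
   so one unit ≈ two-fold and larger = more abundant. Undetected reactions
   are a sentinel (`NA`), never an imputed ceiling.
2. **Clustering** — complete-linkage hierarchical clustering on Euclidean
   distances of the top-variance miRNAs; the cluster number maximises the
   average silhouette width, with a feature-shuffling permutation p-value;
   cluster–clinical associations by Pearson χ² (no continuity correction)
   and a permutation-calibrated global test `Q = y′Z′Zy` on standardised
   expression.
3. **Differential miRNAs** — two-sided Mann–Whitney tests with
   Benjamini–Hochberg FDR, confirmed by logistic regression of the subtype
   on each miRNA adjusted for N/M status, stage and HER2 (Firth-penalized
   fallback under separation); plus the five miRNA-processing genes
   (TRBP2, DICER1, AGO1, AGO2, DROSHA) on the mRNA matrix.
4. **Target inference** — Spearman correlation of each candidate miRNA
   against every gene (midranks, BH jointly over all pairs, both signs
   kept); hypergeometric concordance of correlated genes with predicted
   targets; hypergeometric GO/KEGG-style enrichment of the concordant
   (direct) targets.
5. **Prognosis** — the signed target-gene expression score
   `s = mean(expr[positive targets]) − mean(expr[negative targets])`,
   standardised to median 0 / s.d. 1, validated against the miRNA itself
   by Spearman correlation, and evaluated with per-dataset and pooled
   (dataset-stratified) Cox proportional-hazards models plus Kaplan–Meier
   strata at score 0.
6. **Regulatory effect (RE)** — a per-sample rank score per miRNA family:
   signed mode `RE = (mean rank of non-targets − mean rank of targets) /
   ((G+1)/2)` on expression ranks; symmetric mode ranks absolute deviations
   from each gene's cross-sample median so repression and activation count
   equally. Groups are compared with a SAM-style moderated d-statistic and
   permutation FDR.

## Worked example

```r
library(mirintegrate)

coh  <- generate_cohort(cohort_config(seed = 7))   # 20 IBC + 50 non-IBC
expr <- normalize_global_centre(filter_informative(coh$ct))

hierarchical_cluster(top_varying(expr, 50), k_range = 2:6)
#> Hierarchical clustering: k = 2 clusters over 70 samples
#>   average silhouette width: 0.100

grp <- factor(coh$samples$subtype, levels = c("IBC", "non-IBC"))
de  <- rank_test(expr, grp)
de_hits <- de[!is.na(de$q) & de$q < 0.1, ]           # 15 miRNAs at q < 0.1

pairs <- mirna_mrna_correlations(expr[de_hits$feature_id, ], coh$mrna)
#> 2433 pairs at q < 0.1 (1264 positive, 1169 negative)

cc <- concordant_targets(pairs, coh$target_db, rownames(coh$mrna))
head(cc$summary[cc$summary$concordant, ], 3)
#>   mirna_id n_correlated n_predicted overlap_k            q
#> 2  miR-022          162          60        31 3.916742e-19
#> 3  miR-059          213          60        30 9.310827e-15
#> 4  miR-090          199          60        32 1.266877e-17

m1  <- "miR-022"
pos <- pairs$gene_id[pairs$mirna_id == m1 & pairs$sign == "pos"]
neg <- pairs$gene_id[pairs$mirna_id == m1 & pairs$sign == "neg"]
g   <- cc$intersection_genes[[m1]]
sc  <- standardize_score(target_score(coh$mrna, intersect(pos, g),
                                      intersect(neg, g)))
score_mirna_concordance(sc, expr[m1, ])              # 0.86

cox_evaluate(sc, coh$survival)
#>  dataset_id hazard_ratio      p  n events    setting
#>         DS1        1.160 0.5900 22     15 univariate
#>         DS2        2.151 0.0350 22      9 univariate
#>       Total        1.487 0.0775 44     24 univariate
```

Reading the output: 15 of 384 miRNAs separate IBC from non-IBC at FDR 0.1
(13 were planted — `coh$truth$de_mirnas`); for each, correlated genes are
significantly enriched for the synthetic prediction database, and the
target-gene score of `miR-022` tracks the miRNA itself at Spearman ρ = 0.86
and carries the planted hazard (pooled HR 1.49 per score unit).

Worked examples on real printed tables are bundled too:

```r
chi_square_association(ibc_contingency_tables()$her2)  # p = 0.052
lengths(ibc_direct_targets())                          # 121 / 140 / 19 / 13
```

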