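# evcargo

Analysis of paired tissue / extracellular-vesicle (EV) mRNA expression
profiles, built for porcine muscle and muscle-derived EVs (M-EVs) but
general to any paired compartment design.

Muscle secretes vesicles whose mRNA cargo is selectively loaded: lowly
expressed muscle transcripts tend to be *enriched* in vesicles, and much of
the cargo is truncated, carrying UTR sequence without a complete coding
region. `evcargo` takes gene-level and gene-region-level (5'UTR / CDS /
3'UTR) count matrices and quantifies exactly that:

* **FPKM quantification and filtering** — `compute_fpkm()`,
  `filter_low_expression()` (genes with FPKM < 1 in every sample of both
  compartments are removed).
* **Rank-class enrichment** — per muscle sample, genes are classed as
  `Top100` (abundance ranks 1–100), `Mid` (101–1,000) or `Other`; per
  animal, the percentage of each class with EV FPKM ≥ muscle FPKM
  ("maintained or increased") is computed and compared across classes by
  one-way ANOVA with Fisher's LSD and a compact letter display
  (`assign_rank_classes()`, `maintained_fractions()`, `anova_lsd()`).
  `cumulative_share()` gives the top-n FPKM concentration per sample.
* **MEG calling** — a self-contained two-group negative-binomial Wald test
  (median-of-ratios size factors, method-of-moments dispersion shrunk to a
  mean–dispersion trend, delta-method standard errors, Benjamini–Hochberg
  adjustment). A gene is a MEG (M-EV-enriched gene) iff padj ≤ 0.05 and
  log2FC ≥ 1 over muscle. Catalogs are built per breed and globally and
  compared as a three-way Venn partition (`meg_de()`, `call_megs()`,
  `compare_catalogs()`).
* **Cargo integrity** — per-sample read distribution over the three mRNA
  regions and *full-length potential* calls (reads detected in all three
  regions), with per-compartment consensus sets
  (`region_distribution()`, `classify_full_length()`).
* **Divergence** — log10 transformation, Pearson correlation matrices with
  p-values, and sample-level PCA (`log_transform()`, `pearson_matrix()`,
  `pca_samples()`).
* **Pathway over-representation** — upper-tail hypergeometric tests of MEG
  catalogs against GMT gene sets over the tested-gene universe, with
  cross-breed pathway-set comparison (`ora_test()`, `enrich_all()`,
  `compare_pathway_sets()`).
* **qPCR validation** — 2^-ddCt relative quantification and concordance of
  qPCR with RNA-seq expression levels (`delta_delta_ct()`,
  `validate_concordance()`).
* **A calibrated synthetic generator** — `default_scenario()` /
  `simulate_dataset()` produce complete paired datasets (GTF, counts,
  region counts, sample sheet, qPCR CTs, gene sets) with planted ground
  truth: heavy-tailed muscle expression (top-1,000 genes = 90.94% of
  FPKM), rank-dependent maintained fractions (20% / 25% / 60%), a
  calibrated EV top-1,000 share (73.99%), planted shared and
  breed-specific MEG sets, and truncated EV cargo. The truth object
  enables recovery testing of every stage.

Everything is orchestrated by `run_pipeline()` from a single list or YAML
configuration, writing per-stage TSVs plus `summary.json` and
`manifest.json`.

## Worked example

```r
library(evcargo)

res <- run_pipeline(list(simulate = list(), outdir = "evcargo_demo"))

round(tapply(res$rank_summary$fraction_maintained,
             res$rank_summary$class, mean), 2)
#>    Mid  Other Top100
#>  25.22  62.11  18.75

round(100 * attr(res$shares, "compartment_means"), 2)
#>    MEV muscle
#>  74.14  90.82

res$catalogs$Global
#> meg_catalog [Global]: 2339 MEGs of 11985 tested genes (19.5%)

res$venn$counts["LargeWhite&WildBoar&Global"]
#> LargeWhite&WildBoar&Global
#>                       1600

print(res$concordance$MEV)
#> qPCR/RNA-seq concordance [MEV]: r = 0.967 (p = 3.18e-31, 52 points); per-gene fold r = 0.995
```

Reading the numbers: only ~19% of an animal's 100 most abundant muscle
genes keep or raise their expression in vesicles, against ~62% of genes
below rank 1,000 — low-abundance transcripts are preferentially loaded.
The muscle profile is far more concentrated (top-1,000 genes ≈ 91% of
FPKM) than the vesicle profile (≈ 74%). The global MEG catalog holds 2,339
vesicle-enriched genes, 1,600 of which are the planted breed-shared set
recovered in all three catalogs, and the qPCR panel agrees with RNA-seq
at r ≈ 0.97.

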