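# mirMRA

Discovery of subtype-defining microRNA master regulators from paired
miRNA/mRNA expression cohorts.

## The problem

High-grade serous ovarian cancer partitions into four transcriptional
subtypes; the *mesenchymal* subtype carries the worst prognosis. A recurring
question in such settings is whether a single regulator — here a microRNA —
drives the subtype's expression program. mirMRA implements the complete
analysis chain for answering it:

1. **Subtype classification** — a nearest-shrunken-centroid (PAM) classifier
   built with a two-step gene filter: differential expression (log2FC > 1,
   BH-adjusted p < 0.05, Welch's t) followed by a per-gene ROC-AUC filter
   (AUC > 0.9, top 10 genes). A sample is called mesenchymal when the class
   posterior exceeds 0.5.
2. **Regulatory network inference** — candidate regulators are miRNAs
   downregulated in the subtype (log2FC < −0.5, BH p < 1e−4), candidate
   targets are subtype-DE genes (|log2FC| > 0.25, BH p < 0.05); both
   matrices are z-normalized and integrated via mutual information
   (equal-frequency binning), per-regulator permutation p-values (1000
   permutations, BH at 0.05), bootstrap consensus (100 resamples, support
   ≥ 0.95), data-processing-inequality pruning, and Spearman-based edge
   signs (repression vs induction).
3. **Master regulator analysis (MRA)** — for each miRNA's regulon, an
   upper-tail hypergeometric test of overrepresentation for EMT-signature
   genes, P(X ≥ k) with X ~ Hypergeom(N, K, n), BH-corrected across
   regulators and ranked with the signature-coverage proportion k/K.
4. **Preranked GSEA** — weighted Kolmogorov–Smirnov enrichment score on the
   mesenchymal log2FC ranking, gene-permutation null, NES and
   positive/negative-pool FDR.
5. **Survival** — Kaplan–Meier curves, log-rank tests, mean-expression
   stratification, and uni-/multivariate Cox regression (Breslow ties) with
   age/stage/grade covariates.
6. **Target triangulation** — a Venn-style intersection of the inferred
   regulon, the signature, and sequence-based prediction lists (miRDB-like ∩
   TargetScan-like), with Pearson anticorrelation as supporting evidence.

A first-class synthetic cohort generator (`simulate_cohort()`) emulates a
TCGA-like paired cohort — mesenchymal fraction 104/462, planted
subtype-downregulated regulator miRNAs with signed regulons, classifier
genes, a partially regulon-overlapping signature, and subtype-linked
censored survival — so every stage is testable against known ground truth
without any external download. See `vignettes/mirMRA-methods.Rmd` for the
model details, parameter meanings and known limitations.

## Worked example

```r
library(mirMRA)

co  <- simulate_cohort(reduced_simulation_config(seed = 1))
mes <- co$samples$subtype == "mesenchymal"
net <- infer_network(co$gene_expr, co$mirna_expr, mes, analysis_config(rng_seed = 1))
mra <- rank_master_regulators(
  mra_enrichment(regulons(net), co$truth$signature, net$targets))
mra[, c("regulator", "n", "k", "adj_p", "proportion")]
```

prints

```
synthetic_cohort: 200 samples (36 mesenchymal), 200 genes, 20 miRNAs, 3 planted regulators
regulatory_network: 3 regulators x 98 targets, 134 kept edges
7 signature gene(s) outside the universe dropped
  regulator  n  k   adj_p proportion
1    MIR010 45 18 0.00117      0.783
2    MIR012 48  4 0.99999      0.174
3    MIR003 41  2 0.99999      0.087
```

The planted master regulator (`MIR010`) ranks first: its inferred 45-gene
regulon contains 18 of the 23 in-universe signature genes (coverage 0.783,
BH-adjusted hypergeometric p = 0.0012), while the two planted decoys are
correctly not enriched. The same cohort's survival layer recovers the
planted subtype effect (hazard ratio 2.0):

```r
cox_fit(co$samples$time, co$samples$event,
        data.frame(mesenchymal = as.numeric(mes)))$table
#          term      beta       hr        se ci_lower ci_upper      p_value
# 1 mesenchymal 0.8032119 2.232701 0.2161214  1.46172 3.410333 0.0002020144
```

`run_full_pipeline()` chains all stages (differential expression →
classifier → network → MRA → GSEA → survival → target prioritization) from
one root seed and writes a TSV/JSON report bundle; the same workflow is
available from a shell via `inst/cli/mirMRA.R` (subcommands `simulate`,
`diffexp`, `classify-train`, `classify-apply`, `infer-network`, `mra`,
`gsea`, `survival`, `prioritize-targets`, `run-all`).

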