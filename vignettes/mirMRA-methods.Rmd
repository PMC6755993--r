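---
title: "mirMRA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirMRA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-grade serous ovarian cancer splits into four transcriptional subtypes
(immunoreactive, differentiated, proliferative, mesenchymal), of which the
mesenchymal subtype carries the worst prognosis. mirMRA implements a
network-biology workflow for asking which microRNA, if any, acts as a
*master regulator* of that subtype: a miRNA whose inferred target set
(regulon) is statistically overrepresented for epithelial-mesenchymal
transition (EMT) signature genes. The package chains together the five
analysis layers such a study needs -- subtype classification, signed
regulatory-network inference from paired miRNA/mRNA expression, regulon
enrichment, pathway-level enrichment, and survival stratification -- and
adds a synthetic-cohort generator with planted ground truth so that every
layer can be validated quantitatively without access to any restricted
cohort.

# Subtype classifier

The classifier follows the nearest-shrunken-centroid (PAM) formulation.
Genes are selected in two steps on the z-normalized training cohort:

1. **Differential expression.** Welch's t-test of mesenchymal vs the rest;
   keep genes with log2 fold change > 1 and BH-adjusted p < 0.05.
2. **Discrimination.** Keep genes whose single-gene rank AUC
   (mesenchymal vs rest) exceeds 0.9; if more than 10 survive, keep the top
   10 by AUC (ties broken by |log2FC|, then id).

For each selected gene *i* and class *k*, the standardized centroid
deviation is

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)},\qquad
  m_k = \sqrt{1/n_k - 1/n},$$

where $s_i$ is the pooled within-class standard deviation and
$s_0 = \mathrm{median}(s_i)$ is the usual fudge constant. Deviations are
soft-thresholded, $d'_{ik} = \mathrm{sign}(d_{ik})\max(|d_{ik}|-\Delta, 0)$,
giving shrunken centroids
$\bar x'_{ik} = \bar x_i + m_k (s_i + s_0)\, d'_{ik}$. Note the $m_k$
convention uses $1/n_k - 1/n$ (the overall centroid contains the class-k
samples), not $1/n_k + 1/n$. Classification uses the Gaussian discriminant
$\delta_k(x^*) = \sum_i (x^*_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$
with empirical priors, and posteriors
$p_k \propto \exp(-\delta_k/2)$ evaluated stably. A sample is called
mesenchymal when that class's posterior exceeds 0.5.

Two open design points were settled here: the shrinkage $\Delta$ is chosen
by stratified 10-fold cross-validated accuracy over a 30-point grid from 0
to $\max|d_{ik}|$, ties resolved toward the largest (sparsest) $\Delta$; and
the classifier is trained as a two-class problem (mesenchymal vs rest),
since that is the contrast every downstream stage consumes. A multi-class
fit works unchanged by passing four labels to `train_nsc()`. New cohorts are
always z-normalized *per their own cohort* before classification.

# Regulatory network inference

Candidate regulators are miRNAs downregulated in the mesenchymal subtype
(log2FC < -0.5, BH p < 1e-4); candidate targets are genes differentially
expressed between the subtypes (|log2FC| > 0.25, BH p < 0.05). Both matrices
are independently z-normalized and integrated through four layers:

* **Association.** Plug-in mutual information (nats) on a $B \times B$
  contingency table from equal-frequency (quantile) binning, with
  $B = \mathrm{clamp}(\lfloor\sqrt{n/5}\rfloor, 2, 10)$ and ties broken by
  stable rank order. Quantile binning makes the estimate exactly invariant
  under strictly monotone transforms of either variable on tie-free data.
* **Significance.** Per-regulator permutation null: the regulator's sample
  order is permuted 1000 times (preserving the target correlation
  structure), $p = (1 + \#\{MI_{perm} \ge MI_{obs}\})/(1 + 1000)$, BH over
  all pairs at the 0.05 target FDR.
* **Stability.** Bootstrap consensus: 100 resamples with replacement; within
  each resample all variables are re-binned and a pair counts as a success
  when its MI exceeds that resample's significance cutoff. The cutoff is the
  95th percentile of a fresh 100-permutation null for that regulator, pooled
  over its tested targets -- the resample-level analogue of the permutation
  layer. Pairs need support >= 0.95 to survive.
* **Pruning and signs.** Data-processing-inequality pruning: for every
  triangle (R1-T, R2-T, R1-R2) the weakest association is flagged when its
  MI falls below $(1-\varepsilon)$ times the smaller of the other two
  (default $\varepsilon = 0$, strict); flagged regulator-target edges are
  removed, while regulator-regulator associations are computed only for this
  adjudication and never enter the bipartite network. Edge signs are the
  sign of the Spearman correlation (Pearson available), so repression is
  negative; a zero correlation leaves the sign undefined and drops the edge.

# Master regulator analysis

For each regulon the overlap $k$ with the signature is tested with an
upper-tail hypergeometric probability $P(X \ge k)$,
$X \sim \mathrm{Hypergeom}(N, K, n)$, BH-corrected across regulators. The
universe $N$ is the candidate-target set that entered network inference --
the same conditioning the inference step used -- not the whole genome;
signature genes outside that universe are dropped (with a message) before
counting. Results are ranked by adjusted p, ties broken by the coverage
proportion $k/K$, and the `-log10(adj p)` vs proportion table mirrors the
usual master-regulator scatter.

# Preranked GSEA

The phenotype is the mesenchymal-vs-rest log2 fold change; genes are ranked
descending with a lexicographic tie-break. The enrichment score is the
signed extremum of the weighted Kolmogorov-Smirnov running sum (hits advance
by $|s|^p$ normalized over the set, misses retreat by $1/(N-N_{hit})$),
with weight $p = 1$ by default and $p = 0$ available, where the statistic
reduces exactly to the classical two-sample KS statistic. The null is gene
permutation -- member positions drawn uniformly without replacement --
because the ranking is consumed as a preranked list; phenotype permutation
would need per-sample recomputation outside this module's contract and is a
documented deviation from the original tool's default. The nominal p is
one-sided on the matching ES sign, NES divides ES by the mean |null ES| of
the same sign, and FDR q follows the positive/negative-pool convention.
1000 permutations is the default.

# Survival

Kaplan-Meier product-limit curves, the log-rank test (for two groups,
$(O_1-E_1)^2/V$ on 1 df with hypergeometric variance), and Cox proportional
hazards with Breslow tie handling (the simplest consistent choice) via
Newton-Raphson on the partial likelihood. Expression-based stratification
follows the figure-legend convention: *high* means strictly above the cohort
mean; values equal to the mean go to *low*. Multivariate fits include the
group indicator plus age, stage and grade. A coefficient escaping |beta| >
10 is treated as monotone likelihood: the fit is flagged non-converged and
no hazard ratio is reported.

# Target triangulation

Direct-target candidates for a regulator are the genes simultaneously in
its inferred regulon, in the signature, and in the sequence-based
predictions -- by default the *intersection* of all supplied prediction
sources (a union mode exists behind a flag). The evidence table reports
Pearson correlation (t-based p, BH across the table) between regulator and
gene on the z-normalized cohort, so repression shows up as significant
anticorrelation.

# The synthetic cohort generator

`simulate_cohort()` emulates a TCGA-like paired cohort: ~460 samples, a
mesenchymal fraction of 104/462, per-feature baselines drawn once from
N(7, 1) log2 units (microarray-like intensities; only relative structure
matters downstream), Gaussian noise with sd 0.5. Three miRNAs are planted as
subtype-downregulated regulators (downshift 1.0 log2 units in mesenchymal
samples); each carries a regulon (80 genes at full scale) coupled to the
regulator's centered expression with coefficient 0.8, 90% of edges
repressive. The master regulator's regulon overlaps the 30-gene signature at
60%; decoys overlap at 10% so master-regulator ranking is a discriminative
test rather than a trivial one. Ten classifier genes sit inside the master
regulon on repressed edges (the regulator represses the genes that mark the
subtype) with a 1.5 log2-unit subtype shift; other signature genes get a
small 0.2-unit shift -- deliberately below the 0.25 target-candidate
threshold, so unregulated signature genes stay out of the inference universe
and exercise the universe-conditioning path in the MRA. Survival is
exponential with baseline hazard 0.02/month, hazard ratio 2.0 for
mesenchymal, independent exponential censoring at 0.015/month plus an
administrative cutoff at the 95th percentile of event times. A fixed seed
reproduces the cohort bit-identically.

**Reduced profile.** Recovery checks and the acceptance script run at 200
genes x 20 miRNAs x 200 samples with a 40-gene regulon and all other
defaults. The regulon cannot scale proportionally (it must contain at least
the 18 signature genes it overlaps plus the 10 classifier genes); 40 is the
smallest round size with headroom, keeping regulons at 20% of the reduced
genome. Survival-recovery checks use 2000 samples with a small expression
layer, since only the annotation table matters there. These problem sizes
are the package's validation conditions, stated here so results are
interpretable, and are not revisited per run.

**What the generator does not emulate.** Real cohorts have correlated
baseline expression, batch effects, heavy-tailed noise, probe-level
artifacts, copy-number and methylation structure, and overlapping subtype
boundaries. Passing the planted-truth checks therefore demonstrates that
the algorithms recover the structure they model, under Gaussian noise and
independent features -- not that any particular biological claim
reproduces on real data.

**A deliberate hard case.** Because the planted classifier genes are
strongly subtype-shifted and *all* planted miRNAs are subtype-downshifted,
a decoy regulator and a classifier gene outside its regulon are genuinely
marginally dependent through the subtype, even though no regulatory edge
links them. Any association measure computed on the pooled cohort -- mutual
information included -- must flag such pairs, and neither the
data-processing inequality (the regulator-regulator association is the
weakest leg of those triangles) nor bootstrap consensus (the dependence is
stable) removes them. Edge-level *recall* and *sign accuracy* are therefore
the clean recovery metrics, while edge-level *precision* saturates below 1
at a level set by the number of subtype-shifted non-target genes; the
acceptance suite reports all three. Conditioning the association on subtype
would remove the confound but would also remove the subtype-driven signal
the pipeline is designed to detect.

# Numerical conventions

* Welch's t with Satterthwaite df; two constant groups give t = 0, p = 1
  when means agree, p = 0 with a warning otherwise.
* Mann-Whitney U counts pairs (a < b) with a from the first group, ties one
  half -- the orientation making U/(n+ n-) the AUC of the second group over
  the first. The two-sided exact p (tie-free totals <= 12) doubles the
  smaller tail of the enumerated U distribution, clipped at 1; otherwise a
  normal approximation with tie and continuity correction is used.
* BH is the only multiple-testing procedure, applied once per analysis
  family (per expression matrix, per network, per MRA run, per GSEA
  collection, per evidence table).
* Missing expression tokens NA/NaN/empty are accepted on input; a feature
  row over 20% missing is dropped (logged), the rest mean-imputed, keeping
  downstream algebra total. Identifiers are matched case-sensitively after
  whitespace trimming; no alias resolution.
* Zero-variance rows z-normalize to all zeros with a warning; constant
  vectors have MI 0 by convention; expression is assumed log2 throughout and
  never re-logged.
* The enrichment score is the extremum of larger magnitude; on an exact tie
  between the positive and negative extrema the positive one is reported.
* All randomness (cohort generation, permutation nulls, bootstrap, CV folds,
  GSEA nulls) is seeded; the pipeline derives per-stage seeds from one root
  seed by fixed offsets, so a fixed seed reproduces the full report
  byte-identically.

# Known limitations

* The DE layer uses Welch's t rather than a moderated (empirical-Bayes)
  t; at the simulated cohort sizes the two are close, but small-sample
  variance moderation is out of scope.
* Probe-to-gene collapsing, RMA normalization and cohort download/parsing
  are out of scope: inputs are expected as already-summarized log2
  matrices.
* The network step infers marginal dependence with DPI pruning, not
  causality; confounded edges (above) and indirect effects survive where
  their information content is genuinely high.
* GSEA runs in preranked mode only, and the enrichment-map visualization
  layer of the original workflow is replaced by plain tables.
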