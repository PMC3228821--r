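# transICA

Discovery of co-regulated gene modules in expression data by independent
component analysis (ICA), and mapping of genomic loci that regulate those
modules in *trans*.

## The problem

Most expression quantitative trait loci (eQTLs) detected in population
transcriptomics act in *cis*. *Trans*-acting variants — a regulatory variant
that shifts the expression of many distant genes at once — are individually
weak and drown in the multiple-testing burden of a gene-by-SNP scan. If the
genes affected by one regulator are first collapsed into a single
co-expression *module*, the scan reduces to (modules × SNPs) tests of a much
stronger signal.

`transICA` implements this strategy for gene-by-sample expression matrices
(bulk microarray or RNA-seq intensities; sorted-cell designs such as
monocyte panels are the motivating case) together with SNP genotypes:

1. **Preprocessing** — probe collapsing, a one-sided exact binomial
   detection filter, removal of uncharacterized gene names, arcsinh variance
   stabilization, per-gene standardization.
2. **Sample QC** — classical multidimensional scaling on
   1 − |array correlation| (expression) and 1 − IBS (genotypes) with an
   iterative robust-distance outlier rule.
3. **Decomposition** — the number of components is chosen by a
   permutation-corrected screeplot, then the matrix is factored as
   *X* ≈ *S·A* by multi-restart symmetric FastICA (logcosh negentropy,
   α = 1). Column *k* of *S* is the component's **signature** over genes,
   row *k* of *A* its **pattern** of activation over individuals.
4. **Component filters** — patterns dominated by a single individual
   (variance share > 10%) and signatures with excess kurtosis < 3 are
   dropped.
5. **Modules** — a Gaussian empirical null is fitted to the central bulk of
   each signature; genes with tail-area FDR < 10⁻³ form the module.
6. **Association** — each pattern is scanned against all QC'd SNPs by 2-df
   ANOVA (suggestive at *P* < 10⁻⁷); a suggestive pair is retained only if
   the module is enriched (hypergeometric test at a study-wise Bonferroni
   threshold) in genes individually associated to the SNP at *P* < 10⁻⁵.
7. **Robustness** — associations are re-tested with cell-type contamination
   surrogates as covariates; *trans* effects can be tested for mediation by
   *cis* transcripts; module-level replication in an independent dataset
   uses two explicit criteria.

A synthetic-data module (`simulateDataset()`) generates genotype-driven
transcriptomes with known latent structure — sparse supergaussian
signatures, SNP-driven patterns with a chosen genetic variance fraction,
cis-mediated effects, additive cell-type contamination — so every stage is
verifiable against ground truth.

## The model

The expression of gene *i* in individual *j* is written

x<sub>ij</sub> = Σ<sub>k</sub> s<sub>ik</sub> a<sub>kj</sub> + ε<sub>ij</sub>,

with the statistical dependence between the columns of *S* minimized. ICA
favors sparse, heavy-tailed signatures: most genes near zero, a few genes
strongly positive or negative — exactly the shape expected when a hidden
regulator drives a limited gene set up or down. Unlike PCA, patterns may be
mutually correlated; unlike hard clustering, modules may overlap.

## Worked example

```r
library(transICA)

cfg <- simulationConfig(seed = 5)   # 2000 genes x 300 samples, K_true = 3,
                                    # one SNP-driven pattern (R2 = 0.2)
sim <- simulateDataset(cfg)
res <- runModuleDiscovery(sim$expression, sim$genotypes, seed = 5)

res$K
#> [1] 3
round(componentKurtosis(res$retained), 1)
#>  IC1  IC2  IC3
#> 12.4 13.3 12.8
sapply(res$modules, moduleSize)
#> IC1 IC2 IC3
#>  50  50  50
res$step1
#>    snp target        F df1 df2            p        r2   n
#> 1 snp1    IC2 53.00363   2 297 2.067149e-20 0.2630406 300
res$step2[, c("snp", "component", "kAssoc", "kHit", "p", "pass")]
#>    snp component kAssoc kHit            p pass
#> 1 snp1       IC2     52   50 6.642722e-98 TRUE
evaluateRecovery(sim$truth, res$retained, res$modules)
#>   trueComponent matchedComponent    absCor jaccard
#> 1         true1              IC2 0.9946435       1
#> 2         true2              IC3 0.9952857       1
#> 3         true3              IC1 0.9953003       1
```

Reading the output: the permutation-corrected screeplot selects K = 3
components; all three signatures pass the kurtosis filter (excess kurtosis
≈ 13) and each yields a 50-gene module. Step 1 finds one suggestive
SNP-pattern pair — the planted driver `snp1` against pattern `IC2`,
explaining 26% of the pattern's variance. Step 2 confirms it: 50 of the 52
expression traits associated to `snp1` at *P* < 10⁻⁵ lie inside the 50-gene
module (hypergeometric *P* ≈ 10⁻⁹⁸, far below the study-wise threshold).
The recovery report shows every planted module recovered exactly
(Jaccard 1) with pattern correlations above 0.99.

The same analysis runs from files (TSV/GCT expression, VCF or TSV
genotypes, GMT gene sets) through `runPipeline()` with a YAML
configuration; all stage outputs are persisted as TSV next to the resolved
configuration.

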