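---
title: "Methods: ICA-based module discovery and trans-eQTL mapping"
author: "transICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICA-based module discovery and trans-eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transICA)
```

This vignette documents the statistical model behind `transICA`, the
assumptions each stage makes, the tunable parameters with their defaults and
rationale, the design choices that were genuinely open, and what the
synthetic-data generator does and does not emulate.

## The decomposition model

The standardized expression matrix $X$ (genes $\times$ samples, each gene
centred to mean 0 and scaled to variance 1 with the $n-1$ denominator) is
factored as

$$x_{ij} \;=\; \sum_{k=1}^{K} s_{ik}\, a_{kj} + \varepsilon_{ij},$$

where $s_{ik}$ is the contribution of component $k$ to gene $i$ (column $k$
of $S$ is the component's *signature*) and $a_{kj}$ is the activation of the
component in individual $j$ (row $k$ of $A$ is its *pattern*). ICA chooses
the rotation of the rank-$K$ subspace that minimizes statistical dependence
between the columns of $S$; in practice this selects sparse, heavy-tailed
signatures in which a limited gene set is strongly co-induced or
co-repressed. Patterns may correlate with each other (no orthogonality
constraint, unlike PCA) and modules may overlap (unlike hard clustering).

**Identifiability caveat.** ICA on the *standardized* matrix recovers the
signatures of the standardized model, i.e. the raw loadings divided by each
gene's total standard deviation. This rescaling is harmless in the regime
the method targets — sparse signatures with gene-level noise dominating the
variance of weakly loaded genes — but a hypothetical dense supergaussian
loading matrix without idiosyncratic noise is *not* identifiable after
standardization: forcing every gene to unit variance pushes all genes onto
the unit sphere in component space and destroys the non-Gaussianity that ICA
exploits. The package's tests therefore validate source recovery in the
sparse-plus-noise regime; on weakly loaded genes the per-gene loading
estimate carries sampling noise of order $1/\sqrt{n_{\text{samples}}}$, so
global signature correlations with truth are bounded by estimation noise
even when the rotation is exact (pattern correlations $> 0.99$).

## Preprocessing

The chain is fixed: probe collapsing (arithmetic mean of a gene's probes per
sample, on the raw scale) → detection filter → gene-name filter → arcsinh →
standardization.

* **Detection filter.** A gene is kept when the fraction of samples with a
  detection $p$-value below 0.05 is significantly above the 5% chance rate,
  by a one-sided *exact* binomial test at $\alpha = 0.05$ (both
  configurable). An exact test was chosen over the normal approximation
  because the decision sits at small tail probabilities where the
  approximation is unreliable; the test suite checks the implementation
  against direct summation of the binomial mass for all $n \le 50$.
* **Gene-name filter.** Placeholder identifiers (prefixes KIAA, FLJ, HS.,
  C*n*orf*n*, MGC, LOC, NT_, ENSG) denote uncharacterized transcripts whose
  enrichment results would be uninterpretable; the pattern set is a plain
  regular-expression list, and `C<digits>orf<digits>` encodes the
  chromosome-specific open-reading-frame convention.
* **arcsinh.** $\operatorname{arcsinh}(x) = \ln(x + \sqrt{x^2+1})$
  stabilizes variance across intensity levels; it is logarithm-like for
  large values and linear near zero, so background-level intensities need no
  pseudocount. The transform is a one-shot state transition — reapplication
  is refused.
* **Standardization** uses the $n-1$ variance denominator throughout the
  package (the same convention enters the ANOVA sums of squares), and fails
  loudly on zero-variance genes; the pipeline wrapper drops such genes with
  a warning first.

## Sample QC

Two distances are supported: $1 - |r|$ between arrays over genes
(expression) and $1 - \mathrm{IBS}$ between subjects over SNPs, where IBS is
the mean shared-allele fraction $(2 - |g_i - g_j|)/2$. Classical (Torgerson)
MDS embeds the samples; a sample is flagged when its robust distance —
per-axis $(x - \text{median})/\text{MAD}$, Euclidean norm over the first 2
dimensions — exceeds `kMad = 6`; the MDS is recomputed on survivors for up
to 3 rounds. A deterministic rule replaces visual outlier exclusion because
reproducibility demands one; `kMad = 6` is deliberately permissive (a
homogeneous Gaussian cloud of 500 samples is flagged in well under 5% of
realizations) since the filter exists to catch gross artifacts, not to trim
the population. The threshold, dimensionality and round count are exposed.

## Choosing the number of components

The observed eigenvalue scree (variance fractions from the SVD of the
standardized matrix) is compared with a null scree obtained by permuting the
samples independently within each gene, which preserves every gene's
marginal distribution while destroying co-expression. At step $s$ the
cumulative excess variance absorbed by the $s-1$ accepted components
(observed minus null) is removed from the remaining null variance, and the
bar for the $s$-th observed eigenvalue is the null's *largest* eigenvalue
rescaled to that remaining variance — the top eigenvalue a pure-noise
residual of that magnitude would produce. Comparing rank $s$ against the
null's rank-$s$ eigenvalue instead systematically under-corrects (the
residual after removing real components behaves like a fresh noise matrix,
whose top eigenvalue matches the null's rank 1, not rank $s$) and
over-selects $K$.

The observed eigenvalue must exceed the bar by a relative margin
`nullExcess = 0.05`. The margin absorbs the sampling fluctuation of a
single permutation curve: on pure noise the observed and permuted top
eigenvalues are exchangeable, so a strict comparison would accept a first
component in about half of realizations, while planted components of
practical interest sit several-fold above the bar. One permutation is the
default (`nPerm`); more permutations average the null curve.

## ICA estimation

Whitening is the truncated SVD of the standardized matrix, so the
decomposition lives exactly in the rank-$K$ subspace and
$\lVert X - SA\rVert_F$ equals the rank-$K$ truncation error by
construction. Genes are the observations. The unmixing rotation is estimated
by the symmetric (parallel) fixed-point iteration for the logcosh negentropy
contrast with $\alpha = 1$, with symmetric decorrelation after every update
and convergence declared when the rotation stabilizes to `tol = 1e-4`
(`maxIter = 200`). Ten seeded restarts are run (restart $r$ uses
`seed + r - 1`) and the run with the largest summed negentropy proxy
$(E[\log\cosh u] - E[\log\cosh Z])^2$ is kept; restarts that fail to
converge are recorded and skipped, and only a total failure raises an error.
Two conventions make the output deterministic and comparable across runs:
each signature is oriented so its skewness is $\ge 0$, and signatures are
scaled to unit variance over genes with the magnitude absorbed into $A$.

## Component filters

* **Individual-specific patterns.** The share of pattern variability
  carried by individual $j$ is $(a_j - \bar a)^2 / \sum_{j'} (a_{j'} - \bar
  a)^2$; a component whose maximal share strictly exceeds 10% reflects one
  aberrant sample rather than population co-regulation and is dropped first.
* **Kurtosis.** The signature filter `kurtosis >= 3` is read as *excess*
  kurtosis (moment form $m_4/m_2^2 - 3$; a Gaussian scores 0), because on
  the raw scale a Gaussian already scores 3 and the filter would be
  vacuous. Raw kurtosis is available via `excess = FALSE` for users who
  prefer the other reading.

## Module definition

Each signature's loading distribution is modeled as a mixture of a dominant
Gaussian null and an alternative in the tails. The null is centred at the
median; its scale $\sigma_0$ is the maximum-likelihood $\sigma$ of a
Gaussian truncated to the central 75% quantile window (`centralFraction`),
which is robust to tail contamination by construction; the null proportion
$\eta_0$ is the observed mass of the window divided by the fitted null mass
there (Storey-type), clipped to $(0, 1]$.

Membership uses the tail-area false discovery rate: with
$z_i = |s_{ik} - \text{center}|/\sigma_0$ and two-sided null tail
$P_0(t)$, the FDR at threshold $t$ is $\eta_0 G P_0(t) / \#\{|z| \ge t\}$,
evaluated at the observed $|z|$ and monotonized so q-values are
non-increasing in $|z|$; genes with $q < 10^{-3}$ form the module. A
stricter reading — plain null tail probability below the threshold — is
available as `method = "nullp"`; the q-value rule is the default because a
tail-area FDR is what "FDR < 10⁻³ membership" denotes, and the two rules
coincide on well-separated modules. Membership is invariant to affine
rescaling of the loadings (the scale folds into $\sigma_0$) and to global
sign flips.

Module overlap is the Jaccard ratio; gene-set enrichment is the upper-tail
hypergeometric test within the analyzed-gene universe, with a Bonferroni
family threshold `alphaFamily / #sets` computed over the sets that retain at
least `minSet = 5` genes after intersection with the universe — tiny sets
are untestable and would inflate the family size.

## Genotype QC and the two-step association scan

SNP QC drops variants with minor allele frequency $< 0.01$, exact
Hardy-Weinberg test $p < 10^{-4}$ (exact conditional test on the
heterozygote count given the allele counts), or call rate $< 0.95$. These
cutoffs are conventional GWAS values and configurable; missing genotypes are
handled pairwise per test, with no imputation, and an absent genotype class
reduces the degrees of freedom rather than invalidating the SNP.

Step 1 tests every pattern against every SNP by one-way fixed-effects ANOVA
with genotype as a categorical factor (2 df when all three classes are
present); pairs with $P < 10^{-7}$ are suggestive. The reported $R^2$ is
$SS_{\text{between}}/SS_{\text{total}}$ of the same categorical model, so
the test and the effect size are mutually consistent; an additive-coding
$R^2$ would be smaller whenever dominance is present.

Step 2 guards against a suggestive association carried by one or two genes
(e.g. a strong *cis* eQTL inside the module): the module must be enriched —
upper-tail hypergeometric test — in expression traits individually
associated to the SNP at $P < 10^{-5}$, by reference to the whole set of
analyzed genes (the universe is all genes surviving preprocessing, not the
module union). The enrichment threshold is study-wise Bonferroni,
$\alpha / (\#\text{modules} \times \#\text{SNPs})$, reported with the
mantissa truncated to three significant digits.

Mediation of a *trans* effect by *cis* transcripts is quantified as partial
$R^2$: both the trait and the genotype-class indicators are residualized on
the mediator expressions and the genotype $R^2$ is recomputed; a fully
mediated effect collapses toward zero. Pattern-phenotype correlation uses
the Pearson $t$ transform with pairwise-complete observations.

## Contamination surrogates

Genes specific to a non-target cell lineage are those over-expressed with a
fold change strictly above 2 in that lineage relative to *every* other
lineage in a linear-scale reference profile; a gene can satisfy this for at
most one lineage. The surrogate for a cell type in a sample is the mean of
its specific genes' expression values on the arcsinh (pre-standardization)
scale — standardization would erase the between-sample level differences the
surrogate must capture. Expression data are *not* pre-adjusted before ICA
(adjustment can induce artifactual correlations, since "cell-specific"
genes are usually also expressed at low levels in the target cell);
adjustment is post hoc: each significant SNP-pattern association is
re-tested in a linear model containing all surrogate columns, and it is
labelled contamination-driven when it is significant before adjustment but
not after, judged against the step-1 threshold $10^{-7}$ (configurable —
no sharper criterion for "lost significance" is defensible a priori).

## Replication

A module-SNP association replicates in an independent dataset when (1) at
least two module genes are associated to the SNP at 0.05 after Bonferroni
correction for the *full* module size (even when fewer genes were
measurable in the replication platform), and (2) the count of genes
associated at the nominal 0.05 level exceeds the 5% chance rate by a
one-sided exact binomial test at 0.05. Per-gene replication $p$-values come
from the same 2-df ANOVA, optionally after residualizing expression on
covariates (age, sex, centre); proxy-SNP substitution is the caller's
responsibility. The exact binomial form was chosen over the normal
approximation for the same reason as the detection filter.

## The synthetic-data generator

`simulateDataset()` plants the exact structure the analysis assumes, on the
arcsinh scale:

* **Signatures**: module genes load at $\pm$`loadingEffect` (sign
  equiprobable) with 10% multiplicative jitter; non-members load
  $N(0, \texttt{backgroundSd}^2)$. Fixed-magnitude signed loadings give
  strongly supergaussian signatures, so the kurtosis filter is exercised
  meaningfully. Defaults: 2000 genes × 300 samples, $K_{\text{true}} = 3$,
  50-gene modules, `loadingEffect = 1`, `backgroundSd = 0.05`.
* **Genotypes**: Binomial(2, MAF) draws (Hardy-Weinberg), default MAF 0.3.
* **SNP-driven patterns**: the activation is $\beta g + \epsilon$ with
  $\epsilon \sim N(0,1)$ and $\beta$ set analytically from
  $\mathrm{var}(\beta g) = 2\,\mathrm{maf}(1-\mathrm{maf})\beta^2$ so the
  SNP explains the requested fraction of pattern variance; the default 0.2
  sits inside the 2–25% range that genome-wide module scans report for
  their lead SNPs. Activations are then standardized (which leaves the
  variance fraction unchanged).
* **Cis effects**: `nCisPerComponent = 2` module genes of each driven
  component additionally receive a direct dose effect scaled to explain
  `cisR2 = 0.4` of their expression variance — emulating the situation
  where strong cis eQTLs at the locus mediate the trans associations.
* **Contamination** (optional): per-sample fractions are
  $|N(0, \texttt{fractionSd})|$ truncated at 0.5, and each cell type's
  genes (drawn outside the modules) gain `fraction × profile` with profiles
  uniform on [3, 6] — cell-specific transcripts are strongly expressed in
  the contaminating lineage and near-absent in the target cell, so the
  additive term must be large on the arcsinh scale for the surrogate to be
  estimable. This is the simplest model that reproduces
  contamination-driven artefactual patterns.
* **Noise**: iid $N(0, \texttt{noiseSd}^2)$, default 0.5.
* **Seeding**: one global seed streams per-purpose sub-seeds (genotypes,
  loadings, activations, noise, contamination, cis), so components can be
  regenerated independently.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (one causal SNP per component suffices for the two-step scan),
probe-level artifacts such as cross-hybridization, batch or array effects,
heavy-tailed intensity distributions, and correlated gene-level noise.
Passing tests on this generator therefore demonstrate the statistical
machinery under the model's own assumptions — not robustness to the
platform pathologies real microarray studies face.

## Numerical choices and degenerate inputs

* Variance uses the $n-1$ denominator everywhere.
* The HWE exact test and hypergeometric tails are computed in log space /
  via `phyper`; both are checked against exhaustive enumeration for all
  instances with $N \le 12$.
* ANOVA with zero within-class variance but unequal means reports $p = 0$
  flagged `degenerate`; a single genotype class reports $p = 1$, $R^2 = 0$
  flagged `untestable`.
* Zero-variance surrogate columns are dropped with a warning;
  rank-deficient mediator or surrogate designs fall back to least-norm
  fits with a warning.
* Zero-MAD axes in the outlier rule are skipped with a warning; a MAD of
  zero means the axis carries no robust spread information.
* The empirical-null optimizer searches $\log\sigma$ over
  $[\sigma_w/10,\, 10\,\mathrm{sd}]$, where $\sigma_w$ is the naive sd of
  the central window.

## Problem sizes used by the tests

The suite validates component-number selection on 1000 genes × 200 samples
(10 planted-rank-3 datasets and 10 pure-noise matrices), end-to-end
recovery on 20 simulated studies of 2000 genes × 300 samples with one
SNP-driven 50-gene module at $R^2 = 0.2$, ANOVA calibration on $10^4$ null
replicates plus a 10-pattern × 1000-SNP null scan, and contamination
discrimination on 20 + 20 scenarios of 500 samples. These sizes were chosen
so each run exercises the asymptotic regime the method needs (hundreds of
samples, thousands of genes) while keeping a full suite execution around a
minute.

## Known limitations

* Signatures are identified only up to the per-gene rescaling induced by
  standardization (see the caveat above); loadings of weakly expressed,
  noise-dominated genes are estimated with low precision.
* The number-of-components rule is conservative by design (5% margin over
  the corrected null); components explaining variance close to the noise
  bar will be missed.
* The empirical null assumes the central 75% of loadings is
  null-dominated; a component influencing more than ~25% of the
  transcriptome would inflate $\sigma_0$ and shrink its module.
* The contamination adjustment is post hoc: it flags associations explained
  by admixture but does not correct the decomposition itself.
* `GenotypeData` holds biallelic dose genotypes only; multi-allelic sites
  are skipped at VCF import.
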