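---
title: "Cell-type-aware TWAS: models, assumptions and design choices"
author: "cellTWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-aware TWAS: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellTWAS)
```

## The problem

A transcriptome-wide association study (TWAS) tests, gene by gene, whether
the genetically regulated component of expression (GReX) is associated
with a disease. The standard workflow trains, in a reference cohort with
both genotypes and expression, an elastic-net model of bulk expression on
nearby SNP dosages, and then applies the SNP weights to GWAS genotypes to
obtain predicted expression for association testing.

Bulk tissue, however, is a mixture of cell types. A mammary tissue sample,
for instance, is mostly stroma with a minority of epithelial cells — the
cell of origin of most breast carcinomas. If a variant regulates a gene
only in epithelium, or in opposite directions in epithelium and stroma,
the tissue-level average dilutes or cancels the signal. cellTWAS
implements a cell-type-aware alternative for two cell classes (the cell
type of interest versus everything else): it estimates the proportion of
the cell type of interest in each training sample, trains *per-cell-type*
SNP weights by decomposing the bulk signal, and tests a composite null —
no GReX–disease association in *any* cell type — by combining the
cell-level p-values with the Cauchy combination.

## Estimating the cell-type proportion

Bulk expression of a signature gene $g$ in sample $i$ is modelled as

$$ w_i^g = \pi_i s_i^g + (1 - \pi_i) t_i^g, \qquad
   s_i^g \sim N(\mu_1^g, \sigma_1^{g2}), \quad
   t_i^g \sim N(\mu_2^g, \sigma_2^{g2}), $$

so that marginally $w_i^g$ is Gaussian with mean
$\pi_i \mu_1^g + (1-\pi_i)\mu_2^g$ and variance
$\pi_i^2 \sigma_1^{g2} + (1-\pi_i)^2 \sigma_2^{g2}$ (cell-level noise is
taken independent between the two components; the mixture model itself
never states this variance, so the package adopts the independence form
explicitly). Gene–gene correlations are ignored: the estimator leans on
mean differences of signature genes, not on covariance structure.

A prior per-sample enrichment score $h_i$ (an xCell-style score rescaled
to the unit interval by `rescalePrior()`) is tied to the truth through
$h_i \sim \mathrm{Beta}(\pi_i\delta, (1-\pi_i)\delta)$ — unbiased, with a
learned concentration $\delta$ that calibrates how much the prior is
trusted.

`fitSignatureMixture()` maximizes the joint log-likelihood by block
coordinate ascent rather than a latent-variable EM: because the marginal
of $w$ is available in closed form there is no need for an E-step, the
stationary points are the same, and each block update (per-gene Gaussian
parameters by Nelder–Mead; per-sample $\pi_i$ by 1-D bounded search on
$[0.01, 0.99]$; $\delta$ by 1-D search on $[0.1, 10^4]$, initialized at
10) is accepted only if it does not decrease the objective, which makes
monotonicity a testable invariant rather than a hope. Convergence is a
relative objective change below $10^{-6}$ (at most 500 sweeps).

Label switching is resolved by initializing $\pi$ at the prior: component
1 is anchored to whatever cell type the prior describes, with no ordering
constraint on the means. Flipping the prior ($h \to 1-h$) therefore flips
the estimate and swaps the component parameters — a symmetry the test
suite checks.

`estimateCellProportions()` adds bagging: by default 100 bootstrap draws
of 80% of the samples (with replacement), each refitted, each scoring all
samples; per-sample estimates are aggregated by a tail-truncated mean
dropping the extreme 5% from each tail. Trimming is applied per sample
rather than to whole bootstrap replicates — the alternative reading was
considered and rejected because a replicate can be excellent for most
samples and extreme for one.

## Cell-type-level GReX models

With $\widehat\pi$ in hand, bulk expression of a candidate gene obeys

$$ y_i = \widehat\pi_i u_i + (1 - \widehat\pi_i) v_i, \qquad
   u_i = a_1 + x_i^\top b_1 + z_i^\top c + e_{1i}, \quad
   v_i = a_2 + x_i^\top b_2 + z_i^\top c + e_{2i}. $$

Substituting and writing $\hat c_i = \widehat\pi_i - 0.5$ gives a single
regression whose coefficients are $(b_1 + b_2)/2$ on the SNP block and
$b_1 - b_2$ on the $\hat c$-by-SNP interactions. `trainCellAwareModel()`
fits it with glmnet ($\alpha = 0.5$, $\lambda$ at the ten-fold
cross-validation minimum with seeded folds, matching the tissue-level
convention), penalizing the SNP, interaction and covariate blocks while
leaving the intercept and the $\hat c$ main effect free. This *symmetric*
penalization is the point: both cell types are regularized identically,
so relabelling the cell types merely relabels the model. The package
also ships the raw asymmetric parameterization
(`trainAsymmetricModel()`, penalizing $(b_2, b_1 - b_2, c)$), purely as a
benchmark that demonstrably violates that invariance.

All penalized columns are standardized inside the solver with
coefficients back-scaled, and interaction columns receive no extra
penalty factor; since $\hat c \in (-0.5, 0.5)$, leaving them
unstandardized would implicitly over-penalize the interactions. The
residual $\epsilon_i = \widehat\pi_i e_{1i} + (1-\widehat\pi_i) e_{2i}$
is heteroscedastic in $\widehat\pi_i$; the fit deliberately assumes a
constant variance, trading a negligible loss of estimation accuracy for
the fast solver.

### Deciding specific versus nonspecific

A nonzero fitted $b_1 - b_2$ may be a real cell-type-specific effect or
an artifact of liberal CV-minimum selection. The package assesses it with
a stability bootstrap (`B = 200` resamples): each resample is (a)
refitted by OLS on the columns the full-data fit pre-selected, yielding
percentile confidence intervals of each per-SNP difference, and (b)
re-run through the elastic-net selection at the chosen $\lambda$,
yielding each interaction's selection frequency. The model is declared
cell-type-specific only when some SNP's 95% interval excludes zero *and*
that SNP is re-selected in at least 80% of resamples (a conventional
stability-selection threshold). The interval criterion alone is
anti-conservative — OLS on columns chosen by the penalized fit inherits
the selection's optimism, and in simulations it labelled the majority of
genes with genuinely homogeneous SNP effects as specific — while
re-selection intervals alone are far too conservative. The joint rule
keeps false specificity low under homogeneity while detecting true
heterogeneous architectures most of the time. When the rule is not met
the model collapses to the tissue-level elastic-net fit, with identical
weights in both cell types.

GReX prediction (`predictGrex()`) applies SNP weights only — no
intercepts, no covariates — so predictions transfer to cohorts lacking
the training covariates; genes whose fit selects no SNP are flagged
untrainable and excluded from association testing.

## Association testing

For a cell-type-specific model the two predicted GReX vectors
$\tilde y_1, \tilde y_2$ come from the same genotypes with jointly
learned weights, so each can leak the other's signal; testing them
separately against the phenotype would inflate per-cell-type error. The
package therefore tests the composite null — no association in any cell
type — by fitting one joint GLM (or two marginal GLMs when
$|\mathrm{cor}(\tilde y_1, \tilde y_2)| \ge 0.99$ or one prediction is
constant) and combining the Wald p-values with the Cauchy combination:

$$ T = \tfrac12\tan\{\pi(0.5 - p_1)\} + \tfrac12\tan\{\pi(0.5 - p_2)\},
   \qquad p_{\text{tissue}} = \tfrac12 - \arctan(T)/\pi. $$

The combination is valid under arbitrary dependence, which is exactly
what the leakage situation requires. Weights $\tfrac12, \tfrac12$ are the
default: with weights summing to one the combined p-value always lies
between its inputs and equals them when they agree; the plain unweighted
two-term sum (available via `weights = c(1, 1)`) is anti-conservative
under dependence and is provided only for comparison. Inputs are clipped
to $[10^{-15}, 1 - 10^{-15}]$ before the tangent transform so extreme
p-values remain finite and reproducible.

Nonspecific models make the two predictions identical, and the pipeline
then reduces exactly to a single tissue-level test (`mode = "single"`).
`transcriptomeWide()` annotates a result set with the Bonferroni
threshold (FWER divided by the number of *testable* genes — untrainable
genes leave the denominator, mirroring how such genes are reported as
untestable in practice) and Benjamini–Hochberg discoveries.

## The simulation engine

`runStudy()` reproduces the type-I-error/power design: per replicate, a
training cohort (default $N = 300$) with a 50-SNP genotype block (MAF
uniform on $[0.05, 0.50]$, independent Hardy–Weinberg binomial draws —
an independent-SNP stand-in without linkage disequilibrium, so realized
heritability only approximates a reference-panel simulator), minor
cell-type proportion $\pi \sim \mathrm{Beta}(2, 3)$ (mean 40%),
cell-level expression $u = b_0 + Xb_1 + e$, $v = Xb_2 + e$ with unit
noise and causal SNPs drawn uniformly with random signs, and bulk
$y = \pi u + (1-\pi)v$. An independent GWAS cohort (default $M = 3000$)
shares the causal architecture; disease follows a logistic model in
$(u, v)$ whose intercept is calibrated by root finding so the expected
case fraction is exactly one half (deterministic given the draws, unlike
rejection sampling). Covariates are omitted throughout, which isolates
the behaviour of the predicted GReX.

Scenario presets cross the SNP-expression architecture (homogeneous
`hom-`: one shared causal SNP; heterogeneous `het-`: distinct causal SNPs
with $|b| = 1$ and $b_0 = 1$) with the expression–disease pattern (null;
homogeneous $\eta = (0.2, 0.2)$; major cell $(0, 0.2)$; minor cell
$(0.2, 0)$; opposite $(-0.2, 0.2)$). Proportion misspecification is
injected directly into training via `misspecifyPi()` ($0.8\pi$;
$0.7\pi + 0.2$; Beta draws at concentration 50 or 5.5) — the training
prior otherwise defaults to the truth so that model and test behaviour is
isolated from proportion-estimation noise. Note the Beta scenarios'
correlations with the truth follow from the mixture moments as 0.95 and
0.75 respectively; tests check those closed forms. A latent third cell
type is available in two flavours (`"shared"`: its SNP effects equal cell
2's; `"distinct"`: its own causal SNP); its per-sample proportions are
drawn as $\pi_1 \sim \mathrm{Beta}(2,3)$ with the remainder split 5:1
between cells 2 and 3, giving mean proportions of 40%, 50% and 10% — a
constant-proportion design would make the interaction block collinear
with the SNP block and the decomposition unidentifiable.

Replicates in which a model selects no SNPs count as non-rejections for
that method (such genes are untestable in practice); replicates failing
outright are skipped, with more than 10% failures an error.

## Problem sizes and what the tests show

The shipped test suite and acceptance script run the null calibration at
200 replicates (95% acceptance band $[0.02, 0.09]$ around a nominal
0.05) and the power comparisons at 150–200 replicates per scenario;
proportion-recovery checks use 200 samples and 50 signature genes. These
sizes give Monte Carlo standard errors of 1.5–3.5 percentage points on
rejection rates, tight enough for the qualitative orderings being
checked. What passing shows: the composite test holds its level, the
cell-type-aware test beats the tissue-level baseline when the
association is confined to the minor cell type or has opposite signs in
the two cell types, and loses nothing material when effects are
homogeneous. What it does not show: behaviour under linkage
disequilibrium, under non-Gaussian expression noise, or with real
enrichment-score priors — the generator draws independent SNPs and
Gaussian noise, and real bulk data have neither luxury.

## Known limitations

* Two cell classes only; finer decompositions are out of scope.
* No summary-statistics mode: association testing needs individual-level
  genotypes.
* The model store is plain TSV (with a PredictDB-style single-weight
  export for nonspecific models); no SQLite backend.
* Strand-ambiguous (A/T, C/G) SNPs are dropped during harmonization by
  default rather than resolved by frequency.
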