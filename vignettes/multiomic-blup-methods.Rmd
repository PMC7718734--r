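---
title: "Methods: multi-omic BLUP prediction for inbred line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic BLUP prediction for inbred line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistical machinery it
implements: the mixed models and their assumptions, the numerical choices
inside the REML engine, the cross-validation protocol, the TWAS- and
GO-informed variants, and what the synthetic-data generator does and does
not emulate.

## The model family

All models operate on line means of a panel of inbred lines: each line's
phenotype is the average over many genetically identical individuals, so
most of the usable variation among lines is genetic, and the analysis
works with one observation per line. The base model is

$$ y = \mathbf{1}\mu + \sum_c u_c + e, \qquad
   u_c \sim N(0, K_c\,\sigma^2_c), \qquad e \sim N(0, I\,\sigma^2_e), $$

with one random line effect per relationship kernel $K_c$. The kernels are
linear similarities over standardized feature matrices: the genomic
relationship matrix $G = WW'/p$ over $p$ variant dosages (GBLUP), the
transcriptomic relationship matrix $T = ZZ'/m$ over $m$ log-scale
transcript abundances (TBLUP), both together (GTBLUP), and additionally
the Hadamard product $G \mathbin{\#} T$ as the genome-by-transcriptome
interaction covariance (GTIBLUP). The GO-partitioned variants replace one
layer's kernel with an in-term/out-of-term pair built from a single global
standardization, so that
$|{\rm in}|\,K_{\rm in} + |{\rm out}|\,K_{\rm out} = p\,K_{\rm full}$
holds exactly — an identity the test suite checks on every simulated
bundle.

Assumptions worth stating explicitly: effects are additive within a layer
(the interaction kernel adds one specific multiplicative structure, not
general epistasis); all features of a layer contribute equally in
expectation (an infinitesimal architecture — the TWAS and GO variants
exist precisely to relax this); and lines are exchangeable apart from the
kernel structure (no explicit population structure correction beyond what
the kernels absorb).

## Standardization and kernels

Feature columns are centered and scaled by the *population* (divisor-$n$)
standard deviation. With that convention the mean diagonal of every linear
kernel is exactly 1 and row sums are exactly 0, which makes variance
components directly comparable across layers and gives the test suite
exact invariants instead of approximate ones. The divisor choice only
rescales all variance components jointly and leaves Pearson prediction
accuracy unchanged. Zero-variance columns (monomorphic variants, flat
transcripts) are dropped and reported.

Kernels are built once on all lines, training and test together, because
the similarity matrices are defined over the full panel; variance
components are nonetheless estimated on training lines only. The mild
information flow through the column means is accepted as part of the
protocol and is shared by all models being compared. Standardizing within
each training fold instead is possible but was not adopted: it breaks the
exact partition identity across folds and complicates the paired
comparison of models on shared folds, while simulations show no material
change in the accuracy contrasts.

## The REML engine

`kblup()` maximizes the restricted likelihood of
$V(\theta) = \sum_c \sigma^2_c K_c + \sigma^2_e I$ with the intercept
profiled out.

* **Single-kernel models** are solved exactly: after one symmetric
  eigendecomposition of the kernel, the likelihood is profiled down to a
  one-dimensional search over the genetic proportion
  $\phi = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ on $[0, 1)$, solved by
  golden-section/parabolic search to $10^{-10}$, with the boundary
  $\phi = 0$ compared explicitly. Every cross-validation fold of a
  GBLUP/TBLUP model costs one eigendecomposition and an $O(n)$ profile.
* **Multi-kernel models** use average-information (AI) REML. Each
  iteration forms the projection matrix, takes an AI step on the active
  components with step-halving, and falls back to an EM update (guaranteed
  ascent, slower) when the AI step fails or degrades the likelihood.
* **Non-negativity.** Components are clamped at zero and flagged; a
  clamped component with an outward-pointing score is held fixed by an
  active-set (KKT) rule, which is what lets fits converge cleanly when a
  component — including the residual, whose floor is
  $10^{-10}\,\mathrm{var}(y)$ — sits on the boundary. Permitting negative
  components (as some REML software does) would sometimes fit better in
  likelihood but can produce invalid covariances; prediction accuracy is
  insensitive because a clamped component contributes nothing to the
  predictor.
* **Convergence** is declared when the relative change in restricted
  log-likelihood falls below $10^{-8}$ and either the last AI step
  succeeded or the active-set scores are numerically zero, with a cap of
  200 iterations. All components start at
  $\mathrm{var}(y)/(\text{number of kernels} + 1)$ so the initial total
  equals the sample variance.

The engine is validated two ways, both frozen into the test suite: its
optimum is compared against a coarse grid refined by Nelder-Mead on a
directly coded restricted likelihood (agreement within $10^{-4}$ on
two-kernel problems at $n = 60$), and `blup_predict()` is compared against
the conditional mean obtained by assembling the joint train-plus-test
covariance and applying the partitioned-normal formula (agreement within
$10^{-8}$ at $n \le 30$). If the training covariance is numerically
singular, its diagonal is jittered by $10^{-8}\,\mathrm{tr}(V)/n$ with a
warning.

## Cross-validation protocol

`make_cv_design()` draws, per replicate, a seeded shuffle of the lines
split into $k$ near-equal folds (defaults $k = 5$, 30 replicates). Lines
missing the trait are dropped before fold assignment. One design is shared
across all models and all GO terms of a comparison so the contrasts are
paired. Accuracy is the sample Pearson correlation per fold; fold-level
values are averaged, and the standard error of the mean is taken over all
$k \times \text{reps}$ fold values (the alternative — SEM over replicate
means — is a flag away, but fold-level matches the per-fold averaging of
the summaries). Predictions with zero variance (an all-clamped fit
predicting the training mean) score $r = 0$ with a degenerate flag rather
than `NA`, keeping aggregation total; non-convergent folds are recorded as
missing, excluded from means, and counted in a warning.

In-fold feature selection — the TWAS scan and the random-gene control — is
a deterministic function of that fold's training lines and a seed derived
from (replicate, fold), never of test phenotypes; a test permuting the
held-out phenotypes and checking the selected sets are unchanged guards
the protocol against leakage.

## TWAS- and GO-informed models

The TWAS scan regresses the (already covariate-adjusted) line means on one
transcript at a time by OLS and tests the slope with a two-sided $t$ at
$n-2$ degrees of freedom. No further covariates enter because adjustment
happens upstream on the line means; constant transcripts get $p = 1$.
Selection takes transcripts with $p$ strictly below the threshold; an
empty selection at stringent thresholds degrades that fold to an
intercept-only prediction scoring $r = 0$, so stringent-threshold
accuracies fall rather than error out.

GO terms are eligible when at least five of their genes lie in the
relevant feature universe (expressed genes for transcript models; genes
that mapped variants hit for variant models; the intersection of both
eligibility lists for the combined model). The GO hierarchy is *not*
propagated — a gene belongs only to the terms listed in the input map —
because ancestor closure is an annotation-pipeline decision better made
upstream; users may pre-close the map. Variants map to a gene when they
fall within the gene body extended by a configurable window (default
1 kb, recorded in outputs); the window default is a conventional
cis-regulatory margin, and mapping is inclusive on both boundaries.
Ranking breaks accuracy ties by the larger in-term variance share, then
term id, so the output list is deterministic regardless of evaluation
order.

## Random Forest comparison

The non-parametric comparison is a regression forest on raw transcript
abundances, backed by the `randomForest` package with its documented
regression defaults ($m_{\rm try} = \lfloor m/3 \rfloor$, minimum node
size 5) and 1000 trees. Feature columns are ordered by id before fitting
so results are invariant to column order, and the seed makes fits and
predictions bitwise reproducible.

## The synthetic-data generator

The generator emulates the statistical skeleton the models assume, not
*Drosophila* biology:

* **Genotypes** are fully homozygous dosages in $\{0, 2\}$ with per-variant
  allele frequencies uniform on a configurable band (default
  $[0.05, 0.5]$) and block LD from a first-order copying process (within a
  block, each variant copies its neighbour's allele with probability 0.8
  by default). This produces realistic kernel eigenstructure at desk
  scale; it is not a coalescent and has no allele-frequency spectrum,
  population structure, or recombination map.
* **Expression** gives each gene a handful of randomly placed eQTLs
  (default 5) plus Gaussian noise, scaled so a target fraction of each
  gene's variance is genetic (default 0.5).
* **Phenotypes** follow one of four architectures — variant-additive,
  transcript-mediated, mixed (equal shares), or genome-by-transcriptome
  interaction — with $N(0,1)$ effects applied to *standardized* features,
  so every causal feature contributes equal expected variance, exactly the
  prior the BLUP models assume; this is what makes variance-proportion
  recovery a well-posed check. Noise is orthogonalized against the signal
  and scaled so the realized signal fraction equals the target exactly in
  the simulated sample.
* **Annotation** draws overlapping gene sets as GO terms (an optional
  causal term contains exactly the causal genes) and lays gene spans end
  to end on a toy chromosome so the variant-mapping code paths are
  exercised.

Sexes, when needed, are two independent bundles sharing genotypes; line
means are generated directly with no within-line replicate structure.
Because the generator satisfies the models' assumptions by construction,
passing tests demonstrate the *machinery* — estimation, prediction,
selection, ranking — is correct and leak-free; they do not demonstrate
that real transcriptomes predict real traits, which depends on biology the
generator deliberately omits (correlated expression networks, skewed
allele frequencies, shared eQTL architecture, environment).

## Problem sizes in the tests and acceptance runs

Test fixtures default to 200 lines — the panel size the models were
designed around. The full-scale feature counts (around $10^6$ variants,
$10^4$ transcripts) are pointless at $n = 200$ for *contrast* tests:
single-layer accuracy behaves like
$\sqrt{h^2\, n h^2 / (n h^2 + m_e)}$ in the effective feature count
$m_e$, so with $m \sim 2000$ every model lands near $r \approx 0.2$ and
qualitative contrasts drown in fold noise. The contrast and GO-scan
fixtures therefore use a 400-gene transcriptome (and 150–200 lines, 2
replicates of fivefold CV for scans, 10 for model contrasts), at which the
transcript-mediated signal is estimable and the expected ordering —
TBLUP well above GBLUP on a transcript-mediated trait, the combined model
within noise of the best single layer on a mixed trait, the causal GO term
at the top of the scan with accuracy tracking variance share rather than
term size — is resolvable. The unit suite separately exercises the
full-dilution regime. Variance-proportion recovery uses $n = 200$,
$p = 1000$, all variants causal, 50 seeds per heritability level.

## Data preparation conventions

* Filters are strict inequalities as conventionally printed: variants kept
  at MAF $> 0.05$ and call rate $> 0.8$; genes kept at mean expression
  $> -1.828\ \log_2$FPKM. The expression threshold is the antimode of a
  bimodal abundance distribution and is consumed here as a configuration
  parameter, not re-derived.
* Residual heterozygous calls in an inbred panel are treated as no-calls
  by default (configurable to dosage 1): with full-sib inbreeding they are
  most plausibly genotyping artifacts.
* Remaining missing dosages after filtering are mean-imputed per variant,
  which keeps the kernel formula exact on a complete matrix and is
  standard in genomic prediction.
* Phenotype adjustment regresses each trait on an intercept plus the named
  covariates by OLS and keeps residuals plus the grand mean; aliased
  covariate columns are dropped with a warning; lines missing covariates
  are dropped and reported. This preserves the trait mean and never
  inflates its variance.
* Joining layers always reduces to the sorted intersection of line ids,
  and every object records which of its ids were dropped.

## Known limitations

The engine stores dense $n \times n$ kernels and does dense solves; it is
sized for panels of hundreds of lines, not thousands of individuals. No
standard errors are reported for variance components, and no
likelihood-ratio machinery is provided. The GO scan evaluates terms
marginally; selecting top terms in-training and combining them into one
model would need a bias-aware selection procedure and is deliberately out
of scope.
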