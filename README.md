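# omniblup

Multi-omic best linear unbiased prediction for inbred line panels.

## The problem

Panels of fully inbred, fully sequenced lines — the *Drosophila
melanogaster* Genetic Reference Panel (DGRP) being the canonical example —
allow line-mean phenotypes, genome-wide variants, and transcript abundances
to be measured on the *same genotypes*. A natural question is how much each
molecular layer, alone or combined, can predict a complex trait, and
whether functional annotation (Gene Ontology) sharpens that prediction.
`omniblup` implements this multi-layer prediction analysis as a tested,
reusable pipeline for statistical geneticists: data ingestion (VCF / GFF3 /
TSV), the standard preparation filters, relationship-kernel construction,
multi-kernel REML, replicated cross-validation, TWAS-informed and
GO-partitioned models, a Random Forest comparison, and a synthetic
inbred-panel generator so every stage runs and is verifiable at desk scale.

## The models

The analysis unit is the line mean. The baseline is the linear mixed model

    y = 1 mu + g + e,   g ~ N(0, G sigma2_g),   e ~ N(0, I sigma2_e)

where **G** = W W' / p is the genomic relationship matrix (GRM) from the
centered-and-standardized dosage matrix W of p variants (GBLUP). Swapping
**G** for the transcriptomic relationship matrix **T** = Z Z' / m from m
standardized transcript abundances gives TBLUP; fitting both terms gives
GTBLUP; adding an interaction term with covariance **G # T** (the Hadamard,
element-wise, product) gives GTIBLUP:

    y = 1 mu + g + t + g×t + e

Variance components are estimated by REML (average-information steps with
an EM fallback, components constrained non-negative; single-kernel models
are solved exactly on the heritability profile after one
eigendecomposition). Each component's share of the phenotypic variance is
`sigma2_c / (sum_c sigma2_c + sigma2_e)`. Held-out lines are predicted by
BLUP,

    yhat_test = mu + C V^-1 (y_train - mu),

with `V` the fitted training covariance and `C` the test×train covariance
block, and accuracy is the Pearson correlation r between observed and
predicted line means, averaged over the folds and replicates of a
replicated k-fold cross-validation (5 folds, 30 replicates by default).

On top of the four base models the package provides:

* **TWAS-informed TBLUP** — within each training fold, phenotype is
  regressed on each transcript; transcripts with p below a threshold build
  a trait-specific TRM (with a random-gene control of matched size).
* **GO-partitioned models** — for every GO term with ≥ 5 annotated genes,
  the feature set is split into in-term and out-of-term kernels
  (GO-GBLUP, GO-TBLUP, GO-GTBLUP), each term is scored by cross-validated
  accuracy, and scan diagnostics correlate accuracy with term size and
  with the in-term variance share.
* **Random Forest** on transcript abundances (1000 trees, regression
  defaults) as a non-parametric comparison.

## Worked example

Simulate a 200-line panel whose trait is mediated by 50 transcripts
(h² = 0.7, transcripts 50% under eQTL control), fit the combined model,
and contrast genomic against transcriptomic prediction:

```r
library(omniblup)

bundle <- simulate_bundle(n_lines = 200, p_variants = 2000, n_genes = 400,
                          architecture = "transcript_mediated",
                          h2_target = 0.7, n_causal_genes = 50,
                          genetic_fraction = 0.5, seed = 1)
y   <- trait_values(bundle$phenotype, "trait")
grm <- linear_kernel(standardize_columns(bundle$genotypes$dosages), "GRM")
trm <- linear_kernel(standardize_columns(bundle$expression$abundances), "TRM")

fit <- kblup(y, list(GRM = grm, TRM = trm))
summary(fit)
#> Multi-kernel BLUP fit (REML), n = 200 lines
#> Variance components:
#>   GRM          0 (at boundary)
#>   TRM          0.895537
#>   residual     0.515555
#> Intercept: 6.37847e-17   restricted logLik: -308.4710   converged (5 iter)
#> Variance proportions (training set):
#>   GRM          0.000
#>   TRM          0.635
#>   residual     0.365

cv    <- make_cv_design(sort(names(y)), k = 5, n_reps = 10, seed = 2)
gblup <- run_model_cv("GBLUP", y, genotypes  = bundle$genotypes,  cv = cv)
tblup <- run_model_cv("TBLUP", y, expression = bundle$expression, cv = cv)
gblup
#> GBLUP cross-validation: 5-fold x 10 replicates
#>   mean r = 0.099 +/- 0.014 (SEM over 50 folds)
#>   prop_GRM       0.211 +/- 0.021
#>   prop_residual  0.789 +/- 0.021
tblup
#> TBLUP cross-validation: 5-fold x 10 replicates
#>   mean r = 0.430 +/- 0.016 (SEM over 50 folds)
#>   prop_TRM       0.652 +/- 0.012
#>   prop_residual  0.348 +/- 0.012
```

Because the trait runs through the transcriptome, the transcript kernel
absorbs the signal: in the joint fit the genomic component is clamped at
the zero boundary, and in cross-validation TBLUP (r = 0.43) far outperforms
GBLUP (r = 0.10) while the in-fold variance shares mirror that gap. A GO
scan over such a bundle (`run_go_scan`, `rank_go_terms`,
`go_scan_diagnostics`) recovers the causal term and shows accuracy tracking
the in-term variance share rather than term size.

A thin command-line wrapper over these functions ships in
`inst/cli/omniblup.R` (subcommands `simulate`, `cv`, `twas`, `go-scan`);
repeated runs with the same `--seed` are byte-identical.

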