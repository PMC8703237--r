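# metaboSurrogates

Metabolomics-based surrogates for clinical risk factors: an R package
implementing the full multi-biobank workflow for imputing dichotomous
clinical variables from a quantitative ¹H-NMR metabolite panel, and for
using the resulting surrogate values in downstream epidemiology.

## The problem and the method

Clinical variables (medication use, blood pressure, kidney function,
diabetes status, …) are frequently missing in large cohort collections,
while a standardized ~56-marker NMR metabolomics panel is often available
for everyone. For each dichotomous clinical variable *c<sub>k</sub>* the
package fits a penalized logistic regression over the z-scaled marker
vector *m*,

&nbsp;&nbsp;&nbsp;&nbsp;π<sub>k</sub> = Pr(c<sub>k</sub> = 1 | m) = 1 / (1 + e^−(β₀ + βᵀm)),

with the elastic-net penalty at mixing α = 0.5 and the penalty weight λ
selected by repeated stratified 5-fold cross-validation (minimum mean
held-out binomial deviance). The posterior π<sub>k</sub> — the *metabolic
surrogate* — is a continuous stand-in for the missing variable: it can be
correlated with other surrogates, used as a covariate in metabolome-wide
association studies (MetaboWAS), or entered into Cox models for
all-cause mortality.

The package covers every stage:

| Stage | Functions |
|---|---|
| Synthetic multi-biobank data with planted truth | `simulateCohorts()`, `injectArtifacts()`, `plantSurvival()` |
| Metabolomics QC (panel, filters, NIPALS imputation, z-scaling) | `qcPreprocess()`, `filterSamples()`, `imputeNIPALS()`, `zScale()` |
| Clinical binarization incl. Friedewald LDL, CKD-EPI eGFR | `deriveClinicalVariables()`, `friedewaldLDL()`, `ckdEpiEGFR()` |
| Surrogate training & validation (double 5-fold CV, LOBOV) | `trainSurrogate()`, `evaluateCV()`, `evaluateLOBOV()` |
| Projection & model interchange | `predictSurrogate()`, `writeSurrogateModel()` |
| MetaboWAS with effective-tests Bonferroni correction | `runMetaboWAS()`, `effectiveTests()`, `compareAdjustments()` |
| Clustered Cox mortality association, stepwise AIC | `coxAssociation()`, `surrogateMortality()`, `stepwiseCox()` |
| Reproducible end-to-end run with manifest | `runPipeline()` |

Because the individual-level biobank data this methodology was developed
on are access-restricted, the package ships a synthetic generator whose
ground truth (factor loadings, batch offsets, liability separations with
binormal oracle AUC Φ(d/√2), family-clustered hazards) is fully recorded,
so every stage is testable end to end.

## Worked example

```r
library(metaboSurrogates)
library(SummarizedExperiment)

sim <- simulateCohorts(nCohorts = 4, cohortSizes = 150, seed = 101)
qc  <- qcPreprocess(sim$dataset)
qc$report
#> QCReport
#>   removed: 0 missing-cell, 0 zero-cell, 48 >5 SD outlier
#>   imputed cells: 0 (0.0000% of retained cells)
#>   scaling parameters stored for 56 markers

X <- scaledMatrix(qc$dataset)
y <- colData(qc$dataset)$strong_signal    # planted oracle AUC 0.95
ev <- evaluateCV(X, y, nRepeatsOuter = 1, nRepeatsInner = 1,
                 phenotype = "strong_signal", seed = 3)
ev
#> EvaluationReport 'strong_signal' [cv]: mean AUC = 0.920, weighted AUC = 0.920 (PASS at AUC > 0.70)
#>   5 evaluation folds
```

The report says the double cross-validated AUC of the trained surrogate
(0.920 on this small run) recovers the planted oracle AUC of 0.95 and
clears the AUC > 0.7 adequacy bar. At the full demo scale (10 cohorts ×
500 samples, 5×5-fold double CV) recovery is within ±0.05 for planted
AUCs of 0.95, 0.90, 0.75 and 0.50, in exact rank order.

A complete run — simulation with injected artifacts, QC, clinical
derivation, training/evaluation, projection, MetaboWAS and survival
association, with every artifact hashed into a manifest — is one call:

```r
res <- runPipeline("run1", seed = 5)
```

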