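---
title: "Metabolic surrogates: models, assumptions and design choices"
author: "metaboSurrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic surrogates: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Large epidemiological collections routinely miss clinical variables —
medication status, blood pressure, kidney function — whose absence costs
statistical power. When quantitative ¹H-NMR metabolomics has been assayed,
much of that information is recoverable: the concentration profile of ~56
circulating markers carries signal on a broad set of cardio-metabolic risk
factors. This package builds *metabolic surrogates* for such variables: for
each dichotomous clinical variable $c_k$ a penalized logistic regression

$$\pi_k \;=\; \Pr(c_k = 1 \mid X = m) \;=\; \frac{1}{1 + e^{-(\beta_0 + \beta^T m)}}$$

over the z-scaled marker vector $m$, fitted with the elastic-net penalty
$\lambda\{\alpha\lVert\beta\rVert_1 + (1-\alpha)\lVert\beta\rVert_2^2/2\}$ at
$\alpha = 0.5$. The posterior probability $\pi_k$ — deliberately left
uncalibrated — is the surrogate value: a continuous stand-in that can be
correlated, adjusted for, or entered into survival models in place of the
missing variable.

The modelling assumptions are those of any linear logistic score: the
log-odds are approximately linear in the standardized markers, the training
prevalence (absorbed by $\beta_0$) transfers to the application cohort, and
the marker panel is measured on a comparable scale everywhere. The last two
assumptions are exactly what the leave-one-biobank-out validation (LOBOV)
probes.

## Quality control

`qcPreprocess()` applies, in order: panel restriction (`selectPanel()`,
dropping markers on the exclusion list and failing loudly when a required
marker is absent — working silently with a reduced feature space would make
models incomparable); sample filters; NIPALS imputation of whatever cells
remain missing; z-scaling.

The three sample filters mirror standard practice for this panel type:
remove samples with (1) more than `maxMissing` missing values (default 0),
(2) any zero concentration, (3) any marker further than `sdLimit = 5`
sample SDs from the marker mean. A sample is removed at the first rule it
violates. The mean/SD of rule 3 are computed *after* rules 1–2 by default
(`statsAfterFilters = TRUE`): contaminated samples would otherwise inflate
the SD and hide true outliers; the switch is exposed for users who prefer
the whole-input convention. Zero-variance markers produce no outliers
(guarded division). Note a structural fact the tests also rely on: among
$n$ samples the largest attainable z-score is $(n-1)/\sqrt{n}$, so a 5-SD
rule can only ever fire when roughly 28 or more samples contribute to the
column statistics.

A filtering policy of "drop any sample with a missing value" coexists
uneasily with an imputation step; we resolve it by making the per-sample
missing ceiling configurable: at the default ceiling of 0 the imputation
step only sees data when the user relaxes `maxMissing`, and whatever cells
then remain missing are completed by `imputeNIPALS()`.

NIPALS imputation fits principal components by alternating regressions
whose inner products skip missing entries, and replaces missing cells by
the rank-$k$ reconstruction plus column means. Because the column means
themselves depend on the imputed cells, the fit is wrapped in a refinement
loop that re-centres on the completed matrix until the imputed values
stabilise (relative tolerance `1e-9`, limit 500 rounds, non-convergence is
an error with diagnostics). Components are always fitted to observed cells
only — this matters: if components could see imputed cells, a single
missing cell could be "explained" by a component of its own (a one-cell
spike is itself rank one) and the procedure would happily confirm any
value. On input consistent with a low-rank model the fixed point is the
exact reconstruction, which is what the rank-1 oracle test asserts at
`1e-6`. The component count defaults to the number of components explaining
95% of the variance of the complete rows, capped at 10. The overall missing
fraction is capped (default 5%) because reconstruction quality degrades
beyond a small residue.

Z-scaling uses the sample SD ($n-1$ denominator) throughout; the per-marker
centre/scale are stored in the `QCReport` and inside every trained model,
so projection onto new raw data applies exactly the training
transformation.

## Clinical variable derivation

The 20 dichotomous clinical variables live in a versioned YAML file
(`inst/extdata/clinical_thresholds.yaml`), not in code: thresholds such as
triglycerides ≥ 2.3 mmol/L, hsCRP > 3 mg/L, eGFR ≤ 60 mL/min/1.73 m², the
three age bands (< 45; 45–64; ≥ 65 years) and the sex-specific waist and
haemoglobin cutoffs are data, auditable and replaceable. Comparators are
applied exactly as declared (boundaries inclusive for ≥/≤). Missingness
propagates: any missing required input — including sex where a threshold is
sex-specific — yields a missing derived value, never a silent FALSE.

Composites: LDL cholesterol uses the Friedewald equation
(LDL = TC − HDL − TG/2.2, mmol/L), returning missing above the standard
validity bound TG > 4.5 mmol/L; eGFR uses the 2009 creatinine-based CKD-EPI
equation with the race coefficient omitted by default (the populations this
tooling emulates are described as exclusively Caucasian; the coefficient
remains available behind a flag); creatinine units must be declared, never
guessed. "High pressure" is the AND of systolic ≥ 140 and diastolic ≥ 90
mmHg as the reference threshold table defines it — clinical guidelines
often use OR, which is available behind `highPressureOr = TRUE`. Two
printed thresholds that deviate from common conventions (female waist 93 cm
rather than 88; female low-haemoglobin cutoff above the male one) are
implemented as printed, since the spec file is the single source of truth.

## Surrogate training and evaluation

`trainSurrogate()` delegates the penalized fit to glmnet and owns the
selection protocol: the λ path is glmnet's default (100 values, log-spaced
down four decades from the smallest λ that zeroes every coefficient), and λ
is chosen to minimise the mean held-out binomial deviance across five
repeated stratified 5-fold partitions (the "lambda-min" convention). Folds
are stratified by label; each repeat uses an independent partition; all
partition seeds derive deterministically from the call seed.

`evaluateCV()` wraps this in an outer 5-fold loop repeated five times: the
full inner selection runs from scratch inside every outer training split,
so the outer test fold never influences the hyperparameter — the package
tests this by permuting held-out labels and asserting the trained model is
bit-identical. Performance is summarised as the mean held-out AUC
(Mann–Whitney form, ties counted ½), with AUC > 0.7 as the conventional
adequacy bar.

`evaluateLOBOV()` holds out each cohort entirely, trains on the rest and
scores the held-out cohort, summarising with a mean AUC weighted by
held-out sample count. Held-out cohorts lacking a class are skipped with a
warning rather than scored 0.5: an undefined AUC is not evidence. Batch
heterogeneity makes LOBOV the honest estimate of transfer to an unseen
biobank, and with cohort-level shifts in the generator the LOBOV mean falls
below the CV mean — reproducing the qualitative CV-vs-LOBOV gap expected of
multi-biobank data.

Relative importance scales each model's coefficients by the sum of their
absolute values, making rows sum to one in magnitude and invariant to
positive rescaling; a signed-sum variant sits behind a flag for one-sided
models ("coefficient sum" is ambiguous under mixed signs, and the absolute
convention keeps the quantity a proper composition).

## Metabolome-wide association

`runMetaboWAS()` regresses each marker (rank-inverse-normal transformed by
default) on the phenotype plus covariates; the per-marker effect is the
phenotype coefficient. The RIN transform maps ranks to normal quantiles
with the Blom offset 3/8 and average ranks for ties; alternative offsets
are exposed. The effect direction — metabolite as response, phenotype as
predictor — matches linear-regression-tagged effect estimates in this
literature; a logistic variant (phenotype as response) would answer a
different question and is out of scope.

Multiplicity uses an effective number of tests: the smallest number of
principal components of the RIN-transformed, standardized marker matrix
explaining ≥ 99% of its variance, with threshold 0.05/k_eff. k_eff is
recomputed for every analysis dataset — the reference value of 40 belongs
to one particular cohort and panel, and carrying it to other data would
miscalibrate the correction. Under the global null the family-wise error of
this procedure stays at the nominal level (checked by simulation over 200
datasets).

`compareAdjustments()` implements the confounder-substitution comparison:
paired per-marker estimates under two adjustment sets, their r², sign
agreement, and the 2×2 significance contingency whose raw counts are the
primary output. Discordance *rates* are secondary and carry their
definitions in the output, because rate definitions are not standardised
enough to stand alone.

`confounderSubstitution()` packages the controlled experiment: one
simulated cohort, a confounder phenotype planted along a compact
metabolite axis (the inflammation + glycolysis-related classes — an
inflammatory-glycaemic shift of the kind adiposity produces), an outcome
phenotype overlapping it, a surrogate trained for the confounder, and the
outcome MetaboWAS run with the true liability vs the surrogate as the
adjustment. Two design constraints make the experiment meaningful rather
than vacuous. First, the axis must sit close to the covariance
eigenstructure: the Bayes discriminant any classifier estimates points
along $\Sigma^{-1}w$, not $w$, so a liability planted far from the
eigenstructure cannot be tracked closely by *any* surrogate. Second, the
confounder footprint must be compact: a surrogate is a function of the
markers and absorbs more variance of heavily-loaded markers than the
latent liability itself does; a confounder axis spanning a third of the
panel turns that asymmetry into divergent estimates wherever the axis
loads, while a five-marker axis confines it. With this design the
surrogate correlates with the truth at r ≈ 0.93 and the two adjustment
strategies agree at r² ≈ 0.99 with sign agreement above 0.96.

## Survival association

`coxAssociation()` fits Cox proportional-hazards models with follow-up time
as the time scale, Efron tie handling (the accepted default under moderate
ties), and robust standard errors from the Huber sandwich estimator grouped
by family, so pedigree correlation cannot deflate the reported uncertainty.
Surrogates enter per 1 SD by default so hazard ratios are comparable across
surrogates; the choice is recorded in the output. Left truncation is not
modelled. `stratifiedFDR()` applies Benjamini–Hochberg within each stratum
(all, men, women) independently, flagging FDR < 0.05.

`stepwiseCox()` performs the bidirectional AIC search from the full model:
at each round every single-term removal and addition is scored and the move
with the largest AIC decrease is taken; the search stops when no move
decreases AIC; fixed covariates (age, and sex when unstratified) are never
dropped. AIC uses the ordinary partial likelihood — AIC is
likelihood-based by definition, so the robust variance plays no role in
selection and is used only for the reported inference on the refitted final
model. AIC is the sole stopping criterion; per-term p-values are reported
in the final summary for inspection but do not gate the search (a p-value
cutoff would need an arbitrary threshold the procedure does not define).

## The synthetic generator: what it emulates and what it does not

`simulateCohorts()` is first-class, tested code, not a fixture. It
emulates the statistical structure that the pipeline's guarantees depend
on:

* **Block-correlated, strictly positive concentrations.** Log-scale latent
  factors, one per metabolite class plus a dense factor, with loading 0.7
  (within-class correlation ≈ 0.5) and idiosyncratic noise topping unit
  variance; concentrations are exponentials of this Gaussian, hence
  log-normal and right-skewed — which is precisely why the MetaboWAS stage
  needs the RIN transform and why QC outliers are realistic.
* **Cohort batch effects.** Two components, both on the standardized log
  scale: additive per-cohort, per-marker offsets (SD 0.3) and
  multiplicative per-cohort, per-marker gains (log-SD 0.2). The
  distinction matters: any cohort-constant monotone transform of the
  score — which is all an additive offset (or a single global gain) can
  produce — leaves within-cohort ranking, and hence held-out-biobank AUC,
  untouched. Only marker-specific gain distortions rotate a cohort's
  effective discriminant direction and make transfer to an unseen biobank
  genuinely harder than a held-out fold. The magnitude of real
  between-biobank heterogeneity is not quantified anywhere we could
  anchor to, so both defaults were fixed once at plausibly modest values
  (measurement-level variation) and are exposed in the configuration.
  Note that a single global coefficient vector suffers cohort distortion
  almost equally in CV and LOBOV — the held-out cohort's only advantage
  in CV is a ~1/n<sub>cohorts</sub> tilt of the fit — so the LOBOV-below-CV
  gap only becomes reliably strict under *large* per-marker distortions
  (gain log-SD 0.7 in the gap study), and even then is ~0.02, smaller
  than gaps seen on real biobanks, whose phenotype-definition
  heterogeneity this generator deliberately does not model.
* **Planted phenotypes with known oracle AUC.** Labels are
  Bernoulli(prevalence) and case samples are shifted along the phenotype's
  marker weight vector so that the standardized metabolite-linked
  liability is exactly N(0,1) in controls and N(d,1) in cases: the
  equal-variance binormal model, whose oracle AUC is $\Phi(d/\sqrt{2})$.
  We chose this retrospective construction over thresholding a noisy
  liability because it makes the oracle AUC *exact* rather than
  approximate — the invariant every recovery test is calibrated against.
  The case shift is applied along Σw (not w itself), which makes the
  planted liability the Bayes discriminant of the two equal-covariance
  classes: Φ(d/√2) is then a true ceiling that no classifier can exceed,
  rather than merely the performance of one particular projection.
  Default demo phenotypes plant oracle AUCs of 0.95, 0.90, 0.75 and 0.50
  at prevalence 0.2, each along a class-aligned liability axis (a lipid
  axis, a glycaemic-inflammatory axis, an amino-acid/fluid-balance axis)
  — the way real risk factors express on such a panel, and a direction a
  sparse learner can actually estimate; a dense iid-random direction with
  dozens of tiny loadings is learnable by no method at these sample
  sizes and resembles no biological phenotype.
* **Artifacts with exact masks.** Missing cells, zeros, and outliers
  displaced 8 SDs from the leave-one-out column mean (so they exceed the
  5-SD rule under either statistics convention), each recorded cell by
  cell, giving QC an exact oracle.
* **Family-clustered survival.** Exponential proportional hazards with a
  mean-1 gamma frailty shared within families nested in cohorts, and
  administrative censoring calibrated to a target fraction — the minimal
  model that makes cluster-robust standard errors testable.

It does **not** emulate: the real panel's empirical covariance or
marginals, assay chemistry and detection limits, cohort-specific
age/sex structure, informative missingness, or any correlation between the
raw clinical columns and the metabolome (the raw clinical table has
realistic marginals only). Passing recovery tests on this generator
therefore demonstrates that the *pipeline machinery* is correct and
calibrated — not that any particular real-data AUC would be reproduced.

## Problem sizes and numerical choices

The demo configuration is 10 cohorts × 500 samples — large enough for the
double-CV estimate of a planted AUC to land within ±0.05 and for rank
order across four planted strengths to be stable, small enough for a
desk-scale run. The LOBOV-gap replication uses 20 independent simulations
of 6 cohorts × 200 with a single CV repeat each: the gap's *sign* is the
quantity of interest and is unbiased by the number of repeats. Error
control uses 200 null datasets (family-wise error) and 100 clustered
survival simulations (robust-CI coverage). Determinism is end to end:
every stochastic stage derives its seed from the global seed and the stage
name, and `runPipeline()` hashes every artifact into a manifest so
identical config + seed implies identical hashes.

Numerical conventions worth knowing: sample SD everywhere ($n-1$); AUC
ties counted ½ via average ranks; glmnet's λ path with lambda-min
selection; PCA for k_eff on the correlation scale; eigenvalues below
`1e-9` of the largest treated as rank-deficient; the JSON model artifact
round-trips doubles to one ulp (the TSV dataset format round-trips them
bit-exactly via 17 significant digits).

## Known limitations

* Surrogates are uncalibrated posteriors; applying them to a cohort whose
  prevalence differs from training shifts the score distribution (the
  intercept is fixed). Calibration is deliberately out of scope.
* No between-cohort batch correction is attempted; LOBOV quantifies the
  cost of that decision rather than hiding it.
* The stepwise search optimises AIC greedily and inherits the usual
  instability of stepwise selection under correlated candidates; the trace
  is recorded so the path can be audited.
* The generator's clinical columns are marginally realistic but
  metabolome-independent, so derived-variable prevalences — not
  clinical-metabolite associations — are the testable quantities there.
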