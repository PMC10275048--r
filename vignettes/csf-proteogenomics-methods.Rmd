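---
title: "Methods: CSF proteogenomic pQTL mapping, disease integration and proteomic risk scores"
author: "csfProteoGenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF proteogenomic pQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`csfProteoGenomics` implements, as reusable and tested components, a
proteogenomic analysis chain for aptamer-based cerebrospinal-fluid (CSF)
proteomics with genotype data: quality control, per-aptamer genome-wide
association scans, a two-stage meta-analysis with a principal-component
derived study-wide threshold for trans associations, index and conditional
signal detection, pleiotropic-region grouping, annotation and cell-type
enrichment, integration with a disease GWAS (colocalization, Mendelian
randomization, PWAS), and proteomic risk scores benchmarked against a
polygenic risk score. Because the real cohorts behind such studies are
access-controlled, the package ships a seeded synthetic-cohort generator
that reproduces the statistical structure each stage assumes, together with
a ground-truth table used by the parameter-recovery tests.

## The association model

For each aptamer, levels are log10-transformed and z-scored per aptamer
(`normalizeLevels`), and each variant is tested with the additive linear
model

  z(protein) ~ dosage + age + sex + genetic PCs + cohort dummies,

reporting the dosage coefficient, its standard error, and a two-sided
p-value from the t reference with residual degrees of freedom
(`pqtlScan`). Meta-analysis p-values use the normal reference — a
deliberate mixed convention matching the common tooling (per-cohort linear
models with exact small-sample t tests; inverse-variance meta combining on
the normal scale). Internally the scan residualizes the protein and the
dosage matrix on the covariate design once per missingness pattern, which
is algebraically identical to the full fit and lets the per-variant
statistics reduce to one cross-product per pattern; a genome-scale scan
(5,000 variants x 200 aptamers x 1,000 samples) takes a couple of seconds.

A pair is *cis* when the variant lies within 1 Mb (inclusive boundary — the
windows are quoted without boundary semantics elsewhere, so we fix
inclusivity) of the target gene's transcription start site on the same
chromosome, otherwise *trans*. The study-wide trans threshold divides
5e-8 by K, the number of proteomic principal components needed to explain
95% of protein variance (`transThreshold`); the PCA input is mean-imputed
per aptamer because missingness handling for this step is otherwise
unspecified. Stage gates (discovery p < 0.005, replication p < 0.05,
consistent direction, study-wide meta significance) are applied only in
`significanceFilter`, not during the scans.

Genomic control is computed from two-sided p-values via chi-square
quantiles so it also works on externally supplied summary statistics; each
study's standard errors are inflated by sqrt(lambda) only when lambda > 1,
and only per input study (the meta-level lambda is reported for inspection
but not applied, since double correction is not clearly warranted).

## Signals, conditioning and regions

Index signals are found greedily: the most significant study-wide
significant record seeds a +/-1 Mb window, absorbs every significant record
inside it, and the procedure repeats (`detectIndexSignals`). Ties break by
smaller p, then smaller genomic position, then variant id — everywhere in
the package, which makes the outputs invariant to input order.

Conditionally independent signals are found by exact forward stepwise
regression on individual-level data (`conditionalSignals`): the summary-
statistic approximation used when only summary data are available is
unnecessary here, and the exact computation is strictly more defensible.
Candidates in LD above r² = 0.9 with a selected variant are excluded
(configurable), mirroring the collinearity convention of the summary-based
tools. The conditional threshold per label equals the study-wide cis/trans
threshold.

Pleiotropic regions are connected components of the graph on index variants
with edges at r² >= 0.1 — transitive closure, not cliques, so chained loci
form one region; this is the only reading under which a locus whose ends
are unlinked but share a middle partner stays whole. Manual regions
(generalizing the HLA-style special case) force-merge all index variants in
a declared span plus, optionally, variants in LD with in-span members.
Cross-chromosome grouping is disallowed.

## Enrichment

The most severe consequence of an association is the minimum-severity-rank
category over the index variant and its r² > 0.8 proxies; the severity
order ships as an overrideable configuration (`defaultSeverityOrder`).
Permutation enrichment draws observed-set-sized random variant sets from
the universe, computes proxy-aware most-severe counts under the identical
rule (so the null is exchangeable), and reports empirical p-values with the
add-one convention p = (1 + #{perm >= obs}) / (1 + n_perm). The add-one
rule is ours: the conventional floor statements for permutation tests are
often internally inconsistent, and add-one guarantees p in (0, 1] exactly.

Cell-type specificity follows the 1.5x rule on row-normalized shares over
five brain cell types (astrocytes, neurons, oligodendrocytes,
microglia/macrophages, endothelial cells); set enrichment of specific genes
in a subset uses the exact hypergeometric upper tail.

## Disease integration

Colocalization is single-causal-variant ABF: per-variant Wakefield log
Bayes factors with prior effect sd 0.15·sdY for quantitative traits
(sdY = 1 for z-scored protein) and 0.2 for case-control, hypothesis sums in
log space with priors p1 = p2 = 1e-4, p12 = 1e-5, and a PP.H4 > 0.8 call
rule. Multi-signal (SuSiE-style) colocalization is out of scope.

MR instruments are genome-wide-significant (p < 5e-8) clumped variants.
Clumping defaults are r² = 0.01 within 1 Mb: with a cohort-scale LD
reference the sampling floor of estimated r² is about 1/n, so the
conventional 0.001 threshold of summary-MR tooling would absorb independent
variants by estimation noise alone. Trans instruments are removed when they
sit in a pleiotropic region regulating five or more aptamers or within
500 kb of a configured high-pleiotropy anchor variant; cis instruments in
such regions are retained but flagged. One instrument gives the Wald ratio
(delta-method se); two or more give fixed-effect IVW. Steiger
directionality sums per-instrument r² = z²/(z² + n - 2) per trait and
compares Fisher-z-transformed correlations treating the two samples as
independent, which is exact for the two-sample design. BH-FDR is applied
across tested aptamers.

The PWAS fits per-window weights on covariate-residualized protein with two
candidate models — `top1` (all weight on the most associated variant) and
an L1-penalized linear model — chosen by out-of-fold R², ties preferring
the sparser top1. The elastic-net variant is omitted from the default menu
(the lasso dominates it at these problem sizes); the association statistic
is z = w'z / sqrt(w'(S + 1e-3 I)w) with the LD matrix S from the dosage
reference and a small ridge for stability.

## Biomarker groups

Amyloid- and tau-like analytes are dichotomized per cohort: log10, z-score,
drop |z| > 3, re-z-score, then a two-component unequal-variance Gaussian
mixture by EM with ten restarts jittered around the 25th/75th percentile
initialization; the best log-likelihood wins and exact ties take the lower
cutoff. The cutoff is the posterior-equality point between the component
means (it coincides with the density antimode for well-separated
equal-variance components); amyloid is positive below the cutoff, tau
above. Separability requires the fitted means at least 0.5 pooled sd apart
*and* the two-component fit beating a single Gaussian by BIC: the distance
rule alone cannot flag unimodal data, because a two-component fit of a
plain Gaussian still lands on well-separated means. Non-separable fits
return no cutoff and all-missing labels. A/T classes are the cross-product
of the two labels, missing when either is.

## Risk scores

The naive proteomic risk score is the per-sample mean of
direction-harmonized z-levels over the disease-associated aptamer set
(columns with a negative reported disease effect are sign-flipped). The
sparse refinement imputes missing values within biomarker group (uniform
draw from the group's observed donors, seeded), then fits L1-penalized
logistic regression with the penalty chosen by the cross-validation
one-standard-error rule. We considered the literal smallest-penalty
reading of "the model with the lowest lambda" and the cross-validated
minimum; both over-select at these problem sizes (the minimum rule kept
roughly 50 noise aptamers of 490 in a 10-signal simulation), while the 1se
rule recovers the informative set with few false selections, matching the
sparsity a sparse refinement exists to provide. Both alternatives remain
available via `lambdaRule`.

The PRS comparator clumps GWAS variants (clump-p 1, r² 0.1, 250 kb), sums
effect-allele dosages weighted by GWAS betas over variants with p < 5e-8,
and standardizes; an exclusion region (e.g. a dominant risk locus) can be
dropped before clumping. Model comparison uses ROC AUC with 90% confidence
intervals (DeLong asymptotic; seeded bootstrap below 100 test samples) and
paired DeLong tests on the same held-out samples; train/test overlap is
refused structurally. Scoring an external panel zero-fills missing model
features and reports the fraction of absolute model weight retained.

## The synthetic cohort generator

Genotypes come from latent-Gaussian thresholding: each haplotype is a
block-correlated standard normal vector thresholded at the allele-frequency
quantile, two haplotypes summing to a dosage in [0, 2]. This reproduces the
LD/r² semantics the pipeline needs and nothing more — it is not
population-genetically realistic (no recombination maps, no ancestry
structure, no imputation uncertainty), and passing tests say nothing about
those aspects of real data. Protein levels are generated on the log10
scale (planted effects act per alt-allele dose), exponentiated to positive
RFU-like values; missingness is completely at random per aptamer, unlike
the informative missingness of real assays (noted limitation). Plate scale
factors and CVs are attached so the QC gates have inputs. Biomarkers are
two-component log-normal mixtures tied to a latent liability (amyloid low
in cases, tau high). The disease GWAS simulates a logistic outcome on a
liability built from planted causal aptamer levels (mediation) and/or
direct variant effects, then fits per-variant logistic regressions
(vectorized Newton iterations, verified against `glm` to 1e-14). The
discovery/replication split partitions one cohort via a cohort dummy,
mirroring a two-stage design. Seeds are explicit arguments everywhere; no
generator touches global random state.

Default problem sizes used by the test-suite study conditions: null
calibration runs 20 cohorts of 1,000 samples x 5,000 variants x 200
aptamers; recovery runs plant cis effects of 0.4 sd per allele at MAF >=
0.1 in cohorts of 1,500; integration runs use 2,000-sample single-window
cohorts with a 0.8 sd-per-allele protein effect and a 0.3 log-odds-per-sd
protein-to-disease effect; risk-score runs use 1,500-sample cohorts where
eight proteins carry genetic plus non-genetic disease variance. Effect
sizes are a design choice (no effect-size distribution is available to
emulate); they were fixed once at values a cohort of these sizes can
detect, and the tests then ask whether the pipeline recovers them.

## Numerical conventions

- Quartiles for the outlier mask: type-7 linear interpolation, fixed so the
  masking examples are deterministic.
- The Hardy-Weinberg filter uses the exact conditional test on dosages
  rounded to hard genotypes (synthetic dosages are hard calls; imputation
  uncertainty is out of scope).
- The posterior-equality cutoff is solved on a fine grid between the
  component means with linear interpolation inside the bracketing cell.
- Internal coordinates are 1-based inclusive (VCF convention); BED exports
  convert to 0-based half-open at the boundary.
- All empirical p-values use add-one conventions; all tie-breaks are
  smaller p, then position, then identifier.
- The two-sample proportion test exposes sidedness and continuity options;
  for one published comparison of region shares no standard variant
  reproduces the printed p-value exactly, and the operation makes the
  choices explicit rather than resolving the ambiguity.

## Known limitations

Single-ancestry, unrelated samples only (no kinship-aware association); no
X-chromosome dosage conventions; summary-statistics-only conditional
analysis with an external LD panel is not implemented; colocalization
assumes a single causal variant per trait per window; the generator's LD
and missingness are structural stand-ins, so real-data QC pathologies
(plate effects correlated with biology, informative missingness) are not
exercised by the test suite.
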