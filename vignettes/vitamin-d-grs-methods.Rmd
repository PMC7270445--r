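---
title: "Genetic risk scores for maternal vitamin D status: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for maternal vitamin D status: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Observational associations between maternal serum 25-hydroxyvitamin D
(25(OH)D) and newborn anthropometry are heavily confounded by lifestyle,
nutrition and measurement context. A genetic approach sidesteps part of
that confounding: germline variants that lower circulating 25(OH)D are
fixed at conception and cannot be caused by the outcomes. `vitdgrs`
implements this design for mother-infant cohorts: it aggregates six
well-replicated vitamin D-related single nucleotide polymorphisms (SNPs)
into unweighted genetic risk scores (GRS), tests their association with
25(OH)D across pregnancy, and tests whether the genotype-outcome
relationship on newborn anthropometry is modified by circulating
25(OH)D (a gene-environment interaction).

## The SNP panel and risk scores

The bundled panel covers two pathway groups:

* **synthesis**: *DHCR7* rs12785878, *CYP2R1* rs12794714 — genes acting
  upstream, in cutaneous synthesis and 25-hydroxylation;
* **metabolism**: *GC* rs2282679, *CYP24A1* rs6013897, *VDR* rs2228570
  (FokI) and rs7975232 (ApaI) — transport, catabolism and receptor
  signalling.

Each SNP contributes its count of 25(OH)D-lowering ("risk") alleles
(0, 1 or 2). Three unweighted scores are formed: the total vitamin D-GRS
over all six SNPs (range 0-12), the synthesis-GRS (0-4) and the
metabolism-GRS (0-8). Because the two pathway groups partition the
panel, the total score is identically the sum of the other two for any
complete profile — a property the test suite checks. Scores are
dichotomized at the panel's reporting cut-points (total and metabolism:
<=3 vs >=4; synthesis: <2 vs >=2), which split near the score medians.

The literature states the risk allele unambiguously only for rs12794714
(A) and rs7975232 (A); for the other four SNPs the bundled defaults
follow the conventions of the genome-wide association studies that
established them. The manifest file is the single source of truth: risk
alleles are configuration, and the pipeline refuses genotype data whose
alleles contradict the manifest rather than guessing strand or
orientation.

Missing-data policy is complete-case throughout: a missing constituent
genotype makes every score containing it missing, and no imputation is
performed anywhere. This mirrors the per-analysis sample sizes typical
of cohort reports. A proportional rescaling of incomplete scores was
considered and rejected: with six SNPs the rescaled score changes the
group assignment of borderline participants, silently moving people
across the dichotomization cut.

## Quality control

Per-SNP QC reports the call rate, minor allele frequency (MAF) and a
1-df Pearson chi-square test of Hardy-Weinberg equilibrium (HWE),
comparing observed genotype counts with `(p^2, 2pq, q^2) * n` at the
allele frequency estimated from the same sample. The asymptotic
chi-square is used rather than the exact test because the panel's MAFs
(0.18-0.39) and cohort sizes (~180) put expected counts well above the
usual small-count caveats. A monomorphic SNP returns chi2 = 0, p = 1 by
convention and is flagged in the report instead of erroring, so a QC
sweep over many SNPs never aborts on a degenerate marker.

## Phenotype classification

* Maternal status (IOM): deficient < 12 ng/mL, insufficient 12 to
  < 20 ng/mL, sufficient >= 20 ng/mL. The bands are half-open so they
  partition the line; 19.99 ng/mL is insufficient. (Category summaries
  sometimes print the middle band as "12-19"; the half-open rule is the
  only reading that leaves no gap between 19 and 20.)
* Newborn anthropometry (WHO): low birth weight < 2500 g, short birth
  length < 50 cm, small head circumference < 35 cm; at or above each
  cut-off is normal.
* Pre-pregnancy BMI uses the WHO bands for Asian populations
  (underweight < 18.5, normal < 23.5, overweight < 25, pre-obese < 30,
  obese >= 30 kg/m^2), again half-open at the printed two-decimal upper
  bounds. Banding happens on a 6-decimal rounding of the quotient so a
  value that lands on a cut-off only through floating-point error (e.g.
  76.8 kg at 1.60 m) classifies as the printed arithmetic says.
* The change score is the signed difference T3 - T1 of 25(OH)D, defined
  only when both visits are present. Category transitions between
  trimesters are reported descriptively but the numeric delta is what
  enters the models, since "change in status" has no unique categorical
  encoding.

## Statistical models

Association stages use ordinary least squares with covariate adjustment
(standard errors from the unbiased residual variance, two-sided t
p-values); binary outcomes use logistic regression (IRLS, Wald tests);
categorical outcomes use a one-vs-reference decomposition into binary
logistic fits. The decomposition is an approximation to the joint
multinomial likelihood — each contrast conditions on its own pair of
levels — but it collapses exactly to the single logistic fit for
two-level outcomes and keeps every reported contrast available.

The interaction model for a continuous newborn outcome $y$ is

$$ y = \beta_0 + \beta_g\,\mathrm{GRS} + \beta_e\,25(OH)D +
   \gamma\,(\mathrm{GRS} \times 25(OH)D) + \mathbf{x}^\top\boldsymbol\beta_c + \varepsilon $$

with the product-term coefficient $\gamma$ as the quantity of interest.
The GRS enters as the continuous allele count by default; a
dichotomized-group coding is available to reproduce stratified displays.
The continuous coding is the default because the product term then has
a clean per-allele-per-ng/mL interpretation and does not depend on the
cut-point.

Covariate adjustment sets are per-stage configuration, defaulting to
the conventional sets for each analysis (descriptive status contrasts:
none; status vs anthropometry: age, pre-pregnancy BMI, preterm status,
sun exposure, supplement use; GRS associations: age, BMI, supplement
use, sun exposure, geography; interactions: age, BMI, supplement use,
gestational age at birth, infant sex). The stages never harmonize these
sets silently — differing adjustment sets across published tables are a
fact of the design, not a bug to fix.

Multiple testing uses Bonferroni families declared up front: the
association family has m = 9 tests (3 GRS schemes x 3 25(OH)D outcomes),
the interaction family m = 18 (3 schemes x 2 exposure trimesters x 3
newborn outcomes). Decisions use the unrounded threshold (0.05/9,
0.05/18); a 3-decimal display value (0.006, 0.003) is carried for
reporting. The Kolmogorov-Smirnov normality screen uses the
sample-estimated mean and SD without the Lilliefors correction,
matching the default output of the statistical software common in this
field; its p-values are therefore conservative, and it is a screen,
not a gatekeeper.

The two-group sample-size helper implements
$n = 2 (Z_\alpha + Z_\beta)^2 S^2 / (U_1 - U_2)^2$. With the
conventional inputs (1.96, 1.28, SD 18.5 ng/mL, difference 13.08 ng/mL)
the quotient is 41.9999, i.e. 42 per group.

## The synthetic cohort generator

Individual-level cohort data of this kind are not publicly deposited,
so the package ships a seeded generator that reproduces the statistical
structure the analyses assume, making every stage runnable and testable
end-to-end. The defaults are the package's study conditions:

* **Flow**: 239 enrolled, 53 lost before delivery, 3 completers
  excluded for low DNA yield, leaving 183 analyzable mother-infant
  pairs. (Published flow diagrams for such cohorts sometimes disagree
  with the running text on the enrolment total; the generator follows
  the 239 -> 186 -> 183 accounting and the discrepancy is surfaced here
  rather than resolved.)
* **Genotypes**: risk-allele counts drawn Binomial(2, MAF) per SNP —
  exactly HWE — at MAFs (0.28, 0.35, 0.25, 0.18, 0.39, 0.33), spanning
  the panel's reported 0.18-0.39 range, risk allele = minor allele.
* **25(OH)D**: T1 ~ Normal(14.00, 6.97) ng/mL truncated at 0; T3 is
  centred at 21.21 ng/mL with SD 10.16, latent correlation 0.425 with
  T1, minus `beta_snp` ng/mL per risk allele, centred at the expected
  allele count (2 x sum of MAFs ~ 3.56) so the marginal T3 mean stays
  at its configured value regardless of the genetic effect. The default
  `beta_snp = 1.8` is a calibration, not an estimate: the expected
  allele-count difference between the dichotomized total-GRS groups is
  ~2.55, so 1.8 ng/mL per allele yields the ~4.6 ng/mL group contrast
  reported for third-trimester 25(OH)D. The genetic effect is placed on
  T3 (and hence the change score) and not on T1, mirroring the
  observation that the GRS association appears late in pregnancy; a T1
  effect is configurable for power studies.
* **Outcomes**: birth weight 3204.87 +/- 494.99 g, length 48.56 +/-
  2.87 cm, head circumference 33.89 +/- 2.52 cm, plus a product-term
  effect `gamma_interaction` (default 0.08 cm per risk-allele x ng/mL,
  on centred GRS and T3) on head circumference.
* **Covariates and visit pairs**: age, BMI, height, gestational age,
  outdoor activity, supplementation, geography, and T1/T3 pairs of
  blood pressure, weight, MUAC and haemoglobin at the corresponding
  published moments, with within-pair correlation 0.6 (a conventional
  value; the source tables do not report it).

All randomness comes from one seeded scope (`withr::with_seed`), so the
same seed gives bit-identical cohorts and the caller's RNG stream is
untouched.

**What the generator does not emulate.** Real 25(OH)D is right-skewed;
the generator is truncated-normal, so at the default calibration it
yields ~36% T1 deficiency where a skewed real cohort with the same mean
can show ~47%. Covariates are mutually independent, which makes
adjusted and unadjusted estimates nearly identical and gives the
interaction test more power at n = 183 than correlated real data would
(the synthetic product-term SE is ~0.013 against ~0.03 in comparable
real cohorts). No seasonality, assay error structure or genotyping
batch effects are simulated. Passing tests therefore demonstrate the
correctness and calibration of the *methods*, not properties of any
real population.

## Numerical choices and degenerate inputs

* Rank deficiency in any design matrix is a hard error naming the
  collinear columns, never a silent drop.
* Logistic IRLS runs to a deviance tolerance of 1e-14 (max 100
  iterations) so Wald quantities agree with closed-form 2x2 results to
  1e-6; complete separation is flagged as non-convergence.
* Zero-variance inputs to t tests, correlation or the KS screen are
  errors, except the exactly-degenerate "identical groups" case which
  returns t = 0, p = 1.
* Monomorphic SNPs: chi2 = 0, p = 1, flagged (see QC above); the
  dominant-model stage skips them with a warning.
* Group comparisons with fewer than 3 observations in a group are
  skipped with a warning rather than reported with meaningless degrees
  of freedom.

## Problem sizes used in the tests

The test suite exercises parameter recovery at n = 5000 (interaction
coefficient within 3 SE of its generating value), type-I error with 500
replicate cohorts of n = 200 (rejection rate within 2 Monte-Carlo SE of
5%), generator calibration at n = 20,000 (T1 mean within 0.2 ng/mL of
14.00), an exhaustive HWE oracle over all genotype-count triples with
n <= 30, and 100 random designs against a hand-written normal-equations
oracle. These sizes were chosen to make Monte-Carlo noise small relative
to each tolerance while keeping the default test run fast.

## Known limitations

* The one-vs-reference multinomial decomposition is not the joint
  softmax fit; for strongly unbalanced categories the two can differ.
* The unweighted GRS deliberately ignores per-SNP effect sizes; a
  weighted score would need effect estimates from an external GWAS in
  the same ancestry, which is out of scope.
* No gestational-age-standardized z-scores for newborn anthropometry:
  classification uses the raw WHO cut-offs only.
* VCF ingestion reads GT fields only — no dosages, no phasing, no
  genomic coordinates.
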