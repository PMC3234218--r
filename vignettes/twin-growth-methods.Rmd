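---
title: "Modelling polygenic effects on height growth with twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polygenic effects on height growth with twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`twingrowth` implements a developmental-genetic analysis of height for
longitudinal twin-family cohorts.  This vignette describes the models, their
assumptions, the tunable parameters, the synthetic cohort generator used to
validate everything, and the numerical and design choices that were genuinely
open.

## The piecewise-linear latent growth model

Repeated height measurements $h_{pj}$ on person $p$ at assessment ages
$a_{pj}$ are modelled with two random effects, an intercept $i_p$ and a slope
$s_p$:

$$ h_{pj} = \mu(x_{pj}) + i_p + f(a_{pj})\, s_p + e_{pj}, \qquad
   e_{pj} \sim N(0, \sigma^2_e), $$

with the piecewise-linear loading

$$ f(a) = \min(a, \mathrm{cap}_{\text{sex}}) - a_0 . $$

The origin $a_0 = 10.75$ years is the youngest assessment age, so the
intercept is interpretable as pre-pubertal (roughly age-11) height.  Growth
is assumed complete at 18 in males and 16 in females; freezing the loading
at the cap captures the taper of adolescent growth without a quadratic term.
The mean $\mu(\cdot)$ carries sex-specific intercept and slope means plus
any person-level covariates as fixed effects; a scalar predictor $g_p$ (a
SNP dosage or a weighted genetic score) enters as
$(\beta_i + f(a)\,\beta_s)\, g_p$, so its effects on pre-pubertal height and
on pubertal growth are estimated simultaneously.

Estimation is full-information maximum likelihood: each person contributes
the multivariate-normal density of their observed waves only, with

$$ \Sigma_{jk} = v_i + (f_j + f_k)\, c_{is} + f_j f_k\, v_s +
   \mathbb{1}[j=k]\, \sigma^2_e , $$

so missing waves need no imputation.  The 2×2 random-effect covariance is
parameterized by a log-Cholesky factor (positive-definiteness is structural,
never silently repaired), the likelihood is evaluated in compiled code, and
BFGS starts from pooled OLS coefficients with the residual variance split
heuristically across intercept (80%), slope (2%; its loading spans several
years, so small slope variances move observed variance a lot) and
measurement error (20%).  Two-stage per-person line fits were tried as
starts and abandoned: persons first observed in adulthood give wild
extrapolated intercepts.  Standard errors come from the numerical Hessian;
predictor tests use a $t$ reference with $n_{\text{persons}} - p$ degrees of
freedom.  A single residual variance is shared across waves by default;
`resid_by_wave = TRUE` frees one per wave (either convention is defensible
and both are provided).

## The twin ACE extension

For twin pairs the latent $(i, s)$ vector is decomposed into additive
genetic (A), shared environmental (C) and nonshared (E) bivariate
components, each a 2×2 covariance parameterized by its own Cholesky factor.
The within-twin latent covariance is $A + C + E$; the cross-twin covariance
is $\kappa A + C$ with $\kappa = 1$ for MZ and $1/2$ for DZ pairs; the wave
residual never crosses twins.  Pairs with a fully missing co-twin
contribute their marginal (singleton) likelihood.  Results are reported as
standardized shares per trait plus the cross-trait correlations
$r_g, r_c, r_e$, which is how such decompositions are usually read.

Confidence intervals for shares and correlations are delta-method intervals
from the numerical Hessian, truncated to the parameter ranges.
Profile-likelihood intervals were considered and set aside: profiling nine
variance parameters for every fit is an order of magnitude slower, and in
the recovery simulations below the delta intervals already achieve nominal
coverage at the cohort sizes of interest.  Degenerate components (a share
estimated at a boundary) make the delta SE unreliable there; the recovery
tests monitor coverage rather than assuming it.

### Variance parabolas and score $r^2$ curves

Height is linear in $(i, s)$, so its model-implied variance is quadratic in
the loading: $V(a) = v_i + 2 f(a)\, c_{is} + f(a)^2 v_s$, evaluated with the
total latent covariance (phenotypic) or its A component (genetic).  The
variance a score explains at age $a$ is
$s(a) = (\beta_{ig} + f(a)\beta_{sg})^2 \operatorname{var}(g)$, and the
$r^2$ curve divides it by the **base** model's parabola:

$$ r^2(a) = \frac{s(a)}{V_{\text{base}}(a)} . $$

An alternative would be $1 - V_{\text{score}}(a)/V_{\text{base}}(a)$ from
two independently fitted parabolas; the two agree in expectation, but the
ratio form lets sampling noise in two separate fits produce negative values
and break the ordering between the genetic and phenotypic curves.  With the
explained-variance form the dominance $r^2_g(a) \ge r^2_p(a)$ is structural
whenever the score's variance sits inside A — the genetic denominator is a
subset of the phenotypic one — which is exactly the property the twin
design is meant to expose.  Because genotypes are inherited, treating the
observed score as a mean covariate and attributing the variance it absorbs
to A is the identification assumption; the DZ cross-twin correlation of the
score is handled implicitly by conditioning on the observed scores.

Whether the wave residual belongs in the denominators is not determined by
the model; `include_resid` computes either convention (the default excludes
it, reporting $r^2$ on the latent scale).

### Sex comparison

Male heights are first rescaled per wave to the female wave mean and SD
(an affine map, so male wave moments match female ones exactly); the model
is then fitted per sex and jointly with the nine latent Cholesky parameters
equated (means and wave residuals stay sex-specific), giving a 9-df
likelihood-ratio test for sex differences in the variance structure.

## Genotype QC and the weighted score

Markers are screened in a fixed order — duplicate-sample mismatches, call
rate < 99%, MAF < 1%, more than 2 Mendelian inconsistencies, Hardy-Weinberg
exact $p < 10^{-7}$ (founders only), autosomal sex association
$p < 10^{-7}$, batch effect $p < 10^{-7}$, imputation $r^2 < 0.5$ — and
fail on the first triggered criterion, so the per-reason counts mirror a
sequential screen.  The Hardy-Weinberg test is the conditional exact test:
given the allele counts, heterozygote counts no more probable than the
observed one are summed (verified against full enumeration in the tests).
Mendelian checks use hard calls (dosages rounded; entries more than 0.2
from an integer treated as missing) and the biallelic transmission rules;
MZ pairs count as one offspring.  Screens whose functional form the
pipeline had to fix itself: the sex-association screen is a logistic Rao
score test, the batch screen a one-way ANOVA of dosage means across a
per-sample batch assignment, and heterozygosity outliers are flagged beyond
4 SD.  The imputation cutoff of 0.5 cleanly separates quality values like
.08/.46/.20 (dropped) from .55 and above (kept).

The score is $\mathrm{score}_p = \sum_j \beta_j d_{pj}$ with dosages counted
on each weight's effect allele: reversed allele labels flip the dosage
($d \to 2 - d$), irreconcilable labels exclude the SNP with a warning, and
missing dosages are mean-imputed with twice the sample allele frequency.
With meta-analytic weights in cm, the score is on the cm scale, so a
well-calibrated cohort should regress height on the score with slope ≈ 1.

## Pubertal age

At the age-11 and age-14 waves, chronological age is a noisy proxy for
developmental stage.  Per sex and wave, height is regressed on age and the
1–4 puberty score (plus a menarche indicator for girls at the age-11 wave,
the only wave where menarche status still varies informatively); the fitted
linear composite is rescaled, per sex and wave, to the mean and SD of
chronological age — an affine map, so the first two moments match exactly
and later waves pass through untouched.  Persons missing the puberty score
keep chronological age and are flagged; the rare person whose adjusted ages
would no longer increase across waves reverts to chronological age rather
than producing an invalid table.  Rescaling is done within sex because the
calibration models are sex-specific.

## Adult-height association

Adult height is the last observed measurement; twins whose final assessment
precedes their sex cap are excluded, parents are always eligible.  Family
clustering is handled by two-stage generalized least squares: a null model
$V = \sigma^2_g K + \sigma^2_e I$ is fitted once by ML over family blocks,
where $K$ holds expected relationship coefficients (MZ 1, DZ and
parent–offspring 1/2, spouses 0), and every predictor is then tested under
that fixed $V$ (equivalently, OLS after block-wise whitening).  Expected
rather than genotype-estimated kinship mirrors a design-based clustering
correction; per-SNP one-tailed p-values fold the two-tailed value into the
meta-analytic direction.  Direction concordance is summarized by the exact
lower-tail binomial test, and Bonferroni/nominal counts and QQ coordinates
are reported.

## The synthetic cohort generator

The generator exists so every stage can be validated without the (non-public)
study data; its defaults are the study conditions, not tuning knobs.
Families are MZ/DZ same-sex twin pairs plus both parents.  Genotypes: 176
SNPs with MAF ~ U(0.05, 0.5), parents in Hardy-Weinberg equilibrium,
children by Mendelian transmission (MZ twins share one meiosis).  Latent
structure: total intercept/slope variances 60 cm² and 1.0 (cm/yr)²
(matching age-11 height SDs near 7.7 cm), ACE shares .86/.09/.05 and
.84/.11/.05, correlations $r_g = -.56$, $r_c = r_e = -.03$, wave residual
SD 2 cm.  The score's effect sizes are drawn and rescaled so the centred
score has variance 5.5 cm², which makes it explain about 9% of adult
phenotypic variance (and consequently about 14% of adult genetic variance)
under those components; the score loads on the intercept only, and its
variance is carved out of the A component (the residual polygenic A is the
configured A minus the score covariance, checked for positive
semi-definiteness before sampling).  Wave target ages/SDs follow the
two-cohort schedule (11.8, 14.8, 17.7, 21.0, 24.9, 29.5); 36% of families
form an older cohort first assessed at 17 (waves 11 and 14 unobserved), and
10% of remaining person-waves drop out at random.

Pubertal timing is a latent trait in years whose ACE composition mirrors
the slope's shares — so the transient variance it adds perturbs A, C and E
proportionally and leaves standardized shares recoverable — with sex means
14.5 (M) and 12.3 (F) and SD 1.  Heights receive a transient bonus
proportional to each child's logistic spurt progression relative to peers
(8 cm between fully-pre and fully-post spurt at the same age); the bonus
fades automatically once a cohort's spurts complete, which is what produces
the sex-specific pattern of puberty–height correlations (girls' puberty
score is more informative about height at 11 than at 14, boys the reverse)
and menarche rates (~15% of girls by the age-11 wave, most by 14).  The 1–4
puberty score is a noisy logistic readout of the same progression.

What the generator does **not** emulate: genotyping error and batch
artifacts (QC screens are validated on constructed fixtures instead),
assortative mating, dominance, X-linkage, real LD structure, secular height
trends, and non-normal residuals.  Passing recovery tests therefore shows
the estimators are correct under the stated model, not that the model is
correct for any particular real cohort.

## Validation design and problem sizes

The test suite checks exact worked arithmetic; equivalence of the compiled
likelihoods with dense determinant/solve oracles to 1e-8; the
Hardy-Weinberg and binomial tests against enumeration; parameter recovery
on 10 cohorts of 2000 families (95% delta CIs for the intercept/slope
heritabilities, $r_g$ and the score $r^2$ cover truth in ≥ 90% of
replicates; median $|r_g|$ error under 0.1); structural invariants (shares
sum to one, genetic ≥ phenotypic $r^2$ on the whole grid, MZ ≥ DZ implied
cross-twin covariance, GLS = OLS under identity covariance); and null
calibration of the intercept/slope score test and the GLS association test
(2000 replicates each, rejection at $\alpha = .05$ required to land in
[.04, .06]).  Null replicates redraw the predictor every replicate and
refresh the phenotype-side fit every batch of 80–100, which keeps the
replicate count high while spending optimizer time where it matters.
These sizes were chosen as the smallest that make the Monte-Carlo error
comfortably smaller than the tolerances being asserted.

## Known limitations

- The bivariate ACE model assumes multivariate normality of the latent
  deviations and equal environments across zygosities.
- Delta-method CIs degrade for shares estimated at the 0/1 boundary.
- The two-stage GLS fixes the family covariance at its null estimate; with
  very strong predictors the residual covariance is slightly misspecified.
- The piecewise caps (16/18 years) are assumptions, not estimated, and the
  single change-point linear spline is a coarse description of the growth
  spurt itself; the generator's spurt bonus deliberately creates exactly the
  kind of early-wave misfit the pubertal-age adjustment is meant to absorb.
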