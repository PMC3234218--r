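# twingrowth

Developmental-genetic analysis of height for longitudinal twin-family
cohorts.  Adult height is the end point of two decades of growth, and a
polygenic score built from adult-height GWAS hits need not act uniformly
across that window.  `twingrowth` separates a score's (or a single SNP's)
effect on *pre-pubertal height* from its effect on the *pubertal growth
spurt*, and — using twin zygosity — measures how much of the **genetic**
variance in height the score explains, not just the phenotypic variance.

The package is aimed at quantitative geneticists and biostatisticians
working with longitudinal family data: it provides the full pipeline
(genotype QC, score construction, growth modelling, twin variance
decomposition, pubertal-age adjustment, family-clustered association) plus
a synthetic twin-family cohort generator so every stage is testable without
access to restricted cohort data.

## The model

Height at age $a$ for person $p$ follows a piecewise-linear latent growth
model,

$$ h_{pj} = \mu(x_{pj}) + i_p + f(a_{pj})\,s_p + e_{pj}, \qquad
   f(a) = \min(a, \mathrm{cap}_{\text{sex}}) - 10.75, $$

with caps of 18 y (males) and 16 y (females).  The random intercept $i$ is
height at age 10.75 (pre-pubertal height), the random slope $s$ is growth
per year thereafter.  Fitting is full-information maximum likelihood over
each person's observed waves.  For twin pairs, the $(i, s)$ covariance is
decomposed into additive-genetic (A), shared- (C) and nonshared-
environmental (E) bivariate components, with cross-twin covariance
$\kappa A + C$ ($\kappa = 1$ MZ, $0.5$ DZ).  A genetic score
$\mathrm{score}_p = \sum_j \beta_j d_{pj}$ (meta-analytic weights $\beta_j$,
effect-allele dosages $d$) enters the mean as
$(\beta_{ig} + f(a)\beta_{sg})\,\mathrm{score}_p$; because genotypes are
inherited, the variance it absorbs is attributed to A, and

$$ r^2(a) = \frac{(\beta_{ig} + f(a)\beta_{sg})^2\,\mathrm{var(score)}}
                 {V_{\text{base}}(a)},
\qquad V_{\text{base}}(a) = v + 2f(a)c + f(a)^2 v_s $$

is computed with either the total (phenotypic) or the A-component (genetic)
parabola of the base model.  Adult-height association uses two-stage
generalized least squares with family blocks
$V = \sigma_g^2 K + \sigma_e^2 I$ built from expected relationship
coefficients.

## Worked example

Simulate a cohort of 400 twin families (plus parents), build the score, fit
the twin model and test the score on adult height:

```r
library(twingrowth)

cfg <- cohort_config(n_families = 400, seed = 7)
sim <- simulate_cohort(cfg)

w  <- weight_table(data.frame(snp_id = sim$truth$snps$snp_id,
                              effect_allele = "A",
                              beta = sim$truth$snps$beta))
sc <- compute_score(sim$geno, w)

ace <- fit_twin_ace(sim$phenos, sim$ped)
ace
#> Bivariate ACE latent growth model (400 twin pairs)
#>   logLik -9678.15; constraint: none
#>   intercept A/C/E: 0.81/0.13/0.05   slope A/C/E: 0.75/0.21/0.04
#>   r_g -0.51  r_c -0.68  r_e 0.03  (phenotypic -0.51)

adult <- adult_height_filter(sim$ped, sim$phenos)
vc    <- fit_null_vc(adult, sim$ped, sim$covariates)
gls_assoc(sc$score, vc, expected_sign = +1)
#>       beta         se        t   df        p_two        p_one         r2
#> 1 0.981007 0.08789322 11.16135 1585 6.704243e-28 3.352121e-28 0.07286939
```

Reading the output: pre-pubertal height and pubertal growth are both highly
heritable (A shares .81 and .75 at this modest n; the generating values are
.86 and .84), their genetic correlation is strongly negative (taller
11-year-olds grow less afterwards), and the score — built on the cm scale —
regresses on adult height with slope ≈ 1 and explains ~7% of the
within-family-whitened variance.  At the full default size (1600 families)
the estimates tighten around the generating regime; see below.

The whole pipeline (QC → score → puberty adjustment → growth and twin fits →
r² curves → association) can also be run as configured stages:

```r
cfg <- default_config(seed = 3, out = "out")
run_pipeline(cfg)        # writes per-stage TSV reports + run log into out/
```

or from a shell via the thin wrapper `inst/cli/twingrowth.R`.

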