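# Synthetic twin-family cohort generator.  Families are MZ/DZ twin pairs plus
# both parents; genotypes follow Hardy-Weinberg equilibrium in parents with
# Mendelian transmission to offspring; the latent growth intercept and slope
# carry a bivariate ACE structure with the weighted SNP score embedded in the
# additive-genetic part.

#' Configuration for a synthetic twin-family cohort
#'
#' Returns the full generating configuration with defaults chosen to emulate
#' a two-cohort longitudinal twin-family height study: twin pairs assessed at
#' target ages 11--29, height in cm, a 176-SNP weighted score explaining
#' roughly 9\% of adult phenotypic variance, latent intercept/slope
#' heritabilities of .86/.84 and a genetic correlation of -.56 between them.
#'
#' @param n_families number of twin families (pair + two parents).
#' @param p_mz proportion of monozygotic pairs.
#' @param p_male_pair proportion of male (same-sex) pairs.
#' @param n_snps number of score SNPs.
#' @param maf_range range from which minor-allele frequencies are drawn.
#' @param maf optional vector of per-SNP allele frequencies (overrides draw).
#' @param weights optional vector of per-SNP effect sizes in cm (drawn when
#'   `NULL`, scaled so the score variance equals `score_var`).
#' @param score_var target variance (cm^2) of the centred SNP score.
#' @param score_load_i,score_load_s loadings of the score on the latent
#'   intercept (cm per cm) and slope (cm/yr per cm).
#' @param var_i,var_s total latent intercept and slope variances (cm^2,
#'   (cm/yr)^2).
#' @param ace_intercept,ace_slope named proportions `varA`, `varC`, `varE`
#'   summing to one per trait.
#' @param r_g,r_c,r_e cross-trait (intercept-slope) correlations of the A, C
#'   and E deviations.
#' @param resid_sd wave-level measurement/residual SD in cm.
#' @param mu_i,mu_s named (`M`, `F`) means of the latent intercept (height in
#'   cm at the age origin) and slope (cm/yr).
#' @param wave_ages,wave_sds target assessment ages and their SDs per wave.
#' @param origin age (years) at which the intercept is defined.
#' @param cap_male,cap_female ages at which growth is assumed complete.
#' @param cohort_mix proportion of families in the older cohort (first
#'   assessed at age 17; waves 11 and 14 unobserved).
#' @param missing_rate additional per-person per-wave dropout probability.
#' @param timing_mean,timing_sd named (`M`, `F`) mean and SD of the latent
#'   pubertal-timing age (years); timing is generated as a heritable trait.
#' @param timing_shift transient height separation (cm) between a person
#'   fully through the growth spurt and one not yet started, at the same
#'   chronological age; the bonus follows the logistic spurt progression
#'   and fades once a cohort's spurts are complete.
#' @param timing_scale logistic scale (years) converting age minus timing
#'   into pubertal-stage progression.
#' @param puberty_noise_sd measurement noise SD of the 1--4 puberty score.
#' @param menarche_lag years from the latent timing age to menarche.
#' @param n_pcs number of ancestry principal-component covariates simulated
#'   (pure noise; no confounding is generated).
#' @param seed integer seed governing every random draw.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 1600,
                          p_mz = 0.66,
                          p_male_pair = 0.48,
                          n_snps = 176,
                          maf_range = c(0.05, 0.5),
                          maf = NULL,
                          weights = NULL,
                          score_var = 5.5,
                          score_load_i = 1,
                          score_load_s = 0,
                          var_i = 60,
                          var_s = 1.0,
                          ace_intercept = c(varA = 0.86, varC = 0.09, varE = 0.05),
                          ace_slope = c(varA = 0.84, varC = 0.11, varE = 0.05),
                          r_g = -0.56,
                          r_c = -0.03,
                          r_e = -0.03,
                          resid_sd = 2.0,
                          mu_i = c(M = 146.0, F = 148.8),
                          mu_s = c(M = 4.55, F = 3.17),
                          wave_ages = c(11.77, 14.84, 17.73, 21.0, 24.85, 29.47),
                          wave_sds = c(0.43, 0.51, 0.55, 0.70, 0.80, 0.53),
                          origin = 10.75,
                          cap_male = 18,
                          cap_female = 16,
                          cohort_mix = 0.36,
                          missing_rate = 0.10,
                          timing_mean = c(M = 14.5, F = 12.3),
                          timing_sd = 1.0,
                          timing_shift = 8,
                          timing_scale = 0.8,
                          puberty_noise_sd = 0.3,
                          menarche_lag = 0.5,
                          n_pcs = 10,
                          seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_families >= 1, cfg$n_snps >= 0)
  for (p in c("p_mz", "p_male_pair", "cohort_mix", "missing_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  for (tr in c("ace_intercept", "ace_slope")) {
    sh <- cfg[[tr]]
    if (any(sh < 0) || abs(sum(sh) - 1) > 1e-8)
      stop(tr, " shares must be non-negative and sum to 1")
  }
  for (r in c("r_g", "r_c", "r_e"))
    if (abs(cfg[[r]]) > 1) stop(r, " must lie in [-1, 1]")
  S <- cohort_cov_components(cfg)
  for (nm in c("A", "C", "E")) {
    ev <- eigen(S[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("implied ", nm, " covariance matrix is not PSD")
  }
  ev <- eigen(S$A_res, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("score variance exceeds the additive-genetic variance it must sit inside")
  invisible(cfg)
}

# Implied 2x2 latent covariance components (intercept, slope) and the
# residual-polygenic A after removing the score contribution.
cohort_cov_components <- function(cfg) {
  vi <- cfg$var_i; vs <- cfg$var_s
  Ai <- cfg$ace_intercept[["varA"]] * vi; As <- cfg$ace_slope[["varA"]] * vs
  Ci <- cfg$ace_intercept[["varC"]] * vi; Cs <- cfg$ace_slope[["varC"]] * vs
  Ei <- cfg$ace_intercept[["varE"]] * vi; Es <- cfg$ace_slope[["varE"]] * vs
  A <- matrix(c(Ai, cfg$r_g * sqrt(Ai * As), cfg$r_g * sqrt(Ai * As), As), 2)
  C <- matrix(c(Ci, cfg$r_c * sqrt(Ci * Cs), cfg$r_c * sqrt(Ci * Cs), Cs), 2)
  E <- matrix(c(Ei, cfg$r_e * sqrt(Ei * Es), cfg$r_e * sqrt(Ei * Es), Es), 2)
  L <- c(cfg$score_load_i, cfg$score_load_s)
  Sc <- cfg$score_var * (L %o% L)
  list(A = A, C = C, E = E, score = Sc, A_res = A - Sc)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Marker frequencies and effect sizes, reproducible from the config seed
# alone so that the truth record never depends on downstream sampling.
draw_markers <- function(cfg) {
  with_local_seed(cfg$seed, {
    maf <- cfg$maf %||% runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    if (length(maf) != cfg$n_snps) stop("maf vector length must equal n_snps")
    beta <- cfg$weights
    if (is.null(beta)) {
      raw <- rnorm(cfg$n_snps)
      v <- sum(2 * maf * (1 - maf) * raw^2)
      beta <- if (v > 0) raw * sqrt(cfg$score_var / v) else raw * 0
    }
    if (length(beta) != cfg$n_snps) stop("weights length must equal n_snps")
    data.frame(snp_id = sprintf("rs%06d", seq_len(cfg$n_snps)),
               chrom = as.character(1L + (seq_len(cfg$n_snps) - 1L) %% 22L),
               pos = 1e5L + 1000L * seq_len(cfg$n_snps),
               effect_allele = "A", other_allele = "G",
               maf = maf, beta = beta, stringsAsFactors = FALSE)
  })
}

# Family frame: zygosity, pair sex, cohort, ids.  Older-cohort families are
# encoded by parental/twin birth years <= 1976 so the assignment is
# recoverable from the pedigree alone.
draw_families <- function(cfg) {
  with_local_seed(cfg$seed + 1L, {
    nf <- cfg$n_families
    fam <- sprintf("FAM%05d", seq_len(nf))
    data.frame(
      family_id = fam,
      zygosity = ifelse(runif(nf) < cfg$p_mz, "MZ", "DZ"),
      pair_sex = ifelse(runif(nf) < cfg$p_male_pair, "M", "F"),
      older = runif(nf) < cfg$cohort_mix,
      stringsAsFactors = FALSE)
  })
}

#' Simulate genotypes and pedigree for a twin-family cohort
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at each
#' SNP's allele frequency; each twin receives one allele per parent by
#' Mendelian transmission.  MZ co-twins share a single meiosis, DZ co-twins
#' are independent meioses.
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `geno` (a `genotype_set` of integer dosages),
#'   `ped` (a `pedigree_table`) and `families` (internal family frame).
#' @export
simulate_genotypes <- function(cfg) {
  if (cfg$n_snps <= 0) stop("n_snps must be positive")
  mk <- draw_markers(cfg)
  fams <- draw_families(cfg)
  nf <- nrow(fams); ns <- nrow(mk)
  out <- with_local_seed(cfg$seed + 2L, {
    p <- matrix(rep(mk$maf, each = nf), nf, ns)
    father <- matrix(rbinom(nf * ns, 2L, p), nf, ns)
    mother <- matrix(rbinom(nf * ns, 2L, p), nf, ns)
    t1 <- matrix(rbinom(nf * ns, 1L, father / 2), nf, ns) +
          matrix(rbinom(nf * ns, 1L, mother / 2), nf, ns)
    t2 <- matrix(rbinom(nf * ns, 1L, father / 2), nf, ns) +
          matrix(rbinom(nf * ns, 1L, mother / 2), nf, ns)
    mz <- fams$zygosity == "MZ"
    t2[mz, ] <- t1[mz, ]
    list(father = father, mother = mother, t1 = t1, t2 = t2)
  })
  ids <- rbind(
    data.frame(family_id = fams$family_id, person_id = paste0(fams$family_id, "_T1"),
               role = "twin1", sex = fams$pair_sex, zygosity = fams$zygosity),
    data.frame(family_id = fams$family_id, person_id = paste0(fams$family_id, "_T2"),
               role = "twin2", sex = fams$pair_sex, zygosity = fams$zygosity),
    data.frame(family_id = fams$family_id, person_id = paste0(fams$family_id, "_F"),
               role = "father", sex = "M", zygosity = NA_character_),
    data.frame(family_id = fams$family_id, person_id = paste0(fams$family_id, "_M"),
               role = "mother", sex = "F", zygosity = NA_character_))
  by <- with_local_seed(cfg$seed + 3L, {
    twin_by <- ifelse(fams$older, sample(1972:1976, nf, TRUE), sample(1977:1994, nf, TRUE))
    parent_off <- function() sample(22:40, nf, TRUE)
    c(twin_by, twin_by, twin_by - parent_off(), twin_by - parent_off())
  })
  ids$birth_year <- by
  ped <- pedigree_table(ids)
  dos <- rbind(out$t1, out$t2, out$father, out$mother)
  rownames(dos) <- ids$person_id
  colnames(dos) <- mk$snp_id
  markers <- mk[c("snp_id", "chrom", "pos", "effect_allele", "other_allele")]
  markers$batch_label <- NA_character_
  markers$imputation_r2 <- NA_real_
  list(geno = genotype_set(markers, dos), ped = ped, families = fams)
}

# A-structured trait: parents get independent N(0, S) draws, children the
# mid-parent mean plus a Mendelian-segregation deviation N(0, S/2); MZ
# co-twins share the child draw.  S may be a scalar variance or 2x2 matrix.
rmvn <- function(n, S) {
  S <- as.matrix(S)
  ev <- eigen(S, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n * nrow(S)), n) %*% rt
}

#' Simulate longitudinal heights and puberty measures
#'
#' Latent intercept and slope per person are the sum of the (centred) SNP
#' score contribution, a residual additive-genetic deviation transmitted
#' from parents to twins, a twin-shared environmental deviation, and an
#' individual deviation.  Height at age a is
#' `mu(sex) + i + s * f(a_eff) + residual`, with `f` the piecewise loading
#' and `a_eff` the chronological age shifted by the (heritable) pubertal
#' timing while below the sex cap.  Puberty scores at the 11 and 14 waves
#' follow a logistic function of age minus timing.
#'
#' @param cfg a [cohort_config()].
#' @param ped pedigree from [simulate_genotypes()].
#' @param geno genotype set from [simulate_genotypes()].
#' @return list with `phenos` (a `long_phenotypes` table),
#'   `covariates` (person-level covariate table) and `latent` (per-person
#'   true intercept/slope deviations and scores, for recovery tests).
#' @export
simulate_growth <- function(cfg, ped, geno) {
  mk <- draw_markers(cfg)
  comp <- cohort_cov_components(cfg)
  fams <- unique(ped$family_id)
  nf <- length(fams)
  rule <- loading_rule(cfg$origin, cfg$cap_male, cfg$cap_female)

  score <- as.numeric(geno$dosages %*% mk$beta) - sum(2 * mk$maf * mk$beta)
  names(score) <- rownames(geno$dosages)

  idx <- function(role) ped$person_id[match(paste0(fams, "_", role), ped$person_id)]
  id_t1 <- paste0(fams, "_T1"); id_t2 <- paste0(fams, "_T2")
  id_fa <- paste0(fams, "_F");  id_mo <- paste0(fams, "_M")
  zyg <- ped$zygosity[match(id_t1, ped$person_id)]
  sex_t <- ped$sex[match(id_t1, ped$person_id)]
  older <- ped$birth_year[match(id_t1, ped$person_id)] <= 1976L

  with_local_seed(cfg$seed + 4L, {
    # residual polygenic A (bivariate), parent -> child transmission
    a_fa <- rmvn(nf, comp$A_res); a_mo <- rmvn(nf, comp$A_res)
    a_t1 <- (a_fa + a_mo) / 2 + rmvn(nf, comp$A_res / 2)
    a_t2 <- (a_fa + a_mo) / 2 + rmvn(nf, comp$A_res / 2)
    mz <- zyg == "MZ"
    a_t2[mz, ] <- a_t1[mz, ]
    # shared environment: one draw per twin pair; parents independent
    c_tw <- rmvn(nf, comp$C); c_fa <- rmvn(nf, comp$C); c_mo <- rmvn(nf, comp$C)
    # nonshared environment
    e_t1 <- rmvn(nf, comp$E); e_t2 <- rmvn(nf, comp$E)
    e_fa <- rmvn(nf, comp$E); e_mo <- rmvn(nf, comp$E)
    # pubertal timing (years, centred): ACE composition mirrors the slope's
    # shares, so the transient spurt bonus perturbs A, C and E in proportion
    sh <- sqrt(cfg$ace_slope) * cfg$timing_sd
    ta_fa <- rnorm(nf); ta_mo <- rnorm(nf)
    ta_t1 <- (ta_fa + ta_mo) / 2 + rnorm(nf, 0, 1 / sqrt(2))
    ta_t2 <- (ta_fa + ta_mo) / 2 + rnorm(nf, 0, 1 / sqrt(2))
    ta_t2[mz] <- ta_t1[mz]
    tc_tw <- rnorm(nf); tc_fa <- rnorm(nf); tc_mo <- rnorm(nf)
    tim_t1 <- sh[["varA"]] * ta_t1 + sh[["varC"]] * tc_tw + sh[["varE"]] * rnorm(nf)
    tim_t2 <- sh[["varA"]] * ta_t2 + sh[["varC"]] * tc_tw + sh[["varE"]] * rnorm(nf)
    tim_fa <- sh[["varA"]] * ta_fa + sh[["varC"]] * tc_fa + sh[["varE"]] * rnorm(nf)
    tim_mo <- sh[["varA"]] * ta_mo + sh[["varC"]] * tc_mo + sh[["varE"]] * rnorm(nf)

    L <- c(cfg$score_load_i, cfg$score_load_s)
    latent_for <- function(ids, a, c_, e, sexes) {
      sc <- score[ids]
      data.frame(person_id = ids, sex = sexes,
                 i_dev = sc * L[1] + a[, 1] + c_[, 1] + e[, 1],
                 s_dev = sc * L[2] + a[, 2] + c_[, 2] + e[, 2],
                 score = sc, stringsAsFactors = FALSE)
    }
    lat <- rbind(latent_for(id_t1, a_t1, c_tw, e_t1, sex_t),
                 latent_for(id_t2, a_t2, c_tw, e_t2, sex_t),
                 latent_for(id_fa, a_fa, c_fa, e_fa, rep("M", nf)),
                 latent_for(id_mo, a_mo, c_mo, e_mo, rep("F", nf)))
    lat$timing <- c(tim_t1, tim_t2, tim_fa, tim_mo)

    # assessment ages shared by co-twins (assessed together)
    nw <- length(cfg$wave_ages)
    ages <- matrix(rnorm(nf * nw, rep(cfg$wave_ages, each = nf),
                         rep(cfg$wave_sds, each = nf)), nf, nw)
    ages <- pmax(ages, cfg$origin)   # no one is assessed before the origin age
    ages <- t(apply(ages, 1, sort))  # guard against rare wave inversions

    rows <- vector("list", 2L)
    for (tw in 1:2) {
      ids <- if (tw == 1) id_t1 else id_t2
      tim <- if (tw == 1) tim_t1 else tim_t2
      li <- lat[match(ids, lat$person_id), ]
      for (w in seq_len(nw)) {
        age <- ages[, w]
        f <- piecewise_loading(age, sex_t, rule)
        mu <- cfg$mu_i[sex_t] + cfg$mu_s[sex_t] * f
        # transient spurt-progress bonus: ahead-of-schedule children are
        # taller while spurts are ongoing; vanishes once everyone finishes
        frac <- plogis((age - (cfg$timing_mean[sex_t] + tim)) / cfg$timing_scale)
        ctr <- plogis((age - cfg$timing_mean[sex_t]) /
                        sqrt(cfg$timing_scale^2 + cfg$timing_sd^2))
        ht <- mu + li$i_dev + li$s_dev * f + cfg$timing_shift * (frac - ctr) +
          rnorm(nf, 0, cfg$resid_sd)
        stage <- 1 + 3 * frac
        pub <- pmin(pmax(stage + rnorm(nf, 0, cfg$puberty_noise_sd), 1), 4)
        men <- as.integer(age >= cfg$timing_mean[sex_t] + tim + cfg$menarche_lag)
        keep_pub <- WAVES[w] %in% c(11L, 14L)
        rows[[tw]][[w]] <- data.frame(
          person_id = ids, wave = WAVES[w], age = age, height = ht,
          puberty = if (keep_pub) pub else NA_real_,
          menarche = if (keep_pub) ifelse(sex_t == "F", men, NA_integer_) else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    tw_ph <- do.call(rbind, c(rows[[1]], rows[[2]]))

    # observation pattern: older cohort starts at 17; random dropout after
    fam_of <- sub("_(T1|T2)$", "", tw_ph$person_id)
    drop_wave <- tw_ph$wave %in% c(11L, 14L) & older[match(fam_of, fams)]
    drop_rand <- runif(nrow(tw_ph)) < cfg$missing_rate
    tw_ph <- tw_ph[!(drop_wave | drop_rand), ]
    # everyone keeps at least one wave: restore the age-17 row if all lost
    lost <- setdiff(c(id_t1, id_t2), tw_ph$person_id)
    if (length(lost)) {
      restore <- do.call(rbind, c(rows[[1]], rows[[2]]))
      restore <- restore[restore$person_id %in% lost & restore$wave == 17L, ]
      tw_ph <- rbind(tw_ph, restore)
    }

    # parents: one adult measurement
    p_age <- runif(2L * nf, 38, 55)
    p_ids <- c(id_fa, id_mo)
    p_sex <- rep(c("M", "F"), each = nf)
    lp <- lat[match(p_ids, lat$person_id), ]
    fp <- piecewise_loading(p_age, p_sex, rule)
    p_ht <- cfg$mu_i[p_sex] + cfg$mu_s[p_sex] * fp + lp$i_dev + lp$s_dev * fp +
      rnorm(2L * nf, 0, cfg$resid_sd)
    par_ph <- data.frame(person_id = p_ids, wave = 29L, age = p_age, height = p_ht,
                         puberty = NA_real_, menarche = NA_integer_,
                         stringsAsFactors = FALSE)

    phenos <- long_phenotypes(rbind(tw_ph, par_ph))
    pcs <- matrix(rnorm(nrow(ped) * cfg$n_pcs), nrow(ped))
    colnames(pcs) <- paste0("PC", seq_len(cfg$n_pcs))
    covars <- data.frame(person_id = ped$person_id,
                         sex = as.integer(ped$sex == "M"),
                         birth_year = ped$birth_year - 1980L,
                         cohort = as.integer(older[match(sub("_(T1|T2|F|M)$", "", ped$person_id), fams)]),
                         stringsAsFactors = FALSE)
    covars <- cbind(covars, as.data.frame(pcs))
    list(phenos = phenos, covariates = covars, latent = lat)
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_growth()].
#'
#' @param cfg a [cohort_config()].
#' @return list with `ped`, `geno`, `phenos`, `covariates`, `latent`,
#'   `truth` (the [truth_record()]).
#' @export
simulate_cohort <- function(cfg) {
  g <- simulate_genotypes(cfg)
  gr <- simulate_growth(cfg, g$ped, g$geno)
  list(ped = g$ped, geno = g$geno, phenos = gr$phenos,
       covariates = gr$covariates, latent = gr$latent, truth = truth_record(cfg))
}

#' Generating-parameter record for a configuration
#'
#' Emits every generating value -- variance components, correlations,
#' per-SNP frequencies and effect sizes -- so parameter-recovery tests can
#' compare estimates with truth.
#'
#' @param cfg a [cohort_config()].
#' @return list with `params` (name/value data.frame) and `snps`
#'   (per-SNP maf and beta).
#' @export
truth_record <- function(cfg) {
  comp <- cohort_cov_components(cfg)
  mk <- draw_markers(cfg)
  rule <- loading_rule(cfg$origin, cfg$cap_male, cfg$cap_female)
  f_M <- cfg$cap_male - cfg$origin; f_F <- cfg$cap_female - cfg$origin
  parab <- function(S, f) S[1, 1] + 2 * f * S[1, 2] + f^2 * S[2, 2]
  Tot <- comp$A + comp$C + comp$E
  adult_var <- c(M = parab(Tot, f_M), F = parab(Tot, f_F)) + cfg$resid_sd^2
  L <- c(cfg$score_load_i, cfg$score_load_s)
  score_adult <- c(M = cfg$score_var * (L[1] + f_M * L[2])^2,
                   F = cfg$score_var * (L[1] + f_F * L[2])^2)
  params <- data.frame(
    name = c("varA_intercept", "varC_intercept", "varE_intercept",
             "varA_slope", "varC_slope", "varE_slope",
             "r_g", "r_c", "r_e", "var_i", "var_s", "cov_is",
             "resid_sd", "score_var", "score_load_i", "score_load_s",
             "adult_var_M", "adult_var_F",
             "score_r2_adult_M", "score_r2_adult_F", "score_r2_adult"),
    value = c(cfg$ace_intercept[["varA"]], cfg$ace_intercept[["varC"]],
              cfg$ace_intercept[["varE"]],
              cfg$ace_slope[["varA"]], cfg$ace_slope[["varC"]],
              cfg$ace_slope[["varE"]],
              cfg$r_g, cfg$r_c, cfg$r_e, cfg$var_i, cfg$var_s, Tot[1, 2],
              cfg$resid_sd, cfg$score_var, cfg$score_load_i, cfg$score_load_s,
              adult_var[["M"]], adult_var[["F"]],
              score_adult[["M"]] / adult_var[["M"]],
              score_adult[["F"]] / adult_var[["F"]],
              mean(score_adult / adult_var)),
    stringsAsFactors = FALSE)
  list(params = params, snps = mk)
}

truth_value <- function(truth, name) {
  truth$params$value[match(name, truth$params$name)]
}
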