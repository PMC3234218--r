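test_that("monomorphic markers and MZ/DZ dosage correlations behave as kinship predicts", {
  cfg <- cohort_config(n_families = 2000, n_snps = 3, maf = c(0, 0.3, 0.3),
                       weights = c(0, 0.1, 0.1), seed = 5)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$geno$dosages[, 1] == 0))

  fams <- unique(g$ped$family_id)
  t1 <- g$geno$dosages[paste0(fams, "_T1"), ]
  t2 <- g$geno$dosages[paste0(fams, "_T2"), ]
  zy <- g$ped$zygosity[match(paste0(fams, "_T1"), g$ped$person_id)]
  expect_identical(unname(t1[zy == "MZ", ]), unname(t2[zy == "MZ", ]))
  r_dz <- cor(t1[zy == "DZ", 2], t2[zy == "DZ", 2])
  n_dz <- sum(zy == "DZ")
  se <- (1 - 0.5^2) / sqrt(n_dz - 3)   # Fisher-scale approximation
  expect_lt(abs(r_dz - 0.5), 3 * se)
})

test_that("pure-A limit makes MZ co-twin heights identical at every wave", {
  cfg <- cohort_config(n_families = 60, n_snps = 10, resid_sd = 0,
                       ace_intercept = c(varA = 1, varC = 0, varE = 0),
                       ace_slope = c(varA = 1, varC = 0, varE = 0),
                       missing_rate = 0, cohort_mix = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  ph <- sim$phenos
  fams <- unique(sim$ped$family_id)
  zy <- sim$ped$zygosity[match(paste0(fams, "_T1"), sim$ped$person_id)]
  for (fam in fams[zy == "MZ"]) {
    h1 <- ph$height[ph$person_id == paste0(fam, "_T1")][order(ph$wave[ph$person_id == paste0(fam, "_T1")])]
    h2 <- ph$height[ph$person_id == paste0(fam, "_T2")][order(ph$wave[ph$person_id == paste0(fam, "_T2")])]
    expect_equal(h1, h2, tolerance = 1e-10)
  }
})

test_that("latent intercept twin correlations follow Falconer expectations", {
  sim <- cached("falconer_sim",
                simulate_cohort(cohort_config(n_families = 3000, seed = 21)))
  lat <- sim$latent
  fams <- unique(sim$ped$family_id)
  zy <- sim$ped$zygosity[match(paste0(fams, "_T1"), sim$ped$person_id)]
  i1 <- lat$i_dev[match(paste0(fams, "_T1"), lat$person_id)]
  i2 <- lat$i_dev[match(paste0(fams, "_T2"), lat$person_id)]
  r_mz <- cor(i1[zy == "MZ"], i2[zy == "MZ"])
  r_dz <- cor(i1[zy == "DZ"], i2[zy == "DZ"])
  exp_mz <- 0.86 + 0.09
  exp_dz <- 0.5 * 0.86 + 0.09
  se_mz <- (1 - exp_mz^2) / sqrt(sum(zy == "MZ") - 3)
  se_dz <- (1 - exp_dz^2) / sqrt(sum(zy == "DZ") - 3)
  expect_lt(abs(r_mz - exp_mz), 3 * se_mz)
  expect_lt(abs(r_dz - exp_dz), 3 * se_dz)
})

test_that("wave variances match the variance parabola of the generating model", {
  sim <- cached("falconer_sim",
                simulate_cohort(cohort_config(n_families = 3000, seed = 21)))
  cfg <- cohort_config(n_families = 3000, seed = 21)
  comp <- twingrowth:::cohort_cov_components(cfg)
  Tot <- comp$A + comp$C + comp$E
  ph <- sim$phenos
  sex <- sim$ped$sex[match(ph$person_id, sim$ped$person_id)]
  role <- sim$ped$role[match(ph$person_id, sim$ped$person_id)]
  rule <- loading_rule()
  for (w in c(17L, 29L)) {
    sel <- ph$wave == w & sex == "M" & role %in% c("twin1", "twin2")
    f <- piecewise_loading(ph$age[sel], "M", rule)
    v_model <- mean(Tot[1, 1] + 2 * f * Tot[1, 2] + f^2 * Tot[2, 2]) + cfg$resid_sd^2
    v_obs <- var(ph$height[sel])
    expect_lt(abs(v_obs - v_model) / v_model, 0.12)
  }
})

test_that("zero weights give a score with no explanatory power", {
  cfg <- cohort_config(n_families = 400, n_snps = 20,
                       weights = rep(0, 20), score_var = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  sc <- as.numeric(sim$geno$dosages %*% sim$truth$snps$beta)
  expect_true(all(sc == 0))
  expect_equal(twingrowth:::truth_value(sim$truth, "score_r2_adult"), 0)
})

test_that("truth record lists generating values and is seed-stable for supplied inputs", {
  cfg <- cohort_config(seed = 11)
  tr <- truth_record(cfg)
  expect_equal(twingrowth:::truth_value(tr, "varA_intercept"), 0.86)
  expect_equal(twingrowth:::truth_value(tr, "r_g"), -0.56)
  # drawn weights reproduce under the same seed
  tr2 <- truth_record(cohort_config(seed = 11))
  expect_identical(tr$snps$beta, tr2$snps$beta)
  # user-supplied weights and frequencies are invariant to the seed
  w <- seq(-0.2, 0.2, length.out = 20)
  mafs <- rep(0.25, 20)
  t1 <- truth_record(cohort_config(n_snps = 20, weights = w, maf = mafs, seed = 1))
  t2 <- truth_record(cohort_config(n_snps = 20, weights = w, maf = mafs, seed = 99))
  expect_identical(t1$snps$beta, t2$snps$beta)
  expect_identical(t1$snps$maf, t2$snps$maf)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(cohort_config(ace_intercept = c(varA = 0.9, varC = 0.2, varE = 0.1)),
               "sum to 1")
  expect_error(cohort_config(r_g = -1.4), "r_g")
  expect_error(cohort_config(score_var = 80), "score variance exceeds")
  expect_error(simulate_genotypes(cohort_config(n_snps = 0)), "n_snps")
})

test_that("puberty scores show the sex-specific height-correlation pattern", {
  sim <- cached("falconer_sim",
                simulate_cohort(cohort_config(n_families = 3000, seed = 21)))
  ph <- sim$phenos
  sex <- sim$ped$sex[match(ph$person_id, sim$ped$person_id)]
  cor_hp <- function(s, w) {
    sel <- ph$wave == w & sex == s & !is.na(ph$puberty)
    cor(ph$height[sel], ph$puberty[sel])
  }
  # girls' puberty score correlates more with height at 11 than at 14;
  # boys show the reverse ordering
  expect_gt(cor_hp("F", 11L), cor_hp("F", 14L))
  expect_gt(cor_hp("M", 14L), cor_hp("M", 11L))
  # menarche: a minority of girls at the age-11 wave, most by 14
  men11 <- ph$menarche[ph$wave == 11L & sex == "F"]
  men14 <- ph$menarche[ph$wave == 14L & sex == "F"]
  expect_lt(mean(men11, na.rm = TRUE), 0.35)
  expect_gt(mean(men14, na.rm = TRUE), 0.75)
})
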