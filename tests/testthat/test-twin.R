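ace_params_example <- function() {
  A <- matrix(c(50, -3.5, -3.5, 0.9), 2)
  C <- matrix(c(6, -0.1, -0.1, 0.12), 2)
  E <- matrix(c(3, -0.05, -0.05, 0.06), 2)
  list(A = A, C = C, E = E)
}

test_that("pair likelihood matches the direct matrix-construction oracle", {
  sim <- default_sim()
  dat <- twingrowth:::prepare_pair_data(sim$phenos, sim$ped)
  cp <- ace_params_example()
  params <- list(mean = c(147, 4.2, 2.5, 1.2), A = cp$A, C = cp$C, E = cp$E,
                 var_resid = 4.5)
  stopifnot(ncol(dat$M) == 4)  # both sexes: sex-specific means
  ll <- pair_loglik(params, dat)
  mu <- as.numeric(dat$M %*% params$mean)
  ll_o <- 0
  for (p in seq_len(dat$n_pairs)) {
    a <- dat$ptr[p] + 1L; b <- dat$ptr[p + 1L]
    t1 <- dat$twin[a:b] == 0L
    S <- pair_cov_oracle(dat$f[a:b][t1], dat$f[a:b][!t1], cp$A, cp$C, cp$E,
                         dat$kappa[p], params$var_resid)
    r <- c((dat$y[a:b] - mu[a:b])[t1], (dat$y[a:b] - mu[a:b])[!t1])
    ll_o <- ll_o + dmvn_log(r, S)
  }
  expect_equal(ll, ll_o, tolerance = 1e-8)
})

test_that("MZ sharing and independence limits of the pair covariance hold", {
  cp <- ace_params_example()
  # perfect MZ sharing: with no E and no residual, cross-twin block equals
  # the within-twin block
  f <- c(0.5, 4, 7.25)
  S <- pair_cov_oracle(f, f, cp$A, cp$C, matrix(0, 2, 2), 1, 0)
  expect_equal(S[1:3, 1:3], S[1:3, 4:6], ignore_attr = TRUE)
  # DZ cross-twin intercept covariance is 0.5 varA_i + varC_i
  S_dz <- pair_cov_oracle(0, 0, cp$A, cp$C, cp$E, 0.5, 1)
  expect_equal(S_dz[1, 2], 0.5 * cp$A[1, 1] + cp$C[1, 1])
  # implied MZ cross-twin covariance dominates DZ for PSD A
  S_mz <- pair_cov_oracle(0, 0, cp$A, cp$C, cp$E, 1, 1)
  expect_gte(S_mz[1, 2], S_dz[1, 2])

  # with A = C = 0 the pair likelihood factors into person likelihoods
  sim <- default_sim()
  dat <- twingrowth:::prepare_pair_data(sim$phenos, sim$ped)
  Z0 <- matrix(0, 2, 2)
  params <- list(mean = c(147, 4.2, 2.5, 1.2), A = Z0, C = Z0, E = cp$E,
                 var_resid = 4.5)
  ll_pair <- pair_loglik(params, dat)
  gdat <- twingrowth:::prepare_growth_data(sim$phenos, sim$ped,
    persons = sim$ped$person_id[sim$ped$role %in% c("twin1", "twin2")])
  gparams <- list(mean = params$mean[match(colnames(gdat$M), colnames(dat$M))],
                  var_i = cp$E[1, 1], var_s = cp$E[2, 2], cov_is = cp$E[1, 2],
                  var_resid = 4.5)
  expect_equal(ll_pair, fiml_loglik(gparams, gdat), tolerance = 1e-8)
})

test_that("ACE fit recovers shares near truth, sums shares to one, needs both zygosities", {
  fit <- default_ace_base()
  s <- fit$summaries
  expect_equal(unname(s["shareA_i"] + s["shareC_i"] + s["shareE_i"]), 1,
               tolerance = 1e-8)
  expect_equal(unname(s["shareA_s"] + s["shareC_s"] + s["shareE_s"]), 1,
               tolerance = 1e-8)
  # broad plausibility at n = 500 pairs around the generating .86/.84, r_g -.56
  expect_gt(unname(s["shareA_i"]), 0.55)
  expect_gt(unname(s["shareA_s"]), 0.55)
  expect_lt(unname(s["r_g"]), -0.3)
  expect_lt(unname(s["r_phenotypic"]), -0.3)
  # implied MZ vs DZ cross-twin covariance ordering
  expect_gte(fit$A[1, 1] + fit$C[1, 1], 0.5 * fit$A[1, 1] + fit$C[1, 1])

  sim <- default_sim()
  mz_only <- sim$ped$family_id[!is.na(sim$ped$zygosity) & sim$ped$zygosity == "MZ"]
  ped_mz <- sim$ped[sim$ped$family_id %in% mz_only, ]
  ph_mz <- sim$phenos[sim$phenos$person_id %in% ped_mz$person_id, ]
  expect_error(fit_twin_ace(ph_mz, ped_mz), "both MZ and DZ")
})

test_that("score effects in the twin model concentrate on the intercept", {
  fit <- default_ace_score("both")
  b <- fit$coefficients
  expect_lt(abs(b[["beta_ig"]] - 1), 0.35)
  expect_lt(abs(b[["beta_sg"]]), 0.1)
})

test_that("variance parabola evaluates the quadratic form and its limits", {
  fit <- default_ace_base()
  v0 <- variance_parabola(fit, 10.75, "M", "total")
  expect_equal(v0, fit$A[1, 1] + fit$C[1, 1] + fit$E[1, 1], tolerance = 1e-10)
  expect_equal(variance_parabola(fit, 10.75, "M", "total", include_resid = TRUE),
               v0 + mean(fit$var_resid), tolerance = 1e-10)
  expect_equal(variance_parabola(fit, 10.75, "M", "genetic"), fit$A[1, 1])
  # beyond the male cap the loading is frozen, so the variance is flat
  expect_equal(variance_parabola(fit, 18, "M", "total"),
               variance_parabola(fit, 29, "M", "total"))
  expect_error(variance_parabola(fit, 9, "M"), "below")
  # with zero intercept-slope covariance the parabola is non-decreasing
  fit0 <- fit
  fit0$A[1, 2] <- fit0$A[2, 1] <- 0
  fit0$C[1, 2] <- fit0$C[2, 1] <- 0
  fit0$E[1, 2] <- fit0$E[2, 1] <- 0
  ages <- seq(10.75, 18, by = 0.25)
  v <- variance_parabola(fit0, ages, "M", "total")
  expect_true(all(diff(v) >= -1e-10))
})

test_that("r2 curves are zero for identical fits and genetic r2 dominates phenotypic", {
  base <- default_ace_base()
  rc0 <- r2_curves(base, base, "phenotypic")
  expect_true(all(abs(rc0$curve$r2) < 1e-12))

  both <- default_ace_score("both")
  rp <- r2_curves(base, both, "phenotypic")
  rg <- r2_curves(base, both, "genetic")
  expect_true(all(rp$curve$r2 > 0))
  expect_true(all(rg$curve$r2 >= rp$curve$r2))
  expect_gt(rg$r2_max, rp$r2_max)

  # with no slope-specific score effect generated, the full model gains
  # almost nothing over the intercept-only model
  ionly <- default_ace_score("intercept_only")
  rp_i <- r2_curves(base, ionly, "phenotypic")
  expect_lt(abs(rp$r2_max - rp_i$r2_max), 0.02)
})

test_that("male heights are scaled exactly onto female wave moments before sex comparison", {
  sim <- cached("sex_sim", simulate_cohort(cohort_config(n_families = 350, seed = 33)))
  cmp <- sex_specific_compare(sim$phenos, sim$ped)
  expect_identical(cmp$df, 9L)
  expect_gte(cmp$lrt, 0)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  # the scaling table pins male wave moments onto female ones; verify the
  # transform reproduces the female mean exactly on raw data
  sc <- cmp$scaling[cmp$scaling$wave == 17, ]
  ph <- sim$phenos
  sex <- sim$ped$sex[match(ph$person_id, sim$ped$person_id)]
  tw <- sim$ped$role[match(ph$person_id, sim$ped$person_id)] %in% c("twin1", "twin2")
  hm <- ph$height[ph$wave == 17 & sex == "M" & tw & !is.na(ph$height)]
  scaled <- (hm - sc$male_mean) / sc$male_sd * sc$female_sd + sc$female_mean
  expect_equal(mean(scaled), sc$female_mean, tolerance = 1e-10)
  expect_equal(sd(scaled), sc$female_sd, tolerance = 1e-10)
})
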