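test_that("adult-height eligibility applies the sex caps to twins but not parents", {
  ped <- pedigree_table(data.frame(
    family_id = c("F1", "F1", "F1", "F1", "F2", "F2"),
    person_id = c("mt", "ft", "mo", "fa", "gt", "gt2"),
    role = c("twin1", "twin2", "mother", "father", "twin1", "twin2"),
    sex = c("M", "M", "F", "M", "F", "F"),
    zygosity = c("MZ", "MZ", NA, NA, "DZ", "DZ"),
    birth_year = c(1990L, 1990L, 1960L, 1960L, 1991L, 1991L)))
  ph <- long_phenotypes(data.frame(
    person_id = c("mt", "ft", "mo", "fa", "gt", "gt2"),
    wave = c(17L, 29L, 29L, 29L, 17L, 14L),
    age = c(17.7, 29.1, 45, 46, 16.1, 14.9),
    height = c(178, 180, 165, 178, 166, 160)))
  adult <- adult_height_filter(ped, ph)
  # male twin last seen at 17.7 -> excluded; female at 16.1 -> included;
  # female at 14.9 -> excluded; parents always in
  expect_setequal(adult$person_id, c("ft", "mo", "fa", "gt"))
  expect_equal(adult$adult_height[adult$person_id == "gt"], 166)
})

test_that("a cohort of 6481 with 775 under-cap twins leaves 5706 eligible", {
  n_fam <- 1621  # four-person families, trimmed below to 6481 persons
  ped_df <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    fam <- sprintf("F%04d", i)
    data.frame(family_id = fam,
               person_id = paste0(fam, c("_T1", "_T2", "_MO", "_FA")),
               role = c("twin1", "twin2", "mother", "father"),
               sex = c("M", "M", "F", "M"),
               zygosity = c("DZ", "DZ", NA, NA),
               birth_year = c(1985L, 1985L, 1960L, 1958L))
  }))
  ped_df <- ped_df[seq_len(6481), ]
  ped <- pedigree_table(ped_df)
  is_twin <- ped$role %in% c("twin1", "twin2")
  twin_ids <- ped$person_id[is_twin]
  under <- twin_ids[seq_len(775)]                # assessed last at 17, under the male cap
  ph <- data.frame(person_id = ped$person_id,
                   wave = ifelse(ped$person_id %in% under, 17L, 29L),
                   age = ifelse(ped$person_id %in% under, 17.5,
                                ifelse(is_twin, 29.2, 47)),
                   height = 175)
  adult <- adult_height_filter(ped, long_phenotypes(ph))
  expect_identical(nrow(adult), 5706L)
})

test_that("GLS with identity covariance reproduces OLS to machine precision", {
  sim <- default_sim()
  adult <- adult_height_filter(sim$ped, sim$phenos)
  vc <- fit_null_vc(adult, sim$ped, sim$covariates)
  vc_id <- vc
  vc_id$sigma2_g <- 0
  vc_id$sigma2_e <- 1
  g <- default_score()$score
  row <- gls_assoc(g, vc_id, +1)
  d <- data.frame(y = vc$y, g = as.numeric(g[vc$persons]))
  ols <- lm(y ~ 0 + vc$X + g, data = d)
  sm <- summary(ols)$coefficients
  expect_equal(row$beta, sm["g", "Estimate"], tolerance = 1e-10)
  expect_equal(row$se, sm["g", "Std. Error"], tolerance = 1e-10)
  expect_error(gls_assoc(setNames(rep(1, length(vc$persons)), vc$persons), vc_id),
               "constant")
})

test_that("null variance components match a dense-matrix oracle on small families", {
  cfg <- cohort_config(n_families = 10, n_snps = 5, seed = 19)
  sim <- simulate_cohort(cfg)
  adult <- adult_height_filter(sim$ped, sim$phenos)
  vc <- fit_null_vc(adult, sim$ped)
  # oracle: profile loglik from explicit dense block-diagonal V
  dense_ll <- function(sg2, se2) {
    n <- length(vc$y)
    V <- matrix(0, n, n)
    for (b in vc$blocks) V[b$idx, b$idx] <- sg2 * b$K + se2 * diag(length(b$idx))
    Vi <- solve(V)
    beta <- solve(t(vc$X) %*% Vi %*% vc$X, t(vc$X) %*% Vi %*% vc$y)
    r <- vc$y - vc$X %*% beta
    as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
  }
  expect_equal(vc$loglik, dense_ll(vc$sigma2_g, vc$sigma2_e), tolerance = 1e-6)
  opt <- optim(log(c(20, 10)), function(lp) -dense_ll(exp(lp[1]), exp(lp[2])),
               method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 1000))
  expect_equal(vc$loglik, -opt$value, tolerance = 1e-5)

  # no familial component -> sigma2_g collapses
  ph0 <- sim$phenos
  withr::with_seed(20, ph0$height <- 170 + rnorm(nrow(ph0), 0, 5))
  ph0 <- long_phenotypes(ph0)
  adult0 <- adult_height_filter(sim$ped, ph0)
  vc0 <- fit_null_vc(adult0, sim$ped)
  expect_lt(vc0$sigma2_g / (vc0$sigma2_g + vc0$sigma2_e), 0.25)
})

test_that("fitted family components reproduce the MZ phenotypic correlation", {
  sim <- default_sim()
  adult <- adult_height_filter(sim$ped, sim$phenos)
  vc <- fit_null_vc(adult, sim$ped, sim$covariates)
  icc <- vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e)
  fams <- unique(sim$ped$family_id)
  zy <- sim$ped$zygosity[match(paste0(fams, "_T1"), sim$ped$person_id)]
  a1 <- adult$adult_height[match(paste0(fams, "_T1"), adult$person_id)]
  a2 <- adult$adult_height[match(paste0(fams, "_T2"), adult$person_id)]
  sexM <- sim$ped$sex[match(paste0(fams, "_T1"), sim$ped$person_id)] == "M"
  res1 <- a1 - ave(a1, sexM, FUN = function(x) mean(x, na.rm = TRUE))
  res2 <- a2 - ave(a2, sexM, FUN = function(x) mean(x, na.rm = TRUE))
  r_mz <- cor(res1[zy == "MZ"], res2[zy == "MZ"], use = "complete.obs")
  expect_lt(abs(icc - r_mz), 0.12)
})

test_that("binomial sign test matches the paper-scale constants and summation", {
  expect_equal(round(binomial_sign_test(77, 176), 2), 0.06)
  expect_lt(abs(log10(binomial_sign_test(49, 176)) - log10(2e-9)), 0.5)
  expect_equal(binomial_sign_test(88, 176), binom_tail_oracle(88, 176),
               tolerance = 1e-12)
  for (k in c(0, 10, 60, 120, 176))
    expect_equal(binomial_sign_test(k, 176), binom_tail_oracle(k, 176),
                 tolerance = 1e-12)
  p <- vapply(0:176, binomial_sign_test, numeric(1), n_total = 176)
  expect_true(all(diff(p) >= 0))
  expect_error(binomial_sign_test(1, 0), "positive")
  expect_error(binomial_sign_test(-1, 10), "range")
})

test_that("multiplicity summary computes the Bonferroni partition and QQ data", {
  expect_equal(multiplicity_summary(data.frame(p_one = rep(1, 176)))$bonferroni_threshold,
               0.05 / 176, tolerance = 1e-12)
  all1 <- multiplicity_summary(data.frame(p_one = rep(1, 20)))
  expect_identical(all1$n_bonferroni, 0L)
  expect_identical(all1$n_nominal, 0L)
  withr::with_seed(8, {
    u <- runif(5000)
    qq <- multiplicity_summary(data.frame(p_one = u))$qq
    mid <- qq$expected < 2
    expect_lt(max(abs(qq$observed[mid] - qq$expected[mid])), 0.25)
  })
})

test_that("the association scan recovers the score and per-SNP directions", {
  sim <- default_sim()
  adult <- adult_height_filter(sim$ped, sim$phenos)
  vc <- fit_null_vc(adult, sim$ped, sim$covariates)
  tab <- assoc_scan(sim$geno, default_weights(), vc)
  expect_identical(nrow(tab), 176L)
  expect_true(all(tab$p_one > 0 & tab$p_one <= 1))
  expect_true(all(tab$p_one == tab$p_two / 2 | tab$p_one == 1 - tab$p_two / 2))
  # true effects are in the weight direction: concordance beats chance
  expect_lt(binomial_sign_test(sum(!tab$direction_concordant), nrow(tab)), 0.01)
  sc <- gls_assoc(default_score()$score, vc, +1)
  expect_lt(abs(sc$beta - 1), 3.5 * sc$se)
  expect_lt(sc$p_one, 1e-10)
  expect_gt(sc$r2, 0.02)
})
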