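# Twin extension of the growth model: the latent intercept and slope are
# decomposed into additive-genetic (A), shared-environmental (C) and
# nonshared-environmental (E) bivariate components using MZ/DZ resemblance.
# Cross-twin covariance carries kappa*A + C (kappa = 1 MZ, 0.5 DZ).

prepare_pair_data <- function(phenos, ped, covariates = NULL, score = NULL,
                              rule = loading_rule(),
                              score_cols = c("none", "intercept_only", "slope_only", "both")) {
  score_cols <- match.arg(score_cols)
  ph <- as.data.frame(phenos)
  ph <- ph[!is.na(ph$height) & !is.na(ph$age), ]
  tw <- ped[ped$role %in% c("twin1", "twin2"), ]
  ph <- ph[ph$person_id %in% tw$person_id, ]
  fam <- tw$family_id[match(ph$person_id, tw$person_id)]
  zyg <- tw$zygosity[match(fam, tw$family_id)]
  drop_fam <- unique(fam[is.na(zyg)])
  if (length(drop_fam)) {
    message(length(drop_fam), " pair(s) with unknown zygosity excluded")
    keep <- !(fam %in% drop_fam)
    ph <- ph[keep, ]; fam <- fam[keep]
  }
  role <- tw$role[match(ph$person_id, tw$person_id)]
  ord <- order(fam, role, ph$wave)
  ph <- ph[ord, ]; fam <- fam[ord]; role <- role[ord]
  fams <- unique(fam)
  ptr <- c(0L, cumsum(as.integer(table(factor(fam, levels = fams)))))
  twin_id <- as.integer(role == "twin2")
  kappa <- ifelse(tw$zygosity[match(fams, tw$family_id)] == "MZ", 1, 0.5)
  sex <- tw$sex[match(ph$person_id, tw$person_id)]
  f <- piecewise_loading(ph$age, sex, rule)
  sexM <- as.numeric(sex == "M")
  both_sex <- length(unique(sex)) > 1L
  M <- cbind(`(mu_i)` = 1, `(mu_s)` = f)
  if (both_sex) M <- cbind(M, `(mu_i:sexM)` = sexM, `(mu_s:sexM)` = f * sexM)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cn <- setdiff(names(cv), "person_id")
    X <- as.matrix(cv[match(ph$person_id, cv$person_id), cn, drop = FALSE])
    if (anyNA(X)) stop("missing covariate values for phenotyped twins")
    M <- cbind(M, X)
  }
  score_var <- NA_real_
  if (!is.null(score) && score_cols != "none") {
    if (is.data.frame(score)) score <- setNames(score[[2]], score[[1]])
    g <- as.numeric(score[ph$person_id])
    if (anyNA(g)) stop("score missing for some phenotyped twins")
    score_var <- var(g[!duplicated(ph$person_id)])
    if (score_cols %in% c("intercept_only", "both")) M <- cbind(M, beta_ig = g)
    if (score_cols %in% c("slope_only", "both")) M <- cbind(M, beta_sg = f * g)
  }
  M <- drop_collinear(M)
  list(y = ph$height, f = f, ptr = ptr, twin = twin_id, kappa = kappa, M = M,
       fams = fams, sexM_obs = sexM, n_pairs = length(fams),
       score_var = score_var, wave_idx = match(ph$wave, WAVES))
}

# theta layout: [mean p] [La 3] [Lc 3] [Le 3] [log sd resid (1 or 2 by sex)]
chol2cov <- function(l) {
  L <- matrix(c(exp(l[1]), l[2], 0, exp(l[3])), 2)
  L %*% t(L)
}

ace_theta_parts <- function(theta, p, resid_by_sex = FALSE) {
  A <- chol2cov(theta[p + 1:3])
  C <- chol2cov(theta[p + 4:6])
  E <- chol2cov(theta[p + 7:9])
  nr <- if (resid_by_sex) 2L else 1L
  sig2 <- exp(2 * theta[p + 9 + seq_len(nr)])
  list(mean = theta[seq_len(p)], A = A, C = C, E = E, sig2 = sig2)
}

ace_negloglik <- function(theta, dat, resid_by_sex = FALSE) {
  pp <- ace_theta_parts(theta, ncol(dat$M), resid_by_sex)
  mu <- as.numeric(dat$M %*% pp$mean)
  s2 <- if (length(pp$sig2) == 1L) rep(pp$sig2, length(dat$y))
        else pp$sig2[1L + dat$sexM_obs]
  -ace_loglik_cpp(dat$y, dat$f, dat$ptr, dat$twin, mu, pp$A, pp$C, pp$E,
                  dat$kappa, s2)
}

#' Twin-pair log-likelihood of the ACE growth model
#'
#' Stacks both twins' observed waves; within-twin latent covariance is
#' `A + C + E`, cross-twin is `kappa A + C` with `kappa` 1 for MZ and 0.5
#' for DZ pairs, and the wave residual is uncorrelated across twins.
#'
#' @param params list with `mean` (coefficients matching the mean design),
#'   `A`, `C`, `E` (2x2 covariance matrices of intercept/slope deviations)
#'   and `var_resid`.
#' @param data pair structure as stored in a [fit_twin_ace()] result
#'   (`$data`).
#' @return log-likelihood (scalar).
#' @export
pair_loglik <- function(params, data) {
  mu <- as.numeric(data$M %*% params$mean)
  vr <- params$var_resid
  s2 <- if (length(vr) == 1L) rep(vr, length(data$y)) else vr[1L + data$sexM_obs]
  ace_loglik_cpp(data$y, data$f, data$ptr, data$twin, mu,
                 params$A, params$C, params$E, data$kappa, s2)
}

num_jacobian <- function(fn, x, eps = 1e-5) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

safe_corr <- function(S) {
  d <- sqrt(S[1, 1] * S[2, 2])
  if (d <= 0) return(0)
  S[1, 2] / d
}

ace_summaries <- function(theta, p, resid_by_sex = FALSE) {
  pp <- ace_theta_parts(theta, p, resid_by_sex)
  Tot <- pp$A + pp$C + pp$E
  c(shareA_i = pp$A[1, 1] / Tot[1, 1], shareC_i = pp$C[1, 1] / Tot[1, 1],
    shareE_i = pp$E[1, 1] / Tot[1, 1],
    shareA_s = pp$A[2, 2] / Tot[2, 2], shareC_s = pp$C[2, 2] / Tot[2, 2],
    shareE_s = pp$E[2, 2] / Tot[2, 2],
    r_g = safe_corr(pp$A), r_c = safe_corr(pp$C), r_e = safe_corr(pp$E),
    r_phenotypic = safe_corr(Tot))
}

#' Fit the bivariate ACE twin growth model
#'
#' Maximum-likelihood estimation over MZ and DZ pairs, with the three 2x2
#' latent covariance components parameterized by Cholesky factors.  A
#' genetic score can enter the mean with an intercept effect (`beta_ig`), a
#' slope effect (`beta_sg`) or both, per `constraint`; since genotypes are
#' inherited, the variance the score removes is attributed to the
#' additive-genetic component when variance parabolas are compared.
#'
#' @param phenos a `long_phenotypes` table (twins; other persons ignored).
#' @param ped a `pedigree_table` with zygosity.
#' @param covariates optional covariate table.
#' @param score optional per-person score (named vector or two-column
#'   data.frame).
#' @param constraint which score effects are free: `"none"` (base model,
#'   score unused), `"intercept_only"`, `"slope_only"`, `"both"`.
#' @param rule a [loading_rule()].
#' @param resid_by_sex estimate separate wave-residual variances per sex.
#' @param se compute standard errors and delta-method summaries.
#' @return object of class `ace_fit`: `coefficients`, `A`, `C`, `E`,
#'   `var_resid`, `summaries` (standardized shares and correlations with SEs
#'   and 95\% CIs), `loglik`, `n_pairs`, `theta`, `vcov_theta`, `data`.
#' @export
fit_twin_ace <- function(phenos, ped, covariates = NULL, score = NULL,
                         constraint = c("none", "intercept_only", "slope_only", "both"),
                         rule = loading_rule(), resid_by_sex = FALSE,
                         se = TRUE) {
  constraint <- match.arg(constraint)
  dat <- prepare_pair_data(phenos, ped, covariates, score, rule,
                           score_cols = constraint)
  if (length(unique(dat$kappa)) < 2L)
    stop("both MZ and DZ pairs are required to separate A from C")
  p <- ncol(dat$M)
  # starting values: phenotypic growth fit, split across A/C/E
  gdat <- list(y = dat$y, f = dat$f,
               ptr = seq.int(0L, length(dat$y)),  # placeholder, not used
               M = dat$M, n_persons = dat$n_pairs)
  b0 <- qr.coef(qr(dat$M), dat$y); b0[is.na(b0)] <- 0
  r <- dat$y - as.numeric(dat$M %*% b0)
  vtot <- max(var(r), 4)
  la <- c(0.5 * log(0.6 * vtot), 0, 0.5 * log(0.6 * 0.5))
  lc <- c(0.5 * log(0.2 * vtot), 0, 0.5 * log(0.2 * 0.5))
  le <- c(0.5 * log(0.1 * vtot), 0, 0.5 * log(0.1 * 0.5))
  th0 <- c(b0, la, lc, le, rep(log(max(sd(r) * 0.3, 0.5)),
                               if (resid_by_sex) 2L else 1L))
  opt <- optim(th0, ace_negloglik, dat = dat, resid_by_sex = resid_by_sex,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("ACE optimizer did not report clean convergence (code ",
            opt$convergence, ")")
  th <- opt$par
  pp <- ace_theta_parts(th, p, resid_by_sex)
  names(pp$mean) <- colnames(dat$M)
  sm <- ace_summaries(th, p, resid_by_sex)
  fit <- list(coefficients = pp$mean, A = pp$A, C = pp$C, E = pp$E,
              var_resid = pp$sig2, loglik = -opt$value,
              summaries = sm, constraint = constraint,
              convergence = opt$convergence, n_pairs = dat$n_pairs,
              rule = rule, resid_by_sex = resid_by_sex, theta = th, data = dat)
  if (se) {
    H <- tryCatch(optimHess(th, ace_negloglik, dat = dat,
                            resid_by_sex = resid_by_sex),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V)) {
      fit$vcov_theta <- V
      cse <- sqrt(pmax(diag(V)[seq_len(p)], 0))
      names(cse) <- colnames(dat$M)
      fit$se <- cse
      J <- num_jacobian(function(x) ace_summaries(x, p, resid_by_sex), th)
      sse <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
      lo <- sm - qnorm(0.975) * sse
      hi <- sm + qnorm(0.975) * sse
      shr <- grepl("^share", names(sm))
      lo[shr] <- pmax(lo[shr], 0); hi[shr] <- pmin(hi[shr], 1)
      lo[!shr] <- pmax(lo[!shr], -1); hi[!shr] <- pmin(hi[!shr], 1)
      fit$summary_table <- data.frame(quantity = names(sm), estimate = unname(sm),
                                      se = sse, lo = unname(lo), hi = unname(hi),
                                      row.names = NULL)
      if (constraint != "none") {
        eff <- intersect(c("beta_ig", "beta_sg"), names(pp$mean))
        est <- pp$mean[eff]; ses <- cse[eff]
        tt <- est / ses
        df <- dat$n_pairs - p
        fit$tests <- data.frame(effect = eff, estimate = est, se = ses,
                                t = tt, df = df, p_two = 2 * pt(-abs(tt), df),
                                row.names = NULL)
      }
    }
  }
  class(fit) <- "ace_fit"
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Bivariate ACE latent growth model (", x$n_pairs, " twin pairs)\n", sep = "")
  cat(sprintf("  logLik %.2f; constraint: %s\n", x$loglik, x$constraint))
  s <- x$summaries
  cat(sprintf("  intercept A/C/E: %.2f/%.2f/%.2f   slope A/C/E: %.2f/%.2f/%.2f\n",
              s["shareA_i"], s["shareC_i"], s["shareE_i"],
              s["shareA_s"], s["shareC_s"], s["shareE_s"]))
  cat(sprintf("  r_g %.2f  r_c %.2f  r_e %.2f  (phenotypic %.2f)\n",
              s["r_g"], s["r_c"], s["r_e"], s["r_phenotypic"]))
  invisible(x)
}

#' Model-implied variance of height as a function of age
#'
#' Height is linear in the latent intercept and slope, so its variance is
#' quadratic in the slope loading: `V(a) = v_i + 2 f(a) c_is + f(a)^2 v_s`,
#' with the component covariances taken from the full latent covariance
#' (`total`) or its additive-genetic part (`genetic`, ACE fits only).
#'
#' @param fit a `growth_fit` or `ace_fit`.
#' @param age ages in years (vector), at or above the loading origin.
#' @param sex `"M"` or `"F"` (controls the piecewise cap).
#' @param component `"total"` or `"genetic"`.
#' @param include_resid add the wave residual variance (observed scale).
#' @return variances in cm^2.
#' @export
variance_parabola <- function(fit, age, sex = "M",
                              component = c("total", "genetic"),
                              include_resid = FALSE) {
  component <- match.arg(component)
  f <- piecewise_loading(age, sex, fit$rule)
  S <- if (component == "genetic") {
    if (is.null(fit$A)) stop("genetic component requires an ACE fit")
    fit$A
  } else if (!is.null(fit$A)) fit$A + fit$C + fit$E else fit$G
  v <- S[1, 1] + 2 * f * S[1, 2] + f^2 * S[2, 2]
  if (include_resid) v <- v + mean(fit$var_resid)
  v
}

#' Proportion of variance in height explained by a score, across age
#'
#' The variance the score accounts for at age `a` is
#' `s(a) = (beta_ig + f(a) beta_sg)^2 var(score)` from the score fit; the
#' curve divides it by the base model's variance parabola for the requested
#' component: `r2(a) = s(a) / V_base(a)`.  Because the score is built from
#' inherited genotypes its variance sits inside the additive-genetic part,
#' so the genetic curve (denominator `A` parabola) dominates the phenotypic
#' curve (denominator total parabola) at every age.
#'
#' @param base_fit ACE fit without score effects.
#' @param score_fit ACE fit with score effects under some constraint.
#' @param component `"phenotypic"` or `"genetic"`.
#' @param ages evaluation grid (default origin to 29 years).
#' @param sex sex whose piecewise cap defines the loading.
#' @param include_resid include the wave residual in the denominator
#'   (observed-scale convention).
#' @return object of class `r2_curve`: data.frame `curve` (`age`, `r2`),
#'   `apex_age`, `r2_max`, `model` (the score fit's constraint).
#' @export
r2_curves <- function(base_fit, score_fit,
                      component = c("phenotypic", "genetic"),
                      ages = NULL, sex = "M", include_resid = FALSE) {
  component <- match.arg(component)
  comp <- if (component == "genetic") "genetic" else "total"
  rule <- base_fit$rule
  if (is.null(ages)) ages <- seq(rule$origin, 29, by = 0.05)
  f <- piecewise_loading(ages, sex, rule)
  cf <- score_fit$coefficients
  big <- if ("beta_ig" %in% names(cf)) cf[["beta_ig"]] else 0
  bsg <- if ("beta_sg" %in% names(cf)) cf[["beta_sg"]] else 0
  vs <- score_fit$data$score_var
  s_a <- if (is.na(vs)) rep(0, length(f)) else (big + f * bsg)^2 * vs
  vb <- variance_parabola(base_fit, ages, sex, comp, include_resid)
  if (any(vb <= 0)) stop("base-model variance must be positive on the grid")
  r2 <- s_a / vb
  k <- which.max(r2)
  structure(list(curve = data.frame(age = ages, r2 = r2),
                 apex_age = ages[k], r2_max = r2[k],
                 component = component, model = score_fit$constraint),
            class = "r2_curve")
}

#' @export
print.r2_curve <- function(x, ...) {
  cat(sprintf("%s r2 curve (%s model): max %.3f at age %.2f\n",
              x$component, x$model, x$r2_max, x$apex_age))
  invisible(x)
}

#' Compare ACE variance components between sexes
#'
#' Male heights are first standardized per wave to the female wave mean and
#' variance; the ACE growth model is then fitted separately by sex and
#' jointly with the nine latent (co)variance parameters equated (means and
#' wave residuals stay sex-specific), and the two are compared by a
#' likelihood-ratio test with 9 degrees of freedom.
#'
#' @param phenos a `long_phenotypes` table.
#' @param ped a `pedigree_table`.
#' @param covariates optional covariate table.
#' @param rule a [loading_rule()].
#' @return list with `fit_male`, `fit_female`, `fit_joint`, `lrt`, `df`,
#'   `p`, and the per-wave `scaling` table.
#' @export
sex_specific_compare <- function(phenos, ped, covariates = NULL,
                                 rule = loading_rule()) {
  ph <- as.data.frame(phenos)
  tw <- ped[ped$role %in% c("twin1", "twin2"), ]
  ph <- ph[ph$person_id %in% tw$person_id & !is.na(ph$height), ]
  sex <- tw$sex[match(ph$person_id, tw$person_id)]
  scaling <- NULL
  for (w in unique(ph$wave)) {
    hm <- ph$height[ph$wave == w & sex == "M"]
    hf <- ph$height[ph$wave == w & sex == "F"]
    if (!length(hm) || !length(hf)) {
      message("wave ", w, " observed in one sex only; dropped from scaling")
      ph <- ph[!(ph$wave == w & sex == "M"), ]
      sex <- tw$sex[match(ph$person_id, tw$person_id)]
      next
    }
    sel <- ph$wave == w & sex == "M"
    ph$height[sel] <- (ph$height[sel] - mean(hm)) / sd(hm) * sd(hf) + mean(hf)
    scaling <- rbind(scaling, data.frame(wave = w, male_mean = mean(hm),
                                         male_sd = sd(hm), female_mean = mean(hf),
                                         female_sd = sd(hf)))
  }
  ph <- long_phenotypes(ph)
  ids_m <- tw$person_id[tw$sex == "M"]; ids_f <- tw$person_id[tw$sex == "F"]
  ped_m <- ped[ped$person_id %in% ids_m | ped$role %in% c("mother", "father"), ]
  fit_m <- fit_twin_ace(ph[ph$person_id %in% ids_m, ], ped, covariates,
                        rule = rule, se = FALSE)
  fit_f <- fit_twin_ace(ph[ph$person_id %in% ids_f, ], ped, covariates,
                        rule = rule, se = FALSE)
  fit_j <- fit_twin_ace(ph, ped, covariates, rule = rule,
                        resid_by_sex = TRUE, se = FALSE)
  lrt <- 2 * (fit_m$loglik + fit_f$loglik - fit_j$loglik)
  df <- 9L
  list(fit_male = fit_m, fit_female = fit_f, fit_joint = fit_j,
       lrt = lrt, df = df, p = pchisq(max(lrt, 0), df, lower.tail = FALSE),
       scaling = scaling)
}
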