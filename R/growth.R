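# Phenotypic piecewise-linear latent growth model: random intercept (height
# at the age origin) and random slope (growth per year, capped at a
# sex-specific adult age), fitted by full-information maximum likelihood
# over each person's observed waves.

#' Piecewise loading rule
#'
#' @param origin age (years) at which heights are centred; the intercept is
#'   height at this age.
#' @param cap_male,cap_female ages past which the slope no longer accrues.
#' @return list of class `loading_rule`.
#' @export
loading_rule <- function(origin = 10.75, cap_male = 18, cap_female = 16) {
  if (cap_male <= origin || cap_female <= origin) stop("caps must exceed the origin")
  structure(list(origin = origin, cap_male = cap_male, cap_female = cap_female),
            class = "loading_rule")
}

#' Slope loading at a given age
#'
#' `f(a) = min(a, cap_sex) - origin`; the intercept loading is always 1.
#'
#' @param age ages in years (vector).
#' @param sex `"M"`/`"F"` (recycled).
#' @param rule a [loading_rule()].
#' @return numeric loadings in years.
#' @export
piecewise_loading <- function(age, sex, rule = loading_rule()) {
  if (any(age < rule$origin - 1e-9)) stop("age below the loading origin")
  cap <- ifelse(sex == "M", rule$cap_male, rule$cap_female)
  pmin(age, cap) - rule$origin
}

# Assemble the flat per-observation structure consumed by the C++
# likelihoods.  `sex_of` maps person -> sex (from the pedigree); covariates
# enter the observation mean as person-constant fixed effects; a scalar
# predictor g contributes columns g and f*g (effects on intercept and slope).
prepare_growth_data <- function(phenos, ped, covariates = NULL, predictor = NULL,
                                rule = loading_rule(), persons = NULL) {
  ph <- as.data.frame(phenos)
  ph <- ph[!is.na(ph$height) & !is.na(ph$age), ]
  if (!is.null(persons)) ph <- ph[ph$person_id %in% persons, ]
  sex <- ped$sex[match(ph$person_id, ped$person_id)]
  if (anyNA(sex)) stop("phenotype rows with person_id absent from pedigree")
  ph <- ph[order(ph$person_id, ph$wave), ]
  sex <- ped$sex[match(ph$person_id, ped$person_id)]
  f <- piecewise_loading(ph$age, sex, rule)
  pid <- ph$person_id
  ids <- unique(pid)
  ptr <- c(0L, cumsum(as.integer(table(factor(pid, levels = ids)))))
  sexM <- as.numeric(sex == "M")
  both_sex <- length(unique(sex)) > 1L
  M <- cbind(`(mu_i)` = 1, `(mu_s)` = f)
  if (both_sex) M <- cbind(M, `(mu_i:sexM)` = sexM, `(mu_s:sexM)` = f * sexM)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cn <- setdiff(names(cv), "person_id")
    X <- as.matrix(cv[match(pid, cv$person_id), cn, drop = FALSE])
    if (anyNA(X)) stop("missing covariate values for phenotyped persons")
    colnames(X) <- cn
    M <- cbind(M, X)
  }
  g <- NULL
  if (!is.null(predictor)) {
    if (is.data.frame(predictor)) predictor <- setNames(predictor[[2]], predictor[[1]])
    g <- as.numeric(predictor[pid])
    if (anyNA(g)) stop("predictor missing for some phenotyped persons")
    M <- cbind(M, beta_i = g, beta_s = f * g)
  }
  M <- drop_collinear(M)
  wave_idx <- match(ph$wave, WAVES)
  list(y = ph$height, f = f, ptr = ptr, M = M, ids = ids,
       wave_idx = wave_idx, n_persons = length(ids), has_predictor = !is.null(predictor))
}

# Drop covariate columns that are linearly dependent on the rest of the
# mean design (e.g. a sex covariate when sex-specific means are present).
# Structural growth/predictor columns are never dropped.
drop_collinear <- function(M) {
  r_full <- qr(M)$rank
  if (r_full == ncol(M)) return(M)
  protected <- colnames(M) %in% c("(mu_i)", "(mu_s)", "(mu_i:sexM)",
                                  "(mu_s:sexM)", "beta_i", "beta_s",
                                  "beta_ig", "beta_sg")
  keep <- rep(TRUE, ncol(M))
  for (j in rev(which(!protected))) {
    sub <- M[, keep & seq_len(ncol(M)) != j, drop = FALSE]
    if (qr(sub)$rank == r_full) keep[j] <- FALSE
    if (sum(keep) == r_full) break
  }
  if (any(!keep))
    message("dropping collinear mean column(s): ",
            paste(colnames(M)[!keep], collapse = ", "))
  M[, keep, drop = FALSE]
}

# theta layout: [mean coefs p] [l1 l2 l3] [log sd resid (1 or 6)]
theta_to_parts <- function(theta, p, resid_by_wave) {
  nr <- if (resid_by_wave) length(WAVES) else 1L
  mean_coefs <- theta[seq_len(p)]
  l <- theta[p + 1:3]
  Lc <- matrix(c(exp(l[1]), l[2], 0, exp(l[3])), 2)
  G <- Lc %*% t(Lc)
  sig2 <- exp(2 * theta[p + 3 + seq_len(nr)])
  list(mean = mean_coefs, G = G, sig2 = sig2)
}

growth_negloglik <- function(theta, dat, resid_by_wave = FALSE) {
  pp <- theta_to_parts(theta, ncol(dat$M), resid_by_wave)
  mu <- as.numeric(dat$M %*% pp$mean)
  s2 <- if (length(pp$sig2) == 1L) rep(pp$sig2, length(dat$y)) else pp$sig2[dat$wave_idx]
  -lgm_loglik_cpp(dat$y, dat$f, dat$ptr, mu, pp$G, s2)
}

#' Full-information log-likelihood of the growth model
#'
#' Per person with observed slope loadings `f_1..f_k`, the model-implied
#' covariance is `Sigma_jk = var_i + (f_j+f_k) cov_is + f_j f_k var_s +
#' [j==k] var_resid`; the log-likelihood sums multivariate-normal
#' log-densities over persons (independent in this phenotypic model).
#'
#' @param params list with `mean` (coefficients matching the mean design),
#'   `var_i`, `var_s`, `cov_is`, `var_resid` (scalar, or one value per wave).
#' @param data structure from the internal data preparation, as stored in a
#'   [fit_growth()] result (`$data`).
#' @return log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, data) {
  G <- matrix(c(params$var_i, params$cov_is, params$cov_is, params$var_s), 2)
  mu <- as.numeric(data$M %*% params$mean)
  vr <- params$var_resid
  s2 <- if (length(vr) == 1L) rep(vr, length(data$y)) else vr[data$wave_idx]
  lgm_loglik_cpp(data$y, data$f, data$ptr, mu, G, s2)
}

growth_start <- function(dat) {
  p <- ncol(dat$M)
  b0 <- tryCatch(qr.coef(qr(dat$M), dat$y), error = function(e) rep(0, p))
  b0[is.na(b0)] <- 0
  r <- dat$y - as.numeric(dat$M %*% b0)
  # split the pooled residual variance across intercept, slope (whose
  # loading spans several years, hence the small share) and measurement
  v <- max(var(r), 1e-4)
  c(b0, 0.5 * log(0.8 * v), 0, 0.5 * log(0.02 * v), log(sqrt(0.2 * v)))
}

#' Fit the phenotypic latent growth model
#'
#' Maximizes the FIML likelihood by quasi-Newton (BFGS) from two-stage OLS
#' starting values, with the 2x2 random-effect covariance kept positive
#' semi-definite through a log-Cholesky parameterization.  With a predictor
#' (SNP dosage or genetic score), its effects on the intercept (`beta_i`)
#' and slope (`beta_s`) are estimated simultaneously with everything else.
#'
#' @param phenos a `long_phenotypes` table.
#' @param ped a `pedigree_table` (supplies sex for the piecewise caps).
#' @param covariates optional covariate table (`person_id` + numeric columns),
#'   entering the wave-level mean as fixed effects.
#' @param predictor optional per-person scalar (named vector or two-column
#'   data.frame) whose intercept and slope effects are estimated.
#' @param rule a [loading_rule()].
#' @param resid_by_wave estimate one residual variance per wave instead of a
#'   single shared value.
#' @param se compute standard errors from the numerical Hessian.
#' @param persons optional subset of person ids to fit.
#' @return object of class `growth_fit` with elements `coefficients`
#'   (mean-structure estimates), `G` (random-effect covariance), `var_resid`,
#'   `loglik`, `se` (named vector, when requested), `tests` (per-predictor
#'   Wald tests), `convergence`, `data`.
#' @export
fit_growth <- function(phenos, ped, covariates = NULL, predictor = NULL,
                       rule = loading_rule(), resid_by_wave = FALSE,
                       se = TRUE, persons = NULL) {
  dat <- prepare_growth_data(phenos, ped, covariates, predictor, rule, persons)
  p <- ncol(dat$M)
  th0 <- growth_start(dat)
  if (resid_by_wave) th0 <- c(th0[seq_len(p + 3)], rep(th0[p + 4], length(WAVES)))
  opt <- optim(th0, growth_negloglik, dat = dat, resid_by_wave = resid_by_wave,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("growth model optimizer did not report clean convergence (code ",
            opt$convergence, ")")
  th <- opt$par
  pp <- theta_to_parts(th, p, resid_by_wave)
  names(pp$mean) <- colnames(dat$M)
  fit <- list(coefficients = pp$mean, G = pp$G,
              var_i = pp$G[1, 1], var_s = pp$G[2, 2], cov_is = pp$G[1, 2],
              var_resid = pp$sig2, loglik = -opt$value,
              convergence = opt$convergence, n_persons = dat$n_persons,
              n_obs = length(dat$y), rule = rule, resid_by_wave = resid_by_wave,
              theta = th, data = dat)
  if (se) {
    H <- tryCatch(optimHess(th, growth_negloglik, dat = dat,
                            resid_by_wave = resid_by_wave),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V)) {
      fit$vcov_theta <- V
      fit$se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
      names(fit$se) <- colnames(dat$M)
      if (dat$has_predictor) {
        est <- pp$mean[c("beta_i", "beta_s")]
        ses <- fit$se[c("beta_i", "beta_s")]
        tt <- est / ses
        df <- dat$n_persons - p
        fit$tests <- data.frame(effect = c("beta_i", "beta_s"),
                                estimate = est, se = ses, t = tt, df = df,
                                p_two = 2 * pt(-abs(tt), df),
                                row.names = NULL)
      }
    }
  }
  class(fit) <- "growth_fit"
  fit
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Piecewise-linear latent growth model (FIML)\n")
  cat(sprintf("  persons %d, observations %d, logLik %.2f\n",
              x$n_persons, x$n_obs, x$loglik))
  cat(sprintf("  var_i %.2f  var_s %.3f  cov_is %.3f  (corr %.2f)  resid var %s\n",
              x$var_i, x$var_s, x$cov_is, x$cov_is / sqrt(x$var_i * x$var_s),
              paste(sprintf("%.2f", x$var_resid), collapse = "/")))
  invisible(x)
}

#' Test a predictor's intercept/slope effects against a fitted base model
#'
#' Conditional on the base fit's variance parameters, the maximum-likelihood
#' fixed effects are generalized least squares with the model-implied
#' per-person covariance; this adds the predictor's intercept (`g`) and
#' slope (`f*g`) columns to the mean design and re-estimates all fixed
#' effects in closed form, with Wald t tests.
#'
#' @param fit a [fit_growth()] result without a predictor.
#' @param predictor named per-person scalar (or two-column data.frame).
#' @return data.frame with rows `beta_i`, `beta_s`: estimate, se, t, df,
#'   `p_two`.
#' @export
growth_predictor_test <- function(fit, predictor) {
  dat <- fit$data
  if (dat$has_predictor) stop("base fit must not already contain a predictor")
  if (is.data.frame(predictor)) predictor <- setNames(predictor[[2]], predictor[[1]])
  gp <- as.numeric(predictor[rep(dat$ids, diff(dat$ptr))])
  if (anyNA(gp)) stop("predictor missing for some fitted persons")
  X <- cbind(dat$M, beta_i = gp, beta_s = dat$f * gp)
  p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  s2 <- if (length(fit$var_resid) == 1L) rep(fit$var_resid, length(dat$y))
        else fit$var_resid[dat$wave_idx]
  for (i in seq_len(dat$n_persons)) {
    a <- dat$ptr[i] + 1L; b <- dat$ptr[i + 1L]
    Z <- cbind(1, dat$f[a:b])
    S <- Z %*% fit$G %*% t(Z) + diag(s2[a:b], b - a + 1L)
    L <- chol(S)
    Wx <- backsolve(L, X[a:b, , drop = FALSE], transpose = TRUE)
    Wy <- backsolve(L, dat$y[a:b], transpose = TRUE)
    XtVX <- XtVX + crossprod(Wx); XtVy <- XtVy + crossprod(Wx, Wy)
  }
  Vb <- solve(XtVX)
  beta <- as.numeric(Vb %*% XtVy)
  names(beta) <- colnames(X)
  idx <- match(c("beta_i", "beta_s"), colnames(X))
  se <- sqrt(diag(Vb)[idx])
  tt <- beta[idx] / se
  df <- dat$n_persons - p
  data.frame(effect = c("beta_i", "beta_s"), estimate = beta[idx], se = se,
             t = tt, df = df, p_two = 2 * pt(-abs(tt), df), row.names = NULL)
}

#' One-tailed p-value in an expected direction
#'
#' `p_one = p_two / 2` when the estimate's sign matches the expected sign,
#' `1 - p_two / 2` otherwise.
#'
#' @param estimate estimated effect(s).
#' @param p_two two-tailed p-value(s).
#' @param expected_sign expected direction(s) (+1/-1, e.g. sign of the
#'   meta-analytic weight).
#' @return one-tailed p-value(s).
#' @export
one_tailed_p <- function(estimate, p_two, expected_sign) {
  agree <- sign(estimate) == sign(expected_sign)
  ifelse(agree, p_two / 2, 1 - p_two / 2)
}
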