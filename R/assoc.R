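# Adult-height association with family-clustered generalized least squares:
# eligibility filtering at the sex-specific growth caps, a null variance-
# component fit over expected-relationship family blocks, per-SNP GLS with
# one-tailed tests in the meta-analytic direction, and multiplicity/
# direction-concordance summaries.

#' Select persons with attained adult height
#'
#' Adult height is the last observed measurement.  Twins whose last
#' assessment precedes the sex-specific cap (18 male, 16 female) are
#' excluded; parents are always eligible.  Persons with no height at any
#' wave are dropped.
#'
#' @param ped a `pedigree_table`.
#' @param phenos a `long_phenotypes` table.
#' @param rule a [loading_rule()] (supplies the caps).
#' @return data.frame with `person_id`, `family_id`, `role`, `sex`,
#'   `last_age`, `adult_height` for eligible persons.
#' @export
adult_height_filter <- function(ped, phenos, rule = loading_rule()) {
  ph <- as.data.frame(phenos)
  ph <- ph[!is.na(ph$height) & !is.na(ph$age), ]
  n_noht <- sum(!ped$person_id %in% ph$person_id)
  if (n_noht) message(n_noht, " person(s) without any height measurement excluded")
  ph <- ph[order(ph$person_id, ph$wave), ]
  last <- ph[!duplicated(ph$person_id, fromLast = TRUE), ]
  out <- data.frame(person_id = last$person_id,
                    family_id = ped$family_id[match(last$person_id, ped$person_id)],
                    role = ped$role[match(last$person_id, ped$person_id)],
                    sex = ped$sex[match(last$person_id, ped$person_id)],
                    last_age = last$age, adult_height = last$height,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$role), ]
  cap <- ifelse(out$sex == "M", rule$cap_male, rule$cap_female)
  is_twin <- out$role %in% c("twin1", "twin2")
  out[!(is_twin & out$last_age < cap), , drop = FALSE]
}

# Expected-relationship coefficient blocks per family: MZ co-twins 1,
# DZ co-twins 0.5, parent-offspring 0.5, spouses 0, diagonal 1.
family_blocks <- function(ped, persons) {
  pp <- ped[match(persons, ped$person_id), ]
  fams <- unique(pp$family_id)
  lapply(fams, function(fam) {
    m <- pp[pp$family_id == fam, ]
    k <- nrow(m)
    K <- diag(k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      ri <- m$role[i]; rj <- m$role[j]
      tw <- c("twin1", "twin2"); pa <- c("mother", "father")
      K[i, j] <- if (all(c(ri, rj) %in% tw)) {
        if (identical(m$zygosity[i], "MZ")) 1 else 0.5
      } else if (all(c(ri, rj) %in% pa)) 0 else 0.5
    }
    list(family_id = fam, persons = m$person_id, K = K)
  })
}

vc_loglik <- function(lpar, blocks, y, X) {
  sg2 <- exp(lpar[1]); se2 <- exp(lpar[2])
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  ldet <- 0; parts <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    ii <- blocks[[b]]$idx
    V <- sg2 * blocks[[b]]$K + se2 * diag(length(ii))
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    Xi <- X[ii, , drop = FALSE]; yi <- y[ii]
    Wx <- backsolve(L, Xi, transpose = TRUE)
    Wy <- backsolve(L, yi, transpose = TRUE)
    XtVX <- XtVX + crossprod(Wx); XtVy <- XtVy + crossprod(Wx, Wy)
    ldet <- ldet + 2 * sum(log(diag(L)))
    parts[[b]] <- list(Wx = Wx, Wy = Wy)
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- 0
  for (b in seq_along(blocks)) {
    r <- parts[[b]]$Wy - parts[[b]]$Wx %*% beta
    rss <- rss + sum(r^2)
  }
  list(ll = -0.5 * (length(y) * log(2 * pi) + ldet + rss),
       beta = as.numeric(beta))
}

#' Fit the null (no-SNP) family variance components
#'
#' Maximum likelihood for `V = sigma2_g K + sigma2_e I` within family
#' blocks, with covariate fixed effects profiled out; `K` holds expected
#' relationship coefficients.
#'
#' @param adult output of [adult_height_filter()].
#' @param ped a `pedigree_table`.
#' @param covariates optional covariate table.
#' @return list of class `vc_fit`: `sigma2_g`, `sigma2_e`, `beta`,
#'   `loglik`, `blocks` (with person indices), `X`, `y`, `persons`.
#' @export
fit_null_vc <- function(adult, ped, covariates = NULL) {
  persons <- adult$person_id
  y <- adult$adult_height
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cn <- setdiff(names(cv), "person_id")
    Xc <- as.matrix(cv[match(persons, cv$person_id), cn, drop = FALSE])
    if (anyNA(Xc)) stop("missing covariates for eligible persons")
    X <- cbind(X, Xc)
  } else {
    X <- cbind(X, sexM = as.numeric(adult$sex == "M"))
  }
  blocks <- family_blocks(ped, persons)
  for (b in seq_along(blocks))
    blocks[[b]]$idx <- match(blocks[[b]]$persons, persons)
  if (all(vapply(blocks, function(b) length(b$idx), integer(1)) == 1L))
    stop("only singleton families: sigma2_g is not identified")
  v0 <- var(resid(lm.fit(X, y)))
  opt <- optim(log(c(0.5 * v0, 0.5 * v0)),
               function(lp) -vc_loglik(lp, blocks, y, X)$ll,
               method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-10))
  res <- vc_loglik(opt$par, blocks, y, X)
  structure(list(sigma2_g = exp(opt$par[1]), sigma2_e = exp(opt$par[2]),
                 beta = res$beta, loglik = res$ll, blocks = blocks,
                 X = X, y = y, persons = persons,
                 convergence = opt$convergence),
            class = "vc_fit")
}

# Whiten covariates and outcome once so that every predictor reduces to OLS
# on the transformed data.
gls_context <- function(vc) {
  n <- length(vc$y)
  Wy <- numeric(n); Wx <- matrix(0, n, ncol(vc$X))
  Wmap <- vector("list", length(vc$blocks))
  row0 <- 0L
  for (b in seq_along(vc$blocks)) {
    blk <- vc$blocks[[b]]
    ii <- blk$idx
    V <- vc$sigma2_g * blk$K + vc$sigma2_e * diag(length(ii))
    L <- chol(V)
    rows <- row0 + seq_along(ii)
    Wy[rows] <- backsolve(L, vc$y[ii], transpose = TRUE)
    Wx[rows, ] <- backsolve(L, vc$X[ii, , drop = FALSE], transpose = TRUE)
    Wmap[[b]] <- list(rows = rows, idx = ii, L = L)
    row0 <- row0 + length(ii)
  }
  list(Wy = Wy, Wx = Wx, map = Wmap, persons = vc$persons)
}

#' Family-clustered GLS association of one predictor
#'
#' Estimates the predictor's effect on adult height under the fixed,
#' null-fitted family covariance; reports the GLS estimate, SE, two-tailed
#' and (when an expected direction is supplied) one-tailed p-value, and the
#' variance explained relative to the covariate-only model.
#'
#' @param predictor named per-person vector (dosage or score).
#' @param vc a [fit_null_vc()] result.
#' @param expected_sign optional expected direction of effect (+1/-1), e.g.
#'   the sign of the meta-analytic weight.
#' @param ctx optional pre-computed whitening context (for scans).
#' @return one-row data.frame: `beta`, `se`, `t`, `df`, `p_two`, `p_one`,
#'   `r2`.
#' @export
gls_assoc <- function(predictor, vc, expected_sign = NA, ctx = NULL) {
  if (is.null(ctx)) ctx <- gls_context(vc)
  g <- as.numeric(predictor[ctx$persons])
  if (anyNA(g)) stop("predictor missing for eligible persons")
  if (sd(g) == 0) stop("constant predictor")
  Wg <- numeric(length(g))
  for (m in ctx$map) Wg[m$rows] <- backsolve(m$L, g[m$idx], transpose = TRUE)
  Xf <- cbind(ctx$Wx, g = Wg)
  fit <- lm.fit(Xf, ctx$Wy)
  r <- fit$residuals
  rss1 <- sum(r^2)
  rss0 <- sum(lm.fit(ctx$Wx, ctx$Wy)$residuals^2)
  df <- length(ctx$Wy) - ncol(Xf)
  XtXi <- chol2inv(chol(crossprod(Xf)))
  s2 <- rss1 / df
  beta <- unname(coef(fit)["g"])
  se <- sqrt(s2 * XtXi[ncol(Xf), ncol(Xf)])
  tt <- beta / se
  p2 <- 2 * pt(-abs(tt), df)
  p1 <- if (is.na(expected_sign)) NA_real_ else one_tailed_p(beta, p2, expected_sign)
  data.frame(beta = beta, se = se, t = tt, df = df, p_two = p2, p_one = p1,
             r2 = 1 - rss1 / rss0)
}

#' Per-SNP GLS association scan against a weight table
#'
#' Each weight-table SNP is aligned to its effect allele (flipping reversed
#' markers) and tested by [gls_assoc()] with the one-tailed alternative in
#' the meta-analytic direction.
#'
#' @param geno a post-QC `genotype_set`.
#' @param weights a `weight_table`.
#' @param vc a [fit_null_vc()] result.
#' @param alpha significance level for the summary flags.
#' @return data.frame (`assoc_table`): per SNP `beta`, `se`, `t`, `p_two`,
#'   `p_one`, `direction_concordant`, `nominal_sig`, `bonferroni_sig`.
#' @export
assoc_scan <- function(geno, weights, vc, alpha = 0.05) {
  weights <- weight_table(weights)
  ctx <- gls_context(vc)
  mk <- geno$markers
  rows <- vector("list", nrow(weights))
  for (k in seq_len(nrow(weights))) {
    j <- match(weights$snp_id[k], mk$snp_id)
    if (is.na(j)) next
    d <- geno$dosages[, j]
    if (weights$effect_allele[k] == mk$other_allele[j]) d <- 2 - d
    else if (weights$effect_allele[k] != mk$effect_allele[j]) next
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    if (sd(d[ctx$persons], na.rm = TRUE) == 0) next
    row <- tryCatch(gls_assoc(d, vc, sign(weights$beta[k]), ctx),
                    error = function(e) NULL)
    if (is.null(row)) next
    row$snp_id <- weights$snp_id[k]
    row$weight_beta <- weights$beta[k]
    rows[[k]] <- row
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  tab$direction_concordant <- sign(tab$beta) == sign(tab$weight_beta)
  tab$nominal_sig <- tab$p_one < alpha
  tab$bonferroni_sig <- tab$p_one < alpha / m
  tab[c("snp_id", "beta", "se", "t", "df", "p_two", "p_one", "weight_beta",
        "direction_concordant", "nominal_sig", "bonferroni_sig")]
}

#' Multiple-testing summary and QQ data
#'
#' @param assoc an [assoc_scan()] table (or any table with a `p_one`
#'   column and concordance flags).
#' @param alpha family-wise significance level.
#' @return list with `m`, `bonferroni_threshold`, `n_bonferroni`,
#'   `n_nominal`, `n_discordant`, and `qq` (expected/observed -log10 p).
#' @export
multiplicity_summary <- function(assoc, alpha = 0.05) {
  stopifnot(nrow(assoc) >= 1L)
  p <- assoc$p_one
  m <- length(p)
  thr <- alpha / m
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sort(p)))
  list(m = m, bonferroni_threshold = thr,
       n_bonferroni = sum(p < thr), n_nominal = sum(p < alpha),
       n_discordant = if ("direction_concordant" %in% names(assoc))
         sum(!assoc$direction_concordant) else NA_integer_,
       qq = qq)
}

#' Exact binomial sign test for direction concordance
#'
#' Lower-tail exact probability that at most `n_opposite` of `n_total`
#' direction-independent SNPs land opposite to the meta-analytic direction,
#' under a fair coin.
#'
#' @param n_opposite number of discordant effects.
#' @param n_total number of effects compared.
#' @return one-sided exact p-value `P(X <= n_opposite | n_total, 1/2)`.
#' @export
binomial_sign_test <- function(n_opposite, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_opposite < 0 || n_opposite > n_total) stop("n_opposite out of range")
  pbinom(n_opposite, n_total, 0.5)
}
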