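# Pubertal-age construction: per sex and early wave (11, 14), height is
# regressed on age and puberty score (plus a menarche indicator for girls at
# the age-11 wave); the fitted linear composite, rescaled to the moments of
# chronological age, replaces chronological age at those waves.

#' Fit one pubertal-age calibration model
#'
#' Ordinary least squares of height on age and puberty score and, for
#' females at the age-11 wave, a menarche indicator.  Constant predictors
#' are dropped (collinearity-safe).
#'
#' @param phenos a `long_phenotypes` table.
#' @param ped a `pedigree_table` (supplies sex).
#' @param sex `"M"` or `"F"`.
#' @param wave 11 or 14.
#' @return list with `sex`, `wave`, `coefs` (named weights), `r2`,
#'   `age_mean`, `age_sd` (chronological-age moments of the fitted subset),
#'   `n`.
#' @export
fit_puberty_model <- function(phenos, ped, sex, wave) {
  stopifnot(wave %in% c(11L, 14L))
  ph <- as.data.frame(phenos)
  psex <- ped$sex[match(ph$person_id, ped$person_id)]
  sel <- ph$wave == wave & psex == sex & !is.na(ph$height) & !is.na(ph$age)
  d <- ph[sel, ]
  if (!any(!is.na(d$puberty))) stop("no puberty scores for ", sex, " at wave ", wave)
  use_men <- sex == "F" && wave == 11L
  d$men <- if (use_men) ifelse(is.na(d$menarche), 0L, d$menarche) else NULL
  d <- d[!is.na(d$puberty), ]
  preds <- c("age", "puberty", if (use_men) "men")
  keep <- vapply(preds, function(v) length(unique(d[[v]])) > 1L, logical(1))
  preds <- preds[keep]
  if (!length(preds)) stop("all predictors constant for ", sex, " wave ", wave)
  fml <- stats::reformulate(preds, response = "height")
  fit <- lm(fml, data = d)
  cf <- coef(fit)[preds]
  cf[is.na(cf)] <- 0
  list(sex = sex, wave = as.integer(wave), coefs = cf,
       r2 = summary(fit)$r.squared,
       age_mean = mean(d$age), age_sd = sd(d$age), n = nrow(d))
}

#' Fit the full pubertal-age model (both sexes, waves 11 and 14)
#'
#' @inheritParams fit_puberty_model
#' @return list of class `puberty_model` keyed `"M_11"`, `"M_14"`,
#'   `"F_11"`, `"F_14"`.
#' @export
puberty_model <- function(phenos, ped) {
  entries <- list()
  for (s in c("M", "F")) for (w in c(11L, 14L))
    entries[[paste(s, w, sep = "_")]] <- fit_puberty_model(phenos, ped, s, w)
  structure(entries, class = "puberty_model")
}

#' Pubertal age for a set of phenotype rows
#'
#' Applies the fitted weights to each row's predictors and affinely rescales
#' the composite, per sex and wave, to the mean and SD of chronological age
#' in those rows.  Rows with a missing puberty score keep their
#' chronological age and are flagged.
#'
#' @param model a [puberty_model()].
#' @param phenos rows to adjust (a `long_phenotypes` table or data.frame).
#' @param ped a `pedigree_table`.
#' @return data.frame: the input rows plus `pubertal_age` and
#'   `pubertal_age_imputed` (TRUE where chronological age was retained).
#' @export
pubertal_age <- function(model, phenos, ped) {
  ph <- as.data.frame(phenos)
  psex <- ped$sex[match(ph$person_id, ped$person_id)]
  ph$pubertal_age <- ph$age
  ph$pubertal_age_imputed <- FALSE
  for (s in c("M", "F")) for (w in c(11L, 14L)) {
    m <- model[[paste(s, w, sep = "_")]]
    if (is.null(m)) next
    sel <- which(ph$wave == w & psex == s & !is.na(ph$age))
    if (!length(sel)) next
    d <- ph[sel, ]
    z <- rep(0, nrow(d))
    if ("age" %in% names(m$coefs)) z <- z + m$coefs[["age"]] * d$age
    if ("puberty" %in% names(m$coefs)) z <- z + m$coefs[["puberty"]] * d$puberty
    if ("men" %in% names(m$coefs))
      z <- z + m$coefs[["men"]] * ifelse(is.na(d$menarche), 0, d$menarche)
    ok <- !is.na(z) & !is.na(d$puberty)
    if (sum(ok) >= 2L && sd(z[ok]) > 0) {
      adj <- (z[ok] - mean(z[ok])) / sd(z[ok]) * sd(d$age[ok]) + mean(d$age[ok])
      ph$pubertal_age[sel[ok]] <- adj
    }
    ph$pubertal_age_imputed[sel[!ok]] <- TRUE
  }
  ph
}

#' Replace chronological by pubertal age at the early waves
#'
#' Waves 17 and later pass through unchanged.  Persons whose adjusted ages
#' would break within-person age monotonicity revert to chronological age
#' (flagged), so the result remains a valid phenotype table.
#'
#' @inheritParams pubertal_age
#' @param rule a [loading_rule()]; adjusted ages are floored at its origin
#'   so downstream loadings stay defined.
#' @return a `long_phenotypes` table with adjusted ages and the
#'   `pubertal_age_imputed` flag column.
#' @export
adjust_phenotype_ages <- function(model, phenos, ped, rule = loading_rule()) {
  adj <- pubertal_age(model, phenos, ped)
  adj$age <- pmax(adj$pubertal_age, rule$origin)
  adj$pubertal_age <- NULL
  ord <- order(adj$person_id, adj$wave)
  a <- adj[ord, ]
  bad <- unlist(tapply(a$age, a$person_id, function(x) any(diff(x[!is.na(x)]) <= 0)))
  bad_ids <- names(bad)[bad]
  if (length(bad_ids)) {
    orig <- as.data.frame(phenos)
    sel <- adj$person_id %in% bad_ids
    adj$age[sel] <- orig$age[match(paste(adj$person_id, adj$wave)[sel],
                                   paste(orig$person_id, orig$wave))]
    adj$pubertal_age_imputed[sel] <- TRUE
    message(length(bad_ids), " person(s) reverted to chronological age to keep ages increasing")
  }
  long_phenotypes(adj)
}
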