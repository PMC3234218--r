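# Marker and sample quality control: Hardy-Weinberg exact test on founders,
# Mendelian-consistency screens on trios, call-rate/MAF/sex/batch filters
# applied in a fixed order with first-failing-reason reporting.

#' QC thresholds
#'
#' Defaults: markers fail with more than 1 duplicate-sample mismatch, call
#' rate below 99\%, minor-allele frequency below 1\%, more than 2 Mendelian
#' inconsistencies across families, Hardy-Weinberg exact p below 1e-7,
#' autosomal sex-association p below 1e-7, batch-effect p below 1e-7, or
#' (imputed markers) imputation r-squared below 0.5.  Samples fail with more
#' than 5000 no-calls or heterozygosity more than 4 SD from the cohort mean.
#'
#' @param call_rate_min,maf_min,hwe_p_min,mendel_max,sex_assoc_p_min
#'   marker thresholds (see description).
#' @param batch_p_min,dup_mismatch_max,impute_r2_min marker thresholds.
#' @param sample_nocall_max,het_outlier_sd sample thresholds.
#' @param hard_call_tol dosages farther than this from an integer are
#'   treated as missing when hard calls are needed (HWE, Mendel, duplicates).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.99, maf_min = 0.01,
                          hwe_p_min = 1e-7, mendel_max = 2,
                          sex_assoc_p_min = 1e-7, batch_p_min = 1e-7,
                          dup_mismatch_max = 1, sample_nocall_max = 5000,
                          het_outlier_sd = 4, impute_r2_min = 0.5,
                          hard_call_tol = 0.2) {
  th <- as.list(environment())
  stopifnot(th$call_rate_min > 0, th$call_rate_min <= 1,
            th$maf_min >= 0, th$maf_min < 1,
            th$hwe_p_min > 0, th$hwe_p_min < 1,
            th$mendel_max >= 0, th$dup_mismatch_max >= 0,
            th$sample_nocall_max >= 0, th$impute_r2_min >= 0,
            th$impute_r2_min <= 1)
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test: conditional on the observed allele counts, sums the
#' probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (founders only, by convention).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  na <- 2 * n_aa + n_Aa            # allele-a count
  if (na == 0 || na == 2 * n) return(1)
  rare <- min(na, 2 * n - na)
  hets <- seq.int(rare %% 2, rare, by = 2)
  # log P(n_het = j | n, allele counts), Levene-Haldane distribution
  logp <- function(j) {
    hom_r <- (rare - j) / 2
    hom_c <- n - j - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(j + 1) - lgamma(hom_c + 1) +
      j * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }
  lp <- vapply(hets, logp, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Round dosages to hard calls; entries farther than tol from an integer
# become missing.
hard_calls <- function(dosages, tol = 0.2) {
  hc <- round(dosages)
  hc[abs(dosages - hc) > tol] <- NA
  hc[hc < 0 | hc > 2] <- NA
  hc
}

#' Count Mendelian inconsistencies per marker
#'
#' Dosages are hard-called; for each twin family the offspring genotype is
#' checked against the biallelic transmission rules (a child must receive
#' one allele from each parent).  MZ pairs are counted as a single
#' offspring, DZ twins as two.  Transmissions with a missing parent are
#' skipped.
#'
#' @param geno a `genotype_set`.
#' @param ped a `pedigree_table`.
#' @param tol hard-call tolerance (see [qc_thresholds()]).
#' @return integer vector of inconsistency counts, one per marker.
#' @export
mendel_check <- function(geno, ped, tol = 0.2) {
  hc <- hard_calls(geno$dosages, tol)
  ids <- rownames(hc)
  fams <- unique(ped$family_id)
  role_id <- function(role) {
    out <- rep(NA_character_, length(fams))
    sel <- ped$role == role
    out[match(ped$family_id[sel], fams)] <- ped$person_id[sel]
    out
  }
  fa <- role_id("father"); mo <- role_id("mother")
  t1 <- role_id("twin1"); t2 <- role_id("twin2")
  zy <- ped$zygosity[match(t1, ped$person_id)]
  get_rows <- function(idv) {
    out <- matrix(NA_real_, length(fams), ncol(hc))
    ok <- !is.na(idv) & idv %in% ids
    out[ok, ] <- hc[idv[ok], , drop = FALSE]
    out
  }
  F_ <- get_rows(fa); M_ <- get_rows(mo)
  C1 <- get_rows(t1); C2 <- get_rows(t2)
  # MZ pairs contribute one offspring: prefer twin1's calls, fall back to twin2
  mz <- !is.na(zy) & zy == "MZ"
  tmp <- C1[mz, , drop = FALSE]
  alt <- C2[mz, , drop = FALSE]
  tmp[is.na(tmp)] <- alt[is.na(tmp)]
  C1[mz, ] <- tmp
  C2[mz, ] <- NA_real_
  incomp <- function(C) {
    lo <- (F_ == 2) + (M_ == 2)
    hi <- (F_ >= 1) + (M_ >= 1)
    bad <- !is.na(C) & !is.na(lo) & (C < lo | C > hi)
    colSums(bad, na.rm = TRUE)
  }
  counts <- incomp(C1) + incomp(C2)
  setNames(as.integer(counts), geno$markers$snp_id)
}

# Rao score test of a binary outcome on a single predictor (logistic null
# with intercept only); used for the autosomal sex-association screen.
logistic_score_test <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2L || length(unique(x)) < 2L) return(1)
  pbar <- mean(y)
  U <- sum((y - pbar) * x)
  V <- pbar * (1 - pbar) * sum((x - mean(x))^2)
  if (V <= 0) return(1)
  pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

# One-way ANOVA F test of dosage means across batch groups.
batch_anova_p <- function(x, batch) {
  ok <- !is.na(x) & !is.na(batch)
  if (length(unique(batch[ok])) < 2L || length(unique(x[ok])) < 2L) return(1)
  a <- stats::anova(lm(x[ok] ~ factor(batch[ok])))
  a$`Pr(>F)`[1]
}

#' Apply marker QC filters
#'
#' Each marker is tested against the screens in a fixed order (duplicate
#' mismatches, call rate, MAF, Mendelian inconsistencies, Hardy-Weinberg on
#' founders, autosomal sex association, batch effect, imputation quality)
#' and fails on the first triggered criterion.
#'
#' @param geno a `genotype_set`.
#' @param ped a `pedigree_table` (identifies founders and trios).
#' @param thresholds a [qc_thresholds()].
#' @param sample_batch optional named vector mapping person ids to batch
#'   labels for the batch-effect screen.
#' @param duplicates optional two-column data.frame of duplicate-sample id
#'   pairs for the concordance screen.
#' @return list with `report` (per-marker `snp_id`, `pass`, `reason`),
#'   `counts` (failures per reason), and `geno` (the filtered set).
#' @export
apply_marker_filters <- function(geno, ped, thresholds = qc_thresholds(),
                                 sample_batch = NULL, duplicates = NULL) {
  th <- thresholds
  dos <- geno$dosages
  ns <- ncol(dos)
  hc <- hard_calls(dos, th$hard_call_tol)
  founders <- intersect(ped$person_id[ped$role %in% c("mother", "father")],
                        rownames(dos))
  reason <- rep(NA_character_, ns)

  if (!is.null(duplicates) && nrow(duplicates)) {
    i1 <- match(as.character(duplicates[[1]]), rownames(hc))
    i2 <- match(as.character(duplicates[[2]]), rownames(hc))
    ok <- !is.na(i1) & !is.na(i2)
    if (any(ok)) {
      mism <- colSums(hc[i1[ok], , drop = FALSE] != hc[i2[ok], , drop = FALSE],
                      na.rm = TRUE)
      reason[is.na(reason) & mism > th$dup_mismatch_max] <- "dup_mismatch"
    }
  }
  call_rate <- colMeans(!is.na(dos))
  reason[is.na(reason) & call_rate < th$call_rate_min] <- "call_rate"
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  reason[is.na(reason) & maf < th$maf_min] <- "maf"
  mend <- mendel_check(geno, ped, th$hard_call_tol)
  reason[is.na(reason) & mend > th$mendel_max] <- "mendel"
  if (length(founders)) {
    hwe_p <- vapply(seq_len(ns), function(j) {
      g <- hc[founders, j]
      tab <- c(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 0, na.rm = TRUE))
      if (sum(tab) == 0) return(1)
      hwe_exact_test(tab[1], tab[2], tab[3])
    }, numeric(1))
    reason[is.na(reason) & hwe_p < th$hwe_p_min] <- "hwe"
  }
  sexM <- as.integer(ped$sex[match(rownames(dos), ped$person_id)] == "M")
  sex_p <- vapply(seq_len(ns), function(j) logistic_score_test(sexM, dos[, j]),
                  numeric(1))
  reason[is.na(reason) & sex_p < th$sex_assoc_p_min] <- "sex_assoc"
  if (!is.null(sample_batch)) {
    bt <- sample_batch[rownames(dos)]
    bat_p <- vapply(seq_len(ns), function(j) batch_anova_p(dos[, j], bt),
                    numeric(1))
    reason[is.na(reason) & bat_p < th$batch_p_min] <- "batch"
  }
  r2 <- geno$markers$imputation_r2
  reason[is.na(reason) & !is.na(r2) & r2 < th$impute_r2_min] <- "imputation_r2"

  pass <- is.na(reason)
  report <- data.frame(snp_id = geno$markers$snp_id, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  counts <- table(factor(reason[!pass]))
  filtered <- genotype_set(geno$markers[pass, , drop = FALSE],
                           dos[, pass, drop = FALSE])
  list(report = report, counts = counts, geno = filtered)
}

#' Apply sample QC filters
#'
#' Samples fail with more no-calls than allowed or with heterozygosity
#' (proportion of hard-called heterozygous markers) farther than
#' `het_outlier_sd` SDs from the cohort mean.
#'
#' @inheritParams apply_marker_filters
#' @return list with `report` (per-sample `person_id`, `pass`, `reason`)
#'   and `geno` (the filtered set).
#' @export
apply_sample_filters <- function(geno, thresholds = qc_thresholds()) {
  th <- thresholds
  dos <- geno$dosages
  nocall <- rowSums(is.na(dos))
  hc <- hard_calls(dos, th$hard_call_tol)
  het <- rowMeans(hc == 1, na.rm = TRUE)
  z <- if (sd(het, na.rm = TRUE) > 0) (het - mean(het, na.rm = TRUE)) / sd(het, na.rm = TRUE) else het * 0
  reason <- rep(NA_character_, nrow(dos))
  reason[nocall > th$sample_nocall_max] <- "no_calls"
  reason[is.na(reason) & abs(z) > th$het_outlier_sd] <- "heterozygosity"
  pass <- is.na(reason)
  report <- data.frame(person_id = rownames(dos), pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  filtered <- genotype_set(geno$markers, dos[pass, , drop = FALSE])
  list(report = report, geno = filtered)
}

#' Compute the weighted genetic score
#'
#' `score_p = sum_j beta_j * dosage_pj`, dosages counted on each weight's
#' effect allele.  Markers whose allele labels are reversed relative to the
#' weight table are flipped (`dosage -> 2 - dosage`); markers matching
#' neither orientation are excluded with a warning; weight-table SNPs absent
#' from the genotype set are reported; missing dosages are replaced by twice
#' the sample allele frequency.
#'
#' @param geno a `genotype_set` (post-QC).
#' @param weights a `weight_table`.
#' @return list of class `score_result` with `score` (named per-person
#'   vector, cm scale) and `alignment` (per-SNP action report).
#' @export
compute_score <- function(geno, weights) {
  weights <- weight_table(weights)
  mk <- geno$markers
  idx <- match(weights$snp_id, mk$snp_id)
  action <- rep("absent", nrow(weights))
  score <- rep(0, nrow(geno$dosages))
  names(score) <- rownames(geno$dosages)
  n_imputed <- integer(nrow(weights))
  for (k in seq_len(nrow(weights))) {
    j <- idx[k]
    if (is.na(j)) next
    d <- geno$dosages[, j]
    if (weights$effect_allele[k] == mk$effect_allele[j]) {
      action[k] <- "as_is"
    } else if (weights$effect_allele[k] == mk$other_allele[j]) {
      action[k] <- "flipped"
      d <- 2 - d
    } else {
      action[k] <- "allele_mismatch"
      warning("SNP ", weights$snp_id[k], " matches neither allele orientation; excluded")
      next
    }
    if (anyNA(d)) {
      af <- mean(d, na.rm = TRUE) / 2
      n_imputed[k] <- sum(is.na(d))
      d[is.na(d)] <- 2 * af
    }
    score <- score + weights$beta[k] * d
  }
  if (any(action == "absent"))
    message(sum(action == "absent"), " weight-table SNP(s) absent from the genotype set")
  structure(list(score = score,
                 alignment = data.frame(snp_id = weights$snp_id, action = action,
                                        n_missing_imputed = n_imputed,
                                        stringsAsFactors = FALSE)),
            class = "score_result")
}
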