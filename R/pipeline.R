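# Configuration handling and the stage-chaining pipeline driver.  Every
# stage's tunables appear in the config with the analysis defaults, all
# randomness flows from the single configured seed, and each stage writes a
# TSV report into the output directory.

#' Default pipeline configuration
#'
#' @param seed integer seed for every random draw.
#' @param out output directory.
#' @param stages character vector of stage names, a subset of
#'   `simulate`, `qc`, `score`, `puberty-adjust`, `fit-growth`,
#'   `fit-twin`, `r2-curves`, `assoc`.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, out = "twingrowth_out",
                           stages = c("simulate", "qc", "score",
                                      "puberty-adjust", "fit-growth",
                                      "fit-twin", "r2-curves", "assoc")) {
  cc <- cohort_config(seed = seed)
  structure(list(
    seed = as.integer(seed),
    out = out,
    stages = stages,
    inputs = list(genotypes = NULL, genotype_format = "tsv_dosage",
                  pedigree = NULL, phenotypes = NULL, weights = NULL,
                  covariates = NULL),
    cohort = unclass(cc)[setdiff(names(cc), "seed")],
    qc = unclass(qc_thresholds()),
    loading = list(origin = 10.75, cap_male = 18, cap_female = 16),
    growth = list(resid_by_wave = FALSE),
    assoc = list(alpha = 0.05),
    use_pubertal_age = FALSE
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps the default.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(seed = usr$seed %||% 1L)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), usr), class = "pipeline_config")
}

cfg_cohort <- function(config) {
  do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
}

cfg_rule <- function(config) {
  loading_rule(config$loading$origin, config$loading$cap_male,
               config$loading$cap_female)
}

pipeline_log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  cat(msg, "\n", sep = "", file = state$logfile, append = TRUE)
  invisible(NULL)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, passing state (cohort tables,
#' QC'd genotypes, scores, fits) from stage to stage, and writes per-stage
#' TSV reports plus a run log into the output directory.  Deterministic
#' given the configured seed.
#'
#' @param config a `pipeline_config` from [default_config()] or
#'   [read_config()].
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  known <- c("simulate", "qc", "score", "puberty-adjust", "fit-growth",
             "fit-twin", "r2-curves", "assoc")
  stages <- config$stages
  if (!length(stages)) {
    warning("empty stage list: nothing to do")
    return(invisible(list()))
  }
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  st <- new.env()
  st$logfile <- file.path(config$out, "run.log")
  cat("twingrowth ", as.character(packageVersion("twingrowth")),
      " seed ", config$seed, "\n", sep = "", file = st$logfile)
  writeLines(yaml::as.yaml(unclass(config)), file.path(config$out, "config_used.yaml"))
  rule <- cfg_rule(config)
  results <- list()

  load_inputs <- function() {
    inp <- config$inputs
    need <- function(what) {
      if (is.null(inp[[what]]))
        stop("stage requires input '", what, "' but none configured and no simulate stage ran")
      inp[[what]]
    }
    if (is.null(st$ped)) st$ped <- read_pedigree(need("pedigree"))
    if (is.null(st$phenos)) st$phenos <- read_phenotypes(need("phenotypes"))
    if (is.null(st$geno) && !is.null(inp$genotypes))
      st$geno <- read_genotypes(inp$genotypes, inp$genotype_format)
    if (is.null(st$weights) && !is.null(inp$weights))
      st$weights <- read_weights(inp$weights)
    if (is.null(st$covariates) && !is.null(inp$covariates))
      st$covariates <- read_covariates(inp$covariates)
    invisible(NULL)
  }

  for (stage in stages) {
    pipeline_log(st, "stage ", stage, " start")
    if (stage == "simulate") {
      cc <- cfg_cohort(config)
      sim <- simulate_cohort(cc)
      st$ped <- sim$ped; st$geno <- sim$geno; st$phenos <- sim$phenos
      st$covariates <- sim$covariates
      st$weights <- weight_table(data.frame(snp_id = sim$truth$snps$snp_id,
                                            effect_allele = sim$truth$snps$effect_allele,
                                            beta = sim$truth$snps$beta))
      write_table_tsv(st$ped, file.path(config$out, "pedigree.tsv"))
      write_table_tsv(st$phenos, file.path(config$out, "phenotypes.tsv"))
      write_genotypes(st$geno, file.path(config$out, "genotypes.tsv"), "tsv_dosage")
      write_table_tsv(st$weights, file.path(config$out, "weights.tsv"))
      write_table_tsv(st$covariates, file.path(config$out, "covariates.tsv"))
      write_table_tsv(sim$truth$params, file.path(config$out, "truth_params.tsv"))
      write_table_tsv(sim$truth$snps, file.path(config$out, "truth_snps.tsv"))
      results$simulate <- sim$truth
    } else if (stage == "qc") {
      load_inputs()
      if (is.null(st$geno)) stop("qc stage requires genotypes")
      th <- do.call(qc_thresholds, config$qc)
      sq <- apply_sample_filters(st$geno, th)
      mq <- apply_marker_filters(sq$geno, st$ped, th)
      st$geno <- mq$geno
      write_table_tsv(sq$report, file.path(config$out, "qc_samples.tsv"))
      write_table_tsv(mq$report, file.path(config$out, "qc_markers.tsv"))
      results$qc <- list(samples = sq$report, markers = mq$report,
                         counts = mq$counts)
    } else if (stage == "score") {
      load_inputs()
      if (is.null(st$geno) || is.null(st$weights))
        stop("score stage requires genotypes and weights")
      sc <- compute_score(st$geno, st$weights)
      st$score <- sc$score
      write_table_tsv(data.frame(person_id = names(sc$score), score = sc$score),
                      file.path(config$out, "score.tsv"))
      write_table_tsv(sc$alignment, file.path(config$out, "score_alignment.tsv"))
      results$score <- sc
    } else if (stage == "puberty-adjust") {
      load_inputs()
      pm <- puberty_model(st$phenos, st$ped)
      adj <- adjust_phenotype_ages(pm, st$phenos, st$ped)
      st$phenos_adjusted <- adj
      if (isTRUE(config$use_pubertal_age)) st$phenos <- adj
      write_table_tsv(adj, file.path(config$out, "phenotypes_adjusted.tsv"))
      pm_tab <- do.call(rbind, lapply(pm, function(m)
        data.frame(sex = m$sex, wave = m$wave, r2 = m$r2, n = m$n,
                   w_age = if ("age" %in% names(m$coefs))
                     unname(m$coefs["age"]) else NA_real_,
                   w_puberty = if ("puberty" %in% names(m$coefs))
                     unname(m$coefs["puberty"]) else NA_real_,
                   w_menarche = if ("men" %in% names(m$coefs))
                     unname(m$coefs["men"]) else NA_real_,
                   row.names = NULL)))
      write_table_tsv(pm_tab, file.path(config$out, "puberty_model.tsv"))
      results$puberty <- pm
    } else if (stage == "fit-growth") {
      load_inputs()
      fit <- fit_growth(st$phenos, st$ped, st$covariates,
                        predictor = st$score, rule = rule,
                        resid_by_wave = isTRUE(config$growth$resid_by_wave))
      st$growth_fit <- fit
      est <- data.frame(parameter = c(names(fit$coefficients), "var_i", "var_s",
                                      "cov_is", paste0("var_resid", seq_along(fit$var_resid))),
                        estimate = c(fit$coefficients, fit$var_i, fit$var_s,
                                     fit$cov_is, fit$var_resid))
      write_table_tsv(est, file.path(config$out, "growth_fit.tsv"))
      if (!is.null(fit$tests))
        write_table_tsv(fit$tests, file.path(config$out, "growth_score_tests.tsv"))
      results$growth <- fit
    } else if (stage == "fit-twin") {
      load_inputs()
      base <- fit_twin_ace(st$phenos, st$ped, st$covariates, rule = rule)
      st$twin_base <- base
      fits <- list(base = base)
      if (!is.null(st$score)) {
        for (cs in c("slope_only", "intercept_only", "both"))
          fits[[cs]] <- fit_twin_ace(st$phenos, st$ped, st$covariates,
                                     score = st$score, constraint = cs,
                                     rule = rule, se = (cs == "both"))
        st$twin_score <- fits
      }
      tab <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(model = nm, loglik = f$loglik, t(f$summaries))
      }))
      write_table_tsv(tab, file.path(config$out, "twin_fit.tsv"))
      if (!is.null(base$summary_table))
        write_table_tsv(base$summary_table, file.path(config$out, "twin_base_summary.tsv"))
      results$twin <- fits
    } else if (stage == "r2-curves") {
      if (is.null(st$twin_base) || is.null(st$twin_score))
        stop("r2-curves stage requires fit-twin with a score")
      out <- NULL
      for (cs in c("slope_only", "intercept_only", "both")) {
        for (cp in c("phenotypic", "genetic")) {
          rc <- r2_curves(st$twin_base, st$twin_score[[cs]], component = cp)
          out <- rbind(out, data.frame(model = cs, component = cp,
                                       rc$curve))
        }
      }
      write_table_tsv(out, file.path(config$out, "r2_curves.tsv"))
      results$r2_curves <- out
    } else if (stage == "assoc") {
      load_inputs()
      if (is.null(st$geno) || is.null(st$weights))
        stop("assoc stage requires genotypes and weights")
      adult <- adult_height_filter(st$ped, st$phenos, rule)
      vc <- fit_null_vc(adult, st$ped, st$covariates)
      tab <- assoc_scan(st$geno, st$weights, vc, config$assoc$alpha)
      summ <- multiplicity_summary(tab, config$assoc$alpha)
      sign_p <- binomial_sign_test(summ$n_discordant, summ$m)
      score_row <- NULL
      if (!is.null(st$score))
        score_row <- gls_assoc(st$score, vc, +1)
      write_table_tsv(tab, file.path(config$out, "assoc.tsv"))
      write_table_tsv(summ$qq, file.path(config$out, "assoc_qq.tsv"))
      jsonlite::write_json(
        list(n_eligible = nrow(adult), m = summ$m,
             bonferroni_threshold = summ$bonferroni_threshold,
             n_bonferroni = summ$n_bonferroni, n_nominal = summ$n_nominal,
             n_discordant = summ$n_discordant, sign_test_p = sign_p,
             sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
             score = if (!is.null(score_row)) as.list(score_row)),
        file.path(config$out, "assoc_summary.json"), auto_unbox = TRUE,
        digits = NA)
      results$assoc <- list(adult = adult, vc = vc, table = tab,
                            summary = summ, sign_test_p = sign_p,
                            score = score_row)
    }
    pipeline_log(st, "stage ", stage, " done")
  }
  invisible(results)
}
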