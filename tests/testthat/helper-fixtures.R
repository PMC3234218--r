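# Shared fixtures, built in code.  Expensive simulated cohorts and fits are
# cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Moderate default cohort used by several structural tests.
default_sim <- function() {
  cached("default_sim", simulate_cohort(cohort_config(n_families = 500, seed = 42)))
}

default_weights <- function() {
  sim <- default_sim()
  weight_table(data.frame(snp_id = sim$truth$snps$snp_id,
                          effect_allele = sim$truth$snps$effect_allele,
                          beta = sim$truth$snps$beta))
}

default_score <- function() {
  cached("default_score", compute_score(default_sim()$geno, default_weights()))
}

default_ace_base <- function() {
  cached("default_ace_base", {
    sim <- default_sim()
    fit_twin_ace(sim$phenos, sim$ped, se = FALSE)
  })
}

default_ace_score <- function(constraint = "both") {
  cached(paste0("default_ace_", constraint), {
    sim <- default_sim()
    fit_twin_ace(sim$phenos, sim$ped, score = default_score()$score,
                 constraint = constraint, se = FALSE)
  })
}

# Tiny hand-built pedigree: one family, MZ male twins plus parents.
tiny_ped <- function() {
  pedigree_table(data.frame(
    family_id = "FAM1",
    person_id = c("T1", "T2", "MO", "FA"),
    role = c("twin1", "twin2", "mother", "father"),
    sex = c("M", "M", "F", "M"),
    zygosity = c("MZ", "MZ", NA, NA),
    birth_year = c(1980L, 1980L, 1955L, 1954L)))
}

# Small genotype set with explicit dosages (persons x markers).
tiny_geno <- function(dosages, effect = "A", other = "G", r2 = NA_real_) {
  ns <- ncol(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- paste0("rs", seq_len(ns))
  genotype_set(
    data.frame(snp_id = ids, chrom = "1",
               pos = 1000L * seq_len(ns),
               effect_allele = rep_len(effect, ns),
               other_allele = rep_len(other, ns),
               batch_label = NA_character_,
               imputation_r2 = rep_len(r2, ns)),
    dosages)
}
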