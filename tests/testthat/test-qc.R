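test_that("HWE exact test matches enumeration and is allele-symmetric", {
  expect_identical(hwe_exact_test(0, 0, 50), 1)
  expect_identical(hwe_exact_test(50, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")

  expect_equal(hwe_exact_test(57, 78, 13), hwe_oracle(57, 78, 13), tolerance = 1e-12)
  expect_equal(hwe_exact_test(57, 78, 13), hwe_exact_test(13, 78, 57))

  # all triples with small totals, plus random triples up to n = 200
  for (n in c(1, 2, 5, 9)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                   tolerance = 1e-9)
    }
  }
  withr::with_seed(4, {
    for (k in 1:40) {
      n <- sample(10:200, 1)
      cnt <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
      expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                   hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9)
    }
  })
})

test_that("Mendelian checks flag impossible transmissions only", {
  ped <- tiny_ped()
  # marker 1: parents AA x AA (dosage 2,2), MZ child het -> 1 inconsistency
  # marker 2: parents het x het -> any child ok
  # marker 3: father 0, mother 0, child 2 -> 1 inconsistency
  dos <- rbind(T1 = c(1, 0, 2), T2 = c(1, 2, 2), MO = c(2, 1, 0), FA = c(2, 1, 0))
  colnames(dos) <- paste0("rs", 1:3)
  g <- tiny_geno(dos)
  cnt <- mendel_check(g, ped)
  expect_identical(unname(cnt), c(1L, 0L, 1L))

  # a DZ family counts both twins separately
  ped2 <- pedigree_table(data.frame(
    family_id = "F2", person_id = c("T1", "T2", "MO", "FA"),
    role = c("twin1", "twin2", "mother", "father"), sex = "M",
    zygosity = c("DZ", "DZ", NA, NA), birth_year = 1980L))
  dos2 <- rbind(T1 = 1, T2 = 1, MO = 2, FA = 2)
  colnames(dos2) <- "rs1"
  expect_identical(unname(mendel_check(tiny_geno(dos2), ped2)), 2L)

  # error-free simulated transmission yields zero inconsistencies everywhere
  sim <- default_sim()
  expect_true(all(mendel_check(sim$geno, sim$ped) == 0L))
})

test_that("marker filters fail on the first triggered criterion, stably under permutation", {
  sim <- default_sim()
  g <- sim$geno
  g$dosages[1:30, 2] <- NA                       # call rate 98.5% -> fail
  g$markers$imputation_r2[3] <- 0.08             # imputation fail
  g$markers$imputation_r2[4] <- 0.55             # imputation pass
  res <- apply_marker_filters(g, sim$ped)
  expect_identical(res$report$reason[2], "call_rate")
  expect_identical(res$report$reason[3], "imputation_r2")
  expect_true(res$report$pass[4])
  expect_identical(nrow(res$report), ncol(g$dosages))

  # permuting marker order never changes per-marker outcomes
  perm <- rev(seq_len(ncol(g$dosages)))
  gp <- genotype_set(g$markers[perm, ], g$dosages[, perm])
  resp <- apply_marker_filters(gp, sim$ped)
  expect_identical(resp$report$pass[match(res$report$snp_id, resp$report$snp_id)],
                   res$report$pass)

  # all-pass input comes back identical
  ok <- apply_marker_filters(sim$geno, sim$ped)
  expect_true(all(ok$report$pass))
  expect_identical(ok$geno$dosages, sim$geno$dosages)
})

test_that("of 180 score SNPs, 3 poorly imputed and 1 absent leave 176 scoreable", {
  withr::local_seed(3)
  n_panel <- 179                                  # one of the 180 not on the panel
  dos <- matrix(rbinom(50 * n_panel, 2, 0.3), 50,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("snp%03d", 1:n_panel)))
  r2 <- rep(NA_real_, n_panel)
  r2[1:3] <- c(0.08, 0.46, 0.20)                  # fail at the 0.5 cutoff
  r2[4:20] <- seq(0.55, 1, length.out = 17)       # pass
  g <- tiny_geno(dos, r2 = r2)
  ped <- pedigree_table(data.frame(
    family_id = sprintf("F%02d", 1:25),
    person_id = sprintf("P%02d", 1:50),
    role = rep(c("mother", "father"), 25),
    sex = rep(c("F", "M"), 25), zygosity = NA, birth_year = 1950L))
  res <- apply_marker_filters(g, ped)
  expect_identical(sum(!res$report$pass), 3L)
  expect_true(all(res$report$reason[!res$report$pass] == "imputation_r2"))

  w <- weight_table(data.frame(snp_id = sprintf("snp%03d", 1:180),
                               effect_allele = "A", beta = 0.1))
  suppressMessages(sc <- compute_score(res$geno, w))
  scoreable <- sum(sc$alignment$action %in% c("as_is", "flipped"))
  expect_identical(scoreable, 176L)
})

test_that("score computation aligns alleles, imputes missing dosages, and is linear", {
  dos <- rbind(P1 = c(2, 1), P2 = c(0, 2))
  colnames(dos) <- c("rs1", "rs2")
  g <- tiny_geno(dos)
  w <- weight_table(data.frame(snp_id = c("rs1", "rs2"),
                               effect_allele = "A", beta = c(0.1, -0.2)))
  sc <- compute_score(g, w)
  expect_equal(unname(sc$score["P1"]), 0.1 * 2 - 0.2 * 1)
  expect_equal(unname(sc$score["P2"]), 0.1 * 0 - 0.2 * 2)

  # reversing one SNP's allele labels and flipping its dosages changes nothing
  g2 <- g
  g2$markers$effect_allele[2] <- "G"; g2$markers$other_allele[2] <- "A"
  g2$dosages[, 2] <- 2 - g2$dosages[, 2]
  sc2 <- compute_score(g2, w)
  expect_equal(sc2$score, sc$score)
  expect_identical(sc2$alignment$action[2], "flipped")

  # scaling all betas scales every score
  w3 <- w; w3$beta <- w$beta * 3
  expect_equal(compute_score(g, w3)$score, 3 * sc$score)

  # zero dosages give zero scores; missing dosages use twice the allele freq
  g0 <- tiny_geno(matrix(0, 2, 2, dimnames = dimnames(dos)))
  expect_true(all(compute_score(g0, w)$score == 0))
  gm <- g
  gm$dosages[1, 1] <- NA
  scm <- compute_score(gm, w)
  af <- mean(gm$dosages[, 1], na.rm = TRUE) / 2
  expect_equal(unname(scm$score["P1"]), 0.1 * 2 * af - 0.2 * 1)
  expect_identical(scm$alignment$n_missing_imputed[1], 1L)

  # an unmatchable SNP is excluded with a warning
  g4 <- g
  g4$markers$effect_allele[1] <- "T"; g4$markers$other_allele[1] <- "C"
  expect_warning(sc4 <- compute_score(g4, w), "neither allele")
  expect_identical(sc4$alignment$action[1], "allele_mismatch")
})

test_that("sample filters flag excess no-calls and heterozygosity outliers", {
  withr::local_seed(6)
  dos <- matrix(rbinom(40 * 100, 2, 0.4), 40,
                dimnames = list(sprintf("P%02d", 1:40), sprintf("s%03d", 1:100)))
  dos[1, 1:60] <- NA
  dos[2, ] <- 1                                   # all-het outlier
  g <- tiny_geno(dos)
  res <- apply_sample_filters(g, qc_thresholds(sample_nocall_max = 50))
  expect_identical(res$report$reason[1], "no_calls")
  expect_identical(res$report$reason[2], "heterozygosity")
  expect_true(all(res$report$pass[-(1:2)]))
})
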