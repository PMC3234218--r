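# Readers/writers for the tabular and genotype formats used across the
# pipeline.  All tables are plain data.frames carrying a light S3 class so
# that invariants are checked once, at construction.

PED_ROLES <- c("twin1", "twin2", "mother", "father")

#' Construct and validate a pedigree table
#'
#' A pedigree table has one row per person with columns `family_id`,
#' `person_id`, `role` (twin1/twin2/mother/father), `sex` (M/F), `zygosity`
#' (MZ/DZ, `NA` for parents) and `birth_year`.
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame with class `pedigree_table`.
#' @export
pedigree_table <- function(df) {
  req <- c("family_id", "person_id", "role", "sex", "zygosity", "birth_year")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pedigree table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$person_id <- as.character(df$person_id)
  df$family_id <- as.character(df$family_id)
  df$zygosity <- as.character(df$zygosity)
  if (anyDuplicated(df$person_id)) stop("duplicate person_id in pedigree")
  if (!all(df$role %in% PED_ROLES)) stop("unknown role in pedigree")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  bad_z <- !(df$zygosity %in% c("MZ", "DZ") | is.na(df$zygosity))
  if (any(bad_z)) stop("zygosity must be MZ, DZ or NA")
  tw <- df[df$role %in% c("twin1", "twin2"), ]
  for (fam in unique(tw$family_id)) {
    ft <- tw[tw$family_id == fam, ]
    if (nrow(ft) > 2L) stop("family ", fam, " has more than two twins")
    zy <- unique(ft$zygosity)
    if (length(zy) > 1L) stop("family ", fam, " twins have discordant zygosity")
    if (nrow(ft) == 2L && identical(zy, "MZ") && length(unique(ft$sex)) != 1L)
      stop("family ", fam, ": MZ twins with discordant sex")
  }
  class(df) <- c("pedigree_table", "data.frame")
  df
}

#' Construct and validate a long-format phenotype table
#'
#' One row per person per assessment wave, with columns `person_id`, `wave`
#' (one of 11, 14, 17, 20, 24, 29), `age` in years, `height` in cm, and
#' optionally `puberty` (score in 1--4) and `menarche` (0/1).
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame with class `long_phenotypes`.
#' @export
long_phenotypes <- function(df) {
  req <- c("person_id", "wave", "age", "height")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("phenotype table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$person_id <- as.character(df$person_id)
  df$wave <- as.integer(df$wave)
  if (!all(df$wave %in% WAVES)) stop("unknown wave label; waves must be in {", paste(WAVES, collapse = ","), "}")
  if (anyDuplicated(df[c("person_id", "wave")])) stop("duplicate (person_id, wave)")
  if (any(!is.na(df$height) & df$height <= 0)) stop("height must be positive")
  if (!"puberty" %in% names(df)) df$puberty <- NA_real_
  if (!"menarche" %in% names(df)) df$menarche <- NA_integer_
  pb <- df$puberty
  if (any(!is.na(pb) & (pb < 1 | pb > 4))) stop("puberty score must lie in [1, 4]")
  ord <- order(df$person_id, df$wave)
  ds <- df[ord, ]
  inc <- tapply(ds$age, ds$person_id, function(a) all(diff(a[!is.na(a)]) > 0))
  if (!all(unlist(inc))) stop("age must be strictly increasing across waves within person")
  class(df) <- c("long_phenotypes", "data.frame")
  df
}

#' Construct and validate a SNP weight table
#'
#' @param df data.frame with columns `snp_id`, `effect_allele`, `beta`
#'   (cm per effect-allele copy).
#' @return The validated data.frame with class `weight_table`.
#' @export
weight_table <- function(df) {
  req <- c("snp_id", "effect_allele", "beta")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("weight table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$snp_id <- as.character(df$snp_id)
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in weight table")
  if (any(!is.finite(df$beta))) stop("weight table betas must be finite")
  class(df) <- c("weight_table", "data.frame")
  df
}

#' Construct and validate a genotype set
#'
#' A genotype set couples a marker metadata table (`snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `batch_label`, `imputation_r2`) with a
#' person x marker dosage matrix on the effect allele, entries in \[0, 2\]
#' or `NA`.
#'
#' @param markers data.frame of marker metadata.
#' @param dosages numeric matrix, persons in rows (rownames = person ids),
#'   markers in columns (colnames = snp ids).
#' @return A list with elements `markers` and `dosages`, class `genotype_set`.
#' @export
genotype_set <- function(markers, dosages) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(markers))
  if (length(miss)) stop("marker table missing columns: ", paste(miss, collapse = ", "))
  markers <- as.data.frame(markers)
  markers$snp_id <- as.character(markers$snp_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (!"batch_label" %in% names(markers)) markers$batch_label <- NA_character_
  if (!"imputation_r2" %in% names(markers)) markers$imputation_r2 <- NA_real_
  if (anyDuplicated(markers$snp_id)) stop("duplicate snp_id in marker table")
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(markers)) stop("dosage columns must match marker rows")
  if (is.null(colnames(dosages))) colnames(dosages) <- markers$snp_id
  if (!identical(colnames(dosages), markers$snp_id)) stop("dosage colnames must equal marker snp_ids")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage outside [0, 2]")
  structure(list(markers = markers, dosages = dosages), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$dosages), "persons x", ncol(x$dosages), "markers\n")
  invisible(x)
}

read_tsv_typed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE, quote = "",
             comment.char = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pedigree table from TSV
#' @param path file path.
#' @return A `pedigree_table`.
#' @export
read_pedigree <- function(path) pedigree_table(read_tsv_typed(path))

#' Read a long-format phenotype table from TSV
#' @param path file path.
#' @return A `long_phenotypes` table.
#' @export
read_phenotypes <- function(path) long_phenotypes(read_tsv_typed(path))

#' Read a SNP weight table from TSV
#' @param path file path.
#' @return A `weight_table`.
#' @export
read_weights <- function(path) weight_table(read_tsv_typed(path))

#' Read a covariate table from TSV
#'
#' First column must be `person_id`; remaining columns are numeric covariates.
#' @param path file path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  df <- read_tsv_typed(path)
  if (names(df)[1] != "person_id") stop("covariate table must start with person_id")
  df$person_id <- as.character(df$person_id)
  df
}

#' Read genotype dosages
#'
#' Two dialects are supported.  `tsv_dosage` is a marker-per-row TSV whose
#' leading columns are the marker metadata (`snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `batch_label`, `imputation_r2`) followed
#' by one column per person holding the effect-allele dosage (empty field =
#' missing).  `vcf_dosage` is a VCF whose genotype `DS` field carries the
#' dosage of the ALT allele; the ALT allele is taken as the effect allele and
#' per-site `BATCH` / `R2` INFO keys, when present, populate the batch label
#' and imputation quality.
#'
#' @param path file path.
#' @param format `"tsv_dosage"` or `"vcf_dosage"`.
#' @return A `genotype_set` with dosages counted on the effect allele.
#' @export
read_genotypes <- function(path, format = c("tsv_dosage", "vcf_dosage")) {
  format <- match.arg(format)
  if (format == "tsv_dosage") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

GENO_META_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "batch_label", "imputation_r2")

read_genotypes_tsv <- function(path) {
  df <- read_tsv_typed(path)
  miss <- setdiff(GENO_META_COLS, names(df))
  if (length(miss)) stop("dosage TSV missing metadata columns: ", paste(miss, collapse = ", "))
  persons <- setdiff(names(df), GENO_META_COLS)
  if (!length(persons)) stop("dosage TSV has no person columns")
  dos <- t(as.matrix(df[persons]))
  if (!is.numeric(dos)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dos))) & !is.na(dos))
    stop("non-numeric dosage near data line ", if (length(bad)) ((bad[1] - 1) %% ncol(dos)) + 1 else NA)
  }
  colnames(dos) <- df$snp_id
  rownames(dos) <- persons
  rng <- range(dos, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)[1, ]
    stop("dosage outside [0, 2] for person ", rownames(dos)[bad[1]],
         " at marker ", colnames(dos)[bad[2]])
  }
  genotype_set(df[GENO_META_COLS], dos)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, element = "BATCH")
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "R2")))
  markers <- data.frame(
    snp_id = fx$ID, chrom = fx$CHROM, pos = as.integer(fx$POS),
    effect_allele = fx$ALT, other_allele = fx$REF,
    batch_label = if (is.null(info)) NA_character_ else as.character(info),
    imputation_r2 = if (is.null(r2)) NA_real_ else r2,
    stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds)) stop("VCF has no DS (dosage) genotype field")
  dos <- t(ds)
  colnames(dos) <- markers$snp_id
  rng <- range(dos, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) stop("VCF dosage outside [0, 2]")
  genotype_set(markers, dos)
}

#' Write genotype dosages
#'
#' @param geno a `genotype_set`.
#' @param path output file path.
#' @param format `"tsv_dosage"` or `"vcf_dosage"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("tsv_dosage", "vcf_dosage")) {
  format <- match.arg(format)
  if (format == "tsv_dosage") {
    df <- cbind(geno$markers[GENO_META_COLS], as.data.frame(t(geno$dosages)))
    return(write_tsv(df, path))
  }
  m <- geno$markers
  n <- nrow(geno$dosages)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=BATCH,Number=1,Type=String,Description=\"Genotyping batch label\">",
           "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation r-squared\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(geno$dosages)), collapse = "\t"))
  info <- ifelse(is.na(m$batch_label), "", paste0("BATCH=", m$batch_label))
  info2 <- ifelse(is.na(m$imputation_r2), "", paste0("R2=", m$imputation_r2))
  info <- ifelse(info == "" & info2 == "", ".",
                 ifelse(info == "", info2, ifelse(info2 == "", info, paste(info, info2, sep = ";"))))
  body <- vapply(seq_len(nrow(m)), function(j) {
    ds <- geno$dosages[, j]
    paste(c(m$chrom[j], m$pos[j], m$snp_id[j], m$other_allele[j], m$effect_allele[j],
            ".", "PASS", info[j], "DS",
            ifelse(is.na(ds), ".", format(ds, trim = TRUE, digits = 10))), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a pedigree / phenotype / weight / covariate table to TSV
#' @param df the table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) write_tsv(as.data.frame(df), path)
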