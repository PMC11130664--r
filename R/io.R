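## Plain-text (TSV) readers and writers for the pipeline's standard tables.
## All floating point values are written with >= 10 significant digits.

fmt_num <- function(x) {
  if (is.double(x)) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  else x
}

#' Write a table as TSV
#'
#' Tab-separated, header line, no quoting, doubles at 12 significant digits.
#'
#' @param df Data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a cohort table
#'
#' One row per individual, TSV with header.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) write_tsv(cohort, path)

#' Read a cohort table
#'
#' @param path File path (TSV with an `individual_id` column).
#' @return Cohort data.frame.
#' @export
read_cohort_tsv <- function(path) {
  cohort <- read_tsv(path)
  if (!"individual_id" %in% names(cohort))
    stop("cohort table must have an 'individual_id' column")
  cohort
}

#' Write genotype dosages as TSV
#'
#' Writes the dosage matrix (individuals x variants, individual ids in the
#' first column) and a companion variant-info table
#' (`<path>.variants.tsv`: id, effect_allele, other_allele, frequency).
#'
#' @param genotypes A `genotype_dosage` object.
#' @param path Dosage matrix output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  m <- as.data.frame(genotypes$dosages, check.names = FALSE)
  m <- cbind(individual_id = rownames(genotypes$dosages), m)
  write_tsv(m, path)
  write_tsv(genotypes$variants, paste0(path, ".variants.tsv"))
  invisible(path)
}

#' Read genotype dosages from TSV
#'
#' @param path Dosage matrix path, with `<path>.variants.tsv` alongside.
#' @return A `genotype_dosage` object.
#' @export
read_genotypes_tsv <- function(path) {
  m <- read_tsv(path)
  ids <- m$individual_id
  m$individual_id <- NULL
  d <- as.matrix(m)
  rownames(d) <- ids
  out <- list(dosages = d, variants = read_tsv(paste0(path, ".variants.tsv")))
  class(out) <- "genotype_dosage"
  out
}

#' Read a GWAS weight table
#'
#' Requires the header `id`, `effect_allele`, `other_allele`, `beta`, `eaf`.
#'
#' @param path TSV file path.
#' @return Data.frame.
#' @export
read_weights_tsv <- function(path) {
  w <- read_tsv(path)
  req <- c("id", "effect_allele", "other_allele", "beta", "eaf")
  if (!all(req %in% names(w)))
    stop("weight table must have columns: ", paste(req, collapse = ", "))
  w
}

#' Write a metabolite state matrix as TSV
#'
#' @param mat Individuals x traits matrix.
#' @param path Output path.
#' @export
write_state_matrix_tsv <- function(mat, path) {
  df <- as.data.frame(mat, check.names = FALSE)
  df <- cbind(individual_id = rownames(mat), df)
  write_tsv(df, path)
}

#' Read a metabolite state matrix from TSV
#'
#' @param path File path.
#' @return Numeric matrix with individual ids as rownames.
#' @export
read_state_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  ids <- df$individual_id
  df$individual_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}
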