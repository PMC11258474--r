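#' Read and write the tabular interchange formats
#'
#' Plain-TSV readers/writers for the formats the pipeline consumes and
#' produces: a genotype dosage table (rows = individuals, columns = SNP
#' ids), GWAS summary statistics in the GCTA `.ma` column layout
#' (`SNP A1 A2 freq b se p N`), per-gene cis-eQTL summaries, and an LD
#' correlation matrix.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @name frailtymr-io
NULL

#' @rdname frailtymr-io
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- tibble::as_tibble(genotypes$dosages)
  df <- dplyr::bind_cols(tibble::tibble(person_id = seq_len(nrow(df))), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname frailtymr-io
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$person_id
  dos <- as.matrix(df[setdiff(names(df), "person_id")])
  rownames(dos) <- ids
  dos
}

#' @rdname frailtymr-io
#' @param gwas a GWAS summary tibble (columns as from
#'   [simulate_gwas_summary()]).
#' @export
write_gwas_ma <- function(gwas, path) {
  ma <- tibble::tibble(SNP = gwas$snp, A1 = gwas$effect_allele,
                       A2 = gwas$other_allele, freq = gwas$freq,
                       b = gwas$beta, se = gwas$se, p = gwas$p, N = gwas$n)
  readr::write_tsv(ma, path)
  invisible(path)
}

#' @rdname frailtymr-io
#' @param snp_meta optional tibble (`snp`, `chromosome`, `position`) merged
#'   onto the summary rows, since `.ma` files carry no positions.
#' @export
read_gwas_ma <- function(path, snp_meta = NULL) {
  ma <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    snp = ma$SNP, effect_allele = ma$A1, other_allele = ma$A2,
    freq = ma$freq, beta = ma$b, se = ma$se, p = ma$p, n = ma$N
  )
  if (!is.null(snp_meta)) out <- dplyr::left_join(out, snp_meta, by = "snp")
  out
}

#' @rdname frailtymr-io
#' @param eqtl per-SNP eQTL tibble (`gene`, `snp`, alleles, `b_zx`,
#'   `se_zx`, `p_zx`, `position`).
#' @export
write_eqtl_tsv <- function(eqtl, path) {
  readr::write_tsv(eqtl, path)
  invisible(path)
}

#' @rdname frailtymr-io
#' @export
read_eqtl_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname frailtymr-io
#' @param ld signed LD r matrix with SNP dimnames.
#' @export
write_ld_tsv <- function(ld, path) {
  df <- tibble::as_tibble(ld)
  df <- dplyr::bind_cols(tibble::tibble(snp = rownames(ld)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname frailtymr-io
#' @export
read_ld_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[setdiff(names(df), "snp")])
  rownames(m) <- df$snp
  m
}

#' Read a persons-by-items deficit table
#'
#' Blank cells are treated as missing answers.
#'
#' @param path TSV path.
#' @return tibble with `person_id` (if present) and deficit item columns.
#' @export
read_deficit_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
}
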