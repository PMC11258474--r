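#' Select candidate instruments for a drug-target gene region
#'
#' Filters GWAS summary rows to SNPs inside the flanked gene region that are
#' genome-wide significant and common: position within
#' `[start - flank, end + flank]`, association `p < p_max` (strict), and
#' minor allele frequency `min(freq, 1 - freq) > maf_min` (strict). For the
#' genome-wide instrument class (`drug_class == "genome_wide"` or a `NULL`
#' region) the positional filter is skipped.
#'
#' @param gwas tibble of GWAS summary statistics with columns `snp`,
#'   `chromosome`, `position`, `freq`, `beta`, `se`, `p`.
#' @param region one row of a gene-region table (`gene`, `drug_class`,
#'   `chromosome`, `start`, `end`), or `NULL` for genome-wide selection.
#' @param p_max significance threshold (default 5e-8, strict `<`).
#' @param maf_min minor-allele-frequency floor (default 0.01, strict `>`).
#' @param flank region flank in bp (default 100 kb).
#' @return The filtered GWAS tibble (possibly zero rows, with a warning —
#'   a drug class without usable proxies is a legitimate outcome).
#' @export
select_candidates <- function(gwas, region = NULL, p_max = 5e-8,
                              maf_min = 0.01, flank = 100000) {
  stopifnot(all(c("snp", "position", "freq", "beta", "se", "p") %in% names(gwas)))
  out <- gwas
  genome_wide <- is.null(region) ||
    (!is.null(region$drug_class) && identical(region$drug_class, "genome_wide"))
  if (!genome_wide) {
    if (region$start > region$end) abort("region start must be <= end")
    out <- dplyr::filter(
      out,
      .data$chromosome == region$chromosome,
      .data$position >= region$start - flank,
      .data$position <= region$end + flank
    )
  }
  out <- dplyr::filter(out, .data$p < p_max,
                       pmin(.data$freq, 1 - .data$freq) > maf_min)
  if (nrow(out) == 0) {
    warn(sprintf("no candidate SNPs pass the filters%s",
                 if (genome_wide) "" else paste0(" for region ", region$gene)))
  }
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard greedy clumping: candidates are ranked by GWAS p-value
#' (ascending; ties broken by position, then SNP id), and each SNP is
#' accepted if its squared LD correlation with every already-accepted SNP is
#' below `r2_max`. The output order is the acceptance order, and the result
#' is invariant to the input row order.
#'
#' @param candidates tibble from [select_candidates()] (needs `snp`, `p`,
#'   `position`).
#' @param ld either a signed LD correlation matrix with SNP dimnames, a
#'   `genotype_matrix` reference panel, or a list with an `r2` matrix (as
#'   from [ld_from_panel()]).
#' @param r2_max clumping threshold: retained pairs satisfy `r2 < r2_max`
#'   (default 0.4; sensitivity analyses use 0.1 and 0.01; genome-wide
#'   selection uses 0.001).
#' @return The retained rows of `candidates`, in acceptance order.
#' @export
ld_clump <- function(candidates, ld, r2_max = 0.4) {
  if (nrow(candidates) <= 1) return(candidates)
  r2 <- ld_r2_matrix(ld, candidates$snp)
  known <- candidates$snp %in% rownames(r2)
  if (any(!known)) {
    warn(paste0("SNPs absent from LD reference dropped: ",
                paste(candidates$snp[!known], collapse = ", ")))
    candidates <- candidates[known, , drop = FALSE]
    if (nrow(candidates) <= 1) return(candidates)
  }
  ord <- order(candidates$p, candidates$position, candidates$snp)
  ranked <- candidates[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    ok <- all(r2[ranked$snp[i], ranked$snp[accepted]] < r2_max)
    if (ok) accepted <- c(accepted, i)
  }
  ranked[accepted, , drop = FALSE]
}

# Normalize the several accepted LD inputs to an r^2 matrix.
ld_r2_matrix <- function(ld, snps) {
  if (inherits(ld, "genotype_matrix")) {
    return(suppressWarnings(ld_from_panel(ld, snps))$r2)
  }
  if (is.list(ld) && !is.null(ld$r2)) return(ld$r2)
  if (is.matrix(ld)) {
    if (is.null(rownames(ld))) abort("LD matrix needs SNP dimnames")
    if (max(abs(ld), na.rm = TRUE) <= 1 && any(ld < 0)) return(ld^2)
    # assume a signed r matrix when values lie in [-1, 1]
    return(ld^2)
  }
  abort("unsupported LD reference type")
}

#' Orient instrument weights to the blood-pressure-increasing allele
#'
#' Re-expresses each SNP so that its effect allele raises the exposure:
#' negative-beta SNPs have their allele labels swapped and the sign flipped
#' (downstream dosages are complemented as `2 - g`); zero-beta SNPs are
#' dropped with a warning. After orientation every weight is positive, which
#' the weighted genetic-risk-score formula requires for its scaling to be
#' coherent.
#'
#' @param snps tibble with `snp`, `effect_allele`, `other_allele`, `beta`
#'   (and any other columns, preserved).
#' @param exposure,drug_class optional labels stored on the result.
#' @return A tibble of class `instrument_set` with all betas positive and a
#'   logical `flipped` column.
#' @export
orient_weights <- function(snps, exposure = NULL, drug_class = NULL) {
  zero <- !is.na(snps$beta) & snps$beta == 0
  if (any(zero)) {
    warn(sprintf("%d zero-beta SNP(s) dropped during orientation", sum(zero)))
    snps <- snps[!zero, , drop = FALSE]
  }
  flip <- snps$beta < 0
  out <- snps
  ea <- out$effect_allele
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- ea[flip]
  out$beta <- abs(out$beta)
  if ("freq" %in% names(out)) out$freq[flip] <- 1 - out$freq[flip]
  out$flipped <- flip
  attr(out, "exposure") <- exposure
  attr(out, "drug_class") <- drug_class
  class(out) <- c("instrument_set", class(out))
  out
}
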