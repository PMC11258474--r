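#' Simulate summary-level eQTL + GWAS data for SMR/HEIDI scenarios
#'
#' Generates a cis window of SNPs with an AR-1 LD structure and draws
#' summary-level effect estimates for gene expression (eQTL study) and the
#' outcome (GWAS) under one of four generative scenarios:
#'
#' * `causal` — one causal variant drives expression, and the outcome is
#'   affected only through expression, so the true outcome effects satisfy
#'   `b_zy = b_xy_true * b_zx` at every SNP.
#' * `pleiotropy` — the same single variant affects expression and the
#'   outcome through separate pathways; the marginal effect pattern is
#'   proportional across SNPs, as in the causal scenario (HEIDI cannot, and
#'   should not, distinguish this from causality).
#' * `linkage` — two distinct causal variants in LD, one affecting only
#'   expression, the other only the outcome; the per-SNP ratio
#'   `b_zy / b_zx` then varies across the window, which HEIDI detects.
#' * `null` — expression has a causal variant but the outcome is unaffected.
#'
#' True marginal effects at non-causal SNPs follow the LD correlation with
#' the causal variant; estimates are drawn from a multivariate normal with
#' covariance `D R D` (`R` the LD correlation matrix, `D` the per-SNP
#' standard errors), i.e. the standard sampling model for summary statistics
#' from a single study.
#'
#' @param scenario one of `"causal"`, `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param n_snps number of SNPs in the cis window (>= 2).
#' @param ld_rho AR-1 LD correlation between adjacent SNPs, in `[0, 1)`.
#' @param b_eqtl causal-variant effect on expression (SD per allele).
#' @param b_xy_true causal effect of expression on the outcome (outcome SD
#'   per expression SD); used by `causal`.
#' @param b_direct outcome effect of the second (linkage) or shared
#'   (pleiotropy) causal variant.
#' @param se_zx,se_zy per-SNP standard errors of the eQTL and GWAS estimates.
#' @param causal_index index of the expression causal variant (default the
#'   middle of the window).
#' @param linkage_offset index offset of the outcome causal variant in the
#'   linkage scenario (LD with the expression variant is
#'   `ld_rho^linkage_offset`).
#' @param gene gene symbol attached to the records.
#' @param gene_start,gene_end gene coordinates (bp); SNPs are spaced every
#'   5 kb starting 50 kb upstream of `gene_start`.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return An object of class `summary_scenario`: list with `snps` (tibble:
#'   `gene`, `snp`, `position`, `effect_allele`, `other_allele`, `b_zx`,
#'   `se_zx`, `p_zx`, `b_zy`, `se_zy`, `p_zy`, and the noiseless truths
#'   `b_zx_true`, `b_zy_true`), `ld` (signed r matrix), `scenario`, `gene`,
#'   `gene_start`, `gene_end`.
#' @examples
#' sc <- simulate_summary_scenario("causal", n_snps = 10, seed = 1)
#' head(sc$snps)
#' @export
simulate_summary_scenario <- function(scenario = c("causal", "pleiotropy",
                                                   "linkage", "null"),
                                      n_snps = 30, ld_rho = 0.8,
                                      b_eqtl = 0.8, b_xy_true = 0.3,
                                      b_direct = 0.15,
                                      se_zx = 0.08, se_zy = 0.015,
                                      causal_index = NULL,
                                      linkage_offset = 3L,
                                      gene = "GENE1",
                                      gene_start = 1000000L,
                                      gene_end = 1050000L,
                                      seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_snps < 2) abort("a scenario window needs at least 2 SNPs")
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must be in [0, 1)")
  if (is.null(causal_index)) causal_index <- ceiling(n_snps / 2)
  se_zx <- rep_len(se_zx, n_snps)
  se_zy <- rep_len(se_zy, n_snps)
  if (any(se_zx <= 0) || any(se_zy <= 0)) abort("standard errors must be > 0")

  R <- ar1_matrix(n_snps, ld_rho)
  r_c1 <- R[, causal_index]
  b_zx_true <- r_c1 * b_eqtl
  b_zy_true <- switch(scenario,
    causal = b_xy_true * b_zx_true,
    pleiotropy = r_c1 * b_direct,
    linkage = {
      c2 <- causal_index + linkage_offset
      if (c2 > n_snps) c2 <- causal_index - linkage_offset
      if (c2 < 1) abort("linkage_offset places the outcome variant outside the window")
      R[, c2] * b_direct
    },
    null = rep(0, n_snps)
  )

  withr::local_seed(as.integer(seed))
  L <- chol(psd_clip(R) + diag(1e-10, n_snps))
  bhat_zx <- b_zx_true + drop(rnorm(n_snps) %*% L) * se_zx
  bhat_zy <- b_zy_true + drop(rnorm(n_snps) %*% L) * se_zy

  snps <- tibble::tibble(
    gene = gene,
    snp = sprintf("esnp_%02d", seq_len(n_snps)),
    position = as.integer(gene_start - 50000L + 5000L * (seq_len(n_snps) - 1L)),
    effect_allele = "A", other_allele = "G",
    b_zx = bhat_zx, se_zx = se_zx,
    p_zx = 2 * pnorm(-abs(bhat_zx / se_zx)),
    b_zy = bhat_zy, se_zy = se_zy,
    p_zy = 2 * pnorm(-abs(bhat_zy / se_zy)),
    b_zx_true = b_zx_true, b_zy_true = b_zy_true
  )
  dimnames(R) <- list(snps$snp, snps$snp)
  structure(list(snps = snps, ld = R, scenario = scenario, gene = gene,
                 gene_start = gene_start, gene_end = gene_end),
            class = "summary_scenario")
}

#' @export
print.summary_scenario <- function(x, ...) {
  cat(sprintf("<summary_scenario> '%s': %d SNPs, gene %s [%d-%d]\n",
              x$scenario, nrow(x$snps), x$gene, x$gene_start, x$gene_end))
  invisible(x)
}
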