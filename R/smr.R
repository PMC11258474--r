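#' Pick the top cis-eQTL for a gene
#'
#' Restricts eQTL records to the cis window (within 1 Mb of either gene
#' end) and returns the SNP with the smallest eQTL p-value, provided it
#' passes the instrument significance threshold; ties are broken by larger
#' `|b_zx / se_zx|`, then by smaller position. Genes with no passing cis
#' SNP are skipped (`NULL`, with a message).
#'
#' @param eqtl tibble of per-SNP eQTL records: `snp`, `position`, `b_zx`,
#'   `se_zx`, `p_zx`.
#' @param gene_start,gene_end gene coordinates (bp).
#' @param cis_window cis definition, bp on either side of the gene
#'   (default 1 Mb).
#' @param p_max instrument threshold for the top eQTL (default 5e-8).
#' @return one-row tibble (the top SNP's record) or `NULL`.
#' @export
pick_top_cis_eqtl <- function(eqtl, gene_start, gene_end,
                              cis_window = 1e6, p_max = 5e-8) {
  cis <- dplyr::filter(eqtl,
                       .data$position >= gene_start - cis_window,
                       .data$position <= gene_end + cis_window)
  if (nrow(cis) == 0) {
    rlang::inform("no cis SNPs in window: gene skipped")
    return(NULL)
  }
  cis <- dplyr::filter(cis, .data$p_zx < p_max)
  if (nrow(cis) == 0) {
    rlang::inform("no cis-eQTL passes the significance threshold: gene skipped")
    return(NULL)
  }
  cis <- dplyr::arrange(cis, .data$p_zx, -abs(.data$b_zx / .data$se_zx),
                        .data$position)
  cis[1, , drop = FALSE]
}

#' Summary-data MR ratio test
#'
#' The causal effect of expression on the outcome is estimated by the
#' ratio `b_xy = b_zy / b_zx` at the top cis-eQTL. The test statistic is
#' \deqn{T_{SMR} = \frac{z_{zx}^2 z_{zy}^2}{z_{zx}^2 + z_{zy}^2},}
#' referred to a chi-square with 1 df; the standard error is recovered as
#' `|b_xy| / sqrt(T_SMR)`.
#'
#' @param b_zx,se_zx eQTL effect and standard error (se > 0, b_zx != 0).
#' @param b_zy,se_zy GWAS effect and standard error (se > 0).
#' @return tibble `b_xy`, `se_xy`, `t_smr`, `p_smr` (vectorized).
#' @examples
#' smr_test(0.48, 0.08, 0.144, 0.024)
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  if (any(se_zx <= 0) || any(se_zy <= 0)) abort("standard errors must be > 0")
  if (any(b_zx == 0)) abort("b_zx = 0: the ratio estimate is undefined")
  z_zx2 <- (b_zx / se_zx)^2
  z_zy2 <- (b_zy / se_zy)^2
  t_smr <- z_zx2 * z_zy2 / (z_zx2 + z_zy2)
  b_xy <- b_zy / b_zx
  tibble::tibble(
    b_xy = b_xy,
    se_xy = ifelse(t_smr > 0, abs(b_xy) / sqrt(t_smr), NA_real_),
    t_smr = t_smr,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE)
  )
}

#' Select the SNP set for the HEIDI heterogeneity test
#'
#' From the cis window, keeps SNPs that are informative about heterogeneity
#' around the top cis-eQTL: eQTL association no weaker than
#' `p_eqtl_max` (weak instruments excluded), LD with the top SNP of
#' `r2 <= r2_top_max` (near-perfect proxies excluded since they carry no
#' independent information), optionally `r2 >= r2_min` (near-independent
#' SNPs excluded; off by default). The top SNP itself is excluded from the
#' difference set. If more than `m_max` SNPs remain, the `m_max` with the
#' smallest eQTL p-values are kept.
#'
#' @param eqtl cis eQTL records (`snp`, `p_zx`, ...).
#' @param ld signed LD r matrix with SNP dimnames covering the candidates
#'   and the top SNP.
#' @param top_snp id of the top cis-eQTL.
#' @param p_eqtl_max weak-instrument exclusion (default 1.6e-3; SNPs with
#'   `p_zx > p_eqtl_max` are removed).
#' @param r2_top_max near-perfect-LD exclusion (default 0.9; SNPs with
#'   `r2 > 0.9` to the top SNP are removed).
#' @param r2_min optional lower LD bound (`NULL` = off).
#' @param m_max maximum number of HEIDI SNPs (default 20).
#' @return tibble of retained records (possibly < 3 rows, in which case the
#'   HEIDI test is not computed downstream).
#' @export
select_heidi_snps <- function(eqtl, ld, top_snp, p_eqtl_max = 1.6e-3,
                              r2_top_max = 0.9, r2_min = NULL, m_max = 20) {
  cand <- dplyr::filter(eqtl, .data$snp != top_snp,
                        .data$p_zx <= p_eqtl_max)
  if (nrow(cand) == 0) return(cand)
  r2 <- ld[cand$snp, top_snp]^2
  keep <- r2 <= r2_top_max
  if (!is.null(r2_min)) keep <- keep & r2 >= r2_min
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) > m_max) {
    cand <- dplyr::arrange(cand, .data$p_zx)[seq_len(m_max), , drop = FALSE]
  }
  cand
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Under a single shared causal variant, the ratio estimate
#' `b_xy(i) = b_zy(i)/b_zx(i)` is the same at every cis SNP; heterogeneity
#' across LD-linked SNPs indicates distinct causal variants in linkage.
#' The test forms `d_i = b_xy(i) - b_xy(top)` for each selected SNP,
#' derives the covariance of the `d_i` by the first-order delta method
#' with zero cross-study covariance (independent eQTL and GWAS samples):
#' \deqn{Cov(b_{xy,i}, b_{xy,j}) = r_{ij}\left[
#'   \frac{se_{zy,i} se_{zy,j}}{b_{zx,i} b_{zx,j}} +
#'   \frac{b_{zy,i} b_{zy,j} se_{zx,i} se_{zx,j}}{b_{zx,i}^2 b_{zx,j}^2}
#' \right],}
#' standardizes to `z_i = d_i / sd(d_i)` and sums `T = sum z_i^2`. The null
#' distribution of a sum of correlated squared standard normals is
#' evaluated by seeded Monte-Carlo (default 1e5 draws), with a
#' Satterthwaite moment-matched scaled chi-square as an analytic
#' cross-check.
#'
#' @param records tibble containing the top SNP and the selected HEIDI
#'   SNPs: `snp`, `b_zx`, `se_zx`, `b_zy`, `se_zy`.
#' @param ld signed LD r matrix with dimnames covering all records.
#' @param top_snp id of the top cis-eQTL.
#' @param n_draws Monte-Carlo draws for the null distribution.
#' @param seed seed for the Monte-Carlo draws (restores the caller's RNG
#'   state).
#' @return tibble `t_heidi`, `p_heidi` (Monte-Carlo), `p_heidi_satt`
#'   (Satterthwaite), `n_heidi_snps`, `passed_heidi`
#'   (`p_heidi >= 0.01`; heterogeneity at p < 0.01 flags likely linkage).
#'   If fewer than 3 non-top SNPs are supplied, p-values are `NA`.
#' @export
heidi_test <- function(records, ld, top_snp, n_draws = 1e5, seed = 1L) {
  stopifnot(top_snp %in% records$snp)
  others <- records[records$snp != top_snp, , drop = FALSE]
  m <- nrow(others)
  if (m < 3) {
    return(tibble::tibble(t_heidi = NA_real_, p_heidi = NA_real_,
                          p_heidi_satt = NA_real_, n_heidi_snps = m,
                          passed_heidi = NA))
  }
  top <- records[records$snp == top_snp, , drop = FALSE]
  all_rec <- dplyr::bind_rows(top, others)       # index 1 = top
  ids <- all_rec$snp
  R <- ld[ids, ids]
  bzx <- all_rec$b_zx; sezx <- all_rec$se_zx
  bzy <- all_rec$b_zy; sezy <- all_rec$se_zy
  if (any(bzx == 0)) abort("b_zx = 0 among HEIDI SNPs: ratio undefined")

  # delta-method covariance of the per-SNP ratio estimates
  cov_xy <- R * (tcrossprod(sezy) / tcrossprod(bzx) +
                 tcrossprod(bzy) * tcrossprod(sezx) / tcrossprod(bzx^2))
  # d_i = b_xy(i) - b_xy(top): V_d = A cov_xy A' with A = [-1 | I_m]
  idx <- 2:(m + 1)
  v_d <- cov_xy[idx, idx] - outer(cov_xy[idx, 1], rep(1, m)) -
    outer(rep(1, m), cov_xy[1, idx]) + cov_xy[1, 1]
  sd_d <- sqrt(diag(v_d))
  if (any(!is.finite(sd_d)) || any(sd_d <= 0)) {
    warn("degenerate HEIDI covariance: test not computed")
    return(tibble::tibble(t_heidi = NA_real_, p_heidi = NA_real_,
                          p_heidi_satt = NA_real_, n_heidi_snps = m,
                          passed_heidi = NA))
  }
  d <- (bzy[idx] / bzx[idx]) - (bzy[1] / bzx[1])
  z <- d / sd_d
  t_heidi <- sum(z^2)
  corr_z <- psd_clip(v_d / tcrossprod(sd_d))

  ev <- eigen(corr_z, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  # Satterthwaite: T ~ c * chisq(nu), c = sum(l^2)/sum(l), nu = sum(l)^2/sum(l^2)
  cc <- sum(ev^2) / sum(ev)
  nu <- sum(ev)^2 / sum(ev^2)
  p_satt <- pchisq(t_heidi / cc, df = nu, lower.tail = FALSE)

  p_mc <- withr::with_seed(as.integer(seed), {
    L <- chol(corr_z + diag(1e-10, m))
    zz <- matrix(rnorm(n_draws * m), n_draws, m) %*% L
    tt <- rowSums(zz^2)
    (1 + sum(tt >= t_heidi)) / (n_draws + 1)
  })
  tibble::tibble(t_heidi = t_heidi, p_heidi = p_mc, p_heidi_satt = p_satt,
                 n_heidi_snps = m, passed_heidi = p_mc >= 0.01)
}

#' Run the SMR + HEIDI analysis for one gene
#'
#' Chains the per-gene steps: top cis-eQTL selection, matching of the GWAS
#' record, the SMR ratio test, HEIDI SNP selection and the HEIDI test.
#'
#' @param eqtl per-SNP eQTL records (`snp`, `position`, `b_zx`, `se_zx`,
#'   `p_zx`); alternatively a `summary_scenario`, in which case `gwas`,
#'   `ld` and the gene coordinates are taken from it.
#' @param gwas per-SNP outcome records (`snp`, `b_zy`, `se_zy`).
#' @param ld signed LD r matrix.
#' @param gene_start,gene_end gene coordinates.
#' @param gene,tissue labels for the output row.
#' @param cis_window,p_max top-eQTL selection parameters.
#' @param heidi_method `"bootstrap"` (default) evaluates the HEIDI null by
#'   the selection-replicating parametric bootstrap of [heidi_bootstrap()],
#'   which stays calibrated when the window admits marginal-strength
#'   eQTLs; `"delta"` uses the analytic first-order route of
#'   [heidi_test()]. The delta-method p-values are reported alongside in
#'   either case.
#' @param heidi_seed,heidi_draws,heidi_boot_draws HEIDI Monte-Carlo
#'   settings (`heidi_draws` for the delta-method null, `heidi_boot_draws`
#'   for the bootstrap).
#' @param ... passed to [select_heidi_snps()].
#' @return one-row tibble: `gene`, `tissue`, `top_snp`, `b_xy`, `se_xy`,
#'   `p_smr`, `p_heidi`, `p_heidi_delta`, `p_heidi_satt`, `n_heidi_snps`,
#'   `passed_heidi`; `NULL` if the gene has no qualifying cis-eQTL.
#' @export
run_smr <- function(eqtl, gwas = NULL, ld = NULL, gene_start = NULL,
                    gene_end = NULL, gene = NULL, tissue = NA_character_,
                    cis_window = 1e6, p_max = 5e-8,
                    heidi_method = c("bootstrap", "delta"),
                    heidi_seed = 1L, heidi_draws = 1e5,
                    heidi_boot_draws = 2000, ...) {
  heidi_method <- match.arg(heidi_method)
  if (inherits(eqtl, "summary_scenario")) {
    sc <- eqtl
    gene_start <- gene_start %||% sc$gene_start
    gene_end <- gene_end %||% sc$gene_end
    gene <- gene %||% sc$gene
    ld <- ld %||% sc$ld
    gwas <- gwas %||% sc$snps[c("snp", "b_zy", "se_zy")]
    eqtl <- sc$snps[c("snp", "position", "b_zx", "se_zx", "p_zx")]
  }
  top <- pick_top_cis_eqtl(eqtl, gene_start, gene_end, cis_window, p_max)
  if (is.null(top)) return(NULL)
  cis <- dplyr::filter(eqtl,
                       .data$position >= gene_start - cis_window,
                       .data$position <= gene_end + cis_window)
  merged <- dplyr::inner_join(cis, gwas, by = "snp")
  top_m <- merged[merged$snp == top$snp, , drop = FALSE]
  if (nrow(top_m) == 0) abort("top cis-eQTL has no GWAS record")
  smr <- smr_test(top_m$b_zx, top_m$se_zx, top_m$b_zy, top_m$se_zy)
  sel <- select_heidi_snps(merged, ld, top$snp, ...)
  heidi <- heidi_test(dplyr::bind_rows(top_m, sel), ld, top$snp,
                      n_draws = heidi_draws, seed = heidi_seed)
  if (heidi_method == "bootstrap") {
    boot <- heidi_bootstrap(merged, ld, n_draws = heidi_boot_draws,
                            seed = heidi_seed, ...)
    p_heidi <- boot$p_heidi
    n_heidi <- boot$n_heidi_snps
    passed <- boot$passed_heidi
  } else {
    p_heidi <- heidi$p_heidi
    n_heidi <- heidi$n_heidi_snps
    passed <- heidi$passed_heidi
  }
  tibble::tibble(
    gene = gene %||% NA_character_, tissue = tissue, top_snp = top$snp,
    b_xy = smr$b_xy, se_xy = smr$se_xy, t_smr = smr$t_smr, p_smr = smr$p_smr,
    p_heidi = p_heidi, p_heidi_delta = heidi$p_heidi,
    p_heidi_satt = heidi$p_heidi_satt,
    n_heidi_snps = n_heidi, passed_heidi = passed
  )
}

#' Multiple-testing flags for SMR p-values
#'
#' The Bonferroni threshold across the tested genes is `alpha / n_genes`,
#' reported rounded to one significant digit (0.05/15 genes = 0.003);
#' p-values between the threshold and `alpha` are suggestive.
#'
#' @param p SMR p-values.
#' @param n_genes number of genes tested (default 15).
#' @param alpha family-wise level (default 0.05).
#' @return list with `threshold` (the reported rounded threshold) and
#'   `flag` (factor: significant / suggestive / null).
#' @examples
#' smr_multiple_testing(c(1e-4, 0.01, 0.2))
#' @export
smr_multiple_testing <- function(p, n_genes = 15, alpha = 0.05) {
  thr <- signif(alpha / n_genes, 1)
  flag <- ifelse(p < thr, "significant",
                 ifelse(p < alpha, "suggestive", "null"))
  list(threshold = thr,
       flag = factor(flag, levels = c("significant", "suggestive", "null")))
}
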