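#' HEIDI p-value by selection-replicating parametric bootstrap
#'
#' Evaluates the HEIDI null distribution by simulating the *entire*
#' procedure under the single-shared-causal-variant null: plug-in true
#' eQTL effects are the observed `b_zx` over the full cis window, plug-in
#' outcome effects are `b_xy_hat * b_zx` with `b_xy_hat` the observed
#' top-SNP ratio, and every draw redoes top-SNP selection, the weak-
#' instrument and LD exclusions, and the first-order-delta heterogeneity
#' statistic. This accounts for two effects the analytic (delta + normal)
#' null ignores: the over-dispersion of the ratio estimate at SNPs near
#' the eQTL admission bound, and the conditioning induced by selecting the
#' top SNP and the HEIDI SNP set from the same data.
#'
#' @param records full cis-window records: `snp`, `b_zx`, `se_zx`, `p_zx`,
#'   `b_zy`, `se_zy`.
#' @param ld signed LD r matrix with dimnames covering `records$snp`.
#' @param p_eqtl_max,r2_top_max,m_max,m_min HEIDI selection parameters
#'   (see [select_heidi_snps()]; `m_min` is the minimum SNP count, 3).
#' @param n_draws bootstrap draws (default 2000; the decision boundary is
#'   p = 0.01, so the Monte-Carlo standard error there is ~0.002).
#' @param seed seed for the draws (caller RNG state is restored).
#' @return tibble `t_heidi`, `p_heidi`, `n_heidi_snps`, `passed_heidi`
#'   (`NA` when fewer than `m_min` SNPs qualify).
#' @export
heidi_bootstrap <- function(records, ld, p_eqtl_max = 1.6e-3,
                            r2_top_max = 0.9, m_max = 20, m_min = 3,
                            r2_min = NULL, n_draws = 2000, seed = 1L) {
  if (!is.null(r2_min)) {
    warn("r2_min is not supported by the bootstrap HEIDI null; ignored")
  }
  ids <- records$snp
  R <- ld[ids, ids]
  bzx <- records$b_zx; sezx <- records$se_zx
  bzy <- records$b_zy; sezy <- records$se_zy
  obs <- heidi_stat_block(matrix(bzx, 1), matrix(bzy, 1), sezx, sezy, R,
                          p_eqtl_max, r2_top_max, m_max, m_min)
  if (is.na(obs$t[1])) {
    return(tibble::tibble(t_heidi = NA_real_, p_heidi = NA_real_,
                          n_heidi_snps = obs$m[1], passed_heidi = NA))
  }
  top <- obs$top[1]
  mu_x <- bzx
  mu_y <- (bzy[top] / bzx[top]) * bzx     # plug-in single-causal-variant null
  m <- length(ids)
  boot <- withr::with_seed(as.integer(seed), {
    L <- chol(psd_clip(R) + diag(1e-10, m))
    ex <- (matrix(rnorm(n_draws * m), n_draws) %*% L) *
      matrix(sezx, n_draws, m, byrow = TRUE)
    ey <- (matrix(rnorm(n_draws * m), n_draws) %*% L) *
      matrix(sezy, n_draws, m, byrow = TRUE)
    heidi_stat_block(sweep(ex, 2, mu_x, "+"), sweep(ey, 2, mu_y, "+"),
                     sezx, sezy, R, p_eqtl_max, r2_top_max, m_max, m_min)
  })
  valid <- !is.na(boot$t)
  p <- (1 + sum(boot$t[valid] >= obs$t[1])) / (1 + sum(valid))
  tibble::tibble(t_heidi = obs$t[1], p_heidi = p,
                 n_heidi_snps = obs$m[1], passed_heidi = p >= 0.01)
}

# Vectorized HEIDI statistic over rows of (BX, BY): per-row top selection,
# SNP admission, first-order-delta standardization, T = sum z^2.
heidi_stat_block <- function(BX, BY, sezx, sezy, R, p_eqtl_max, r2_top_max,
                             m_max, m_min) {
  nd <- nrow(BX); m <- ncol(BX)
  SX <- matrix(sezx, nd, m, byrow = TRUE)
  SY <- matrix(sezy, nd, m, byrow = TRUE)
  P <- 2 * pnorm(-abs(BX / SX))
  top <- max.col(-P, ties.method = "first")
  ti <- cbind(seq_len(nd), top)
  bx_t <- BX[ti]; by_t <- BY[ti]
  sx_t <- SX[ti]; sy_t <- SY[ti]
  Rt <- t(R)[top, , drop = FALSE]                 # r(i, top_j), nd x m
  var_i <- SY^2 / BX^2 + BY^2 * SX^2 / BX^4
  var_t <- sy_t^2 / bx_t^2 + by_t^2 * sx_t^2 / bx_t^4
  cov_it <- Rt * (SY * sy_t / (BX * bx_t) +
                  BY * by_t * SX * sx_t / (BX^2 * bx_t^2))
  d <- BY / BX - by_t / bx_t
  v <- pmax(var_i + var_t - 2 * cov_it, .Machine$double.eps)
  z2 <- d^2 / v
  keep <- (P <= p_eqtl_max) & (Rt^2 <= r2_top_max)
  keep[ti] <- FALSE
  cnt <- rowSums(keep)
  over <- which(cnt > m_max)
  for (j in over) {                               # cap rarely binds
    kj <- which(keep[j, ])
    drop_j <- kj[order(P[j, kj])][-seq_len(m_max)]
    keep[j, drop_j] <- FALSE
  }
  tvals <- rowSums(z2 * keep)
  mfinal <- rowSums(keep)
  tvals[mfinal < m_min] <- NA_real_
  list(t = tvals, m = as.integer(mfinal), top = top)
}
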