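#' Build a genetic risk score from an instrument set
#'
#' The weighted score follows the standard rescaled form
#' \deqn{GRS = (\beta_1 SNP_1 + \cdots + \beta_n SNP_n) \times n / \sum_i \beta_i,}
#' i.e. a weighted allele count rescaled so its units remain allele counts
#' (equivalently, `n` times the beta-weighted mean dosage). The unweighted
#' score is the plain sum of effect-allele dosages. Dosages are oriented to
#' the instrument set's effect allele: SNPs flagged `flipped` contribute
#' `2 - g`.
#'
#' Missing dosages are mean-imputed per SNP (with a message), keeping the
#' scored sample size constant.
#'
#' @param genotypes a `genotype_matrix` (or plain dosage matrix with SNP
#'   column names).
#' @param instruments an `instrument_set` from [orient_weights()] (columns
#'   `snp`, `beta`, optional `flipped`).
#' @param weighting `"weighted"` or `"unweighted"`.
#' @return A tibble `person_id`, `grs`, with attributes `weighting` and
#'   `n_snps`.
#' @examples
#' inst <- orient_weights(tibble::tibble(
#'   snp = c("a", "b"), effect_allele = "A", other_allele = "G",
#'   beta = c(0.5, 1.5)))
#' dos <- matrix(c(1, 2), 1, dimnames = list(NULL, c("a", "b")))
#' build_grs(dos, inst)  # (0.5*1 + 1.5*2) * 2 / 2 = 3.5
#' @export
build_grs <- function(genotypes, instruments,
                      weighting = c("weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  if (nrow(instruments) == 0) abort("empty instrument set: no score can be built")
  missing <- setdiff(instruments$snp, colnames(dos))
  if (length(missing) > 0) {
    abort(paste0("instrument SNPs absent from genotypes: ",
                 paste(missing, collapse = ", ")))
  }
  g <- dos[, instruments$snp, drop = FALSE]
  flipped <- instruments$flipped %||% rep(FALSE, nrow(instruments))
  if (any(flipped)) {
    g[, flipped] <- 2 - g[, flipped, drop = FALSE]
  }
  if (anyNA(g)) {
    n_imp <- sum(is.na(g))
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
    rlang::inform(sprintf("mean-imputed %d missing dosage value(s)", n_imp))
  }
  beta <- instruments$beta
  if (weighting == "weighted") {
    if (sum(beta) == 0) abort("sum of instrument weights is zero: cannot scale")
    score <- drop(g %*% beta) * nrow(instruments) / sum(beta)
  } else {
    score <- rowSums(g)
  }
  out <- tibble::tibble(person_id = seq_len(nrow(g)), grs = score)
  attr(out, "weighting") <- weighting
  attr(out, "n_snps") <- nrow(instruments)
  out
}

#' First-stage instrument-strength diagnostics
#'
#' Simple linear regression of (adjusted) blood pressure on the genetic risk
#' score, returning the variance explained and the F statistic
#' `F = (r2/k) / ((1 - r2)/(n - k - 1))` with `k = 1` (the score is the
#' single instrument). F above 10 is the conventional strong-instrument
#' bar.
#'
#' @param bp numeric vector of adjusted blood pressure (mmHg).
#' @param grs numeric vector (or the tibble from [build_grs()]).
#' @return tibble with `r_squared`, `f_stat`, `n`, `k`.
#' @export
first_stage_stats <- function(bp, grs) {
  if (is.data.frame(grs)) grs <- grs$grs
  keep <- !is.na(bp) & !is.na(grs)
  bp <- bp[keep]; grs <- grs[keep]
  n <- length(bp)
  if (n <= 2) abort("need more than 2 complete observations")
  if (var(grs) == 0) abort("zero-variance genetic risk score")
  r2 <- cor(bp, grs)^2
  k <- 1
  tibble::tibble(
    r_squared = r2,
    f_stat = (r2 / k) / ((1 - r2) / (n - k - 1)),
    n = n, k = k
  )
}
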