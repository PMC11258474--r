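#' @importFrom rlang %||% abort warn .data
#' @importFrom stats pchisq pnorm qnorm rnorm runif rbinom coef vcov lm var
#'   cor sd quantile setNames ks.test plogis
NULL

#' Round half away from zero
#'
#' Base `round()` rounds half to even; tabulated percentages here follow the
#' conventional half-up rule so that printed one-decimal percentages match
#' hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' AR-1 correlation matrix
#'
#' @param n dimension.
#' @param rho lag-1 correlation, in [0, 1).
#' @return n x n matrix with entries rho^|i-j|.
#' @export
ar1_matrix <- function(n, rho) {
  stopifnot(n >= 1, rho >= 0, rho < 1)
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

# Clip eigenvalues to keep a correlation matrix positive semi-definite,
# then restore the unit diagonal.
psd_clip <- function(mat, tol = 1e-10) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  if (all(e$values >= -tol)) return(mat)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(out), tol))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

# Derive a stage-specific 31-bit seed from a root seed so that each pipeline
# stage consumes an independent, reproducible stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 2654435 + h * 97 + 13) %% .Machine$integer.max)
}
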