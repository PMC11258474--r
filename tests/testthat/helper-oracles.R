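# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (loops, exhaustive enumeration) kept
# separate from the package's vectorized code paths.

# Weighted score by double loop, straight off the formula
# (b1*g1 + ... + bn*gn) * n / sum(b).
oracle_grs <- function(dosages, beta) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + beta[j] * dosages[i, j]
    out[i] <- s * m / sum(beta)
  }
  out
}

# Greedy-clump oracle by exhaustive enumeration: among all admissible
# subsets (every pair below the r2 threshold) that are maximal (no further
# SNP can be added), the greedy result is the lexicographically smallest
# under the p-value ranking (ties by position then id). Enumerates all 2^m
# subsets; m <= 12.
oracle_clump <- function(candidates, r2, r2_max) {
  m <- nrow(candidates)
  stopifnot(m <= 12)
  ord <- order(candidates$p, candidates$position, candidates$snp)
  adm <- r2[candidates$snp[ord], candidates$snp[ord], drop = FALSE] < r2_max
  best <- NULL
  for (code in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0)
    if (length(sel) == 0) next
    ok <- TRUE
    for (a in sel) for (b in sel) if (a != b && !adm[a, b]) ok <- FALSE
    if (!ok) next
    maximal <- TRUE
    for (extra in setdiff(seq_len(m), sel)) {
      if (all(adm[extra, sel])) maximal <- FALSE
    }
    if (!maximal) next
    if (is.null(best)) {
      best <- sel
    } else {
      # lexicographic comparison on sorted rank vectors
      a <- sort(sel); b <- sort(best)
      k <- min(length(a), length(b))
      cmp <- 0
      for (i in seq_len(k)) {
        if (a[i] != b[i]) { cmp <- ifelse(a[i] < b[i], -1, 1); break }
      }
      if (cmp == 0) cmp <- ifelse(length(a) > length(b), -1, 0)
      if (cmp < 0) best <- sel
    }
  }
  candidates$snp[ord][sort(best)]
}

# Random candidate window + LD panel for clumping tests.
make_clump_case <- function(seed, n_snps = 12, n_panel = 400) {
  set.seed(seed)
  rho <- runif(1, 0.2, 0.9)
  lat <- matrix(rnorm(n_panel * n_snps), n_panel, n_snps)
  for (k in 2:n_snps) {
    lat[, k] <- rho * lat[, k - 1] + sqrt(1 - rho^2) * lat[, k]
  }
  maf <- runif(n_snps, 0.1, 0.5)
  q0 <- qnorm((1 - maf)^2)
  q1 <- qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  dos <- sweep(lat, 2, q0, ">") + sweep(lat, 2, q1, ">")
  storage.mode(dos) <- "double"
  colnames(dos) <- sprintf("s%02d", seq_len(n_snps))
  cand <- tibble::tibble(
    snp = colnames(dos),
    chromosome = 1L,
    position = seq_len(n_snps) * 1000L,
    freq = maf,
    beta = rnorm(n_snps, 0, 0.5),
    se = 0.05,
    p = runif(n_snps, 1e-12, 1e-8)
  )
  list(candidates = cand, ld = ld_from_panel(dos))
}

# Tiny deficit table with known values.
make_deficit_tbl <- function(rows) {
  k <- length(rows[[1]])
  out <- do.call(rbind, rows)
  colnames(out) <- deficit_item_names(k)
  tibble::as_tibble(out)
}
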