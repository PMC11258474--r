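#' Simulate LD-blocked biallelic genotype dosages
#'
#' Genotypes are generated per LD block from a latent multivariate normal
#' with AR-1 correlation `rho`, thresholded to dosages {0, 1, 2} at each
#' SNP's Hardy-Weinberg genotype-frequency quantiles for its target minor
#' allele frequency. Blocks are independent; SNPs within a block are placed
#' on one chromosome inside the matching [default_gene_regions()] region
#' (or at generic positions when the block count differs from the map).
#'
#' @param config a [sim_config()].
#' @return An object of class `genotype_matrix`: a list with `dosages`
#'   (n_individuals x n_snps numeric matrix, column names = SNP ids) and
#'   `snp_meta` (tibble: `snp`, `block`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `maf` target, `maf_observed`
#'   recomputed from dosages).
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 500, seed = 42))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  blocks <- config$ld_blocks
  regions <- default_gene_regions()

  withr::local_seed(derive_seed(config$seed, "genotypes"))
  dos_list <- vector("list", length(blocks))
  meta_list <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    m <- as.integer(blocks[[b]]$n_snps)
    rho <- blocks[[b]]$rho
    maf <- runif(m, blocks[[b]]$maf_range[1], blocks[[b]]$maf_range[2])
    # AR-1 latent field built recursively: z_k = rho z_{k-1} + sqrt(1-rho^2) e_k
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho > 0) {
      for (k in 2:m) z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * z[, k]
    }
    q0 <- qnorm((1 - maf)^2)             # below: 0 copies of effect allele
    q1 <- qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
    g <- sweep(z, 2, q0, ">") + sweep(z, 2, q1, ">")
    storage.mode(g) <- "double"

    if (b <= nrow(regions)) {
      chr <- regions$chromosome[b]
      pos <- regions$start[b] + as.integer(seq(5000, 95000, length.out = m))
    } else {
      chr <- b
      pos <- 1000000L + 12000L * seq_len(m)
    }
    ids <- sprintf("rs%d_%d", b, seq_len(m))
    colnames(g) <- ids
    dos_list[[b]] <- g
    meta_list[[b]] <- tibble::tibble(
      snp = ids, block = b, chromosome = as.integer(chr),
      position = as.integer(pos),
      effect_allele = "A", other_allele = "G", maf = maf
    )
  }
  dosages <- do.call(cbind, dos_list)
  meta <- dplyr::bind_rows(meta_list)
  meta$maf_observed <- pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2)
  structure(list(dosages = dosages, snp_meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(utils::head(x$snp_meta, 5))
  invisible(x)
}

#' Pairwise LD (r and r-squared) from a dosage panel
#'
#' @param genotypes a `genotype_matrix` or a plain dosage matrix.
#' @param snps optional SNP ids to restrict to.
#' @return list with `r` (signed dosage correlation matrix) and `r2`.
#' @export
ld_from_panel <- function(genotypes, snps = NULL) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  if (!is.null(snps)) {
    missing <- setdiff(snps, colnames(dos))
    if (length(missing) > 0) {
      warn(paste0("SNPs absent from LD reference dropped: ",
                  paste(missing, collapse = ", ")))
    }
    dos <- dos[, intersect(snps, colnames(dos)), drop = FALSE]
  }
  r <- suppressWarnings(cor(dos))
  r[is.na(r)] <- 0
  diag(r) <- 1
  list(r = r, r2 = r^2)
}
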