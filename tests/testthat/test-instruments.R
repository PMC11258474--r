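region_fixture <- function() {
  tibble::tibble(gene = "G1", drug_class = "BB", chromosome = 1L,
                 start = 1000000L, end = 2000000L)
}

test_that("candidate selection applies the window, significance and MAF rules strictly", {
  reg <- region_fixture()
  gwas <- tibble::tibble(
    snp = sprintf("s%d", 1:7),
    chromosome = c(1L, 1L, 1L, 1L, 1L, 1L, 2L),
    position = c(900000L, 899999L, 2100000L, 2100001L, 1500000L, 1500001L, 1500000L),
    freq = c(0.3, 0.3, 0.3, 0.3, 0.01, 0.995, 0.3),
    beta = 0.5, se = 0.05,
    p = c(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9)
  )
  out <- select_candidates(gwas, reg)
  # flank boundary: exactly start-100kb and end+100kb stay, one bp beyond drops;
  # MAF exactly 0.01 (either allele) drops; other chromosome drops
  expect_setequal(out$snp, c("s1", "s3"))

  gwas2 <- dplyr::mutate(gwas[5:5, ], freq = 0.3, p = 5e-8)
  expect_warning(out2 <- select_candidates(gwas2, reg), "no candidate")
  expect_equal(nrow(out2), 0)
  gwas2$p <- 4.99e-8
  expect_equal(nrow(select_candidates(gwas2, reg)), 1)

  # genome-wide class ignores the region bounds
  expect_equal(nrow(select_candidates(gwas, NULL)), 5)
})

test_that("greedy clumping keeps the smaller-p SNP in perfect LD and everything when independent", {
  cand <- tibble::tibble(snp = c("a", "b"), chromosome = 1L,
                         position = c(100L, 200L), freq = 0.3,
                         beta = 0.5, se = 0.05, p = c(1e-10, 1e-9))
  r_perfect <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(ld_clump(cand, r_perfect, r2_max = 0.4)$snp, "a")
  r_zero <- diag(2); dimnames(r_zero) <- dimnames(r_perfect)
  expect_setequal(ld_clump(cand, r_zero, r2_max = 0.4)$snp, c("a", "b"))
})

test_that("clumping is invariant to input row order and respects its threshold", {
  for (seed in 1:20) {
    case <- make_clump_case(seed)
    for (r2m in c(0.4, 0.1, 0.01)) {
      kept <- ld_clump(case$candidates, case$ld, r2_max = r2m)
      shuf <- case$candidates[sample(nrow(case$candidates)), ]
      expect_identical(ld_clump(shuf, case$ld, r2_max = r2m)$snp, kept$snp)
      if (nrow(kept) > 1) {
        sub <- case$ld$r2[kept$snp, kept$snp]
        expect_true(all(sub[upper.tri(sub)] < r2m))
      }
    }
    n_kept <- vapply(c(0.4, 0.1, 0.01), function(r2m)
      nrow(ld_clump(case$candidates, case$ld, r2_max = r2m)), 1L)
    expect_true(all(diff(n_kept) <= 0))
  }
})

test_that("greedy clumping agrees with the exhaustive oracle on small windows", {
  for (seed in 1:10) {
    case <- make_clump_case(seed + 500)
    kept <- ld_clump(case$candidates, case$ld, r2_max = 0.4)
    expect_identical(sort(kept$snp),
                     sort(oracle_clump(case$candidates, case$ld$r2, 0.4)))
  }
})

test_that("SNPs absent from the LD reference are dropped with a warning", {
  case <- make_clump_case(3)
  cand <- dplyr::bind_rows(case$candidates, dplyr::mutate(
    case$candidates[1, ], snp = "missing_snp", p = 1e-15))
  expect_warning(kept <- ld_clump(cand, case$ld, r2_max = 0.4), "absent")
  expect_false("missing_snp" %in% kept$snp)
})

test_that("weight orientation flips alleles and signs and drops zero betas", {
  snps <- tibble::tibble(
    snp = c("a", "b", "c"),
    effect_allele = c("A", "C", "T"), other_allele = c("G", "T", "A"),
    freq = c(0.2, 0.6, 0.4), beta = c(-0.3, 0.5, 0)
  )
  expect_warning(out <- orient_weights(snps), "zero-beta")
  expect_equal(out$snp, c("a", "b"))
  expect_equal(out$effect_allele, c("G", "C"))
  expect_equal(out$other_allele, c("A", "T"))
  expect_equal(out$beta, c(0.3, 0.5))
  expect_equal(out$freq, c(0.8, 0.6))
  expect_equal(out$flipped, c(TRUE, FALSE))
})

test_that("orientation leaves the score's association with BP unchanged", {
  cfg <- sim_config(n_individuals = 4000, seed = 44)
  g <- simulate_genotypes(cfg)
  co <- adjust_bp(simulate_cohort(g, cfg))
  nz <- which(cfg$snp_effects_sbp != 0)[1:10]
  meta <- g$snp_meta[nz, ]
  signs <- rep(c(1, -1), 5)             # flip half the SNPs' reporting
  raw <- tibble::tibble(snp = meta$snp, effect_allele = meta$effect_allele,
                        other_allele = meta$other_allele,
                        beta = signs * cfg$snp_effects_sbp[nz])
  oriented <- orient_weights(raw)
  grs_oriented <- build_grs(g, oriented)
  # raw signed score: same dosages, signed weights
  raw_score <- drop(g$dosages[, raw$snp] %*% raw$beta)
  r2_oriented <- first_stage_stats(co$sbp_adj, grs_oriented)$r_squared
  r2_raw <- cor(co$sbp_adj, raw_score)^2
  expect_equal(r2_oriented, r2_raw, tolerance = 1e-12)
})

test_that("a drug class with no passing SNPs yields an empty, usable set", {
  cfg <- sim_config(n_individuals = 2000, seed = 51)
  g <- simulate_genotypes(cfg)
  gwas <- simulate_gwas_summary(g, cfg, "sbp")
  ld <- ld_from_panel(g)
  sets <- suppressWarnings(select_instruments(gwas, ld = ld, exposure = "sbp"))
  expect_equal(nrow(sets$ARB), 0)
  expect_gt(nrow(sets$BB), 0)
  expect_gt(nrow(sets$genome_wide), 0)
  expect_error(build_grs(g, sets$ARB), "empty")
})
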