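eqtl_fixture <- function() {
  tibble::tibble(
    snp = c("a", "b", "c", "d"),
    position = c(500000L, 900000L, 2050000L, 2000001L + 1000000L),
    b_zx = c(0.5, 0.6, 0.4, 0.7), se_zx = 0.05,
    p_zx = c(1e-12, 1e-20, 1e-9, 1e-30)
  )
}

test_that("top cis-eQTL selection honours the 1 Mb window and the p threshold", {
  eq <- eqtl_fixture()
  # gene on [1e6, 2e6]; SNP d sits at end + 1Mb + 1bp: outside the cis window
  top <- pick_top_cis_eqtl(eq, 1000000L, 2000000L)
  expect_equal(top$snp, "b")
  # a single passing SNP is returned as-is
  one <- pick_top_cis_eqtl(eq[1, ], 1000000L, 2000000L)
  expect_equal(one$snp, "a")
  # no SNP below 5e-8: the gene is skipped
  weak <- dplyr::mutate(eq, p_zx = pmax(p_zx, 5e-8))
  expect_message(out <- pick_top_cis_eqtl(weak, 1000000L, 2000000L), "skipped")
  expect_null(out)
})

test_that("the SMR ratio test reproduces its closed-form cases", {
  null <- smr_test(0.5, 0.05, 0, 0.02)
  expect_equal(null$b_xy, 0)
  expect_equal(null$t_smr, 0)
  expect_equal(null$p_smr, 1)
  z6 <- smr_test(6, 1, 6, 1)
  expect_equal(z6$t_smr, 18)
  expect_equal(z6$p_smr, pchisq(18, 1, lower.tail = FALSE))
  expect_error(smr_test(0, 0.05, 0.1, 0.02), "undefined")
  expect_error(smr_test(0.5, -0.1, 0.1, 0.02), "standard errors")
})

test_that("T_SMR is symmetric in the two z-statistics and scale-invariant", {
  a <- smr_test(0.8, 0.1, 0.03, 0.015)
  b <- smr_test(0.03, 0.015, 0.8, 0.1)
  expect_equal(a$t_smr, b$t_smr)
  expect_equal(a$p_smr, b$p_smr)
  s <- smr_test(0.8 * 7, 0.1 * 7, 0.03 * 7, 0.015 * 7)
  expect_equal(a$t_smr, s$t_smr)
})

test_that("the chi-square SMR p-value matches a parametric Monte-Carlo oracle", {
  # regime of use: the exposure is the *top* cis-eQTL, selected at
  # p < 5e-8 and in practice far beyond it (z = 15 here)
  b_zx <- 1.5; se_zx <- 0.1; se_zy <- 0.02
  obs <- smr_test(b_zx, se_zx, 1.94 * se_zy, se_zy)
  set.seed(123)
  n_sim <- 1e5
  bzx_star <- rnorm(n_sim, b_zx, se_zx)       # eQTL signal present
  bzy_star <- rnorm(n_sim, 0, se_zy)          # outcome null
  t_star <- smr_test(bzx_star, se_zx, bzy_star, se_zy)$t_smr
  p_emp <- mean(t_star >= obs$t_smr)
  expect_lt(abs(obs$p_smr - p_emp) / p_emp, 0.10)
  # at a weaker (borderline-threshold) eQTL the approximation degrades but
  # stays close in absolute terms
  obs8 <- smr_test(0.8, 0.1, 1.94 * se_zy, se_zy)
  t8 <- smr_test(rnorm(n_sim, 0.8, 0.1), 0.1, rnorm(n_sim, 0, se_zy), se_zy)$t_smr
  expect_lt(abs(obs8$p_smr - mean(t8 >= obs8$t_smr)), 0.01)
})

test_that("HEIDI SNP selection applies the weak-instrument and LD exclusions", {
  eq <- tibble::tibble(
    snp = c("top", sprintf("s%02d", 1:30)),
    position = 1000000L + 1000L * (0:30),
    b_zx = 0.5, se_zx = 0.05,
    p_zx = c(1e-20, 2e-3, seq(1e-6, 1.5e-3, length.out = 29))
  )
  ld <- diag(31) * 0.0
  dimnames(ld) <- list(eq$snp, eq$snp)
  ld[, "top"] <- ld["top", ] <- 0.3
  ld["s02", "top"] <- ld["top", "s02"] <- sqrt(0.95)  # r2 = 0.95 with top
  diag(ld) <- 1
  sel <- select_heidi_snps(eq, ld, "top")
  expect_false("top" %in% sel$snp)        # difference set excludes the top SNP
  expect_false("s01" %in% sel$snp)        # p_zx = 2e-3 > 1.6e-3
  expect_false("s02" %in% sel$snp)        # r2 > 0.9 with the top SNP
  expect_equal(nrow(sel), 20)             # 28 eligible capped at m_max
  expect_true(all(sel$p_zx <= sort(eq$p_zx[-(1:3)])[20]))
})

test_that("HEIDI needs at least three informative SNPs", {
  sc <- simulate_summary_scenario("causal", n_snps = 5, seed = 3)
  few <- sc$snps[1:3, ]
  out <- heidi_test(few, sc$ld, few$snp[1])
  expect_true(is.na(out$p_heidi))
  expect_equal(out$n_heidi_snps, 2)
})

test_that("exactly proportional effects give zero heterogeneity", {
  # the noiseless identity: when every SNP carries b_zy = b_xy * b_zx
  # exactly, all per-SNP ratios coincide, so every difference is zero
  sc <- simulate_summary_scenario("causal", b_xy_true = 0.3, seed = 6)
  rec <- sc$snps[c(15, 10, 12, 18, 20), ]
  rec$b_zx <- rec$b_zx_true
  rec$b_zy <- 0.3 * rec$b_zx_true
  out <- heidi_test(rec, sc$ld, rec$snp[1], n_draws = 5000, seed = 2)
  expect_equal(out$t_heidi, 0)
  expect_gt(out$p_heidi, 0.99)
  expect_gt(out$p_heidi_satt, 0.99)
})

test_that("HEIDI p-values do not depend on the ordering of the SNP set", {
  sc <- simulate_summary_scenario("causal", seed = 14)
  merged <- sc$snps
  sel <- select_heidi_snps(merged, sc$ld, "esnp_15")
  top <- merged[merged$snp == "esnp_15", ]
  a <- heidi_test(dplyr::bind_rows(top, sel), sc$ld, "esnp_15",
                  n_draws = 20000, seed = 5)
  perm <- sel[rev(seq_len(nrow(sel))), ]
  b <- heidi_test(dplyr::bind_rows(top, perm), sc$ld, "esnp_15",
                  n_draws = 20000, seed = 5)
  expect_equal(a$t_heidi, b$t_heidi, tolerance = 1e-12)
  expect_equal(a$p_heidi_satt, b$p_heidi_satt, tolerance = 1e-12)
  expect_equal(a$p_heidi, b$p_heidi, tolerance = 0.02)  # Monte-Carlo jitter only
})

test_that("Monte-Carlo and Satterthwaite HEIDI p-values agree within a factor of two", {
  ratios <- c()
  for (s in 1:40) {
    sc <- simulate_summary_scenario(if (s %% 2) "causal" else "linkage", seed = s)
    row <- run_smr(sc, heidi_method = "delta", heidi_draws = 20000,
                   heidi_seed = s)
    if (!is.na(row$p_heidi_delta) && row$p_heidi_delta >= 0.01 &&
        row$p_heidi_delta <= 0.5) {
      ratios <- c(ratios, row$p_heidi_satt / row$p_heidi_delta)
    }
  }
  expect_gt(length(ratios), 5)
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("the bootstrap HEIDI null is seeded and flags linkage", {
  sc <- simulate_summary_scenario("causal", seed = 23)
  a <- run_smr(sc, heidi_seed = 11, heidi_draws = 5000, heidi_boot_draws = 1000)
  b <- run_smr(sc, heidi_seed = 11, heidi_draws = 5000, heidi_boot_draws = 1000)
  expect_identical(a, b)
  expect_true(a$n_heidi_snps <= 20)

  rej <- vapply(1:30, function(s) {
    r <- run_smr(simulate_summary_scenario("linkage", seed = s),
                 heidi_seed = s, heidi_draws = 2000, heidi_boot_draws = 1500)
    !is.na(r$p_heidi) && r$p_heidi < 0.01
  }, TRUE)
  expect_gt(mean(rej), 0.2)           # power far above the 1% null rate
})

test_that("SMR multiple-testing flags use the 15-gene Bonferroni threshold", {
  mt <- smr_multiple_testing(c(1e-4, 0.0029, 0.003, 0.01, 0.2))
  expect_equal(mt$threshold, 0.003)
  expect_equal(as.character(mt$flag),
               c("significant", "significant", "suggestive", "suggestive", "null"))
})
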