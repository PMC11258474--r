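test_that("genotype generation is deterministic and holds target allele frequencies", {
  cfg <- sim_config(n_individuals = 2000, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$snp_meta, g2$snp_meta)
  expect_true(all(g1$dosages %in% c(0, 1, 2)))
  expect_equal(ncol(g1$dosages), nrow(g1$snp_meta))
  # observed MAF within 3 Monte-Carlo SEs of the target, and within 0.05
  se <- sqrt(g1$snp_meta$maf * (1 - g1$snp_meta$maf) / (2 * cfg$n_individuals))
  dev <- abs(g1$snp_meta$maf_observed - g1$snp_meta$maf)
  expect_true(all(dev < 3 * se))
  expect_true(all(dev < 0.05))
})

test_that("uncorrelated blocks give near-independent dosages", {
  cfg <- sim_config(
    n_individuals = 10000,
    ld_blocks = list(list(n_snps = 8L, maf_range = c(0.5, 0.5), rho = 0)),
    snp_effects_sbp = rep(0, 8), seed = 7
  )
  g <- simulate_genotypes(cfg)
  r <- ld_from_panel(g)$r
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
})

test_that("high AR-1 latent correlation maps to strong dosage LD", {
  cfg <- sim_config(
    n_individuals = 10000,
    ld_blocks = list(list(n_snps = 6L, maf_range = c(0.3, 0.45), rho = 0.9)),
    snp_effects_sbp = rep(0, 6), seed = 8
  )
  g <- simulate_genotypes(cfg)
  r2 <- ld_from_panel(g)$r2
  adjacent <- r2[cbind(1:5, 2:6)]
  expect_true(all(adjacent > 0.5))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(ld_blocks = list(
    list(n_snps = 4L, maf_range = c(0.1, 0.4), rho = 1)
  ), snp_effects_sbp = rep(0, 4)), "rho")
  expect_error(sim_config(snp_effects_sbp = rep(0, 3)), "effect")
  expect_error(sim_config(med_prob = 1.5), "med_prob")
  expect_error(sim_config(deficit_intercepts = c(0.5, 1.2)), "prevalences")
  cfg <- sim_config(n_individuals = 50, seed = 1)
  g <- simulate_genotypes(cfg)
  bad <- sim_config(n_individuals = 60, seed = 1)
  expect_error(simulate_cohort(g, bad), "rows")
})

test_that("null cohort decouples blood pressure from frailty", {
  cfg <- sim_config(n_individuals = 20000, theta_sbp = 0,
                    confounder_effect = 0, seed = 21)
  co <- compute_fi(simulate_cohort(simulate_genotypes(cfg), cfg))
  expect_lt(abs(cor(co$sbp_true, co$fi, use = "complete.obs")), 0.02)
})

test_that("degenerate noiseless config yields constant blood pressure", {
  cfg <- sim_config(
    n_individuals = 200,
    ld_blocks = list(list(n_snps = 4L, maf_range = c(0.2, 0.4), rho = 0.3)),
    snp_effects_sbp = rep(0, 4), snp_effects_dbp = rep(0, 4),
    confounder_effect_bp = 0, covariate_bp_scale = 0,
    sbp_noise_sd = 0, dbp_noise_sd = 0, seed = 5
  )
  co <- simulate_cohort(simulate_genotypes(cfg), cfg)
  expect_equal(var(co$sbp_true), 0)
  expect_equal(var(co$dbp_true), 0)
})

test_that("a positive causal effect makes frailty rise across BP tertiles", {
  cfg <- sim_config(n_individuals = 20000, seed = 31)
  co <- compute_fi(simulate_cohort(simulate_genotypes(cfg), cfg))
  ter <- cut(co$sbp_true, quantile(co$sbp_true, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE)
  m <- tapply(co$fi, ter, mean, na.rm = TRUE)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("systolic readings exceed diastolic readings for everyone", {
  cfg <- sim_config(n_individuals = 5000, seed = 12)
  co <- simulate_cohort(simulate_genotypes(cfg), cfg)
  expect_true(all(co$sbp_1 > co$dbp_1))
  two <- co$n_bp_readings == 2
  expect_true(all(co$sbp_2[two] > co$dbp_2[two]))
  expect_true(all(is.na(co$sbp_2[!two])))
})

test_that("medication masking is exactly inverted by the +15/+10 adjustment", {
  cfg <- sim_config(n_individuals = 10000, reading_noise_sd = 0, seed = 13)
  co <- adjust_bp(simulate_cohort(simulate_genotypes(cfg), cfg))
  expect_gt(mean(co$on_bp_med), 0.02)
  expect_equal(co$sbp_adj, co$sbp_true, tolerance = 1e-12)
  two <- co$n_bp_readings == 2
  expect_equal(co$dbp_adj[two], co$dbp_true[two], tolerance = 1e-12)
})

test_that("the multinomial outcome mode draws a three-level category", {
  cfg <- sim_config(n_individuals = 20000, outcome_model = "multinomial",
                    theta_sbp = 0, confounder_effect = 0, seed = 17)
  co <- simulate_cohort(simulate_genotypes(cfg), cfg)
  expect_s3_class(co$frailty_category, "factor")
  expect_identical(levels(co$frailty_category),
                   c("non_frail", "pre_frail", "frail"))
  pr <- prop.table(table(co$frailty_category))
  expect_equal(unname(pr[["non_frail"]]), 1 / (1 + exp(log(0.497)) + exp(log(0.051))),
               tolerance = 0.02)
})

test_that("summary scenarios are seeded and respect the noiseless ratio identity", {
  s1 <- simulate_summary_scenario("causal", seed = 4)
  s2 <- simulate_summary_scenario("causal", seed = 4)
  expect_identical(s1$snps, s2$snps)
  expect_error(simulate_summary_scenario("wrong", seed = 1))
  # LD matrix well-formed
  expect_equal(s1$ld, t(s1$ld))
  expect_equal(unname(diag(s1$ld)), rep(1, nrow(s1$ld)))
  expect_gt(min(eigen(s1$ld, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # se -> 0: per-SNP ratio collapses to the causal effect everywhere
  s0 <- simulate_summary_scenario("causal", se_zx = 1e-10, se_zy = 1e-10,
                                  b_xy_true = 0.3, seed = 9)
  expect_equal(s0$snps$b_zy / s0$snps$b_zx, rep(0.3, nrow(s0$snps)),
               tolerance = 1e-6)
})

test_that("linkage scenario centres the outcome signal on the second variant", {
  sc <- simulate_summary_scenario("linkage", n_snps = 21, causal_index = 8,
                                  linkage_offset = 5, se_zy = 1e-10, seed = 2)
  expect_equal(which.max(abs(sc$snps$b_zy_true)), 13)
  expect_equal(which.max(abs(sc$snps$b_zx_true)), 8)
})
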