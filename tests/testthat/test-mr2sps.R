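test_that("BP adjustment averages readings then inverts medication masking", {
  d <- tibble::tibble(
    sbp_1 = c(130, 120, 100, NA),
    sbp_2 = c(140, NA, 110, NA),
    dbp_1 = c(85, 80, 70, NA),
    dbp_2 = c(85, NA, 72, NA),
    on_bp_med = c(FALSE, TRUE, FALSE, FALSE)
  )
  expect_message(out <- adjust_bp(d), "no BP readings")
  expect_equal(out$sbp_adj, c(135, 135, 105, NA))
  expect_equal(out$dbp_adj, c(85, 90, 71, NA))
})

first_stage_fixture <- function(n = 2000, seed = 70) {
  set.seed(seed)
  d <- tibble::tibble(
    grs = rnorm(n, 10, 2),
    age = runif(n, 40, 70),
    sex = factor(sample(c("f", "m"), n, TRUE))
  )
  d$sbp_adj <- 100 + 1.5 * d$grs + 0.3 * d$age + 2 * (d$sex == "m") +
    rnorm(n, 0, 8)
  d
}

test_that("the first stage is a well-behaved OLS of BP on score plus covariates", {
  d <- first_stage_fixture()
  s1 <- fit_first_stage(d, d$grs, "sbp_adj", covariates = c("age", "sex"))
  expect_gt(s1$grs_beta, 0)
  fit <- s1$fit
  expect_lt(abs(cor(fit$residuals, fit$fitted.values)), 1e-10)
  expect_lte(var(fit$fitted.values), var(d$sbp_adj))
  expect_gt(s1$stats$f_stat, 10)

  d$dup <- d$age                     # exact collinearity
  expect_error(fit_first_stage(d, d$grs, "sbp_adj", covariates = c("age", "dup")),
               "rank-deficient|dup")

  d2 <- d; d2$age[1:5] <- NA
  expect_message(s2 <- fit_first_stage(d2, d2$grs, "sbp_adj",
                                       covariates = c("age", "sex")),
                 "dropped 5")
  expect_equal(s2$stats$n, nrow(d) - 5)
  expect_true(all(is.na(s2$fitted[1:5])))
})

test_that("a two-category second stage matches ordinary logistic regression", {
  set.seed(71)
  n <- 3000
  d <- tibble::tibble(
    age = runif(n, 40, 70),
    sex = factor(sample(c("f", "m"), n, TRUE))
  )
  fb <- rnorm(n, 150, 3)
  eta <- -1 + 0.1 * (fb - 150) + 0.01 * (d$age - 55)
  d$fi_category <- factor(ifelse(runif(n) < plogis(eta), "frail", "non_frail"),
                          levels = c("non_frail", "frail"))
  s2 <- fit_second_stage(d, fb, covariates = c("age", "sex"))
  g <- stats::glm(I(fi_category == "frail") ~ I(fb - mean(fb)) +
                    I(age - mean(age)) + sex,
                  data = d, family = stats::binomial)
  expect_equal(unname(s2$coefficients$estimate), unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(s2$coefficients$std_error),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
})

test_that("second-stage coefficients are invariant to covariate order", {
  set.seed(72)
  n <- 2000
  d <- tibble::tibble(
    age = runif(n, 40, 70),
    bmi = rnorm(n, 27, 4),
    sex = factor(sample(c("f", "m"), n, TRUE)),
    fi_category = factor(sample(c("non_frail", "pre_frail", "frail"), n, TRUE,
                                c(0.6, 0.3, 0.1)),
                         levels = c("non_frail", "pre_frail", "frail"))
  )
  fb <- rnorm(n, 150, 3)
  a <- fit_second_stage(d, fb, covariates = c("age", "bmi", "sex"))
  b <- fit_second_stage(d, fb, covariates = c("sex", "bmi", "age"))
  ca <- dplyr::filter(a$coefficients, term == ".fitted_bp")
  cb <- dplyr::filter(b$coefficients, term == ".fitted_bp")
  expect_equal(ca$estimate, cb$estimate, tolerance = 1e-8)
  expect_equal(ca$std_error, cb$std_error, tolerance = 1e-8)
})

test_that("RRR scaling follows exp(-unit * coef) with ordered Wald bounds", {
  null <- scale_to_rrr(0, 0.01, unit = 10)
  expect_equal(null$rrr, 1)
  expect_lt(null$ci_low, 1); expect_gt(null$ci_high, 1)
  expect_equal(scale_to_rrr(0.02, 0.005, unit = 10)$rrr, exp(-0.2))
  dec <- scale_to_rrr(0.013, 0.004, unit = 10, direction = "decrease")
  inc <- scale_to_rrr(0.013, 0.004, unit = 10, direction = "increase")
  expect_equal(dec$rrr, 1 / inc$rrr)
  expect_equal(dec$ci_low, 1 / inc$ci_high)
  expect_equal(dec$p, inc$p)
  expect_true(all(dec$ci_low <= dec$rrr & dec$rrr <= dec$ci_high))
  expect_error(scale_to_rrr(0.1, 0, unit = 10), "standard errors")
  expect_error(scale_to_rrr(0.1, 0.01, unit = -5), "unit")
})

test_that("multiple-testing flags use the 0.025 and 0.05 bounds", {
  expect_equal(as.character(significance_flags(c(0.001, 0.024, 0.025, 0.03, 0.049, 0.05, 0.06))),
               c("significant", "significant", "suggestive", "suggestive",
                 "suggestive", "null", "null"))
})

test_that("confounding biases the naive model while the instrumented model stays null", {
  cfg <- sim_config(
    n_individuals = 20000,
    ld_blocks = lapply(1:3, function(i) list(n_snps = 8L, maf_range = c(0.15, 0.45), rho = 0.5)),
    snp_effects_sbp = rep(1.25 * c(0.9, 0.7, 0, 0.55, 0, 0.8, 0, 0.65), 3),
    theta_sbp = 0, confounder_effect = 0.5, confounder_effect_bp = 6,
    covariate_bp_scale = 0, outcome_model = "multinomial", seed = 77
  )
  cfg$snp_effects_dbp <- 0.55 * cfg$snp_effects_sbp
  g <- simulate_genotypes(cfg)
  co <- adjust_bp(simulate_cohort(g, cfg))
  nz <- cfg$snp_effects_sbp != 0
  inst <- orient_weights(tibble::tibble(
    snp = g$snp_meta$snp[nz], effect_allele = "A", other_allele = "G",
    beta = cfg$snp_effects_sbp[nz]))
  grs <- build_grs(g, inst)
  iv <- mr_2sps(co, grs, "sbp", outcome_col = "frailty_category",
                covariates = character(0))
  nv <- mr_naive(co, "sbp", outcome_col = "frailty_category",
                 covariates = character(0))
  z_iv <- with(tidy(iv), log_rrr_per_mmhg / se_per_mmhg)
  z_nv <- with(tidy(nv), log_rrr_per_mmhg / se_per_mmhg)
  expect_true(all(abs(z_iv) < 3))
  expect_gt(max(abs(z_nv)), 4)
})

test_that("the full 2SPS wrapper returns tidy estimates and an age filter works", {
  cfg <- sim_config(n_individuals = 4000, seed = 81)
  g <- simulate_genotypes(cfg)
  co <- compute_fi(adjust_bp(simulate_cohort(g, cfg)))
  nz <- cfg$snp_effects_sbp != 0
  inst <- orient_weights(tibble::tibble(
    snp = g$snp_meta$snp[nz], effect_allele = "A", other_allele = "G",
    beta = cfg$snp_effects_sbp[nz]))
  grs <- build_grs(g, inst)
  fit <- mr_2sps(co, grs, "sbp", drug_class = "genome_wide")
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_setequal(td$contrast, c("pre_frail_vs_non_frail", "frail_vs_non_frail"))
  expect_true(all(td$ci_low <= td$rrr & td$rrr <= td$ci_high))
  expect_true(all(td$rrr > 0))
  expect_equal(td$unit, c(10, 10))
  gl <- glance(fit)
  expect_gt(gl$f_stat, 10)
  old <- mr_2sps(co, grs, "sbp", age_min = 60)
  expect_lt(glance(old)$n, gl$n)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
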