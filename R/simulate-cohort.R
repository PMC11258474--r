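#' Simulate a cohort of blood-pressure phenotypes, covariates and deficits
#'
#' Builds the individual-level synthetic cohort on top of a genotype matrix.
#' True systolic BP is additive in the SNP effects, covariate effects, a
#' shared confounder U ~ N(0,1) and Gaussian noise; diastolic BP follows the
#' same structure with its own effects. Individuals whose true SBP exceeds
#' the medication threshold are assigned antihypertensive treatment with
#' probability `med_prob`, and their *observed* BP (the recorded readings)
#' is reduced by 15/10 mmHg systolic/diastolic, so the conventional +15/+10
#' correction applied by [adjust_bp()] exactly inverts the masking.
#'
#' Frailty outcomes come in two flavours (see [sim_config()]):
#' * `"deficits"` — each of the (default 49) binary health-deficit items is
#'   drawn from a liability model `a_j + theta_sbp * trueSBP_c +
#'   confounder_effect * U + h_i + e_ij > 0`, with `h_i` a person-level
#'   shared liability term and `e_ij` independent standard normal; items are
#'   conditionally independent given the liability terms.
#' * `"multinomial"` — the frailty category is drawn directly from a
#'   multinomial logit on structural (long-term) SBP with a known per-mmHg
#'   log-relative-risk-ratio, giving exact ground truth for estimator
#'   calibration.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param config the same [sim_config()] used for the genotypes.
#' @return A tibble with one row per individual: identifiers, covariates
#'   (age, sex, center, smoking, alcohol, bmi, deprivation, array,
#'   pc1..pc10), the latent `confounder`, true BP (`sbp_true`, `dbp_true`,
#'   structural `sbp_struct`), medication status `on_bp_med`, recorded
#'   readings `sbp_1`, `sbp_2`, `dbp_1`, `dbp_2` (second reading `NA` for
#'   single-reading individuals), `n_bp_readings`, and either deficit item
#'   columns `deficit_01` ... or a `frailty_category` factor.
#' @examples
#' cfg <- sim_config(n_individuals = 300, seed = 7)
#' cohort <- simulate_cohort(simulate_genotypes(cfg), cfg)
#' @export
simulate_cohort <- function(genotypes, config) {
  validate_sim_config(config)
  dos <- genotypes$dosages
  n <- config$n_individuals
  if (nrow(dos) != n) abort("genotype matrix rows must equal n_individuals")
  if (ncol(dos) != length(config$snp_effects_sbp)) {
    abort("snp effect vector length must equal the number of SNPs")
  }

  withr::local_seed(derive_seed(config$seed, "cohort"))

  age <- runif(n, 40, 70)
  sex <- factor(sample(c("female", "male"), n, TRUE, c(0.54, 0.46)),
                levels = c("female", "male"))
  center <- factor(sample(sprintf("c%02d", 1:8), n, TRUE),
                   levels = sprintf("c%02d", 1:8))
  smoking <- factor(sample(c("never", "previous", "current"), n, TRUE,
                           c(0.55, 0.35, 0.10)),
                    levels = c("never", "previous", "current"))
  alcohol_levels <- c("never", "occasionally", "1-3_per_month",
                      "1-2_per_week", "3-4_per_week", "daily")
  alcohol <- factor(sample(alcohol_levels, n, TRUE,
                           c(0.08, 0.11, 0.11, 0.26, 0.23, 0.21)),
                    levels = alcohol_levels)
  bmi <- rnorm(n, 27, 4)
  deprivation <- factor(sample(sprintf("fifth_%d", 1:5), n, TRUE),
                        levels = sprintf("fifth_%d", 1:5))
  array <- factor(sample(c("axiom", "bileve"), n, TRUE, c(0.9, 0.1)),
                  levels = c("axiom", "bileve"))
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  confounder <- rnorm(n)

  cs <- config$covariate_bp_scale
  cov_sbp <- cs * (0.35 * (age - 55) + 4 * (sex == "male") +
    0.5 * (bmi - 27) +
    seq(-0.8, 0.8, length.out = 8)[as.integer(center)] +
    c(0, 0.5, 1.5)[as.integer(smoking)] +
    seq(-1, 1.5, length.out = 6)[as.integer(alcohol)] +
    seq(-0.5, 0.8, length.out = 5)[as.integer(deprivation)] +
    0.3 * (array == "bileve") + drop(pcs %*% rep(0.15, 10)))
  cov_dbp <- cs * (0.12 * (age - 55) + 2 * (sex == "male") +
    0.4 * (bmi - 27) +
    0.4 * (seq(-0.8, 0.8, length.out = 8)[as.integer(center)] +
             c(0, 0.5, 1.5)[as.integer(smoking)] +
             seq(-1, 1.5, length.out = 6)[as.integer(alcohol)]) +
    drop(pcs %*% rep(0.08, 10)))

  g_sbp <- drop(dos %*% config$snp_effects_sbp)
  g_dbp <- drop(dos %*% config$snp_effects_dbp)
  sbp_struct <- 135 + g_sbp + cov_sbp + config$confounder_effect_bp * confounder
  dbp_struct <- 82 + g_dbp + cov_dbp +
    (2 / 3) * config$confounder_effect_bp * confounder
  sbp_true <- sbp_struct + rnorm(n, 0, config$sbp_noise_sd)
  dbp_true <- dbp_struct + rnorm(n, 0, config$dbp_noise_sd)
  dbp_true <- pmin(dbp_true, sbp_true - 10)  # physiological ordering

  on_bp_med <- sbp_true > config$med_threshold & runif(n) < config$med_prob
  sbp_obs <- sbp_true - 15 * on_bp_med
  dbp_obs <- dbp_true - 10 * on_bp_med
  n_readings <- ifelse(runif(n) < config$prop_single_reading, 1L, 2L)
  rn <- config$reading_noise_sd
  sbp_1 <- sbp_obs + rnorm(n, 0, rn)
  sbp_2 <- ifelse(n_readings == 2L, sbp_obs + rnorm(n, 0, rn), NA_real_)
  dbp_1 <- pmin(dbp_obs + rnorm(n, 0, rn), sbp_1 - 2)
  dbp_2 <- ifelse(n_readings == 2L,
                  pmin(dbp_obs + rnorm(n, 0, rn), sbp_2 - 2), NA_real_)

  out <- tibble::tibble(
    person_id = seq_len(n),
    age = age, sex = sex, center = center, smoking = smoking,
    alcohol = alcohol, bmi = bmi, deprivation = deprivation, array = array
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(pcs))
  out$confounder <- confounder
  out$sbp_struct <- sbp_struct
  out$sbp_true <- sbp_true
  out$dbp_true <- dbp_true
  out$on_bp_med <- on_bp_med
  out$n_bp_readings <- n_readings
  out$sbp_1 <- sbp_1
  out$sbp_2 <- sbp_2
  out$dbp_1 <- dbp_1
  out$dbp_2 <- dbp_2

  if (config$outcome_model == "deficits") {
    out <- dplyr::bind_cols(out, simulate_deficits(sbp_true, confounder, config))
  } else {
    theta <- config$theta_sbp          # per-mmHg log-RRR, both contrasts
    eta_pre <- log(0.497) + theta * (sbp_struct - 135) +
      config$confounder_effect * confounder
    eta_frail <- log(0.051) + theta * (sbp_struct - 135) +
      config$confounder_effect * confounder
    denom <- 1 + exp(eta_pre) + exp(eta_frail)
    u <- runif(n)
    p_non <- 1 / denom
    p_pre <- exp(eta_pre) / denom
    cat_idx <- 1L + (u > p_non) + (u > p_non + p_pre)
    out$frailty_category <- factor(
      c("non_frail", "pre_frail", "frail")[cat_idx],
      levels = c("non_frail", "pre_frail", "frail")
    )
  }
  out
}

# Liability-model deficit items; RNG state comes from the caller.
simulate_deficits <- function(sbp_true, confounder, config) {
  n <- length(sbp_true)
  p0 <- config$deficit_intercepts
  k <- length(p0)
  shift <- config$theta_sbp * (sbp_true - mean(sbp_true)) +
    config$confounder_effect * confounder +
    rnorm(n, 0, config$frailty_het_sd)
  var_s <- var(shift)
  a <- qnorm(p0) * sqrt(1 + var_s)   # keeps marginal prevalence near p0
  liab <- outer(shift, a, "+") + matrix(rnorm(n * k), n, k)
  items <- (liab > 0) * 1L

  # person-level missingness: mostly sparse, a small group misses many items
  high <- runif(n) < config$high_missing_prop
  rate <- ifelse(high, config$high_missing_rate, config$deficit_missing_rate)
  miss <- matrix(runif(n * k), n, k) < rate
  items[miss] <- NA_integer_
  colnames(items) <- deficit_item_names(k)
  tibble::as_tibble(items)
}

#' Names of the synthetic deficit items
#'
#' The first eight items are labelled as the cardiometabolic subset used by
#' the modified frailty index; the labels are synthetic stand-ins, not a
#' published item list.
#'
#' @param k number of items.
#' @return character vector of column names.
#' @export
deficit_item_names <- function(k = 49) {
  stopifnot(k >= 1)
  nm <- sprintf("deficit_%02d", seq_len(k))
  n_cm <- min(8L, k)
  nm[seq_len(n_cm)] <- sprintf("deficit_cm_%02d", seq_len(n_cm))
  nm
}

#' Cardiometabolic deficit item subset (synthetic default)
#'
#' @param k total number of items.
#' @return character vector with the 8 cardiometabolic item names.
#' @export
cardiometabolic_items <- function(k = 49) {
  grep("^deficit_cm_", deficit_item_names(k), value = TRUE)
}

#' Synthetic GWAS summary statistics for the simulated genome
#'
#' Emulates a large external GWAS of blood pressure over the same SNP panel:
#' per-SNP marginal effects are derived from the configured joint effects and
#' the empirical dosage covariance (so LD is reflected in the marginals), and
#' estimates are drawn with sampling noise at the standard error implied by
#' the GWAS sample size.
#'
#' @param genotypes a `genotype_matrix` (LD/allele-frequency reference).
#' @param config the [sim_config()] carrying the true SNP effects.
#' @param exposure `"sbp"` or `"dbp"`.
#' @param n_gwas external GWAS sample size.
#' @param pheno_sd phenotype SD used for the standard-error scale (mmHg).
#' @return A tibble in `.ma` layout: `snp`, `effect_allele`, `other_allele`,
#'   `freq`, `beta`, `se`, `p`, `n`, plus `chromosome`, `position`.
#' @export
simulate_gwas_summary <- function(genotypes, config,
                                  exposure = c("sbp", "dbp"),
                                  n_gwas = 750000, pheno_sd = NULL) {
  exposure <- match.arg(exposure)
  beta_joint <- if (exposure == "sbp") config$snp_effects_sbp else config$snp_effects_dbp
  if (is.null(pheno_sd)) pheno_sd <- if (exposure == "sbp") 19 else 11
  dos <- genotypes$dosages
  # marginal per-SNP effects: joint effects propagated through within-block
  # dosage covariance (blocks are independent by construction, so the
  # cross-block covariance is exactly zero rather than panel noise)
  blocks <- genotypes$snp_meta$block
  marginal <- numeric(ncol(dos))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    Cb <- stats::cov(dos[, idx, drop = FALSE])
    marginal[idx] <- drop(Cb %*% beta_joint[idx]) / diag(Cb)
  }

  withr::local_seed(derive_seed(config$seed, paste0("gwas_", exposure)))
  freq <- colMeans(dos) / 2
  se <- pheno_sd / sqrt(n_gwas * 2 * freq * (1 - freq))
  beta_hat <- rnorm(length(se), marginal, se)
  p <- 2 * pnorm(-abs(beta_hat / se))
  tibble::tibble(
    snp = genotypes$snp_meta$snp,
    chromosome = genotypes$snp_meta$chromosome,
    position = genotypes$snp_meta$position,
    effect_allele = genotypes$snp_meta$effect_allele,
    other_allele = genotypes$snp_meta$other_allele,
    freq = freq, beta = beta_hat, se = se, p = p, n = n_gwas
  )
}
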