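#' Default antihypertensive drug-target gene map
#'
#' An illustrative map from drug classes to target-gene regions, used by the
#' synthetic cohort generator and the pipeline. Classes follow the common
#' antihypertensive families: ACE inhibitors (ACEi), beta-blockers (BB),
#' calcium-channel blockers (CCB), thiazide diuretics, plus an angiotensin-
#' receptor-blocker (ARB) region that carries no blood-pressure signal in the
#' synthetic genome, so pipelines must handle a drug class with zero usable
#' instruments. Coordinates are synthetic (one block per chromosome); real
#' analyses supply their own map.
#'
#' @return A tibble with columns `gene`, `drug_class`, `chromosome`, `start`,
#'   `end` (1-based inclusive bp).
#' @export
default_gene_regions <- function() {
  tibble::tribble(
    ~gene,      ~drug_class, ~chromosome, ~start,   ~end,
    "ACE",      "ACEi",      1L,          1000000L, 1100000L,
    "ADRB1",    "BB",        2L,          1000000L, 1100000L,
    "KCNH2",    "BB",        3L,          1000000L, 1100000L,
    "CACNA1C",  "CCB",       4L,          1000000L, 1100000L,
    "CACNB2",   "CCB",       5L,          1000000L, 1100000L,
    "SLC12A3",  "thiazide",  6L,          1000000L, 1100000L,
    "AGTR1",    "ARB",       7L,          1000000L, 1100000L
  )
}

# Per-block per-SNP effect template (mmHg per effect allele on SBP).
# Roughly half the SNPs in a signal block carry an effect, sized so the
# combined score explains a few percent of blood-pressure variance, as for
# real blood-pressure risk scores.
.block_effect_template <- c(0.9, 0.7, 0, 0.55, 0, 0.8, 0, 0.65)

#' Simulation configuration for the synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator: LD-blocked
#' genotypes, additive SNP effects on systolic/diastolic blood pressure (BP),
#' covariate and confounder effects, the medication-masking mechanism, and
#' the liability model that turns BP into accumulated health deficits.
#'
#' The defaults define the package's reference synthetic cohort: 20,000
#' individuals; seven 8-SNP LD blocks (one per target gene in
#' [default_gene_regions()], the ARB block carrying no effect); per-allele
#' effects of 0.55-0.9 mmHg on SBP (0.55 times that on DBP); a causal effect
#' `theta_sbp` of SBP on frailty liability of 0.015 liability-SD per mmHg; a
#' standard-normal confounder adding 3 mmHg/SD to SBP and 0.25 liability-SD
#' to every deficit; and 49 binary deficit items with baseline prevalences
#' spread over 1-18%.
#'
#' Medication masking: individuals whose true SBP exceeds `med_threshold`
#' are assigned antihypertensive medication with probability `med_prob`, and
#' their *observed* BP is reduced by 15/10 mmHg (systolic/diastolic), so the
#' standard +15/+10 correction of [adjust_bp()] exactly inverts it.
#'
#' @param n_individuals cohort size (>= 1).
#' @param ld_blocks list of blocks, each `list(n_snps=, maf_range=c(lo,hi),
#'   rho=)` with `rho` the AR-1 latent correlation in `[0, 1)` and MAF range
#'   within `(0, 0.5]`.
#' @param snp_effects_sbp,snp_effects_dbp numeric vectors, mmHg per effect
#'   allele, one entry per SNP across all blocks.
#' @param theta_sbp causal effect of true SBP on frailty liability
#'   (liability-SD per mmHg); 0 gives the null model.
#' @param confounder_effect effect of the shared confounder U ~ N(0,1) on
#'   frailty liability (liability-SD per SD of U).
#' @param confounder_effect_bp effect of U on true SBP (mmHg per SD); DBP
#'   receives 2/3 of it.
#' @param med_threshold,med_prob medication assignment: true SBP above
#'   `med_threshold` (mmHg) receives medication with probability `med_prob`.
#' @param deficit_intercepts baseline deficit prevalences in (0,1), one per
#'   item (default 49 items spread over 0.01-0.18).
#' @param frailty_het_sd SD of a person-level shared frailty-liability term;
#'   deficits remain conditionally independent given the liability terms.
#' @param sbp_noise_sd,dbp_noise_sd residual SD of true BP (mmHg).
#' @param reading_noise_sd per-reading measurement noise SD (mmHg).
#' @param prop_single_reading fraction of individuals with one BP reading.
#' @param deficit_missing_rate baseline per-item missingness; a small
#'   fraction of individuals (`high_missing_prop`) instead miss items at
#'   `high_missing_rate`, so the >=10-missing-item exclusion rule has cases
#'   to act on.
#' @param high_missing_prop,high_missing_rate see `deficit_missing_rate`.
#' @param covariate_bp_scale multiplier on all covariate effects on BP;
#'   0 removes the covariate pathway (used by the estimator-calibration
#'   configuration so the instrument-only regressions are correctly
#'   specified).
#' @param outcome_model `"deficits"` draws 49 liability-model items and
#'   derives the frailty index; `"multinomial"` draws the frailty category
#'   directly from a multinomial logit on structural (long-term) SBP with
#'   per-mmHg log-RRR `theta_sbp` (exact ground-truth RRR, used for
#'   estimator calibration).
#' @param seed integer root seed; every generator output is a pure function
#'   of (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       ld_blocks = NULL,
                       snp_effects_sbp = NULL,
                       snp_effects_dbp = NULL,
                       theta_sbp = 0.015,
                       confounder_effect = 0.25,
                       confounder_effect_bp = 3,
                       med_threshold = 160,
                       med_prob = 0.7,
                       deficit_intercepts = NULL,
                       frailty_het_sd = 0.45,
                       sbp_noise_sd = 16,
                       dbp_noise_sd = 10,
                       reading_noise_sd = 3,
                       prop_single_reading = 0.03,
                       deficit_missing_rate = 0.01,
                       high_missing_prop = 0.03,
                       high_missing_rate = 0.25,
                       covariate_bp_scale = 1,
                       outcome_model = c("deficits", "multinomial"),
                       seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  if (is.null(ld_blocks)) {
    ld_blocks <- lapply(1:7, function(i) {
      list(n_snps = 8L, maf_range = c(0.1, 0.45), rho = 0.5)
    })
  }
  n_snps <- sum(vapply(ld_blocks, function(b) as.integer(b$n_snps), 1L))
  if (is.null(snp_effects_sbp)) {
    snp_effects_sbp <- unlist(lapply(seq_along(ld_blocks), function(i) {
      m <- ld_blocks[[i]]$n_snps
      eff <- rep_len(.block_effect_template, m)
      if (i == length(ld_blocks)) eff <- rep(0, m)  # ARB-like block: no proxy
      eff
    }))
  }
  if (is.null(snp_effects_dbp)) snp_effects_dbp <- 0.55 * snp_effects_sbp
  if (is.null(deficit_intercepts)) {
    deficit_intercepts <- seq(0.01, 0.18, length.out = 49)
  }

  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    ld_blocks = ld_blocks,
    snp_effects_sbp = snp_effects_sbp,
    snp_effects_dbp = snp_effects_dbp,
    theta_sbp = theta_sbp,
    confounder_effect = confounder_effect,
    confounder_effect_bp = confounder_effect_bp,
    med_threshold = med_threshold,
    med_prob = med_prob,
    deficit_intercepts = deficit_intercepts,
    frailty_het_sd = frailty_het_sd,
    sbp_noise_sd = sbp_noise_sd,
    dbp_noise_sd = dbp_noise_sd,
    reading_noise_sd = reading_noise_sd,
    prop_single_reading = prop_single_reading,
    deficit_missing_rate = deficit_missing_rate,
    high_missing_prop = high_missing_prop,
    high_missing_rate = high_missing_rate,
    covariate_bp_scale = covariate_bp_scale,
    outcome_model = outcome_model,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1) abort("n_individuals must be >= 1")
  for (b in cfg$ld_blocks) {
    if (b$rho < 0 || b$rho >= 1) abort("ld block rho must be in [0, 1)")
    if (b$n_snps < 1) abort("ld block must contain at least one SNP")
    mr <- b$maf_range
    if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
      abort("maf_range must be an increasing pair within (0, 0.5]")
    }
  }
  n_snps <- sum(vapply(cfg$ld_blocks, function(b) as.integer(b$n_snps), 1L))
  if (length(cfg$snp_effects_sbp) != n_snps ||
      length(cfg$snp_effects_dbp) != n_snps) {
    abort("snp effect vectors must have one entry per SNP across all blocks")
  }
  if (cfg$med_prob < 0 || cfg$med_prob > 1) abort("med_prob must be in [0, 1]")
  if (any(cfg$deficit_intercepts <= 0) || any(cfg$deficit_intercepts >= 1)) {
    abort("deficit_intercepts are baseline prevalences and must lie in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_snps <- sum(vapply(x$ld_blocks, function(b) as.integer(b$n_snps), 1L))
  cat("<sim_config>\n",
      sprintf("  %d individuals, %d SNPs in %d LD blocks\n",
              x$n_individuals, n_snps, length(x$ld_blocks)),
      sprintf("  theta_sbp = %.4g, confounder = %.3g (liability) / %.3g mmHg\n",
              x$theta_sbp, x$confounder_effect, x$confounder_effect_bp),
      sprintf("  %d deficit items, outcome model '%s', seed %d\n",
              length(x$deficit_intercepts), x$outcome_model, x$seed),
      sep = "")
  invisible(x)
}
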