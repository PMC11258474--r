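#' Average blood-pressure readings and invert medication masking
#'
#' Computes per-person mean systolic/diastolic BP over the available
#' readings (one or two), then adds 15 mmHg (systolic) and 10 mmHg
#' (diastolic) for individuals on antihypertensive medication — the
#' conventional correction that restores an estimate of underlying
#' untreated blood pressure.
#'
#' @param data cohort tibble.
#' @param sbp_cols,dbp_cols reading column names (second and later readings
#'   may be `NA` for persons with fewer readings).
#' @param med_col name of the logical on-medication column.
#' @return The tibble with `sbp_adj` and `dbp_adj` appended. Persons with
#'   no readings at all get `NA` (a message reports the count); drop them
#'   before modelling.
#' @examples
#' adjust_bp(tibble::tibble(sbp_1 = 120, sbp_2 = NA, dbp_1 = 80,
#'                          dbp_2 = NA, on_bp_med = TRUE))
#' @export
adjust_bp <- function(data, sbp_cols = c("sbp_1", "sbp_2"),
                      dbp_cols = c("dbp_1", "dbp_2"),
                      med_col = "on_bp_med") {
  sbp <- rowMeans(as.matrix(data[sbp_cols]), na.rm = TRUE)
  dbp <- rowMeans(as.matrix(data[dbp_cols]), na.rm = TRUE)
  none <- rowSums(!is.na(as.matrix(data[sbp_cols]))) == 0
  if (any(none)) {
    rlang::inform(sprintf("%d person(s) with no BP readings: adjusted BP is NA",
                          sum(none)))
    sbp[none] <- NA_real_
    dbp[none] <- NA_real_
  }
  med <- as.logical(data[[med_col]])
  out <- tibble::as_tibble(data)
  out$sbp_adj <- sbp + 15 * med
  out$dbp_adj <- dbp + 10 * med
  out
}

#' Default covariate set for the MR regressions
#'
#' Age, sex, assessment center, smoking status, alcohol intake, BMI,
#' deprivation, genotyping array and the first 10 genetic principal
#' components.
#'
#' @return character vector of column names.
#' @export
mr_covariates <- function() {
  c("age", "sex", "center", "smoking", "alcohol", "bmi", "deprivation",
    "array", paste0("pc", 1:10))
}

#' First stage of the two-stage predictor substitution
#'
#' Ordinary least squares of adjusted blood pressure on the genetic risk
#' score plus covariates (categorical covariates enter as treatment-coded
#' dummies with the first level as reference). Incomplete rows are dropped
#' with a message. The fitted values are the genetically predicted BP
#' carried into the second stage.
#'
#' @param data cohort tibble containing the BP column and covariates.
#' @param grs numeric vector aligned with `data` rows (or [build_grs()]
#'   output).
#' @param bp_col name of the adjusted-BP column (e.g. `"sbp_adj"`).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return list with `fitted` (NA for dropped rows), `kept` (logical row
#'   mask), `stats` (tibble: `r_squared` — partial r2 of the score given
#'   covariates, `f_stat` of the score term, `n`, `k`), `grs_beta`, and the
#'   `lm` fit.
#' @export
fit_first_stage <- function(data, grs, bp_col, covariates = mr_covariates()) {
  if (is.data.frame(grs)) grs <- grs$grs
  df <- data.frame(.bp = data[[bp_col]], .grs = grs,
                   data[intersect(covariates, names(data))],
                   check.names = FALSE)
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    rlang::inform(sprintf("first stage: dropped %d incomplete row(s)",
                          sum(!keep)))
  }
  df <- df[keep, , drop = FALSE]
  fit <- lm(.bp ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("rank-deficient first-stage design; collinear terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)
  tval <- sm$coefficients[".grs", "t value"]
  n <- nrow(df)
  f_grs <- tval^2
  partial_r2 <- tval^2 / (tval^2 + fit$df.residual)
  fitted_all <- rep(NA_real_, nrow(data))
  fitted_all[keep] <- fit$fitted.values
  list(
    fitted = fitted_all,
    kept = keep,
    stats = tibble::tibble(r_squared = partial_r2, f_stat = f_grs,
                           n = n, k = 1),
    grs_beta = unname(cf[".grs"]),
    fit = fit
  )
}

#' Second stage: multinomial logistic regression on predicted BP
#'
#' Maximum-likelihood multinomial logit of the frailty category
#' (reference level `non_frail`) on the stage-one fitted blood pressure and
#' the same covariate set, via `nnet::multinom` with tight convergence
#' settings. The coefficient on fitted BP is the log relative-risk ratio
#' per mmHg for each contrast.
#'
#' @param data cohort tibble containing the outcome and covariates.
#' @param fitted_bp stage-one fitted values aligned with `data` rows.
#' @param outcome_col name of the frailty-category factor column.
#' @param covariates covariate column names (must match stage one).
#' @return list with `coefficients` (tibble: `contrast`, `term`,
#'   `estimate`, `std_error`), `fit` (the `multinom` object), `n`,
#'   `converged`.
#' @export
fit_second_stage <- function(data, fitted_bp, outcome_col = "fi_category",
                             covariates = mr_covariates()) {
  df <- data.frame(.y = data[[outcome_col]], .fitted_bp = fitted_bp,
                   data[intersect(covariates, names(data))],
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.y <- droplevels(df$.y)
  # centre numeric predictors: slopes and their standard errors are
  # unchanged, but the information matrix is far better conditioned
  # (mmHg-scale predictors otherwise make the intercept column collinear)
  num <- vapply(df, is.numeric, TRUE) & names(df) != ".y"
  df[num] <- lapply(df[num], function(v) v - mean(v))
  if (nlevels(df$.y) < 2) abort("outcome has fewer than 2 observed categories")
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                        maxit = 500, reltol = 1e-12, MaxNWts = 5000)
  converged <- fit$convergence == 0
  if (!converged) warn("second-stage multinomial fit did not converge")
  cf <- coef(fit)
  if (is.null(dim(cf))) {             # two-category collapse: plain logit
    cf <- matrix(cf, nrow = 1, dimnames = list(levels(df$.y)[2], names(cf)))
  }
  X <- stats::model.matrix(stats::as.formula(".y ~ ."), data = df)
  pol <- multinom_polish(cf, X, df$.y)
  cf <- pol$cf
  se_mat <- multinom_se(cf, X, pol$prob)
  terms <- colnames(cf)
  res <- purrr::map_dfr(rownames(cf), function(lev) {
    tibble::tibble(contrast = paste0(lev, "_vs_", levels(df$.y)[1]),
                   term = terms, estimate = cf[lev, ],
                   std_error = se_mat[lev, ])
  })
  list(coefficients = res, fit = fit, n = nrow(df), converged = converged)
}

# Newton polish of the multinomial-logit solution: nnet's quasi-Newton stop
# leaves coefficients a little short of the maximum, so a few analytic
# Newton steps push the score below 1e-8, after which a two-category
# collapse agrees with glm's IRLS solution to well under 1e-6.
multinom_polish <- function(cf, X, y, tol = 1e-8, max_iter = 10) {
  K1 <- nrow(cf)
  p <- ncol(X)
  Y <- vapply(rownames(cf), function(lev) as.numeric(y == lev),
              numeric(length(y)))
  theta <- as.vector(t(cf))
  for (it in seq_len(max_iter)) {
    eta <- X %*% matrix(theta, ncol = K1, dimnames = NULL)
    expeta <- exp(eta)
    prob_k <- expeta / (1 + rowSums(expeta))
    score <- as.vector(crossprod(X, Y - prob_k))       # class-major blocks
    if (max(abs(score)) < tol) break
    info <- matrix(0, K1 * p, K1 * p)
    for (k in seq_len(K1)) {
      for (l in seq_len(k)) {
        w <- if (k == l) prob_k[, k] * (1 - prob_k[, k]) else
          -prob_k[, k] * prob_k[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1) * p + seq_len(p)
        ci <- (l - 1) * p + seq_len(p)
        info[ri, ci] <- blk
        if (k != l) info[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    theta <- theta + step
  }
  eta <- X %*% matrix(theta, ncol = K1)
  expeta <- exp(eta)
  prob_k <- expeta / (1 + rowSums(expeta))
  list(cf = matrix(theta, nrow = K1, byrow = TRUE, dimnames = dimnames(cf)),
       prob = cbind(1 - rowSums(prob_k), prob_k))
}

# Wald standard errors from the observed information of the multinomial
# logit, built in vectorized form (the generic numeric Hessian is slow at
# cohort scale). For the canonical logit link observed and expected
# information coincide, so a two-category collapse reproduces glm's SEs.
multinom_se <- function(cf, X, prob) {
  K1 <- nrow(cf)                              # non-reference classes
  p <- ncol(X)
  prob <- as.matrix(prob)
  if (ncol(prob) == 1) prob <- cbind(1 - prob, prob)
  info <- matrix(0, K1 * p, K1 * p)
  for (k in seq_len(K1)) {
    for (l in seq_len(k)) {
      pk <- prob[, k + 1]
      w <- if (k == l) pk * (1 - pk) else -pk * prob[, l + 1]
      blk <- crossprod(X, X * w)
      ri <- (k - 1) * p + seq_len(p)
      ci <- (l - 1) * p + seq_len(p)
      info[ri, ci] <- blk
      if (k != l) info[ci, ri] <- t(blk)
    }
  }
  vc <- tryCatch(solve(info), error = function(e) {
    warn("singular information matrix in the multinomial second stage")
    matrix(NA_real_, K1 * p, K1 * p)
  })
  matrix(sqrt(pmax(diag(vc), 0)), nrow = K1, byrow = TRUE,
         dimnames = dimnames(cf))
}

#' Scale a per-mmHg log-RRR to a clinical blood-pressure decrement
#'
#' Converts a multinomial coefficient (log relative-risk ratio per mmHg
#' *increase*) into the relative risk ratio per `unit`-mmHg *decrease*
#' (10 mmHg systolic / 5 mmHg diastolic by convention), with a 95% Wald
#' confidence interval and two-sided p-value.
#'
#' @param coef log-RRR per mmHg.
#' @param se standard error of `coef` (> 0).
#' @param unit mmHg decrement (10 for SBP, 5 for DBP).
#' @param direction `"decrease"` (default) or `"increase"`.
#' @return tibble `rrr`, `ci_low`, `ci_high`, `p`, `unit`, `direction`.
#' @examples
#' scale_to_rrr(0.02, 0.005, unit = 10)  # rrr = exp(-0.2)
#' @export
scale_to_rrr <- function(coef, se, unit, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (any(se <= 0)) abort("standard errors must be > 0")
  if (any(unit <= 0)) abort("unit must be > 0")
  s <- if (direction == "decrease") -1 else 1
  est <- s * unit * coef
  lo <- est - 1.96 * unit * se
  hi <- est + 1.96 * unit * se
  tibble::tibble(
    rrr = exp(est),
    ci_low = exp(pmin(lo, hi)),
    ci_high = exp(pmax(lo, hi)),
    p = 2 * pnorm(-abs(coef / se)),
    unit = unit, direction = direction
  )
}

#' Multiple-testing significance flags for the MR estimates
#'
#' With two blood-pressure exposures the Bonferroni-corrected significance
#' level is `alpha / n_tests` = 0.025; p-values between that and `alpha`
#' are flagged suggestive.
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of exposures tested (default 2).
#' @return factor with levels `significant`, `suggestive`, `null`.
#' @examples
#' significance_flags(c(0.001, 0.03, 0.06))
#' @export
significance_flags <- function(p, alpha = 0.05, n_tests = 2) {
  thr <- alpha / n_tests
  out <- ifelse(p < thr, "significant",
                ifelse(p < alpha, "suggestive", "null"))
  factor(out, levels = c("significant", "suggestive", "null"))
}

#' One-sample Mendelian randomization by two-stage predictor substitution
#'
#' Runs the full 2SPS estimator: OLS of adjusted BP on the genetic risk
#' score plus covariates, then multinomial logistic regression of the
#' frailty category on the stage-one fitted BP with the same covariates.
#' Estimates are reported as relative risk ratios per `unit`-mmHg decrease
#' in BP (default 10 for systolic, 5 for diastolic).
#'
#' Standard errors are naive Wald errors from the second stage (no
#' correction for first-stage estimation uncertainty), the common 2SPS
#' convention; with instruments this strong the correction is negligible.
#'
#' @param data cohort tibble with adjusted BP (see [adjust_bp()]), the
#'   frailty category and covariates.
#' @param grs [build_grs()] output or numeric vector.
#' @param exposure `"sbp"` or `"dbp"`; picks `sbp_adj`/`dbp_adj` and the
#'   default unit.
#' @param outcome_col frailty-category column.
#' @param covariates covariate column names used in both stages.
#' @param unit mmHg decrement for reporting (default 10 SBP / 5 DBP).
#' @param age_min optional minimum age (e.g. 60 for the older-participant
#'   subgroup analysis).
#' @param drug_class optional label stored on the result.
#' @return object of class `mr2sps_fit`; see [tidy.mr2sps_fit()] and
#'   [glance.mr2sps_fit()].
#' @export
mr_2sps <- function(data, grs, exposure = c("sbp", "dbp"),
                    outcome_col = "fi_category",
                    covariates = mr_covariates(),
                    unit = NULL, age_min = NULL, drug_class = NULL) {
  exposure <- match.arg(exposure)
  if (is.null(unit)) unit <- if (exposure == "sbp") 10 else 5
  if (is.data.frame(grs)) grs <- grs$grs
  if (!is.null(age_min)) {
    keep <- !is.na(data$age) & data$age >= age_min
    data <- data[keep, , drop = FALSE]
    grs <- grs[keep]
  }
  bp_col <- paste0(exposure, "_adj")
  s1 <- fit_first_stage(data, grs, bp_col, covariates)
  s2 <- fit_second_stage(data, s1$fitted, outcome_col, covariates)
  est <- dplyr::filter(s2$coefficients, .data$term == ".fitted_bp")
  est <- dplyr::bind_cols(
    est[c("contrast")],
    scale_to_rrr(est$estimate, est$std_error, unit),
    tibble::tibble(log_rrr_per_mmhg = est$estimate,
                   se_per_mmhg = est$std_error)
  )
  est$flag <- significance_flags(est$p)
  est$exposure <- toupper(exposure)
  est$drug_class <- drug_class %||% NA_character_
  structure(list(
    estimates = est[c("exposure", "drug_class", "contrast", "rrr", "ci_low",
                      "ci_high", "p", "flag", "unit", "log_rrr_per_mmhg",
                      "se_per_mmhg")],
    first_stage = s1$stats,
    grs_beta = s1$grs_beta,
    second_stage_n = s2$n,
    converged = s2$converged,
    exposure = toupper(exposure), unit = unit,
    drug_class = drug_class
  ), class = "mr2sps_fit")
}

#' Naive (non-instrumented) multinomial regression of frailty on BP
#'
#' The observational comparator: regresses the frailty category directly on
#' measured adjusted BP with the same covariates. With confounding and
#' measurement noise this estimate is biased — contrasting it with
#' [mr_2sps()] is the motivation for the instrumented design.
#'
#' @inheritParams mr_2sps
#' @return object of class `mr2sps_fit` (flagged naive).
#' @export
mr_naive <- function(data, exposure = c("sbp", "dbp"),
                     outcome_col = "fi_category",
                     covariates = mr_covariates(), unit = NULL) {
  exposure <- match.arg(exposure)
  if (is.null(unit)) unit <- if (exposure == "sbp") 10 else 5
  bp_col <- paste0(exposure, "_adj")
  s2 <- fit_second_stage(data, data[[bp_col]], outcome_col, covariates)
  est <- dplyr::filter(s2$coefficients, .data$term == ".fitted_bp")
  est <- dplyr::bind_cols(
    est[c("contrast")],
    scale_to_rrr(est$estimate, est$std_error, unit),
    tibble::tibble(log_rrr_per_mmhg = est$estimate,
                   se_per_mmhg = est$std_error)
  )
  est$flag <- significance_flags(est$p)
  est$exposure <- toupper(exposure)
  est$drug_class <- "naive"
  structure(list(
    estimates = est[c("exposure", "drug_class", "contrast", "rrr", "ci_low",
                      "ci_high", "p", "flag", "unit", "log_rrr_per_mmhg",
                      "se_per_mmhg")],
    first_stage = NULL, second_stage_n = s2$n, converged = s2$converged,
    exposure = toupper(exposure), unit = unit, drug_class = "naive"
  ), class = "mr2sps_fit")
}

#' @export
print.mr2sps_fit <- function(x, ...) {
  cat(sprintf("<mr2sps_fit> %s%s, RRR per %g mmHg decrease (n = %d)\n",
              x$exposure,
              if (!is.null(x$drug_class)) paste0(" / ", x$drug_class) else "",
              x$unit, x$second_stage_n))
  print(x$estimates[c("contrast", "rrr", "ci_low", "ci_high", "p", "flag")])
  if (!is.null(x$first_stage)) {
    cat(sprintf("first stage: partial r2 = %.4f, F = %.1f\n",
                x$first_stage$r_squared, x$first_stage$f_stat))
  }
  invisible(x)
}
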