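#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR fit into one row per outcome contrast
#'
#' @param x an `mr2sps_fit`.
#' @param ... unused.
#' @return tibble with `exposure`, `drug_class`, `contrast`, `rrr`,
#'   `ci_low`, `ci_high`, `p`, `flag`, `unit` (RRR per `unit`-mmHg
#'   decrease).
#' @method tidy mr2sps_fit
#' @export
tidy.mr2sps_fit <- function(x, ...) {
  x$estimates
}

#' One-row model summary of an MR fit
#'
#' @param x an `mr2sps_fit`.
#' @param ... unused.
#' @return tibble with `exposure`, `drug_class`, `n`, first-stage
#'   `r_squared` and `f_stat` (NA for the naive comparator), `converged`.
#' @export
glance.mr2sps_fit <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure,
    drug_class = x$drug_class %||% NA_character_,
    n = x$second_stage_n,
    r_squared = if (is.null(x$first_stage)) NA_real_ else x$first_stage$r_squared,
    f_stat = if (is.null(x$first_stage)) NA_real_ else x$first_stage$f_stat,
    converged = x$converged
  )
}

#' Forest plot of MR relative risk ratios
#'
#' @param object an `mr2sps_fit` or a combined estimates tibble (e.g.
#'   `run_report$mr`).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mr2sps_fit
#' @export
autoplot.mr2sps_fit <- function(object, ...) {
  plot_mr_forest(tidy(object))
}

#' @rdname autoplot.mr2sps_fit
#' @param estimates tibble with `drug_class`, `contrast`, `rrr`, `ci_low`,
#'   `ci_high`, `exposure`.
#' @export
plot_mr_forest <- function(estimates, ...) {
  df <- dplyr::filter(estimates, !is.na(.data$rrr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rrr,
                                   y = interaction(.data$drug_class,
                                                   .data$exposure, sep = " / "),
                                   colour = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "RRR per BP decrement (10 mmHg SBP / 5 mmHg DBP)",
                  y = NULL, colour = "Contrast") +
    ggplot2::theme_minimal()
}

#' Effect-versus-effect plot for an SMR locus
#'
#' Plots per-SNP outcome effects against expression effects; under a single
#' shared causal variant the points fall on a line through the origin with
#' slope `b_xy`.
#'
#' @param scenario a `summary_scenario` (or tibble with `b_zx`, `b_zy`,
#'   `se_zx`, `se_zy`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_smr_locus <- function(scenario, ...) {
  df <- if (inherits(scenario, "summary_scenario")) scenario$snps else scenario
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b_zx, y = .data$b_zy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b_zy - 1.96 * .data$se_zy,
                                        ymax = .data$b_zy + 1.96 * .data$se_zy),
                           colour = "grey60", width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "eQTL effect on expression (b_zx)",
                  y = "GWAS effect on outcome (b_zy)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
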