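#' Select clumped, oriented instruments for every drug class
#'
#' Applies [select_candidates()], [ld_clump()] and [orient_weights()] per
#' drug class in the gene-region map, pooling regions of multi-gene classes
#' before clumping, and adds a `genome_wide` class over all SNPs (clumped at
#' its own, stricter threshold). Classes without passing SNPs are kept as
#' zero-row sets (a drug with "no proxy available" must flow through the
#' pipeline, not break it).
#'
#' @param gwas GWAS summary tibble (see [simulate_gwas_summary()]).
#' @param regions gene-region map, default [default_gene_regions()].
#' @param ld LD reference (see [ld_clump()]).
#' @param p_max,maf_min,flank candidate filters.
#' @param r2_max clump threshold within drug-gene regions (default 0.4).
#' @param r2_genome_wide clump threshold for the genome-wide set
#'   (default 0.001).
#' @param exposure label stored on each instrument set.
#' @return named list of `instrument_set` tibbles, one per drug class plus
#'   `genome_wide`.
#' @export
select_instruments <- function(gwas, regions = default_gene_regions(), ld,
                               p_max = 5e-8, maf_min = 0.01, flank = 100000,
                               r2_max = 0.4, r2_genome_wide = 0.001,
                               exposure = NULL) {
  classes <- unique(regions$drug_class)
  out <- lapply(classes, function(cl) {
    regs <- regions[regions$drug_class == cl, , drop = FALSE]
    cand <- suppressWarnings(dplyr::bind_rows(lapply(seq_len(nrow(regs)), function(i) {
      select_candidates(gwas, regs[i, ], p_max, maf_min, flank)
    })))
    cand <- dplyr::distinct(cand, .data$snp, .keep_all = TRUE)
    if (nrow(cand) == 0) {
      warn(sprintf("drug class %s: no proxy available", cl))
      return(orient_weights(cand[0, , drop = FALSE], exposure, cl))
    }
    orient_weights(ld_clump(cand, ld, r2_max), exposure, cl)
  })
  names(out) <- classes
  gw <- suppressWarnings(select_candidates(gwas, NULL, p_max, maf_min))
  out$genome_wide <- orient_weights(ld_clump(gw, ld, r2_genome_wide),
                                    exposure, "genome_wide")
  out
}

#' Frailty-category descriptives
#'
#' Counts and percentages by frailty category, in the layout of a baseline
#' characteristics table; percentages use half-up rounding to one decimal
#' and are recomputed from the counts.
#'
#' @param x either a cohort tibble with a category column, or a named/
#'   unnamed integer vector of category counts.
#' @param category_col category column name when `x` is a data frame.
#' @return tibble `category`, `n`, `pct`.
#' @examples
#' descriptives(c(non_frail = 192952, pre_frail = 95907, frail = 9759))
#' @export
descriptives <- function(x, category_col = "fi_category") {
  if (is.data.frame(x)) {
    counts <- table(x[[category_col]])
  } else {
    counts <- x
    if (is.null(names(counts))) {
      names(counts) <- c("non_frail", "pre_frail", "frail")[seq_along(counts)]
    }
  }
  n <- as.integer(counts)
  tibble::tibble(
    category = names(counts),
    n = n,
    pct = round_half_up(100 * n / sum(n), 1)
  )
}

#' Run the full synthetic drug-target MR pipeline
#'
#' Executes every stage on a synthetic cohort: genotype and cohort
#' generation, BP adjustment, frailty-index construction, per-class
#' instrument selection from a simulated external GWAS, genetic risk
#' scores, two-stage predictor substitution MR for both exposures and all
#' drug classes, and per-gene SMR + HEIDI on simulated summary-level data.
#' All randomness derives from `config$seed`, so reruns are byte-identical.
#'
#' @param config a [sim_config()] (must use the deficit outcome model).
#' @param regions gene-region map (default [default_gene_regions()]).
#' @param out_dir optional directory; when given, the report tables are
#'   written as TSV and the diagnostics as JSON.
#' @param smr_scenario generative scenario used for the per-gene
#'   summary-level data (default `"causal"`).
#' @param heidi_draws HEIDI Monte-Carlo draws.
#' @param max_missing missing-item exclusion threshold.
#' @return object of class `run_report`: list with `mr` (per class x
#'   exposure x contrast estimates), `smr`, `descriptives`, `diagnostics`
#'   (first-stage F/r2 per exposure, exclusion counts), `instruments`.
#' @export
run_pipeline <- function(config = sim_config(), regions = default_gene_regions(),
                         out_dir = NULL, smr_scenario = "causal",
                         heidi_draws = 1e5, max_missing = 10) {
  if (config$outcome_model != "deficits") {
    abort("run_pipeline expects the deficit-based outcome model")
  }
  genotypes <- simulate_genotypes(config)
  cohort <- simulate_cohort(genotypes, config)
  cohort <- adjust_bp(cohort)
  cohort <- compute_fi(cohort, max_missing = max_missing)
  n_undefined <- sum(is.na(cohort$fi))
  analytic <- dplyr::filter(cohort, !is.na(.data$fi))

  ld <- ld_from_panel(genotypes)
  mr_rows <- list()
  diag_rows <- list()
  inst_all <- list()
  for (exposure in c("sbp", "dbp")) {
    gwas <- simulate_gwas_summary(genotypes, config, exposure)
    inst <- select_instruments(gwas, regions, ld, exposure = exposure)
    inst_all[[exposure]] <- inst
    for (cl in names(inst)) {
      iset <- inst[[cl]]
      if (nrow(iset) == 0) {
        mr_rows[[paste(exposure, cl)]] <- tibble::tibble(
          exposure = toupper(exposure), drug_class = cl,
          contrast = NA_character_, rrr = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, flag = factor(NA, levels =
            c("significant", "suggestive", "null")),
          unit = if (exposure == "sbp") 10 else 5,
          log_rrr_per_mmhg = NA_real_, se_per_mmhg = NA_real_,
          note = "no proxy available"
        )
        next
      }
      grs <- build_grs(genotypes, iset)
      fit <- mr_2sps(analytic, grs$grs[analytic$person_id],
                     exposure = exposure, drug_class = cl)
      est <- fit$estimates
      est$note <- NA_character_
      mr_rows[[paste(exposure, cl)]] <- est
      diag_rows[[paste(exposure, cl)]] <- dplyr::bind_cols(
        tibble::tibble(exposure = toupper(exposure), drug_class = cl,
                       n_snps = nrow(iset)),
        fit$first_stage
      )
    }
  }
  mr_tbl <- dplyr::bind_rows(mr_rows)
  diag_tbl <- dplyr::bind_rows(diag_rows)

  # summary-level stage: one simulated cis dataset per mapped gene
  smr_rows <- list()
  genes <- regions$gene
  for (i in seq_along(genes)) {
    sc <- simulate_summary_scenario(
      smr_scenario, gene = genes[i],
      gene_start = regions$start[i], gene_end = regions$end[i],
      seed = derive_seed(config$seed, paste0("smr_", genes[i]))
    )
    row <- run_smr(sc, heidi_seed = derive_seed(config$seed, "heidi"),
                   heidi_draws = heidi_draws)
    if (!is.null(row)) smr_rows[[genes[i]]] <- row
  }
  smr_tbl <- dplyr::bind_rows(smr_rows)
  if (nrow(smr_tbl) > 0) {
    mt <- smr_multiple_testing(smr_tbl$p_smr, n_genes = max(nrow(smr_tbl), 1))
    smr_tbl$flag <- mt$flag
  }

  report <- structure(list(
    mr = mr_tbl,
    smr = smr_tbl,
    descriptives = descriptives(analytic),
    diagnostics = list(
      first_stage = diag_tbl,
      n_total = nrow(cohort),
      n_analytic = nrow(analytic),
      n_fi_undefined = n_undefined,
      n_missing_item_excluded = sum(cohort$fi_excluded, na.rm = TRUE),
      seed = config$seed
    ),
    instruments = inst_all
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  analytic n = %d (of %d)\n", x$diagnostics$n_analytic,
              x$diagnostics$n_total))
  print(x$descriptives)
  cat(sprintf("  MR rows: %d; SMR genes: %d\n", nrow(x$mr), nrow(x$smr)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$mr, file.path(out_dir, "mr_estimates.tsv"))
  readr::write_tsv(report$smr, file.path(out_dir, "smr_results.tsv"))
  readr::write_tsv(report$descriptives, file.path(out_dir, "descriptives.tsv"))
  readr::write_tsv(report$diagnostics$first_stage,
                   file.path(out_dir, "first_stage.tsv"))
  jsonlite::write_json(
    report$diagnostics[c("n_total", "n_analytic", "n_fi_undefined",
                         "n_missing_item_excluded", "seed")],
    file.path(out_dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
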