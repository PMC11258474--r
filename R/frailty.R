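#' Compute the deficit-accumulation frailty index
#'
#' The frailty index (FI) of a person is the sum of deficit values present
#' divided by the number of deficit items with a non-missing answer, giving
#' a ratio in \[0, 1\]. Item values may be fractional in \[0, 1\] (partial
#' deficits), though the synthetic generator produces binary items.
#'
#' The modified FI used in cardiometabolic sensitivity analyses is obtained
#' by excluding a configured item subset (`exclude_items`); the result is
#' flagged `modified = TRUE` whenever any items were excluded.
#'
#' @param data a data frame with one row per person and the deficit items in
#'   columns (missing answers as `NA`); non-deficit columns are preserved.
#' @param items character vector of deficit column names; defaults to every
#'   column matching `^deficit_`.
#' @param exclude_items optional character vector of item columns to drop
#'   before computing the FI (e.g. [cardiometabolic_items()]).
#' @param max_missing persons with at least this many missing items are
#'   flagged `fi_excluded = TRUE` (the missing-data sensitivity rule);
#'   `Inf` disables the flag.
#' @return The input tibble with columns `fi` (NA when every item is
#'   missing), `n_items_answered`, `n_items_missing`, `fi_category`,
#'   `fi_modified`, `fi_excluded` appended.
#' @examples
#' d <- tibble::tibble(deficit_01 = c(0, 1, NA), deficit_02 = c(0, 1, 1))
#' compute_fi(d, items = c("deficit_01", "deficit_02"))
#' @export
compute_fi <- function(data, items = NULL, exclude_items = NULL,
                       max_missing = Inf) {
  if (is.null(items)) items <- grep("^deficit_", names(data), value = TRUE)
  if (length(items) == 0) abort("no deficit item columns found")
  missing_cols <- setdiff(items, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("deficit columns absent from data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_total <- length(items)
  used <- setdiff(items, exclude_items)
  if (length(used) == 0) abort("all deficit items excluded")
  mat <- as.matrix(data[used])
  if (any(mat < 0 | mat > 1, na.rm = TRUE)) {
    abort("deficit values must lie in [0, 1]")
  }
  n_answered <- rowSums(!is.na(mat))
  n_missing_all <- rowSums(is.na(as.matrix(data[items])))
  fi <- ifelse(n_answered > 0,
               rowSums(mat, na.rm = TRUE) / n_answered, NA_real_)
  if (any(n_answered == 0)) {
    warn(sprintf("%d person(s) with no answered items: FI undefined (NA)",
                 sum(n_answered == 0)))
  }
  out <- tibble::as_tibble(data)
  out$fi <- fi
  out$n_items_answered <- as.integer(n_answered)
  out$n_items_missing <- as.integer(n_missing_all)
  out$fi_category <- categorize_fi(fi)
  out$fi_modified <- length(setdiff(items, used)) > 0
  out$fi_excluded <- n_missing_all >= max_missing
  out
}

#' Assign frailty categories from the frailty index
#'
#' Categories follow the validated clinical cutoffs: non-frail for FI below
#' 0.12, pre-frail for FI from 0.12 to 0.24 (closed interval), frail above
#' 0.24.
#'
#' @param fi numeric vector of frailty-index values in \[0, 1\] (`NA`
#'   allowed and propagated).
#' @return factor with levels `non_frail`, `pre_frail`, `frail`.
#' @examples
#' categorize_fi(c(0.119, 0.12, 0.24, 0.25))
#' @export
categorize_fi <- function(fi) {
  bad <- !is.na(fi) & (fi < 0 | fi > 1)
  if (any(bad)) abort("frailty index values must lie in [0, 1]")
  out <- rep(NA_character_, length(fi))
  out[!is.na(fi) & fi < 0.12] <- "non_frail"
  out[!is.na(fi) & fi >= 0.12 & fi <= 0.24] <- "pre_frail"
  out[!is.na(fi) & fi > 0.24] <- "frail"
  factor(out, levels = c("non_frail", "pre_frail", "frail"))
}

#' Flag persons excluded by the missing-item rule
#'
#' The missing-data sensitivity analysis restricts to persons with fewer
#' than `max_missing` missing deficit items (default: excluded when 10 or
#' more items are missing).
#'
#' @param data data frame with deficit item columns.
#' @param items deficit column names (default: all `^deficit_` columns).
#' @param max_missing exclusion threshold (missing-count at or above which a
#'   person is excluded).
#' @return logical vector, `TRUE` = person retained.
#' @export
apply_missingness_filter <- function(data, items = NULL, max_missing = 10) {
  if (is.null(items)) items <- grep("^deficit_", names(data), value = TRUE)
  n_missing <- rowSums(is.na(as.matrix(data[items])))
  n_missing < max_missing
}
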