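# Regression metrics, error-uncertainty rank correlation, and the
# selective-prediction coverage sweep.

#' Regression metrics for yield predictions
#'
#' MAE, RMSE and the coefficient of determination, tidy-eval style on a
#' data frame of predictions. R^2 is `1 - SSres/SStot` with SStot about the
#' mean of the observed values; when the observed values are constant R^2 is
#' undefined and returned as `NaN` with a warning.
#'
#' @param data A data frame.
#' @param truth,estimate Columns of observed and predicted yields (unquoted).
#' @return A one-row tibble: `mae`, `rmse`, `r2`, `n`.
#' @examples
#' d <- tibble::tibble(y = c(0, 10), yhat = c(1, 9))
#' regression_metrics(d, y, yhat)
#' @export
regression_metrics <- function(data, truth, estimate) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yhat <- rlang::eval_tidy(rlang::enquo(estimate), data)
  stopifnot(length(y) == length(yhat))
  if (length(y) < 2L) stopf("need at least two observations")
  e <- y - yhat
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) {
    warnf("constant observed values: R^2 is undefined")
    NaN
  } else {
    1 - sum(e^2) / ss_tot
  }
  tibble::tibble(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2,
                 n = length(y))
}

#' Spearman rank correlation between absolute error and uncertainty
#'
#' Measures uncertainty-quantification quality: a well-calibrated uncertainty
#' score ranks exactly the reactions the model gets wrong. Ties receive
#' average ranks; a constant argument makes the correlation undefined
#' (returned as `NA` with a warning).
#'
#' @param data A data frame.
#' @param truth,estimate Observed and predicted yield columns (unquoted).
#' @param score Uncertainty score column (unquoted).
#' @return A one-row tibble: `spearman_rho`, `n`.
#' @export
spearman_error_uncertainty <- function(data, truth, estimate, score) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yhat <- rlang::eval_tidy(rlang::enquo(estimate), data)
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  stopifnot(length(y) == length(yhat), length(y) == length(s))
  if (length(y) < 2L) stopf("need at least two observations")
  abs_err <- abs(y - yhat)
  if (stats::sd(abs_err) == 0 || stats::sd(s) == 0) {
    warnf("constant errors or scores: Spearman rho is undefined")
    return(tibble::tibble(spearman_rho = NA_real_, n = length(y)))
  }
  tibble::tibble(
    spearman_rho = stats::cor(abs_err, s, method = "spearman"),
    n = length(y)
  )
}

# Indices of the ceil(coverage * n) lowest-uncertainty rows; ties are broken
# by original row order (stable), so exact coverage fractions are reproduced
# regardless of score ties.
kept_indices <- function(score, coverage) {
  n <- length(score)
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 1) {
    stopf("coverage must lie in (0, 1]")
  }
  keep_n <- ceiling(coverage * n)
  order(score, seq_len(n))[seq_len(keep_n)]
}

#' Selective-prediction metrics at one coverage rate
#'
#' Keeps the `ceiling(coverage * n)` predictions with the smallest
#' uncertainty score (stable sort, ties by original row order) and computes
#' MAE/RMSE on the kept subset: the metric a practitioner sees after
#' abstaining on the most uncertain reactions.
#'
#' @inheritParams spearman_error_uncertainty
#' @param coverage Fraction of predictions retained, in `(0, 1]`.
#' @return A one-row tibble: `coverage`, `kept_n`, `mae`, `rmse`.
#' @export
selective_metrics <- function(data, truth, estimate, score, coverage) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yhat <- rlang::eval_tidy(rlang::enquo(estimate), data)
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  stopifnot(length(y) == length(yhat), length(y) == length(s))
  keep <- kept_indices(s, coverage)
  e <- y[keep] - yhat[keep]
  tibble::tibble(coverage = coverage, kept_n = length(keep),
                 mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Coverage sweep for selective prediction
#'
#' [selective_metrics()] evaluated over a grid of coverage rates (default
#' 100% down to 30% in steps of 10). The coverage-1 row always equals the
#' unrejected metrics.
#'
#' @inheritParams selective_metrics
#' @param coverages Numeric vector of coverage rates, each in `(0, 1]`.
#' @return A tibble of class `yieldnet_coverage` with one row per coverage.
#' @export
coverage_curve <- function(data, truth, estimate, score,
                           coverages = seq(1.0, 0.3, by = -0.1)) {
  tq <- rlang::enquo(truth); eq <- rlang::enquo(estimate)
  sq <- rlang::enquo(score)
  rows <- lapply(coverages, function(cv) {
    selective_metrics(data, !!tq, !!eq, !!sq, coverage = cv)
  })
  structure(dplyr::bind_rows(rows),
            class = c("yieldnet_coverage", "tbl_df", "tbl", "data.frame"))
}
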