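# broom-style tidiers for fitted/derived objects.

#' Tidy an FDR curve
#'
#' @param x A [fdr_curve()] result.
#' @param ... Unused.
#' @return A plain tibble of the curve rows.
#' @method tidy ctds_fdr_curve
#' @export
tidy.ctds_fdr_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an FDR curve
#'
#' @param x A [fdr_curve()] result.
#' @param alpha Threshold used for the accepted-count columns.
#' @param ... Unused.
#' @return Tibble with `n_psms`, `n_targets`, `n_decoys`, `factor`,
#'   `n_excluded`, `min_q_tds`, `min_q_ctds`, `n_accepted_tds`,
#'   `n_accepted_ctds` at `alpha`.
#' @method glance ctds_fdr_curve
#' @export
glance.ctds_fdr_curve <- function(x, alpha = 0.01, ...) {
  n <- nrow(x)
  tibble::tibble(
    n_psms = n,
    n_targets = x$cum_target[n],
    n_decoys = x$cum_decoy[n],
    factor = attr(x, "factor") %||% NA_real_,
    n_excluded = attr(x, "n_excluded"),
    min_q_tds = min(x$q_tds),
    min_q_ctds = min(x$q_ctds),
    n_accepted_tds = accept_at(x, alpha, "tds")$n_accepted,
    n_accepted_ctds = accept_at(x, alpha, "ctds")$n_accepted
  )
}

#' Tidy an estimator evaluation
#'
#' @param x An [evaluate_estimators()] result.
#' @param ... Unused.
#' @method tidy ctds_eval
#' @export
tidy.ctds_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row-per-method summary of an estimator evaluation
#'
#' @param x An [evaluate_estimators()] result.
#' @param ... Unused.
#' @return Tibble with per-method mean absolute calibration error and mean
#'   absolute FMR deviation from the nominal threshold.
#' @method glance ctds_eval
#' @export
glance.ctds_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)]) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_abs_error = mean(.data$abs_error, na.rm = TRUE),
      mean_fmr_deviation = mean(abs(.data$fmr - .data$alpha), na.rm = TRUE),
      mean_n_accepted = mean(.data$n_accepted),
      .groups = "drop"
    )
}
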