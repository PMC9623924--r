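# ggplot2 visualisations of curves, probability distributions and
# estimator evaluations.

#' Plot an FDR curve
#'
#' Estimated FDR (q-values) of each method against the number of accepted
#' target PSMs.
#'
#' @param object A [fdr_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctds_fdr_curve
#' @export
autoplot.ctds_fdr_curve <- function(object, ...) {
  dat <- tidy.ctds_fdr_curve(object)
  qcols <- intersect(c("q_tds", "q_tds_corrected", "q_ctds"), names(dat))
  long <- dat |>
    dplyr::select(dplyr::all_of(c("cum_target", qcols))) |>
    tidyr::pivot_longer(dplyr::all_of(qcols),
      names_to = "method", values_to = "q",
      names_prefix = "q_"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cum_target, y = .data$q, colour = .data$method
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "accepted target PSMs", y = "estimated FDR (q-value)",
      colour = "method"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an estimator evaluation
#'
#' Estimated FDR and true false-discovery proportion (and FMR when present)
#' against the nominal threshold, per method; the identity line marks
#' perfect calibration.
#'
#' @param object An [evaluate_estimators()] result.
#' @param what `"calibration"` (|estimate - true FDP|), `"fmr"` or
#'   `"fdp"` (true FDP vs nominal).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctds_eval
#' @export
autoplot.ctds_eval <- function(object, what = c("fdp", "fmr", "calibration"), ...) {
  what <- match.arg(what)
  dat <- tidy.ctds_eval(object)
  y <- switch(what, fdp = "true_fdp", fmr = "fmr", calibration = "abs_error")
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$alpha, y = .data[[y]], colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "FDR threshold", colour = "method") +
    ggplot2::theme_minimal()
  if (what != "calibration") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed")
  }
  p + ggplot2::labs(y = switch(what,
    fdp = "true false-discovery proportion",
    fmr = "entrapment false match rate",
    calibration = "|estimate - true FDP|"
  ))
}

#' Histogram of candidate target probabilities
#'
#' The distribution of the per-spectrum probability that an incorrect match
#' lands on a target candidate, split by the assigned label, optionally
#' after applying a correction factor to the decoy counts.
#'
#' @param psms PSM tibble with `label`, `target_count`, `decoy_count`.
#' @param factor Optional correction factor.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_p_distribution <- function(psms, factor = NULL, bins = 50) {
  p <- corrected_p_target(psms$target_count, psms$decoy_count, factor %||% 1)
  dat <- tibble::tibble(p_target = p, label = psms$label)
  dat <- dat[!is.na(dat$p_target), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p_target)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0.5) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "P(incorrect match is a target candidate)", y = "spectra") +
    ggplot2::theme_minimal()
}
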