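# FDR estimation: classical target-decoy (TDS), candidate-weighted (cTDS),
# q-values, threshold acceptance, entrapment FMR, probability summaries.

#' Target-decoy FDR estimators
#'
#' `tds_fdr()` is the classical estimate `(D + 1) / T` from `T` target and
#' `D` decoy PSMs; `tds_fdr_corrected()` multiplies it by a correction
#' factor used when the target and decoy databases differ in size;
#' `correction_factor()` computes that factor as the ratio of target to
#' decoy PSMs at a low rank (rank 5 by default), where matches are assumed
#' incorrect.
#'
#' @param T_count Number of target PSMs (>= 1).
#' @param D_count Number of decoy PSMs (>= 0).
#' @param factor Positive correction factor.
#' @return Estimated FDR (may exceed 1; reported uncapped).
#' @examples
#' tds_fdr(100, 0)            # 0.01
#' tds_fdr_corrected(100, 1, 0.5)
#' @export
tds_fdr <- function(T_count, D_count) {
  if (any(T_count < 1)) {
    abort("FDR is undefined with zero target PSMs (T must be >= 1).")
  }
  (D_count + 1) / T_count
}

#' @rdname tds_fdr
#' @export
tds_fdr_corrected <- function(T_count, D_count, factor) {
  stopifnot(factor > 0)
  tds_fdr(T_count, D_count) * factor
}

#' @rdname tds_fdr
#' @param psms PSM tibble with columns `rank` and `label`.
#' @param rank Rank whose PSMs are used (default 5).
#' @export
correction_factor <- function(psms, rank = 5L) {
  at <- psms[psms$rank == rank, ]
  n_t <- sum(at$label == "target")
  n_d <- sum(at$label == "decoy")
  if (n_d == 0) {
    abort(sprintf(
      "No decoy PSMs at rank %d; cannot form a correction factor. Try a different rank.",
      rank
    ))
  }
  n_t / n_d
}

#' Candidate-weighted FDR estimate (cTDS)
#'
#' Weights every hit by the expectation of a geometric random variable: an
#' incorrectly matched spectrum lands on a target candidate with probability
#' `p_target`, so each observed decoy hit represents `1/p_decoy` incorrect
#' matches and each target hit `1/p_target`. The estimate is
#' `sum(1/p_decoy over decoy PSMs) / sum(1/p_target over target PSMs)`.
#' When every spectrum has equal target and decoy candidate counts this
#' reduces exactly to `D / T`.
#'
#' PSMs whose probabilities are undefined (no candidates on either side) are
#' excluded from both sums; their number is returned in the `n_excluded`
#' attribute.
#'
#' @param psms PSM tibble carrying `label`, `target_count`, `decoy_count`
#'   (e.g. from [annotate_psms()] or [simulate_search()]).
#' @return The cTDS FDR estimate (uncapped), with attribute `n_excluded`.
#' @export
ctds_fdr <- function(psms) {
  req <- c("label", "target_count", "decoy_count")
  if (!all(req %in% names(psms))) {
    abort("`psms` must carry label, target_count and decoy_count columns.")
  }
  total <- psms$target_count + psms$decoy_count
  undefined <- total == 0
  p_t <- psms$target_count / total
  p_d <- psms$decoy_count / total
  is_t <- psms$label == "target" & !undefined
  is_d <- psms$label == "decoy" & !undefined
  if (!any(is_t)) {
    abort("cTDS FDR is undefined without target PSMs.")
  }
  denom <- sum(1 / p_t[is_t])
  num <- sum(1 / p_d[is_d])
  structure(num / denom, n_excluded = sum(undefined))
}

#' Score-ordered FDR curve with TDS and cTDS estimates and q-values
#'
#' Sorts rank-1 PSMs by descending score (ties: decoys before targets — the
#' conservative order — then by spectrum id for determinism) and computes at
#' every cutoff the cumulative target count `T`, decoy count `D`, the TDS
#' estimate `(D + 1)/T`, optionally its correction-factor-scaled version,
#' and the cTDS estimate from cumulative geometric weights. q-values are the
#' running minimum of each estimate from the most permissive cutoff upward,
#' capped at 1; raw FDR columns are left uncapped.
#'
#' @param psms PSM tibble with `spectrum_id`, `rank`, `score`, `label` and
#'   candidate counts. Rows with `rank != 1` are dropped.
#' @param factor Optional correction factor; when supplied the curve gains
#'   `fdr_tds_corrected` and `q_tds_corrected` columns.
#' @return A tibble of class `ctds_fdr_curve` with columns `score`,
#'   `spectrum_id`, `label`, `cum_target`, `cum_decoy`, `fdr_tds`,
#'   `fdr_ctds`, `q_tds`, `q_ctds` (and corrected variants when `factor`
#'   is given). Attribute `n_excluded` counts PSMs excluded from the cTDS
#'   sums for lack of candidates.
#' @export
fdr_curve <- function(psms, factor = NULL) {
  psms <- psms[psms$rank == 1L, ]
  if (nrow(psms) == 0) {
    abort("No rank-1 PSMs to build an FDR curve from.")
  }
  if (anyDuplicated(psms$spectrum_id)) {
    abort("More than one rank-1 PSM for the same spectrum id.")
  }
  is_decoy <- psms$label == "decoy"
  ord <- order(-psms$score, !is_decoy, psms$spectrum_id)
  psms <- psms[ord, ]
  is_t <- psms$label == "target"
  cum_t <- cumsum(is_t)
  cum_d <- cumsum(!is_t)
  total <- psms$target_count + psms$decoy_count
  undefined <- is.na(total) | total == 0
  w_t <- ifelse(is_t & !undefined, total / psms$target_count, 0)
  w_d <- ifelse(!is_t & !undefined, total / psms$decoy_count, 0)
  cum_wt <- cumsum(w_t)
  cum_wd <- cumsum(w_d)
  fdr_tds <- ifelse(cum_t > 0, (cum_d + 1) / cum_t, Inf)
  fdr_ctds <- ifelse(cum_wt > 0, cum_wd / cum_wt, Inf)
  qval <- function(fdr) pmin(rev(cummin(rev(fdr))), 1)
  out <- tibble::tibble(
    score = psms$score,
    spectrum_id = psms$spectrum_id,
    label = psms$label,
    cum_target = cum_t,
    cum_decoy = cum_d,
    fdr_tds = fdr_tds,
    fdr_ctds = fdr_ctds,
    q_tds = qval(fdr_tds),
    q_ctds = qval(fdr_ctds)
  )
  if (!is.null(factor)) {
    out$fdr_tds_corrected <- fdr_tds * factor
    out$q_tds_corrected <- qval(out$fdr_tds_corrected)
  }
  extra <- setdiff(
    intersect(c("ref_class", "truth"), names(psms)),
    names(out)
  )
  for (col in extra) out[[col]] <- psms[[col]]
  structure(
    out,
    class = c("ctds_fdr_curve", class(out)),
    n_excluded = sum(undefined),
    factor = factor
  )
}

curve_q_column <- function(curve, method) {
  col <- switch(method,
    tds = "q_tds",
    ctds = "q_ctds",
    tds_corrected = "q_tds_corrected"
  )
  if (!col %in% names(curve)) {
    abort(sprintf(
      "Method '%s' not available on this curve (was `factor` supplied to fdr_curve()?).",
      method
    ))
  }
  curve[[col]]
}

#' Accept PSMs at an FDR threshold
#'
#' Takes the largest score prefix of an FDR curve whose q-value is at most
#' `alpha` and returns its score cutoff and accepted target-PSM count.
#' q-value thresholding makes accepted sets nested across `alpha`.
#'
#' @param curve A [fdr_curve()] result.
#' @param alpha FDR threshold in (0, 1].
#' @param method `"ctds"`, `"tds"` or `"tds_corrected"`.
#' @return One-row tibble: `method`, `alpha`, `score_cutoff` (`NA` when no
#'   prefix qualifies), `n_accepted` (accepted target PSMs), `n_decoy`
#'   (decoys above the cutoff).
#' @export
accept_at <- function(curve, alpha = 0.01, method = c("ctds", "tds", "tds_corrected")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha <= 1)
  q <- curve_q_column(curve, method)
  ok <- which(q <= alpha)
  if (length(ok) == 0) {
    return(tibble::tibble(
      method = method, alpha = alpha,
      score_cutoff = NA_real_, n_accepted = 0L, n_decoy = 0L
    ))
  }
  i <- max(ok)
  tibble::tibble(
    method = method,
    alpha = alpha,
    score_cutoff = curve$score[i],
    n_accepted = curve$cum_target[i],
    n_decoy = curve$cum_decoy[i]
  )
}

#' Accepted PSM rows at a threshold
#'
#' Convenience accessor returning the curve rows above (and including) the
#' acceptance cutoff of [accept_at()].
#'
#' @inheritParams accept_at
#' @return The accepted prefix of the curve (possibly zero rows).
#' @export
accepted_psms <- function(curve, alpha = 0.01, method = c("ctds", "tds", "tds_corrected")) {
  method <- match.arg(method)
  q <- curve_q_column(curve, method)
  ok <- which(q <= alpha)
  if (length(ok) == 0) return(curve[0, ])
  curve[seq_len(max(ok)), ]
}

#' Entrapment false match rate
#'
#' Among accepted target PSMs labelled by provenance, the ratio of hits to
#' the entrapment database over hits to the reference database,
#' `FMR = n_entrapment / n_reference`. Decoy PSMs in the input are ignored.
#'
#' @param accepted Tibble of accepted PSMs with columns `label` and
#'   `ref_class` (`"reference"` or `"entrapment"` for target PSMs).
#' @return The FMR; `NA` with a warning when there are no reference hits.
#' @export
fmr <- function(accepted) {
  if (!"ref_class" %in% names(accepted)) {
    abort("`accepted` must carry a ref_class column (reference/entrapment).")
  }
  t_rows <- accepted[accepted$label == "target", ]
  n_ref <- sum(t_rows$ref_class == "reference", na.rm = TRUE)
  n_ent <- sum(t_rows$ref_class == "entrapment", na.rm = TRUE)
  if (n_ref == 0) {
    warn("No reference target PSMs; FMR is undefined.")
    return(NA_real_)
  }
  n_ent / n_ref
}

#' Summarise the distribution of candidate target probabilities
#'
#' For target and decoy PSMs separately, the fraction of spectra whose
#' probability of an incorrect match being a target candidate is below,
#' exactly at, and above 0.5. Equality is tested on the integer counts
#' (`target_count == decoy_count`, or `target_count == decoy_count * factor`
#' when a correction factor is supplied), not on floating-point ratios.
#'
#' @param psms PSM tibble with `label`, `target_count`, `decoy_count`.
#' @param factor Optional correction factor applied to decoy counts.
#' @return Tibble with one row per label: `label`, `n`, `frac_below`,
#'   `frac_equal`, `frac_above` (rows sum to 1 when `n > 0`).
#' @export
p_distribution_summary <- function(psms, factor = NULL) {
  f <- factor %||% 1
  stopifnot(f > 0)
  d_eff <- psms$decoy_count * f
  total <- psms$target_count + d_eff
  keep <- !is.na(total) & total > 0
  dat <- tibble::tibble(
    label = psms$label[keep],
    below = psms$target_count[keep] < d_eff[keep],
    equal = psms$target_count[keep] == d_eff[keep]
  )
  dat |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_below = mean(.data$below),
      frac_equal = mean(.data$equal),
      frac_above = mean(!.data$below & !.data$equal),
      .groups = "drop"
    )
}
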