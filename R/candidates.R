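# Precursor-mass candidate index and per-spectrum candidate counts.

#' Build a precursor-mass index over digested peptides
#'
#' Indexes all (mass, origin) pairs of a peptide mass table — one entry per
#' modification variant per distinct peptide sequence — for O(log n + hits)
#' range queries. Entrapment peptides index as targets (an entrapment
#' database is part of the target database during search).
#'
#' @param peptide_table Tibble with columns `mass` and `origin`
#'   ([peptide_mass_table()] output).
#' @return A `ctds_mass_index` object.
#' @export
build_mass_index <- function(peptide_table) {
  stopifnot(nrow(peptide_table) > 0, all(c("mass", "origin") %in% names(peptide_table)))
  is_target <- peptide_table$origin != "decoy"
  t_mass <- sort(peptide_table$mass[is_target])
  d_mass <- sort(peptide_table$mass[!is_target])
  structure(
    list(target = t_mass, decoy = d_mass),
    class = "ctds_mass_index"
  )
}

#' @export
print.ctds_mass_index <- function(x, ...) {
  cat(sprintf(
    "<ctds_mass_index> %d target and %d decoy mass entries (%.4f-%.4f Da)\n",
    length(x$target), length(x$decoy),
    min(x$target, x$decoy), max(x$target, x$decoy)
  ))
  invisible(x)
}

#' @export
length.ctds_mass_index <- function(x) length(x$target) + length(x$decoy)

# Count of sorted `masses` within [m(1 - tol), m(1 + tol)], vectorised over m.
count_in_window <- function(masses, m, tol_ppm) {
  half <- m * tol_ppm * 1e-6
  lo <- m - half
  hi <- m + half
  findInterval(hi, masses) - findInterval(lo, masses, left.open = TRUE)
}

#' Count candidate peptides per spectrum
#'
#' For each spectrum, counts the indexed target and decoy mass entries whose
#' mass lies within `|mass - neutral_mass| <= neutral_mass * tol_ppm * 1e-6`
#' (symmetric window, boundary inclusive), and derives the probability that
#' an incorrect match lands on a target candidate,
#' `p_target = target_count / (target_count + decoy_count)`, its complement
#' `p_decoy`, and the geometric-expectation weights `w_target = 1/p_target`
#' and `w_decoy = 1/p_decoy` used by the candidate-weighted FDR estimator.
#' Spectra with no candidates get `NA` probabilities and weights.
#'
#' @param index A [build_mass_index()] object.
#' @param spectra Tibble with columns `spectrum_id`, `neutral_mass`
#'   (monoisotopic, uncharged, Da) and optionally `charge`.
#' @param tol_ppm Precursor tolerance in parts per million.
#' @return Tibble with columns `spectrum_id`, `target_count`, `decoy_count`,
#'   `p_target`, `p_decoy`, `w_target`, `w_decoy`.
#' @export
count_candidates <- function(index, spectra, tol_ppm = 20) {
  stopifnot(inherits(index, "ctds_mass_index"), tol_ppm > 0)
  if (any(spectra$neutral_mass <= 0)) {
    abort("All `neutral_mass` values must be positive.")
  }
  m <- spectra$neutral_mass
  t_count <- count_in_window(index$target, m, tol_ppm)
  d_count <- count_in_window(index$decoy, m, tol_ppm)
  total <- t_count + d_count
  p_t <- ifelse(total > 0, t_count / total, NA_real_)
  p_d <- ifelse(total > 0, d_count / total, NA_real_)
  tibble::tibble(
    spectrum_id = spectra$spectrum_id,
    target_count = as.integer(t_count),
    decoy_count = as.integer(d_count),
    p_target = p_t,
    p_decoy = p_d,
    w_target = ifelse(!is.na(p_t) & p_t > 0, 1 / p_t, NA_real_),
    w_decoy = ifelse(!is.na(p_d) & p_d > 0, 1 / p_d, NA_real_)
  )
}

#' Attach candidate counts to a PSM table
#'
#' Joins per-spectrum candidate counts onto PSMs. Counts already embedded in
#' the PSM table (e.g. emitted by a search engine) take precedence;
#' disagreements with the computed counts are reported with a message. PSMs
#' with neither embedded nor computable counts are an error.
#'
#' @param psms PSM tibble (see [read_psm_table()]).
#' @param counts [count_candidates()] output.
#' @return `psms` with `target_count`, `decoy_count`, `p_target`, `p_decoy`,
#'   `w_target`, `w_decoy` columns filled.
#' @export
annotate_psms <- function(psms, counts) {
  if (nrow(psms) == 0) return(psms)
  has_embedded <- all(c("target_count", "decoy_count") %in% names(psms)) &&
    any(!is.na(psms$target_count))
  computed <- counts[match(psms$spectrum_id, counts$spectrum_id), ]
  if (has_embedded) {
    own_ok <- !is.na(psms$target_count) & !is.na(psms$decoy_count)
    both <- own_ok & !is.na(computed$target_count)
    mismatch <- both & (psms$target_count != computed$target_count |
                          psms$decoy_count != computed$decoy_count)
    if (any(mismatch)) {
      inform(sprintf(
        "%d PSM(s) carry embedded candidate counts that differ from the computed ones; embedded counts kept.",
        sum(mismatch)
      ))
    }
    t_count <- ifelse(own_ok, psms$target_count, computed$target_count)
    d_count <- ifelse(own_ok, psms$decoy_count, computed$decoy_count)
  } else {
    t_count <- computed$target_count
    d_count <- computed$decoy_count
  }
  missing <- is.na(t_count) | is.na(d_count)
  if (any(missing)) {
    abort(sprintf(
      "No candidate counts available for spectrum id(s): %s",
      paste(head(unique(psms$spectrum_id[missing]), 10), collapse = ", ")
    ))
  }
  total <- t_count + d_count
  psms$target_count <- as.integer(t_count)
  psms$decoy_count <- as.integer(d_count)
  psms$p_target <- ifelse(total > 0, t_count / total, NA_real_)
  psms$p_decoy <- ifelse(total > 0, d_count / total, NA_real_)
  psms$w_target <- ifelse(t_count > 0, total / t_count, NA_real_)
  psms$w_decoy <- ifelse(d_count > 0, total / d_count, NA_real_)
  psms
}

#' Correction-factor-adjusted target probability
#'
#' Recomputes `p_target` after scaling the decoy candidate count by a
#' correction factor (the rank-5 target/decoy PSM ratio of
#' [correction_factor()]), `target / (target + decoy * factor)`. With
#' `factor = 1` this is the plain candidate ratio. Used to view candidate
#' probability distributions from unequal-size decoy databases on a common
#' scale.
#'
#' @param target_count,decoy_count Integer candidate counts (vectorised).
#' @param factor Positive correction factor.
#' @return Numeric vector of adjusted probabilities; `NA` (with a warning)
#'   where both counts are zero.
#' @export
corrected_p_target <- function(target_count, decoy_count, factor = 1) {
  stopifnot(factor > 0)
  total <- target_count + decoy_count * factor
  if (any(total == 0)) {
    warn("Some spectra have zero candidates on both sides; returning NA for them.")
  }
  ifelse(total > 0, target_count / total, NA_real_)
}

#' Export candidate counts as TSV
#'
#' @param counts [count_candidates()] output.
#' @param path Output path.
#' @export
write_candidate_counts <- function(counts, path) {
  readr::write_tsv(
    counts[, c("spectrum_id", "target_count", "decoy_count", "p_target")],
    path
  )
  invisible(path)
}
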