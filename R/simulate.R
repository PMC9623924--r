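# Ground-truth simulation of search results for validating FDR estimators.

#' Simulation configuration
#'
#' Defines the generative model for a synthetic search-result population:
#' a fraction `frac_incorrect` of spectra get an incorrect best match; an
#' incorrect match has per-spectrum candidate counts `target_count ~
#' 1 + Poisson(lambda_target)` and `decoy_count ~ 1 + Poisson(lambda_decoy)`
#' and is assigned the target label with probability
#' `target_count / (target_count + decoy_count)`; scores follow a
#' two-component Gaussian mixture with the correct component above the
#' incorrect one. Correct matches also receive drawn candidate counts (a
#' correct match still has a candidate list). Incorrect target matches are
#' flagged `ref_class = "entrapment"`; correct matches are `"reference"`
#' unless flipped to entrapment with probability `entrap_frac`. Ranks
#' `2..n_ranks` are always incorrect and exercise the rank-based correction
#' factor.
#'
#' The defaults put the bulk of candidate probabilities near 0.5 with a few
#' percent exactly at 0.5, the regime observed in large-scale human searches.
#'
#' @param n_spectra Number of spectra.
#' @param frac_incorrect Fraction of spectra whose best match is incorrect.
#' @param lambda_target,lambda_decoy Poisson means of the candidate-count
#'   model (counts are `1 + Poisson(lambda)`).
#' @param mu_correct,sd_correct,mu_incorrect,sd_incorrect Score mixture.
#' @param entrap_frac Probability a correct match is labelled entrapment.
#' @param n_ranks Ranks generated per spectrum (rank 1 plus incorrect
#'   sub-ranks).
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_spectra = 50000L,
                       frac_incorrect = 0.3,
                       lambda_target = 100,
                       lambda_decoy = 100,
                       mu_correct = 3, sd_correct = 1,
                       mu_incorrect = 0, sd_incorrect = 1,
                       entrap_frac = 0,
                       n_ranks = 5L,
                       seed = 1L) {
  cfg <- list(
    n_spectra = as.integer(n_spectra),
    frac_incorrect = frac_incorrect,
    lambda_target = lambda_target,
    lambda_decoy = lambda_decoy,
    mu_correct = mu_correct, sd_correct = sd_correct,
    mu_incorrect = mu_incorrect, sd_incorrect = sd_incorrect,
    entrap_frac = entrap_frac,
    n_ranks = as.integer(n_ranks),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_spectra >= 1,
    cfg$frac_incorrect >= 0, cfg$frac_incorrect <= 1,
    cfg$lambda_target > 0, cfg$lambda_decoy > 0,
    cfg$sd_correct > 0, cfg$sd_incorrect > 0,
    cfg$mu_correct > cfg$mu_incorrect,
    cfg$entrap_frac >= 0, cfg$entrap_frac <= 1,
    cfg$n_ranks >= 1
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a random protein database
#'
#' I.i.d. sequences with lengths 10 + Poisson(mean_length - 10) and residues
#' drawn from `aa_freqs`. A fixture generator for the digestion, decoy and
#' candidate-index modules.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param mean_length Mean sequence length (>= 10).
#' @param aa_freqs Named probability vector over the 20 residues.
#' @param seed Integer seed.
#' @return Protein tibble ([read_fasta()] layout), `origin = "target"`.
#' @export
simulate_proteome <- function(n_proteins, mean_length = 300,
                              aa_freqs = NULL, seed = 1L) {
  stopifnot(n_proteins >= 1, mean_length >= 10)
  if (is.null(aa_freqs)) {
    aa_freqs <- setNames(rep(1 / 20, 20), names(aa_masses))
  }
  if (abs(sum(aa_freqs) - 1) > 1e-9) abort("`aa_freqs` must sum to 1.")
  with_seed(seed, {
    lens <- 10L + rpois(n_proteins, mean_length - 10)
    letters20 <- names(aa_freqs)
    seqs <- vapply(lens, function(L) {
      paste(sample(letters20, L, replace = TRUE, prob = aa_freqs), collapse = "")
    }, character(1))
    tibble::tibble(
      accession = sprintf("SIM%05d", seq_len(n_proteins)),
      description = "simulated protein",
      sequence = seqs,
      origin = "target"
    )
  })
}

#' Simulate a search-result population with known ground truth
#'
#' Draws rank-1 PSMs for `n_spectra` spectra under the generative model of
#' [sim_config()], plus always-incorrect sub-rank PSMs at ranks
#' `2..n_ranks`. The per-spectrum truth (correct flag, drawn candidate
#' counts, assigned label) is returned alongside.
#'
#' @param config A [sim_config()].
#' @return List with `psms` (tibble: `spectrum_id`, `rank`, `peptide`,
#'   `score`, `label`, `ref_class`, `target_count`, `decoy_count`,
#'   `p_target`, `truth`) and `truth` (rank-1 per-spectrum tibble).
#' @export
simulate_search <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_spectra
    ids <- sprintf("S%07d", seq_len(n))
    correct <- runif(n) >= config$frac_incorrect
    t_count <- 1L + rpois(n, config$lambda_target)
    d_count <- 1L + rpois(n, config$lambda_decoy)
    p_t <- t_count / (t_count + d_count)
    # Label: correct matches are targets; incorrect ones follow the
    # candidate-count ratio.
    label <- ifelse(correct, "target",
      ifelse(runif(n) < p_t, "target", "decoy")
    )
    score <- ifelse(correct,
      rnorm(n, config$mu_correct, config$sd_correct),
      rnorm(n, config$mu_incorrect, config$sd_incorrect)
    )
    ref_class <- rep(NA_character_, n)
    is_t <- label == "target"
    ref_class[is_t & correct] <- ifelse(
      runif(sum(is_t & correct)) < config$entrap_frac, "entrapment", "reference"
    )
    ref_class[is_t & !correct] <- "entrapment"
    rank1 <- tibble::tibble(
      spectrum_id = ids,
      rank = 1L,
      peptide = NA_character_,
      score = score,
      label = label,
      ref_class = ref_class,
      target_count = t_count,
      decoy_count = d_count,
      p_target = p_t,
      truth = ifelse(correct, "correct", "incorrect")
    )
    sub <- NULL
    if (config$n_ranks > 1L) {
      m <- n * (config$n_ranks - 1L)
      st <- 1L + rpois(m, config$lambda_target)
      sd_ <- 1L + rpois(m, config$lambda_decoy)
      sp <- st / (st + sd_)
      sub <- tibble::tibble(
        spectrum_id = rep(ids, config$n_ranks - 1L),
        rank = rep(2:config$n_ranks, each = n),
        peptide = NA_character_,
        score = rnorm(m, config$mu_incorrect, config$sd_incorrect),
        label = ifelse(runif(m) < sp, "target", "decoy"),
        ref_class = NA_character_,
        target_count = st,
        decoy_count = sd_,
        p_target = sp,
        truth = "incorrect"
      )
      sub$ref_class[sub$label == "target"] <- "entrapment"
    }
    truth <- tibble::tibble(
      spectrum_id = ids,
      correct = correct,
      target_count = t_count,
      decoy_count = d_count,
      label = label
    )
    list(psms = dplyr::bind_rows(rank1, sub), truth = truth)
  })
}

#' Evaluate FDR estimators against simulated ground truth
#'
#' Builds the FDR curve of the rank-1 PSMs (with the rank-based correction
#' factor when sub-ranks are available) and, for each threshold and each of
#' TDS, corrected TDS and cTDS, reports the accepted target count, the
#' estimator's value at the cutoff, the true false-discovery proportion
#' among accepted targets, the entrapment FMR (when `ref_class` is present),
#' and the absolute calibration error `|estimate - true FDP|`.
#'
#' @param psms PSM tibble from [simulate_search()] (must carry `truth`).
#' @param alphas FDR thresholds.
#' @param factor_rank Rank used for the correction factor; set `NULL` to
#'   skip the corrected-TDS method.
#' @return Tibble of class `ctds_eval`: one row per (alpha, method) with
#'   columns `alpha`, `method`, `n_accepted`, `score_cutoff`,
#'   `fdr_estimate`, `true_fdp`, `fmr`, `abs_error`.
#' @export
evaluate_estimators <- function(psms, alphas = seq(0.01, 0.10, by = 0.01),
                                factor_rank = 5L) {
  if (!"truth" %in% names(psms)) {
    abort("`psms` must carry a truth column (correct/incorrect).")
  }
  factor <- NULL
  if (!is.null(factor_rank) && any(psms$rank == factor_rank)) {
    factor <- tryCatch(correction_factor(psms, rank = factor_rank),
      error = function(e) NULL
    )
  }
  curve <- fdr_curve(psms, factor = factor)
  is_t <- curve$label == "target"
  cum_false_t <- cumsum(is_t & curve$truth == "incorrect")
  has_ref <- "ref_class" %in% names(curve) && any(!is.na(curve$ref_class))
  if (has_ref) {
    cum_ref <- cumsum(is_t & !is.na(curve$ref_class) & curve$ref_class == "reference")
    cum_ent <- cumsum(is_t & !is.na(curve$ref_class) & curve$ref_class == "entrapment")
  }
  methods <- c("tds", if (!is.null(factor)) "tds_corrected", "ctds")
  rows <- purrr::map(methods, function(m) {
    q <- curve_q_column(curve, m)
    purrr::map(alphas, function(a) {
      ok <- which(q <= a)
      if (length(ok) == 0) {
        return(tibble::tibble(
          alpha = a, method = m, n_accepted = 0L, score_cutoff = NA_real_,
          fdr_estimate = NA_real_, true_fdp = NA_real_, fmr = NA_real_,
          abs_error = NA_real_
        ))
      }
      i <- max(ok)
      n_acc <- curve$cum_target[i]
      true_fdp <- if (n_acc > 0) cum_false_t[i] / n_acc else NA_real_
      fmr_val <- if (has_ref && cum_ref[i] > 0) cum_ent[i] / cum_ref[i] else NA_real_
      tibble::tibble(
        alpha = a, method = m,
        n_accepted = n_acc,
        score_cutoff = curve$score[i],
        fdr_estimate = q[i],
        true_fdp = true_fdp,
        fmr = fmr_val,
        abs_error = abs(q[i] - true_fdp)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("ctds_eval", class(rows)), factor = factor)
}
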