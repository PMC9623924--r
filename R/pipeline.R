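# End-to-end workflow: decoy generation -> digestion -> mass index ->
# candidate counting -> FDR estimation, with a re-run manifest.

#' Run the complete candidate-weighted FDR pipeline
#'
#' Validates all inputs up front, then: generates a decoy database from the
#' target FASTA, digests target and decoy proteins, builds the precursor
#' mass index, counts candidates for every spectrum, annotates the PSM
#' table, fits the FDR curve (TDS, corrected TDS when sub-ranks allow a
#' correction factor, and cTDS) and applies the acceptance threshold(s).
#' Writes `counts.tsv`, `curve.tsv`, `thresholds.tsv` and `manifest.json`
#' into `out_dir`; the manifest records the package version, all
#' parameters (including seeds) and input file digests, enough to re-run
#' the command.
#'
#' @param target_fasta Target protein FASTA path.
#' @param spectra_file Spectrum precursor list ([read_spectra()] format).
#' @param psms_file PSM table ([read_psm_table()] format).
#' @param out_dir Output directory (created if needed).
#' @param method Decoy generation method (see [generate_decoy_db()]).
#' @param seed Seed for stochastic decoy methods.
#' @param tol_ppm Precursor tolerance (ppm).
#' @param alphas FDR thresholds to report.
#' @param decoy_prefix Decoy accession prefix.
#' @param k de Bruijn order.
#' @param max_missed,min_length,max_length Digestion parameters.
#' @param factor_rank Rank for the correction factor (`NULL` to skip).
#' @param entrap_prefix Optional accession prefix identifying entrapment
#'   proteins in the target FASTA; enables FMR reporting.
#' @return Invisibly, a list with `counts`, `curve`, `thresholds`,
#'   `manifest`.
#' @export
run_ctds_pipeline <- function(target_fasta, spectra_file, psms_file, out_dir,
                              method = "reverse", seed = 1L, tol_ppm = 20,
                              alphas = 0.01, decoy_prefix = "DECOY_", k = 2L,
                              max_missed = 2L, min_length = 7L, max_length = 50L,
                              factor_rank = 5L, entrap_prefix = NULL) {
  for (f in c(target_fasta, spectra_file, psms_file)) {
    if (!file.exists(f)) abort(sprintf("Input file not found: %s", f))
  }
  method <- match.arg(method, decoy_methods)
  stopifnot(tol_ppm > 0, all(alphas > 0 & alphas <= 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  targets <- read_fasta(target_fasta, decoy_prefix = decoy_prefix,
                        entrap_prefix = entrap_prefix)
  if (any(targets$origin == "decoy")) {
    abort("Target FASTA already contains decoy-prefixed accessions.")
  }
  spectra <- read_spectra(spectra_file)
  psms <- read_psm_table(psms_file, decoy_prefix = decoy_prefix)

  decoys <- generate_decoy_db(targets, method = method, seed = seed,
                              decoy_prefix = decoy_prefix, k = k)
  db <- dplyr::bind_rows(targets, decoys)
  peptides <- digest_proteins(db, max_missed = max_missed,
                              min_length = min_length, max_length = max_length)
  masses <- peptide_mass_table(peptides)
  index <- build_mass_index(masses)
  counts <- count_candidates(index, spectra, tol_ppm = tol_ppm)
  inform(sprintf(
    "Pipeline: %d proteins (+%d decoys), %d peptides, %d indexed masses, %d spectra (%d with zero candidates).",
    nrow(targets), nrow(decoys), nrow(peptides), length(index),
    nrow(spectra), sum(counts$target_count + counts$decoy_count == 0)
  ))
  psms <- annotate_psms(psms, counts)
  factor <- NULL
  if (!is.null(factor_rank) && any(psms$rank == factor_rank)) {
    factor <- tryCatch(correction_factor(psms, rank = factor_rank),
                       error = function(e) NULL)
  }
  curve <- fdr_curve(psms, factor = factor)
  methods <- c("tds", if (!is.null(factor)) "tds_corrected", "ctds")
  thresholds <- purrr::map(alphas, function(a) {
    purrr::map(methods, function(m) {
      row <- accept_at(curve, a, m)
      if ("ref_class" %in% names(curve) && any(!is.na(curve$ref_class))) {
        row$fmr <- fmr(accepted_psms(curve, a, m))
      }
      row
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  version <- as.character(utils::packageVersion("ctds"))
  params <- list(
    method = method, seed = seed, tol_ppm = tol_ppm, alphas = alphas,
    decoy_prefix = decoy_prefix, k = k, max_missed = max_missed,
    min_length = min_length, max_length = max_length,
    factor_rank = factor_rank, entrap_prefix = entrap_prefix,
    correction_factor = factor
  )
  manifest <- list(
    tool = "ctds", version = version, subcommand = "pipeline",
    parameters = params,
    inputs = list(
      target_fasta = unname(tools::md5sum(target_fasta)),
      spectra_file = unname(tools::md5sum(spectra_file)),
      psms_file = unname(tools::md5sum(psms_file))
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  hdr <- sprintf("ctds %s pipeline method=%s seed=%d tol_ppm=%g", version,
                 method, seed, tol_ppm)
  write_tsv_commented(counts[, c("spectrum_id", "target_count", "decoy_count",
                                 "p_target")],
                      file.path(out_dir, "counts.tsv"), hdr)
  write_tsv_commented(tidy.ctds_fdr_curve(curve),
                      file.path(out_dir, "curve.tsv"), hdr)
  write_tsv_commented(thresholds, file.path(out_dir, "thresholds.tsv"), hdr)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(counts = counts, curve = curve, thresholds = thresholds,
                 manifest = manifest))
}
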