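# Tab-separated readers/writers for PSM tables and spectrum precursor lists.

psm_required_cols <- c("spectrum_id", "rank", "peptide", "score")

#' Read a PSM table
#'
#' Tab-separated with a header and optional leading `#` comment lines.
#' Required columns: `spectrum_id`, `rank`, `peptide`, `score`, and either a
#' `label` column (`target`/`decoy`) or a `protein` accession column from
#' which the label is derived via `decoy_prefix`. Optional columns
#' `ref_class`, `target_count`, `decoy_count`, `truth` are kept when
#' present.
#'
#' @param path Path to the TSV file.
#' @param decoy_prefix Prefix used to derive `label` from a `protein`
#'   column when no `label` column exists.
#' @return PSM tibble.
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  psms <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(psm_required_cols, names(psms))
  if (length(missing) > 0) {
    abort(sprintf(
      "PSM table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (!"label" %in% names(psms)) {
    if (!"protein" %in% names(psms)) {
      abort("PSM table needs a `label` column or a `protein` column to derive it from.")
    }
    psms$label <- ifelse(startsWith(psms$protein, decoy_prefix), "decoy", "target")
  }
  bad <- setdiff(unique(psms$label), c("target", "decoy"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown label value(s): %s", paste(bad, collapse = ", ")))
  }
  psms
}

#' Write a PSM table
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @export
write_psm_table <- function(psms, path, comments = NULL) {
  write_tsv_commented(psms, path, comments)
}

#' Read a spectrum precursor list
#'
#' Tab-separated with header `spectrum_id  neutral_mass  charge`; masses are
#' neutral monoisotopic in Da.
#'
#' @param path Path to the TSV file.
#' @return Tibble with those columns.
#' @export
read_spectra <- function(path) {
  sp <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(c("spectrum_id", "neutral_mass"), names(sp))
  if (length(missing) > 0) {
    abort(sprintf(
      "Spectrum list %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (any(sp$neutral_mass <= 0)) {
    abort("All neutral masses must be positive.")
  }
  if (!"charge" %in% names(sp)) sp$charge <- NA_integer_
  sp
}

#' Read precursor information from an MGF file
#'
#' Extracts `TITLE`, `PEPMASS` and `CHARGE` from each `BEGIN IONS` block and
#' converts the precursor m/z to a neutral monoisotopic mass,
#' `neutral_mass = (pepmass - proton) * charge` with the proton mass
#' 1.00727646 Da. Peak lists are skipped.
#'
#' @param path Path to an MGF file.
#' @return Tibble with `spectrum_id`, `neutral_mass`, `charge`.
#' @export
read_mgf_precursors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0 || length(begins) != length(ends)) {
    abort(sprintf("%s does not look like a valid MGF file.", path))
  }
  grab <- function(block, key) {
    hit <- grep(paste0("^", key, "="), block, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  rows <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    pepmass <- as.numeric(strsplit(grab(block, "PEPMASS"), "\\s+")[[1]][1])
    charge <- as.integer(sub("\\+$", "", grab(block, "CHARGE")))
    title <- grab(block, "TITLE")
    tibble::tibble(
      spectrum_id = title %||% NA_character_,
      pepmass = pepmass,
      charge = charge
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(is.na(out$pepmass) | is.na(out$charge))) {
    abort("Every MGF block needs PEPMASS and CHARGE to derive a neutral mass.")
  }
  tibble::tibble(
    spectrum_id = ifelse(is.na(out$spectrum_id),
      sprintf("scan%05d", seq_len(nrow(out))), out$spectrum_id
    ),
    neutral_mass = (out$pepmass - mass_proton) * out$charge,
    charge = out$charge
  )
}

# Write a tibble as TSV with an optional leading '#' comment block.
write_tsv_commented <- function(x, path, comments = NULL) {
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}
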