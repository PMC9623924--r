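# In-silico tryptic digestion.

#' Tryptic digestion of one protein sequence
#'
#' Fully tryptic digestion: cleavage C-terminal to K or R, by default not
#' when the next residue is proline (the usual trypsin rule in database
#' search engines). Peptides with up to `max_missed` internal uncleaved K/R
#' sites are returned; length bounds are applied afterwards and either bound
#' can be disabled with `NULL`.
#'
#' @param sequence Single protein sequence string.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param min_length,max_length Peptide length bounds; `NULL` disables.
#' @param proline_rule If `TRUE`, K/R followed by P is not cleaved.
#' @return Tibble with columns `peptide`, `missed_cleavages`, `start`, `end`
#'   (1-based residue coordinates in the protein).
#' @examples
#' tryptic_digest("GCNKYQWR", max_missed = 1, min_length = NULL)
#' @export
tryptic_digest <- function(sequence, max_missed = 2L,
                           min_length = 7L, max_length = 50L,
                           proline_rule = TRUE) {
  assert_scalar_string(sequence, "sequence")
  stopifnot(max_missed >= 0)
  chars <- chars_of(sequence)
  n <- length(chars)
  cleave <- chars %in% c("K", "R")
  if (proline_rule && n > 1) {
    followed_by_p <- c(chars[-1] == "P", FALSE)
    cleave <- cleave & !followed_by_p
  }
  cleave[n] <- FALSE # a terminal site produces no extra boundary
  bounds <- c(0L, which(cleave), n) # piece i spans (bounds[i], bounds[i+1]]
  n_pieces <- length(bounds) - 1L
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    k <- n_pieces - m
    if (k < 1L) break
    starts <- bounds[seq_len(k)] + 1L
    ends <- bounds[seq_len(k) + m + 1L]
    out[[m + 1L]] <- tibble::tibble(
      peptide = substring(sequence, starts, ends),
      missed_cleavages = m,
      start = starts,
      end = ends
    )
  }
  res <- dplyr::bind_rows(out)
  len <- nchar(res$peptide)
  keep <- rep(TRUE, nrow(res))
  if (!is.null(min_length)) keep <- keep & len >= min_length
  if (!is.null(max_length)) keep <- keep & len <= max_length
  res[keep, ]
}

#' Digest a protein database
#'
#' Applies [tryptic_digest()] to every protein and aggregates to distinct
#' (peptide, origin) pairs, collecting parent accessions.
#'
#' @param proteins Tibble as returned by [read_fasta()].
#' @inheritParams tryptic_digest
#' @return Tibble with columns `peptide`, `origin`, `missed_cleavages`
#'   (minimum over occurrences), `parents` (accessions, `;`-collapsed).
#' @export
digest_proteins <- function(proteins, max_missed = 2L,
                            min_length = 7L, max_length = 50L,
                            proline_rule = TRUE) {
  stopifnot(nrow(proteins) > 0)
  per <- purrr::map2(proteins$sequence, proteins$accession, function(s, acc) {
    d <- tryptic_digest(s, max_missed, min_length, max_length, proline_rule)
    if (nrow(d) == 0) return(NULL)
    d$accession <- acc
    d
  })
  all <- dplyr::bind_rows(per)
  if (nrow(all) == 0) {
    return(tibble::tibble(
      peptide = character(), origin = character(),
      missed_cleavages = integer(), parents = character()
    ))
  }
  all$origin <- proteins$origin[match(all$accession, proteins$accession)]
  all |>
    dplyr::group_by(.data$peptide, .data$origin) |>
    dplyr::summarise(
      missed_cleavages = min(.data$missed_cleavages),
      parents = paste(sort(unique(.data$accession)), collapse = ";"),
      .groups = "drop"
    )
}

#' Expand digested peptides to modification-variant masses
#'
#' One row per (peptide, origin, variant mass). Peptides containing residues
#' with no defined monoisotopic mass (B, J, O, U, X, Z) are excluded with an
#' informational message giving the count.
#'
#' @param peptides Tibble from [digest_proteins()] (columns `peptide`,
#'   `origin`; other columns are carried along).
#' @inheritParams peptide_masses
#' @return Input rows expanded with a numeric `mass` column and `n_var_mods`
#'   (number of variable modifications in that variant).
#' @export
peptide_mass_table <- function(peptides,
                               fixed_mods = fixed_carbamidomethyl,
                               variable_mods = variable_oxidation,
                               max_var_mods = 3L) {
  has_bad <- grepl(paste0("[", paste(nonstandard_residues, collapse = ""), "]"),
                   peptides$peptide)
  if (any(has_bad)) {
    inform(sprintf(
      "Excluding %d peptide(s) containing residues without a defined monoisotopic mass.",
      sum(has_bad)
    ))
    peptides <- peptides[!has_bad, ]
  }
  base <- base_mass_vec(peptides$peptide, fixed_mods)
  # Variant expansion: one extra mass per count of variable-modifiable
  # residues, cheap because counts are computed vectorised per mod residue.
  if (length(variable_mods) == 0 || max_var_mods == 0L) {
    out <- peptides
    out$mass <- base
    out$n_var_mods <- 0L
    return(tibble::as_tibble(out))
  }
  counts <- lapply(names(variable_mods), function(r) {
    pmin(stringr::str_count(peptides$peptide, stringr::fixed(r)), max_var_mods)
  })
  if (length(variable_mods) == 1L) {
    nvar <- counts[[1]]
    reps <- nvar + 1L
    idx <- rep.int(seq_len(nrow(peptides)), reps)
    k <- sequence(reps) - 1L
    out <- peptides[idx, ]
    out$mass <- base[idx] + k * unname(variable_mods[1])
    out$n_var_mods <- k
    return(tibble::as_tibble(out))
  }
  # General case: small per-peptide enumeration.
  rows <- purrr::map(seq_len(nrow(peptides)), function(i) {
    ms <- peptide_masses(peptides$peptide[i], fixed_mods, variable_mods, max_var_mods)
    out <- peptides[rep(i, length(ms)), ]
    out$mass <- ms
    out$n_var_mods <- as.integer(round((ms - ms[1]) / min(variable_mods)))
    out
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}

#' Export a peptide table as TSV
#'
#' Columns `peptide`, `missed_cleavages`, `mass`, `origin`, `parents`.
#'
#' @param peptides Tibble with those columns (e.g. [peptide_mass_table()]
#'   output joined with digestion metadata).
#' @param path Output path.
#' @export
write_peptides <- function(peptides, path) {
  cols <- intersect(
    c("peptide", "missed_cleavages", "mass", "origin", "parents", "n_var_mods"),
    names(peptides)
  )
  readr::write_tsv(peptides[, cols], path)
  invisible(path)
}
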