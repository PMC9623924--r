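# FASTA reading and writing for target/decoy protein databases.

#' Read a protein FASTA file into a tibble
#'
#' Parses a (multi-line) FASTA file into one row per entry. The accession is
#' the header token before the first whitespace; records whose accession
#' starts with `decoy_prefix` are flagged `origin = "decoy"`, and ones
#' starting with `entrap_prefix` (when non-`NULL`) `origin = "entrapment"`.
#' Sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @param entrap_prefix Optional accession prefix marking entrapment entries.
#' @return A tibble with columns `accession`, `description`, `sequence`,
#'   `origin` (one of `"target"`, `"decoy"`, `"entrapment"`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "GCNKYQWR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_", entrap_prefix = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    abort(sprintf("FASTA file is empty: %s", path))
  }
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf(
      "Malformed FASTA: line %d of %s does not start a '>' header.",
      first, path
    ))
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  sequence <- unname(toupper(as.character(seqs)))
  bad <- which(!grepl("^[A-Z]+$", sequence))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed FASTA: entry '%s' has an empty sequence or non-letter characters.",
      accession[bad[1]]
    ))
  }
  origin <- rep("target", length(accession))
  if (!is.null(entrap_prefix)) {
    origin[startsWith(accession, entrap_prefix)] <- "entrapment"
  }
  origin[startsWith(accession, decoy_prefix)] <- "decoy"
  tibble::tibble(
    accession = accession,
    description = description,
    sequence = sequence,
    origin = origin
  )
}

#' Write a protein tibble to FASTA
#'
#' Round-trips with [read_fasta()]: accessions and sequences are reproduced
#' exactly. Headers are `>accession description` (description omitted when
#' empty).
#'
#' @param proteins Tibble with columns `accession`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param line_width Residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, line_width = 60L) {
  if (nrow(proteins) == 0) {
    abort("`proteins` must contain at least one record.")
  }
  desc <- proteins$description %||% rep("", nrow(proteins))
  headers <- ifelse(nzchar(desc),
    paste(proteins$accession, desc),
    proteins$accession
  )
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}
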