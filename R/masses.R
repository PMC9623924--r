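# Monoisotopic mass arithmetic for peptides.

#' Monoisotopic residue masses and mass constants
#'
#' Standard monoisotopic masses (Da) of the 20 amino-acid residues, the mass
#' of water added to a free peptide, and the proton mass used when converting
#' precursor m/z to neutral mass.
#'
#' @format `aa_masses` is a named numeric vector of length 20.
#' @export
aa_masses <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
  V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname aa_masses
#' @export
mass_water <- 18.0105646837

#' @rdname aa_masses
#' @export
mass_proton <- 1.00727646

#' Default modification sets
#'
#' Carbamidomethylation of cysteine as the fixed modification and oxidation
#' of methionine as the variable modification, the common high-resolution
#' search configuration. Each is a named numeric vector mapping a residue
#' letter to a mass delta in Da.
#'
#' @export
fixed_carbamidomethyl <- c(C = 57.021464)

#' @rdname fixed_carbamidomethyl
#' @export
variable_oxidation <- c(M = 15.994915)

# Residues with no defined monoisotopic mass (ambiguity/rare codes).
nonstandard_residues <- c("B", "J", "O", "U", "X", "Z")

#' Monoisotopic masses of a peptide with modifications
#'
#' Computes the neutral monoisotopic mass of a peptide: the sum of its
#' residue masses plus water, plus fixed-modification deltas on every
#' matching residue, and one additional mass per distinct count of
#' variable-modified residues up to `max_var_mods`. With oxidation on M as
#' the only variable modification a peptide with k methionines yields
#' `min(k, max_var_mods) + 1` masses.
#'
#' @param sequence Single peptide string over the 20 standard letters.
#' @param fixed_mods Named numeric vector residue -> delta (Da), applied to
#'   every matching residue. Default carbamidomethyl C.
#' @param variable_mods Named numeric vector residue -> delta (Da), applied
#'   to 0..n matching residues. Default oxidation M.
#' @param max_var_mods Maximum total number of variable modifications.
#' @return Sorted numeric vector of neutral monoisotopic masses in Da; the
#'   first element is the mass with fixed modifications only.
#' @examples
#' peptide_masses("GCNK")
#' peptide_masses("MM") # 3 masses: 0, 1 or 2 oxidations
#' @export
peptide_masses <- function(sequence,
                           fixed_mods = fixed_carbamidomethyl,
                           variable_mods = variable_oxidation,
                           max_var_mods = 3L) {
  assert_scalar_string(sequence, "sequence")
  chars <- chars_of(sequence)
  unknown <- setdiff(unique(chars), names(aa_masses))
  if (length(unknown) > 0) {
    abort(sprintf(
      "No monoisotopic mass defined for residue(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  base <- sum(aa_masses[chars]) + mass_water
  if (length(fixed_mods) > 0) {
    base <- base + sum(fixed_mods[chars], na.rm = TRUE)
  }
  if (length(variable_mods) == 0 || max_var_mods == 0L) {
    return(base)
  }
  # One count axis per variable-modifiable residue type present.
  counts <- lapply(names(variable_mods), function(r) {
    0:min(sum(chars == r), max_var_mods)
  })
  grid <- expand.grid(counts)
  keep <- rowSums(grid) <= max_var_mods
  grid <- grid[keep, , drop = FALSE]
  deltas <- as.matrix(grid) %*% unname(variable_mods)
  sort(unique(base + as.numeric(deltas)))
}

# Fast vectorised base mass (fixed mods applied, no variable mods) for a
# character vector of peptides; NA for peptides with non-standard letters.
base_mass_vec <- function(peptides, fixed_mods = fixed_carbamidomethyl) {
  tab <- aa_masses
  if (length(fixed_mods) > 0) {
    tab[names(fixed_mods)] <- tab[names(fixed_mods)] + fixed_mods
  }
  pieces <- strsplit(peptides, "", fixed = TRUE)
  lens <- lengths(pieces)
  flat <- unlist(pieces, use.names = FALSE)
  m <- unname(tab[flat]) # NA for unknown letters
  idx <- rep.int(seq_along(peptides), lens)
  sums <- rep(NA_real_, length(peptides))
  agg <- rowsum(m, idx, na.rm = FALSE)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  sums + mass_water
}
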