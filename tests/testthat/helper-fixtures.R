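# Shared fixture builders; everything is generated in code at test time.

random_proteins <- function(n, mean_length = 60, seed = 1) {
  simulate_proteome(n, mean_length = mean_length, seed = seed)
}

# Minimal PSM tibble with equal candidate counts unless overridden.
make_psms <- function(score, label, target_count = 1L, decoy_count = 1L,
                      rank = 1L, spectrum_id = NULL, ...) {
  n <- length(score)
  tibble::tibble(
    spectrum_id = spectrum_id %||% sprintf("S%04d", seq_len(n)),
    rank = rep_len(rank, n),
    peptide = NA_character_,
    score = score,
    label = label,
    target_count = as.integer(rep_len(target_count, n)),
    decoy_count = as.integer(rep_len(decoy_count, n)),
    ...
  )
}

# Brute-force candidate counting: linear scan over every (mass, origin) pair.
brute_force_counts <- function(mass_table, spectra, tol_ppm) {
  purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    m <- spectra$neutral_mass[i]
    hit <- abs(mass_table$mass - m) <= m * tol_ppm * 1e-6
    tibble::tibble(
      spectrum_id = spectra$spectrum_id[i],
      target_count = sum(hit & mass_table$origin != "decoy"),
      decoy_count = sum(hit & mass_table$origin == "decoy")
    )
  })
}

# Multiset comparison helper.
same_multiset <- function(a, b) identical(sort(a), sort(b))

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
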