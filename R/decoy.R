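# Decoy protein database generation: reverse, pseudo-reverse, shuffle,
# pseudo-shuffle and de Bruijn methods.

decoy_methods <- c("reverse", "pseudo_reverse", "shuffle", "pseudo_shuffle", "de_bruijn")

#' Decoy sequence generators
#'
#' Protein-level decoy constructions. `reverse_protein()` reverses the whole
#' sequence; `pseudo_reverse_protein()` reverses only the stretches between
#' cleavage anchors, leaving every K and R at its original position so the
#' decoy digests into peptides with the same masses as the target;
#' `shuffle_protein()` permutes the whole sequence uniformly at random;
#' `pseudo_shuffle_protein()` permutes each inter-anchor stretch
#' independently; `debruijn_decoy()` regenerates each inter-anchor stretch by
#' a walk on that stretch's order-`k` de Bruijn graph (see Details).
#'
#' For the anchor-preserving methods the sequence is segmented at every K or
#' R (no proline exception): each anchor stays in place and only the
#' residues between anchors are rearranged, so tryptic cleavage sites are
#' conserved. `"GCNKYQWR"` pseudo-reverses to `"NCGKWQYR"`.
#'
#' @details
#' The de Bruijn construction turns each inter-anchor segment into its
#' multiset of k-mers (edges between (k-1)-mer nodes) and draws a walk that
#' consumes every edge exactly once, starting from the segment's first
#' (k-1)-mer; where several outgoing edges remain, the next edge is chosen
#' with probability proportional to `aa_freqs` of the emitted letter. A
#' successful walk reproduces the segment's residue composition exactly.
#' Segments shorter than `k`, or segments for which no edge-exhausting walk
#' is found within `max_tries` attempts, fall back to a pseudo-shuffle of the
#' segment (counted in the `fallbacks` attribute).
#'
#' Stochastic generators consume the session RNG; seed handling for whole
#' databases lives in [generate_decoy_db()].
#'
#' @param sequence Single protein sequence string.
#' @param aa_freqs Named probability vector over the 20 residues (must sum
#'   to 1); typically [aa_frequencies()] of the target database.
#' @param k de Bruijn order (k-mer length), >= 2.
#' @param max_tries Walk attempts per segment before falling back.
#' @return The decoy sequence (same length as the input).
#' @examples
#' reverse_protein("GCNKYQWR")        # "RWQYKNCG"
#' pseudo_reverse_protein("GCNKYQWR") # "NCGKWQYR"
#' @export
reverse_protein <- function(sequence) {
  assert_scalar_string(sequence, "sequence")
  paste(rev(chars_of(sequence)), collapse = "")
}

#' @rdname reverse_protein
#' @export
pseudo_reverse_protein <- function(sequence) {
  assert_scalar_string(sequence, "sequence")
  chars <- chars_of(sequence)
  seg <- anchor_segments(chars)
  for (idx in seg$segments) {
    if (length(idx) > 1) chars[idx] <- chars[rev(idx)]
  }
  paste(chars, collapse = "")
}

#' @rdname reverse_protein
#' @export
shuffle_protein <- function(sequence) {
  assert_scalar_string(sequence, "sequence")
  chars <- chars_of(sequence)
  paste(chars[sample.int(length(chars))], collapse = "")
}

#' @rdname reverse_protein
#' @export
pseudo_shuffle_protein <- function(sequence) {
  assert_scalar_string(sequence, "sequence")
  chars <- chars_of(sequence)
  seg <- anchor_segments(chars)
  for (idx in seg$segments) {
    if (length(idx) > 1) chars[idx] <- chars[idx][sample.int(length(idx))]
  }
  paste(chars, collapse = "")
}

#' @rdname reverse_protein
#' @export
debruijn_decoy <- function(sequence, aa_freqs, k = 2L, max_tries = 20L) {
  assert_scalar_string(sequence, "sequence")
  stopifnot(k >= 2)
  if (abs(sum(aa_freqs) - 1) > 1e-9) {
    abort("`aa_freqs` must sum to 1.")
  }
  chars <- chars_of(sequence)
  seg <- anchor_segments(chars)
  fallbacks <- 0L
  for (idx in seg$segments) {
    if (length(idx) <= 1) next
    s <- chars[idx]
    new <- if (length(s) <= k) NULL else debruijn_walk(s, aa_freqs, k, max_tries)
    if (is.null(new)) {
      new <- s[sample.int(length(s))]
      fallbacks <- fallbacks + 1L
    }
    chars[idx] <- new
  }
  out <- paste(chars, collapse = "")
  attr(out, "fallbacks") <- fallbacks
  out
}

# Edge-exhausting random walk on the order-k de Bruijn graph of `s`
# (a character vector). Returns a character vector of the same length and
# composition, or NULL if no complete walk was found.
debruijn_walk <- function(s, aa_freqs, k, max_tries) {
  n <- length(s)
  n_edges <- n - k + 1L
  from <- vapply(seq_len(n_edges), function(i) {
    paste(s[i:(i + k - 2L)], collapse = "")
  }, character(1))
  emit <- s[(seq_len(n_edges)) + k - 1L]
  to <- vapply(seq_len(n_edges), function(i) {
    paste(s[(i + 1L):(i + k - 1L)], collapse = "")
  }, character(1))
  start <- from[1]
  for (try in seq_len(max_tries)) {
    remaining <- rep(TRUE, n_edges)
    node <- start
    path <- integer(n_edges)
    ok <- TRUE
    for (step in seq_len(n_edges)) {
      cand <- which(remaining & from == node)
      if (length(cand) == 0) { ok <- FALSE; break }
      if (length(cand) == 1) {
        e <- cand
      } else {
        w <- aa_freqs[emit[cand]]
        w[is.na(w) | w <= 0] <- .Machine$double.eps
        e <- cand[sample.int(length(cand), 1L, prob = w)]
      }
      path[step] <- e
      remaining[e] <- FALSE
      node <- to[e]
    }
    if (ok) {
      return(c(s[1:(k - 1L)], emit[path]))
    }
  }
  NULL
}

#' Residue frequencies of a protein database
#'
#' @param proteins Protein tibble ([read_fasta()] layout) or a character
#'   vector of sequences.
#' @return Named probability vector over the residues observed, restricted
#'   to the 20 standard letters.
#' @export
aa_frequencies <- function(proteins) {
  seqs <- if (is.data.frame(proteins)) proteins$sequence else proteins
  tab <- table(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  tab <- tab[names(tab) %in% names(aa_masses)]
  freqs <- as.numeric(tab) / sum(tab)
  setNames(freqs, names(tab))
}

#' Generate a decoy database from a target database
#'
#' Produces one decoy per target protein with accession
#' `paste0(decoy_prefix, accession)`. Stochastic methods (shuffle,
#' pseudo-shuffle, de Bruijn) are fully reproducible from `seed`: each
#' protein gets its own RNG stream derived from `(seed, accession)`, so
#' adding or removing proteins does not change the decoys of the others.
#' For the de Bruijn method the residue frequencies are computed from the
#' pooled target records.
#'
#' @param proteins Target protein tibble ([read_fasta()] layout); all rows
#'   must have `origin == "target"` or `"entrapment"`.
#' @param method One of `"reverse"`, `"pseudo_reverse"`, `"shuffle"`,
#'   `"pseudo_shuffle"`, `"de_bruijn"`.
#' @param seed Integer seed for the stochastic methods.
#' @param decoy_prefix Accession prefix for the generated decoys.
#' @param k de Bruijn order.
#' @return Tibble of decoy records (`origin = "decoy"`), one per input row,
#'   same column layout as the input.
#' @examples
#' prot <- tibble::tibble(accession = "P1", description = "",
#'                        sequence = "GCNKYQWR", origin = "target")
#' generate_decoy_db(prot, method = "reverse")
#' @export
generate_decoy_db <- function(proteins, method = "reverse", seed = 1L,
                              decoy_prefix = "DECOY_", k = 2L) {
  method <- match.arg(method, decoy_methods)
  if (any(proteins$origin == "decoy")) {
    abort("`proteins` must contain target records only.")
  }
  decoy_acc <- paste0(decoy_prefix, proteins$accession)
  clash <- intersect(decoy_acc, proteins$accession)
  if (any(startsWith(proteins$accession, decoy_prefix)) || length(clash) > 0) {
    abort(sprintf(
      "Decoy prefix '%s' collides with existing accessions (e.g. %s).",
      decoy_prefix,
      head(c(clash, proteins$accession[startsWith(proteins$accession, decoy_prefix)]), 1)
    ))
  }
  freqs <- if (method == "de_bruijn") aa_frequencies(proteins) else NULL
  decoy_seq <- vapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    switch(method,
      reverse = reverse_protein(s),
      pseudo_reverse = pseudo_reverse_protein(s),
      shuffle = with_seed(
        derive_seed(seed, proteins$accession[i]),
        shuffle_protein(s)
      ),
      pseudo_shuffle = with_seed(
        derive_seed(seed, proteins$accession[i]),
        pseudo_shuffle_protein(s)
      ),
      de_bruijn = with_seed(
        derive_seed(seed, proteins$accession[i]),
        as.character(debruijn_decoy(s, freqs, k = k))
      )
    )
  }, character(1))
  out <- proteins
  out$accession <- decoy_acc
  out$sequence <- decoy_seq
  out$origin <- "decoy"
  if ("description" %in% names(out)) {
    out$description <- sprintf("%s decoy of %s", method, proteins$accession)
  }
  out
}
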