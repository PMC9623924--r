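# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit polynomial hash of a string; used to derive a
# per-protein RNG stream from (seed, accession) so that adding or removing
# proteins does not perturb the decoys of the others.
string_hash <- function(x) {
  m <- 2147483647 # 2^31 - 1
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, key) {
  (as.integer(seed) %% 2147483647L + string_hash(key)) %% 2147483647L
}

# Split a protein into cleavage-anchor segments: every K or R is an anchor
# that stays in place, residues between anchors form the mutable segments.
# Returns a list with integer vector `anchor_pos` and a list of integer
# vectors `segments` (positions of each inter-anchor segment, possibly empty).
anchor_segments <- function(chars) {
  is_anchor <- chars %in% c("K", "R")
  n <- length(chars)
  bounds <- c(0L, which(is_anchor), if (!is_anchor[n]) n)
  segs <- vector("list", length(bounds) - 1L)
  for (i in seq_along(segs)) {
    lo <- bounds[i] + 1L
    hi <- if (i == length(segs) && !is_anchor[n]) bounds[i + 1L] else bounds[i + 1L] - 1L
    segs[[i]] <- if (lo <= hi) lo:hi else integer(0)
  }
  list(anchor_pos = which(is_anchor), segments = segs)
}

chars_of <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
}
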