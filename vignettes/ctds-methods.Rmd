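---
title: "Candidate-weighted target-decoy FDR estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-weighted target-decoy FDR estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctds)
```

## The problem

Shotgun proteomics searches match tandem mass spectra against a protein
database and must control the false discovery rate (FDR) of the resulting
peptide-spectrum matches (PSMs). The standard control is the target-decoy
strategy (TDS): spectra are searched against the real (target) database
concatenated with an artificial (decoy) database, and the FDR of a
score-thresholded set is estimated as

$$\widehat{\mathrm{FDR}}_{\mathrm{TDS}} = \frac{D + 1}{T},$$

where $T$ and $D$ are the target and decoy PSM counts above the threshold.
This rests on the assumption that an incorrectly matched spectrum is equally
likely to land on a target or a decoy peptide. That assumption is a property
of each spectrum's *candidate list*: the peptides whose mass lies within the
precursor tolerance of the spectrum's neutral mass. If spectrum $i$ has
$t_i$ target and $d_i$ decoy candidates, an incorrect match is a target with
probability

$$P(t_i) = \frac{t_i}{t_i + d_i},$$

which is exactly $1/2$ only when $t_i = d_i$. With protein-level shuffled
decoys (or any size-mismatched decoy database) the counts are systematically
unequal, and TDS is corrected by a global factor — the ratio of target to
decoy PSMs at a low rank (rank 5 here), where essentially all matches are
incorrect.

The candidate-weighted estimator (cTDS) instead treats each observed hit as
the outcome of a per-spectrum Bernoulli trial. The number of incorrect
matches represented by one observed decoy hit is geometric with success
probability $P(d_i)$, so its expectation is $1/P(d_i)$, and likewise
$1/P(t_i)$ for target hits:

$$\widehat{\mathrm{FDR}}_{\mathrm{cTDS}}
 = \frac{\sum_{i \in D} 1/P(d_i)}{\sum_{i \in T} 1/P(t_i)}.$$

When $t_i = d_i$ for every spectrum both weights are 2 and the estimate
reduces exactly to $D/T$; no correction factor is needed regardless of the
decoy construction, which is the estimator's point.

Two conventions differ between the estimators and are kept exactly as
defined: TDS carries the $+1$ in the numerator, cTDS does not. The
reduction property is therefore $D/T$ versus $(D+1)/T$, a difference of
$1/T$.

## Pipeline components

### Digestion and masses

`tryptic_digest()` performs fully tryptic digestion: cleavage C-terminal to
K/R, by default suppressed before proline (the default trypsin rule of the
search engine whose parameters the pipeline mirrors), up to 2 missed
cleavages, peptide length 7–50. The paper-style search conditions do not
state length bounds, so both are configurable and can be disabled. Masses
are neutral monoisotopic: residue masses plus water, carbamidomethyl-C
fixed, oxidation-M variable (one additional mass per oxidation count, up to
3 by default). Non-standard letters (B, J, O, U, X, Z) have no defined
monoisotopic mass; peptides containing them are dropped from mass indexing
with a reported count. Charge handling ($m/z \to$ neutral mass with the
proton mass 1.00727646 Da) happens only in the spectrum readers.

### Decoy generation

Five protein-level constructions are provided. Whole-sequence reverse and
uniform shuffle; pseudo-reverse and pseudo-shuffle, which segment the
protein at every K/R (anchors stay in place) and rearrange only the
residues between anchors, so tryptic cleavage sites — and for
pseudo-reverse, the digested peptide masses — are conserved; and a de
Bruijn construction that regenerates each inter-anchor segment by a random
walk on the segment's order-$k$ ($k = 2$ by default) de Bruijn graph.

Decoy segmentation deliberately applies **no proline exception**: the
worked examples of all anchor-preserving methods are reproduced exactly
under plain K/R segmentation. A consequence worth knowing: the
peptide-mass-equivalence of pseudo-reverse decoys is exact under
cleavage-after-every-K/R digestion, and only approximate when the proline
rule is active, because a reversal can move a proline next to an anchor.

The de Bruijn walk consumes the segment's k-mer edge multiset exactly once
(an Eulerian-style path from the segment's first $(k-1)$-mer, which is the
only possible start of an edge-exhausting walk), choosing among parallel
outgoing edges with probability proportional to the database residue
frequencies. A successful walk conserves the segment's residue composition
by construction. Short segments (length $\le k$) and segments where no
complete walk is found in 20 attempts fall back to a pseudo-shuffle, with a
`fallbacks` count attached. Two caveats are documented rather than hidden:
for short or low-complexity segments the edge multiset often admits a
*single* Eulerian path, so the decoy segment equals the target segment —
an inherent property of k-let-preserving shuffles, not a bug — and the
printed literature example of this construction is treated as one
admissible outcome (length, anchors and composition are checked, not byte
equality), since the published description fixes neither $k$ nor the
traversal.

Stochastic generators are reproducible from a single integer seed, using a
per-protein RNG stream derived from (seed, accession) so that adding or
removing proteins does not perturb the decoys of the others. The de Bruijn
method is deterministic given the seed, but its output additionally depends
on the pooled database frequencies, and often on nothing else (see above).

### Candidate counting

`build_mass_index()` sorts all (mass, origin) pairs — one entry per
modification variant per distinct peptide sequence, deduplicated across
parent proteins within each of target/decoy — and `count_candidates()`
answers each spectrum with two binary searches per side:
$|m - m_s| \le m_s \cdot \mathrm{tol} \cdot 10^{-6}$, symmetric and
boundary-inclusive, 20 ppm by default, no isotope-error offsets. The
candidate unit (distinct sequence-variant, not per-protein occurrence)
mirrors how search engines enumerate scoring candidates. Spectra with no
candidates at all get undefined probabilities and are excluded from cTDS
sums with a diagnostic count.

`corrected_p_target()` implements the adjusted view
$t_i / (t_i + f \cdot d_i)$ used to compare probability distributions from
unequal-size decoy databases on a common scale; the literature shows such a
corrected view without printing the formula, so this form — scaling the
decoy count by the rank-5 factor $f$ — is a documented choice of this
package.

### Curves, q-values, thresholds

`fdr_curve()` sorts rank-1 PSMs by descending score with decoys ranked
above targets at equal score (the conservative tie-break, then spectrum id
for determinism), accumulates $T$, $D$ and the geometric weights, and
reports raw estimates uncapped, with q-values (running minimum from the
most permissive cutoff) capped at 1. Ranks 2–5 are used only for the
correction factor. Thresholding (`accept_at()`) is on q-values rather than
raw prefix FDR so that accepted sets are nested in the threshold; the
source material says only "at a 1% FDR threshold", and this is the
package's resolution of that ambiguity.

The entrapment false match rate of an accepted set is
$\mathrm{FMR} = \#\mathrm{entrapment} / \#\mathrm{reference}$ over its
target PSMs, where entrapment proteins are known-irrelevant sequences mixed
into the target database so that hits to them approximate false positives.

## The simulator

`simulate_search()` is the package's ground-truth stand-in for benchmark
experiments on real cell-line and synthetic-peptide data, which require a
search engine and proteome-scale databases. Its generative model:

* a spectrum is incorrect with probability `frac_incorrect` (default 0.3);
* candidate counts are $1 + \mathrm{Poisson}(\lambda)$ per side — the $+1$
  guarantees the matched peptide is itself a candidate — with
  $\lambda_t = \lambda_d = 100$ by default;
* an incorrect match is labelled target with probability exactly
  $t_i/(t_i+d_i)$ given its drawn counts; correct matches are targets;
* scores are $N(3, 1)$ for correct and $N(0, 1)$ for incorrect matches
  (only the ordering matters to the estimators, not the score law);
* incorrect target matches carry `ref_class = "entrapment"`, correct ones
  `"reference"` (optionally flipped with probability `entrap_frac`,
  default 0 — an idealized entrapment experiment in which provenance flags
  every false positive);
* ranks 2–5 are always incorrect, so the rank-5 correction factor can be
  computed end to end.

The default $\lambda = 100$ was chosen so the candidate-probability
distribution matches the qualitative shape reported for large human
searches: mass concentrated near 0.5, with
$P(t_i = d_i) = e^{-2\lambda} I_0(2\lambda) \approx 2.8\%$ of spectra at
exactly 0.5 — inside the 1.1–4.9% range observed on real data. What the
simulator does *not* emulate: score distributions of a real search engine,
correlation between a spectrum's mass and its candidate counts, shared
peptides between spectra, and peptide-level or protein-level effects.
Passing tests therefore demonstrate estimator correctness under the stated
sampling model, not performance on any particular instrument or database.

`evaluate_estimators()` compares TDS, factor-corrected TDS and cTDS at a
grid of thresholds against the known false-discovery proportion (FDP) and
the simulated-entrapment FMR. Under candidate asymmetry
($\lambda_d > \lambda_t$: incorrect matches favour decoys) plain TDS
overestimates the FDR and accepts too few PSMs, while cTDS tracks the true
FDP far more closely:

```{r asymmetry, eval = FALSE}
sim <- simulate_search(sim_config(
  n_spectra = 50000, lambda_target = 1, lambda_decoy = 3, seed = 1
))
glance(evaluate_estimators(sim$psms))
```

A small upward bias of cTDS remains in this regime (true FDP $\approx$
1.2$\times$ the nominal threshold at $\lambda_t = 1$): the denominator
$\sum_T 1/P(t_i)$ averages $E[1/p]$ over *correct* matches, which by
Jensen's inequality exceeds the $1/E[p]$ that exact calibration would
require. The gap shrinks as $\lambda$ grows (about 0.5% at the default
$\lambda = 100$, where the package's calibration check operates) and
vanishes when all counts are equal.

## Numerical and design choices

* **Problem sizes.** The validation study uses $5 \times 10^4$ spectra per
  replicate and 20 replicates for the asymmetric comparison — large enough
  that the binomial error of an FDP at 1% is a few parts in $10^4$, small
  enough to iterate quickly.
* **Ties and degenerate input.** Score ties: decoy before target, then
  spectrum id. Zero-candidate spectra: excluded from cTDS with a count.
  Zero targets in a prefix: FDR reported as `Inf`, q capped at 1. A zero
  decoy count at the factor rank is an error suggesting a different rank.
* **Masses.** Residue monoisotopic masses are embedded constants validated
  against an independent mass calculator to $10^{-5}$ Da; mass additivity
  holds to $10^{-6}$ Da.
* **Seeds.** Every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state; identical inputs and seeds give
  byte-identical outputs, which the test suite asserts.

## Limitations

cTDS needs per-spectrum candidate counts, which most search engines do not
emit; the pipeline computes them from the database and the precursor list
under the same digestion and tolerance settings as the search, which is
faithful only if those settings truly match. Peptide-level decoy databases
make cTDS coincide with TDS by construction. Fragment-level information is
deliberately out of scope: the fragment tolerance is recorded in
configurations but never used.
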