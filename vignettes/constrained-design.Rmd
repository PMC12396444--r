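---
title: "Epitope-constrained beam search for protein sequence design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope-constrained beam search for protein sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Therapeutic proteins can provoke cytotoxic T-lymphocyte (CTL) responses.
CTLs inspect short peptides (mostly 8–10 residues) displayed on the cell
surface by MHC class I molecules; an individual carries up to six MHC-I
alleles (two each of HLA-A, HLA-B and HLA-C). Central tolerance removes
CTLs reactive against *self* peptides — subsequences of the host
proteome — so a designed protein is immunologically inconspicuous if every
short segment of it is either (1) a self k-mer, or (2) predicted never to
be presented by the patient's particular alleles ("hidden").

`epibeam` implements a decoding strategy for autoregressive protein
sequence models that enforces this property *by construction*: every
k-mer of the finished design, up to length 10, is checked during
generation. The library also provides the supporting pieces: an exact
proteome k-mer index, a fast position-weight-matrix (PWM) surrogate for
MHC-I presentation prediction, sequence-level immunogenicity metrics, and
a max-min procedure for selecting a maximally dissimilar alternative
genotype.

## The permissibility rule

Let `min_self_kmer_len` = m (default 6) and `max_checked_kmer_len` = M
(default 10, the longest canonical MHC-I peptide). When a candidate
residue is placed, every k-mer window it completes is classified:

* **k ≤ m** — the k-mer must occur in the reference proteome
  (`SELF`), otherwise the extension is rejected (`FORBIDDEN`).
* **m < k ≤ M** — a proteome k-mer is `SELF`; a non-self k-mer that the
  presentation model predicts *not presented* by any genotype allele (or
  whose length falls outside 8–10, where MHC-I presentation is not
  defined in this framework) is `HIDDEN_NONSELF` — allowed but
  penalized; a non-self k-mer predicted presented is `FORBIDDEN`.

Because the per-length member sets of the index are substring-closed, a
single membership test of the length-m suffix settles all shorter
suffixes, which is what makes the decoder's inner loop cheap.

For strict left-to-right decoding the completed windows are exactly the
suffixes ending at the new position (lengths 1..min(M, position)). When
a template declares unresolved positions, those are pre-sampled first
(seeded, unconstrained, temperature 1) and the window rule generalizes to
"all windows that became fully filled at this step"; windows never span
chain breaks. Whether windows spanning pre-sampled residues should be
checked at all was genuinely open; we check them, because the guarantee
on the finished sequence (every window classified, none forbidden) is
otherwise unobtainable.

## The search

The decoder maintains `width` beams (default 10). Each beam is extended
by each of 21 candidate tokens (20 residues plus `unknown`); only
permissible candidates survive. Candidates are ranked by an estimated
*future* log-probability:

* the candidate's own log-probability under the sequence model,
* plus a greedy lookahead of `depth` steps (default `2 * m`): at each
  step the most probable *permissible* residue is taken and its
  log-probability added,
* plus penalties: if the immediate extension introduced hidden non-self
  k-mers, `depth * log(non_self_prob_factor)` (the factor is 0.9 by
  default, so hidden continuations are discouraged, not banned); each
  lookahead step that itself introduces hidden k-mers adds one further
  `log(non_self_prob_factor)`.

Scaling a candidate's future probability by `non_self_prob_factor^depth`
leaves open how hidden k-mers encountered *inside* the lookahead should
be treated. We apply the full exponent to the immediate extension and
one factor per offending lookahead step; both contributions can be switched off independently
(`penalize_immediate`, `penalize_lookahead`), so either reading is
available. A lookahead that dead-ends is truncated, charging a floor of
`log(1/21)` per missing step — dead-end paths must rank below live ones
without crashing the search; the magnitude is one uniform-candidate
choice per lost step and is configurable (`lookahead_floor`).

The top `width` candidates across all beams are kept; beams sharing
their last 5 residues (`dedupe_suffix_len`) are then collapsed to the
most likely one, which prevents beam collapse onto a shared suffix. We
cut to `width` first and deduplicate second (possibly leaving fewer than
`width` beams); the opposite order is a defensible variant. If *no* candidate of any
beam is permissible, the step falls back to unconstrained top-width
extensions and records the position — a fallback-flagged design carries
no guarantee and the CLI exits nonzero for it. When all positions are
filled, the beam with the highest sum of per-residue log-probabilities is
the design; exact ties break lexicographically so decoding is
deterministic end to end.

With `width` at least the number of permissible sequences and `depth` 0,
the search provably returns the global argmax over permissible
sequences; the test suite checks this against exhaustive enumeration on
4-letter, length-6 instances.

## The presentation surrogate

NetMHCpan-class predictors are too slow to call once per candidate
k-mer, and are externally licensed trained models besides. During design
`epibeam` therefore uses one PWM per (allele, peptide length 8/9/10),
trained from labelled presented peptides:

`w[a, p] = log2((count(a at p) + c) / (n + 20 c) / bg[a])`

with pseudocount `c = 0.5` and a uniform background `bg` by default
(overridable with proteome-derived frequencies). Scores are
additive; peptides containing `X` score `-Inf`. The threshold is the
nearest-rank empirical quantile of scores on ≥ 1000 background peptides
such that 2% of random peptides are called presented — the same
percentile-rank convention (rank < 2%) used by presentation predictors.
Nearest-rank avoids interpolation ambiguity, a score equal to the
threshold counts as presented, and a genotype presents a peptide if *any*
of its (deduplicated) alleles does. An external predictor can be slotted
in through the same verdict-file panel format; nothing in the decoder
depends on the surrogate's internals.

## Synthetic study conditions

All tests and the acceptance script run on synthetic data generated by
the package itself:

* **Proteomes** — i.i.d. residues, uniform by default, 500 proteins of
  200–400 residues for full-scale runs (enough that every 5-mer context
  typically has at least one continuation, so the self-6mer constraint
  is hard but satisfiable); 4–6-letter alphabets and lengths 20–30 where
  brute-force oracles must enumerate the whole sequence space. A motif
  embedding mode plants chosen k-mers so tests can force specific self
  sets.
* **Alleles** — an anchor motif at P2 and the C-terminus (the
  information-rich positions of real class-I motifs): ground-truth
  presentation is "carries both anchor residues", with optional label
  noise (`1 - sharpness`). The ground truth is available to tests
  independently of any trained PWM, so surrogate fidelity is measurable:
  with noise-free labels and the deployed 2% calibration the PWM agrees
  with the ground truth on ≈ 99% of held-out peptides.
* **Sequence models** — a toy autoregressive model placing
  `concentration/(1+concentration)` of its mass on a target residue per
  position, the rest on a seeded blend of uniform and first-order
  (previous-residue) background. It exposes its exact probability table,
  making exhaustive decode oracles computable. Full-scale runs use
  concentration 4 and blend 0.5: strong but not overwhelming preferences,
  so the constraints actually bite.

What the synthetic conditions do *not* emulate: real proteome
composition and repeat structure, real HLA motif chemistry, and a real
inverse-folding model's context sensitivity. Passing tests therefore
demonstrate the correctness of the machinery (the guarantee, the search,
the calibration), not the structural viability of designs; an adapter
seam is left for plugging in an external inverse-folding model and
predictor.

## Numerical and degenerate-input choices

* K-mers are encoded internally as exact base-20 integers (20^10 < 2^53),
  with per-length sorted sets and binary-search membership; member
  listings and all file formats remain plain text and round-trip exactly.
* `X` and rare letters (B, J, O, U, Z — mapped to `X`) never form self
  k-mers, never score on a PWM, and make any containing window non-self;
  `*` splits a record into independent segments. Exclusion is the
  conservative reading — self-ness is simply undefined for ambiguous
  residues.
* The `unknown` token is enumerated as a candidate but its length-1
  window is never self, so it can only ever enter a design through
  fallback.
* Empty proteomes, empty beams, over-long queries, mixed peptide
  lengths, sub-1000 calibration sets and missing (allele, length) PWMs
  all raise immediate, specific errors.

## Evaluation metrics

For a finished design the package reports the fraction of length-k
windows found in the proteome (k = 5..10), the fraction of presented
non-self 8–10mers (presented non-self windows over *all* 8–10mer
windows), and for each non-self 8–10mer an ungapped **BLOSUM62
dissimilarity**: its self-score minus the best ungapped score against any
same-length proteome k-mer (equal lengths are forced by the no-indel
alignment; the comparison uses the same windows the index was built
from). Diagonal dominance of BLOSUM62 over the 20 standard residues —
asserted when the matrix is loaded from Biostrings — makes the
dissimilarity non-negative, and it is zero exactly when some proteome
k-mer attains the self score. Re-evaluating a fallback-free design with
the decode-time presentation model always yields a presented non-self
fraction of exactly 0 — this is the safety guarantee, and the test suite
re-derives it by brute-force re-classification of every window of every
design.

## Problem sizes used in the checks

The shipped checks use a 500-protein synthetic proteome (200–400
residues), two synthetic alleles, and 20 designs of length 60 decoded
with the default policy for the zero-leakage property; 50 exhaustive
4-letter length-6 instances for search optimality; around 1000 random
k-mers for the dissimilarity scan; 100,000 background peptides for
calibration; and 10,000 held-out peptides for surrogate fidelity. These
sizes were chosen so each property is exercised well past its edge cases
while the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The guarantee is relative to the predictor used during decoding; a
  different evaluation predictor (e.g. a NetMHCpan-class tool in place
  of the PWM surrogate) can flag peptides the decoder considered hidden.
* Only canonical 8–10mer MHC-I peptides are modelled; longer presented
  peptides are covered only insofar as they contain an 8–10mer core.
  MHC-II, proteasomal cleavage and TAP transport are out of scope.
* Raising `min_self_kmer_len` beyond 6 shrinks the permissible sequence
  space drastically; with a random synthetic proteome, self-7mer walks
  are mostly confined to verbatim proteome segments.
* The max-min alternative-genotype selection assumes allele names parse
  to a gene (HLA-A/B/C-style) and at least two candidates per gene.
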