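# Seeded generators for synthetic inputs: proteomes, anchored alleles with
# labelled peptide sets, and toy autoregressive sequence models. These stand
# in for the external resources a production run would use (a reference
# proteome, predictor-labelled peptides, an inverse-folding model) so that
# every stage of the pipeline runs and is testable offline.

#' Generate a synthetic proteome
#'
#' Residues are drawn i.i.d. from `residue_freqs` over `alphabet`. An
#' optional motif-embedding mode plants given k-mers at random positions so
#' tests can force specific self sets.
#'
#' @param n_proteins Number of records (>= 0).
#' @param length_range Integer vector `c(min, max)` protein length.
#' @param alphabet Character vector, subset of the 20 standard residues.
#'   Restricting to 4-6 letters keeps brute-force oracles feasible.
#' @param residue_freqs Optional per-letter frequencies (same length as
#'   `alphabet`, summing to 1); default uniform.
#' @param embed_motifs Optional character vector of k-mers to overwrite into
#'   random positions of random proteins (one occurrence each per protein
#'   chosen).
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(n_proteins, length_range = c(200L, 400L),
                              alphabet = aa_alphabet(), residue_freqs = NULL,
                              embed_motifs = NULL, seed = 1L) {
  stopifnot(n_proteins >= 0, length(alphabet) >= 1)
  if (is.null(residue_freqs)) residue_freqs <- rep(1 / length(alphabet), length(alphabet))
  stopifnot(length(residue_freqs) == length(alphabet),
            abs(sum(residue_freqs) - 1) < 1e-8)
  if (n_proteins == 0L) return(setNames(character(0), character(0)))
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(alphabet, L, replace = TRUE, prob = residue_freqs),
            collapse = "")
    }, character(1))
    if (!is.null(embed_motifs)) {
      for (m in embed_motifs) {
        i <- sample.int(n_proteins, 1L)
        L <- nchar(seqs[i]); k <- nchar(m)
        if (L >= k) {
          at <- sample.int(L - k + 1L, 1L)
          substr(seqs[i], at, at + k - 1L) <- m
        }
      }
    }
    setNames(seqs, sprintf("synthetic_protein_%04d", seq_len(n_proteins)))
  })
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Define a synthetic MHC-I allele by anchor positions
#'
#' Ground-truth presentation is "the peptide carries the anchor residue at
#' every anchor position"; `sharpness` < 1 flips labels with probability
#' `1 - sharpness` (label noise, intended range 0-10%). Real class-I motifs
#' concentrate information at P2 and the C-terminus, which the default
#' anchors imitate.
#'
#' @param name Allele name, e.g. `"SYN-A*01:01"`.
#' @param anchor_positions Integer positions, 1-based; negative values
#'   count from the C-terminus (`-1` = last residue), so one spec covers
#'   peptide lengths 8-10.
#' @param anchor_residues Character vector, one residue per anchor position.
#' @param sharpness Label reliability in (0.9, 1] typically; 1 = noise-free.
#' @return An `allele_spec` list.
#' @export
allele_spec <- function(name, anchor_positions, anchor_residues,
                        sharpness = 1) {
  stopifnot(length(anchor_positions) == length(anchor_residues),
            all(anchor_positions != 0),
            all(anchor_residues %in% AA20), sharpness > 0, sharpness <= 1)
  structure(list(name = name, anchor_positions = as.integer(anchor_positions),
                 anchor_residues = anchor_residues, sharpness = sharpness),
            class = "allele_spec")
}

#' Ground-truth presentation for an anchored synthetic allele
#'
#' @param spec An [allele_spec()].
#' @param peptides Character vector of equal-length peptides.
#' @return Logical vector (noise-free ground truth, independent of any PWM).
#' @export
anchor_ground_truth <- function(spec, peptides) {
  k <- nchar(peptides[1])
  pos <- resolve_anchor_positions(spec, k)
  res <- rep(TRUE, length(peptides))
  for (i in seq_along(pos)) {
    res <- res & substr(peptides, pos[i], pos[i]) == spec$anchor_residues[i]
  }
  res
}

resolve_anchor_positions <- function(spec, k) {
  pos <- ifelse(spec$anchor_positions < 0L,
                k + 1L + spec$anchor_positions, spec$anchor_positions)
  if (any(pos < 1L | pos > k)) stop("anchor position out of range for k = ", k)
  as.integer(pos)
}

#' Generate a labelled peptide set for a synthetic allele
#'
#' Emits `n_peptides` length-`k` peptides, roughly half drawn from the
#' anchored ("presented") distribution and half uniform background, labelled
#' by the anchor ground truth with `1 - sharpness` label noise.
#'
#' @param spec An [allele_spec()].
#' @param k Peptide length (8, 9 or 10 in production; smaller in unit tests).
#' @param n_peptides Total number of labelled peptides.
#' @param seed Integer seed.
#' @return A list with `peptides`, `labels` (noisy training labels) and
#'   `truth` (noise-free ground truth).
#' @export
generate_synthetic_allele <- function(spec, k, n_peptides, seed = 1L) {
  apos <- resolve_anchor_positions(spec, k)
  withr::with_seed(seed, {
    n_pos <- n_peptides %/% 2L
    n_bg <- n_peptides - n_pos
    rand_pep <- function(n) {
      if (n == 0L) return(character(0))
      m <- matrix(sample(AA20, n * k, replace = TRUE), nrow = n)
      apply(m, 1L, paste, collapse = "")
    }
    pos <- rand_pep(n_pos)
    for (i in seq_along(apos)) {
      substr(pos, apos[i], apos[i]) <- spec$anchor_residues[i]
    }
    peptides <- c(pos, rand_pep(n_bg))
    truth <- anchor_ground_truth(spec, peptides)
    flip <- stats::runif(n_peptides) > spec$sharpness
    list(peptides = peptides, labels = xor(truth, flip), truth = truth)
  })
}

#' Toy autoregressive sequence model
#'
#' A position-wise mixture: with weight `concentration / (1 + concentration)`
#' the mass sits on `target[p]`; the remainder follows a background that
#' blends uniform with a seeded first-order (previous-residue conditioned)
#' transition matrix, weighted by `markov_blend`. The model satisfies the
#' decoder's sequence-model contract (normalized log-probabilities over the
#' 21 tokens) and exposes its exact probability table so brute-force decode
#' oracles can be computed.
#'
#' Tokens outside `alphabet` (including the unknown token `X`) receive a
#' vanishing but finite probability so log-probabilities stay finite.
#'
#' @param target Target sequence (non-empty, letters within `alphabet`).
#' @param concentration Non-negative mass multiplier on the target residue;
#'   `Inf`-like behaviour is approached as it grows; 0 = pure background.
#' @param markov_blend Weight in `[0, 1]` of the first-order background.
#' @param seed Integer seed for the random transition matrix.
#' @param alphabet Residue alphabet the model puts real mass on.
#' @return A `seq_model` list with elements `length`, `alphabet`, `logits`
#'   (function of `(assignment_codes, position)` returning 21 log-probs in
#'   token order) and `prob_table(position, prev_code)`.
#' @export
toy_sequence_model <- function(target, concentration = 4, markov_blend = 0.5,
                               seed = 1L, alphabet = NULL) {
  stopifnot(nchar(target) >= 1, concentration >= 0,
            markov_blend >= 0, markov_blend <= 1)
  tgt_codes <- aa_codes(target)
  stopifnot(!anyNA(tgt_codes))
  if (is.null(alphabet)) alphabet <- sort(unique(strsplit(target, "")[[1]]))
  ab_codes <- vapply(alphabet, function(a) aa_codes(a), integer(1),
                     USE.NAMES = FALSE)
  stopifnot(all(tgt_codes %in% ab_codes))
  na <- length(alphabet)
  trans <- withr::with_seed(seed, {
    m <- matrix(stats::rgamma(na * na, shape = 2), nrow = na)
    m / rowSums(m)
  })
  eps <- 1e-12
  L <- nchar(target)
  w_t <- concentration / (1 + concentration)

  # probability vector over the 21 tokens for (position, prev residue code)
  prob_table <- function(position, prev_code = NA_integer_) {
    base <- rep(1 / na, na)
    if (!is.na(prev_code) && prev_code %in% ab_codes) {
      base <- (1 - markov_blend) * base +
        markov_blend * trans[match(prev_code, ab_codes), ]
    }
    p_ab <- (1 - w_t) * base
    p_ab[match(tgt_codes[position], ab_codes)] <-
      p_ab[match(tgt_codes[position], ab_codes)] + w_t
    p <- rep(eps, 21L)
    p[ab_codes + 1L] <- p[ab_codes + 1L] + p_ab
    p / sum(p)
  }

  structure(list(
    length = L,
    alphabet = alphabet,
    alphabet_codes = ab_codes,
    prob_table = prob_table,
    logits = function(assignment_codes, position) {
      prev <- if (position > 1L) assignment_codes[position - 1L] else NA_integer_
      log(prob_table(position, prev))
    }
  ), class = "seq_model")
}
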