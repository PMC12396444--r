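# Permissibility rules: classify k-mers as SELF / HIDDEN_NONSELF /
# FORBIDDEN and decide whether a candidate extension of a partial sequence
# is permissible. Short k-mers (length <= min_self_kmer_len) must come from
# the reference proteome; longer checked k-mers may instead be predicted
# not presented ("hidden"), at a probability penalty during decoding.

KMER_SELF <- "SELF"
KMER_HIDDEN <- "HIDDEN_NONSELF"
KMER_FORBIDDEN <- "FORBIDDEN"

#' Permissibility policy
#'
#' @param min_self_kmer_len K-mers up to this length must be proteome
#'   ("self") k-mers (default 6; 5 relaxes the constraint).
#' @param max_checked_kmer_len Longest k-mer length checked at all
#'   (default 10, the longest canonical MHC-I peptide).
#' @param non_self_prob_factor Multiplicative probability penalty in
#'   `[0, 1]` applied (on the log scale, during decoding) when an extension
#'   introduces hidden non-self k-mers (default 0.9; 0 forbids them
#'   outright in effect, 1 disables the penalty).
#' @return A `permissibility_policy`.
#' @export
permissibility_policy <- function(min_self_kmer_len = 6L,
                                  max_checked_kmer_len = 10L,
                                  non_self_prob_factor = 0.9) {
  stopifnot(min_self_kmer_len >= 1,
            min_self_kmer_len <= max_checked_kmer_len,
            non_self_prob_factor >= 0, non_self_prob_factor <= 1)
  structure(list(min_self_kmer_len = as.integer(min_self_kmer_len),
                 max_checked_kmer_len = as.integer(max_checked_kmer_len),
                 non_self_prob_factor = non_self_prob_factor),
            class = "permissibility_policy")
}

#' Classify a k-mer under a policy
#'
#' For lengths `k <= min_self_kmer_len` the k-mer must appear in the
#' reference proteome (`SELF`, else `FORBIDDEN`). For longer checked
#' lengths, a proteome k-mer is `SELF`; otherwise it is `HIDDEN_NONSELF`
#' when no presentation call applies (length outside 8-10) or when the
#' model predicts non-presentation for the genotype, and `FORBIDDEN` when
#' it is predicted presented.
#'
#' @param kmers Character vector of k-mers (lengths within
#'   `1..policy$max_checked_kmer_len`).
#' @param index A [build_kmer_index()] result.
#' @param model A [presentation_model()], or `NULL` for a never-presenting
#'   model (no peptide is ever called presented).
#' @param genotype A [genotype()]; ignored when `model` is `NULL`.
#' @param policy A [permissibility_policy()].
#' @return Character vector over `"SELF"`, `"HIDDEN_NONSELF"`,
#'   `"FORBIDDEN"`.
#' @export
classify_kmer <- function(kmers, index, model, genotype, policy) {
  lens <- nchar(kmers)
  if (any(lens < 1L) || any(lens > policy$max_checked_kmer_len)) {
    stop("k-mer longer than max_checked_kmer_len (",
         policy$max_checked_kmer_len, ")")
  }
  self <- is_self(index, kmers)
  out <- rep(KMER_SELF, length(kmers))
  short <- lens <= policy$min_self_kmer_len
  out[short & !self] <- KMER_FORBIDDEN
  long_ns <- !short & !self
  if (any(long_ns)) {
    pres_len <- lens %in% 8:10
    check <- long_ns & pres_len
    out[long_ns & !pres_len] <- KMER_HIDDEN
    if (any(check)) {
      if (is.null(model)) {
        out[check] <- KMER_HIDDEN
      } else {
        pres <- is_presented(model, genotype, kmers[check])
        out[check] <- ifelse(pres, KMER_FORBIDDEN, KMER_HIDDEN)
      }
    }
  }
  out
}

#' Windows completed by filling one position
#'
#' Returns every window of length `1..max_len` that contains `pos`, is now
#' fully filled, and was not fully filled before `pos` was placed (since
#' `pos` is newly filled, these are exactly the fully-filled windows
#' containing it). For strict left-to-right decoding this reduces to the
#' suffixes ending at `pos` of lengths `1..min(max_len, pos)`. Windows
#' never span chain breaks.
#'
#' @param filled Logical vector: which positions carry a residue (with
#'   `pos` itself filled).
#' @param pos The just-filled position.
#' @param max_len Longest window length to report.
#' @param chain Optional integer vector of chain ids (same length as
#'   `filled`); windows stay within one chain. Default: a single chain.
#' @return Integer matrix with columns `start`, `len`, one row per window.
#' @export
completed_windows <- function(filled, pos, max_len,
                              chain = rep(1L, length(filled))) {
  n <- length(filled)
  if (pos < 1L || pos > n || !filled[pos]) {
    stop("pos must be a filled position inside the assignment")
  }
  res_start <- integer(0)
  res_len <- integer(0)
  for (len in seq_len(max_len)) {
    lo <- max(1L, pos - len + 1L)
    hi <- min(pos, n - len + 1L)
    if (lo > hi) next
    for (s in lo:hi) {
      idx <- s:(s + len - 1L)
      if (all(filled[idx]) && all(chain[idx] == chain[pos])) {
        res_start <- c(res_start, s)
        res_len <- c(res_len, len)
      }
    }
  }
  cbind(start = res_start, len = res_len)
}

#' Verdict on one candidate extension
#'
#' Places `candidate_residue` at `pos` and classifies every window newly
#' completed by that placement. The extension is permissible iff no such
#' window is `FORBIDDEN`; the number of `HIDDEN_NONSELF` windows is
#' reported for penalty accounting. The unknown token `X` makes every
#' containing k-mer non-self, so it is forbidden whenever any window is
#' checked (the length-1 window always is).
#'
#' @param assignment Character vector of residues with `NA` at unfilled
#'   positions.
#' @param pos Position to fill.
#' @param candidate_residue One of the 21 tokens (20 residues + `"X"`).
#' @param index,model,genotype,policy See [classify_kmer()].
#' @param chain Optional chain id vector (see [completed_windows()]).
#' @return A list with `permissible`, `hidden_nonself_count` and
#'   `checked_kmers` (data.frame of `kmer`, `class`).
#' @export
extension_verdict <- function(assignment, pos, candidate_residue, index,
                              model, genotype, policy,
                              chain = rep(1L, length(assignment))) {
  stopifnot(candidate_residue %in% TOKENS)
  a <- assignment
  a[pos] <- candidate_residue
  filled <- !is.na(a)
  win <- completed_windows(filled, pos, policy$max_checked_kmer_len, chain)
  if (nrow(win) == 0L) {
    return(list(permissible = TRUE, hidden_nonself_count = 0L,
                checked_kmers = data.frame(kmer = character(0),
                                           class = character(0))))
  }
  kmers <- vapply(seq_len(nrow(win)), function(i) {
    paste(a[win[i, 1L]:(win[i, 1L] + win[i, 2L] - 1L)], collapse = "")
  }, character(1))
  cls <- classify_kmer(kmers, index, model, genotype, policy)
  list(permissible = !any(cls == KMER_FORBIDDEN),
       hidden_nonself_count = sum(cls == KMER_HIDDEN),
       checked_kmers = data.frame(kmer = kmers, class = cls))
}
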