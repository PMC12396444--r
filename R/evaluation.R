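# Sequence-level immunogenicity metrics: self-kmer fractions by length,
# the fraction of presented non-self 8-10mers, and an ungapped BLOSUM62
# dissimilarity of each non-self 8-10mer to its closest proteome k-mer.

seq_windows <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k = ", k)
  substring(sequence, 1:(L - k + 1L), k:L)
}

# drop windows overlapping 'X' (excluded from all metric denominators)
x_free <- function(windows) windows[!grepl("X", windows, fixed = TRUE)]

#' Fraction of length-k windows that are self
#'
#' @param sequence Amino-acid sequence (length >= k). Windows containing
#'   `X` are excluded from the denominator.
#' @param index A [build_kmer_index()] result with `max_len >= k`.
#' @param k Window length.
#' @return Fraction in `[0, 1]`.
#' @export
self_kmer_fraction <- function(sequence, index, k) {
  w <- x_free(seq_windows(sequence, k))
  if (length(w) == 0L) return(NA_real_)
  mean(is_self(index, w))
}

#' Fraction of presented non-self 8-10mers
#'
#' Counts windows of lengths 8, 9 and 10 that are both absent from the
#' proteome and predicted presented by at least one genotype allele,
#' divided by the total number of 8-10mer windows.
#'
#' @param sequence Amino-acid sequence (length >= 8).
#' @param index A [build_kmer_index()] result.
#' @param model A [presentation_model()], or `NULL` (never presenting, so
#'   the fraction is 0).
#' @param genotype A [genotype()].
#' @return Fraction in `[0, 1]`.
#' @export
presented_nonself_fraction <- function(sequence, index, model, genotype) {
  if (nchar(sequence) < 8L) stop("sequence shorter than 8")
  total <- 0L
  presented_ns <- 0L
  for (k in 8:10) {
    if (nchar(sequence) < k) next
    w <- x_free(seq_windows(sequence, k))
    total <- total + length(w)
    if (length(w) == 0L || is.null(model)) next
    ns <- w[!is_self(index, w)]
    if (length(ns)) presented_ns <- presented_ns +
        sum(is_presented(model, genotype, ns))
  }
  presented_ns / total
}

#' Load and validate the BLOSUM62 substitution matrix
#'
#' Subsets the canonical BLOSUM62 table to the 20 standard residues and
#' asserts symmetry and row diagonal dominance (each residue scores itself
#' at least as high as any substitution), which makes the dissimilarity
#' below non-negative.
#'
#' @return 20x20 integer matrix in [aa_alphabet()] order.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  stopifnot(isSymmetric(unname(m)),
            all(diag(m) >= apply(m, 1L, max)))
  m
}

#' Ungapped BLOSUM62 dissimilarity to the proteome
#'
#' For each query k-mer, finds the same-length proteome k-mer with the
#' highest ungapped position-wise BLOSUM62 score and subtracts that from
#' the query's score against itself. A k-mer present in the proteome (or
#' whose self score is attained by some proteome k-mer) scores 0; larger
#' values mean less self-like.
#'
#' @param kmers Character vector of k-mers, lengths 8-10 (lengths may be
#'   mixed), standard residues only.
#' @param index A [build_kmer_index()] result whose member sets define the
#'   proteome k-mers searched.
#' @param matrix Substitution matrix from [blosum62_matrix()] (loaded if
#'   `NULL`).
#' @return Integer vector of non-negative dissimilarities.
#' @export
blosum62_dissimilarity <- function(kmers, index, matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  lens <- nchar(kmers)
  stopifnot(all(lens >= 8L), all(lens <= 10L), all(lens <= index$max_len))
  out <- integer(length(kmers))
  for (k in unique(lens)) {
    if (length(index$sets[[k]]) == 0L) {
      stop("proteome contains no k-mer of length ", k)
    }
    pm <- kmer_codes_to_mat(index$sets[[k]], k)  # n x k proteome residues
    sel <- which(lens == k)
    qm <- peptide_code_matrix(kmers[sel], k)
    if (anyNA(qm)) stop("k-mers must use standard residues only")
    for (i in seq_along(sel)) {
      q <- qm[i, ]
      sc <- numeric(nrow(pm))
      for (j in seq_len(k)) sc <- sc + matrix[cbind(q[j] + 1L, pm[, j] + 1L)]
      out[sel[i]] <- sum(matrix[cbind(q + 1L, q + 1L)]) - max(sc)
    }
  }
  out
}

#' Full immunogenicity report for one design
#'
#' @param sequence Designed amino-acid sequence.
#' @param index A [build_kmer_index()] result.
#' @param model A [presentation_model()] or `NULL`.
#' @param genotype A [genotype()].
#' @param sequence_id Identifier carried into the report.
#' @param ks Self-fraction window lengths (default 5:10).
#' @param dissimilarities Also score each non-self 8-10mer against the
#'   proteome with [blosum62_dissimilarity()] (default TRUE).
#' @return A `design_report` list: `sequence_id`, `self_fraction_by_k`,
#'   `presented_nonself_fraction`, and a `dissimilarities` data.frame
#'   (`kmer`, `score`) over the non-self 8-10mers.
#' @export
design_report <- function(sequence, index, model, genotype,
                          sequence_id = "design", ks = 5:10,
                          dissimilarities = TRUE) {
  sf <- vapply(ks, function(k) self_kmer_fraction(sequence, index, k),
               numeric(1))
  names(sf) <- paste0("k", ks)
  ns <- character(0)
  for (k in 8:10) {
    if (nchar(sequence) < k) next
    w <- x_free(seq_windows(sequence, k))
    ns <- c(ns, w[!is_self(index, w)])
  }
  dis <- if (dissimilarities && length(ns)) {
    data.frame(kmer = ns, score = blosum62_dissimilarity(ns, index))
  } else {
    data.frame(kmer = character(0), score = integer(0))
  }
  structure(list(
    sequence_id = sequence_id,
    self_fraction_by_k = sf,
    presented_nonself_fraction =
      presented_nonself_fraction(sequence, index, model, genotype),
    dissimilarities = dis), class = "design_report")
}
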