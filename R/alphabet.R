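# Amino-acid alphabet and the base-20 integer encoding used internally.
#
# Every k-mer over the 20 standard residues maps to an exact double:
# code(a_1..a_k) = sum_i idx(a_i) * 20^(k-i), idx in 0..19. 20^10 < 2^53,
# so codes up to the maximum checked k-mer length are exact and order-
# preserving within a length, which gives O(log n) membership via sorted
# vectors and lets suffix codes be extended incrementally during decoding.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in the conventional
#' alphabetical order used throughout the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 21 decode tokens: 20 standard residues plus the 'unknown' token.
TOKENS <- c(AA20, "X")

# Ambiguous / rare letters mapped to 'X' on ingest (selenocysteine and
# friends are dropped from the self set, like 'X').
RARE_TO_X <- c("B", "J", "O", "U", "Z")

# utf8 -> 0-based residue index; NA for anything that is not one of the 20.
.aa_code_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[vapply(AA20, utf8ToInt, integer(1))] <- 0:19
  lut
})

# Character string -> integer codes 0..19 (NA for non-standard letters).
aa_codes <- function(s) {
  u <- utf8ToInt(s)
  out <- rep(NA_integer_, length(u))
  ok <- u >= 1L & u <= 127L
  out[ok] <- .aa_code_lut[u[ok]]
  out
}

codes_to_string <- function(codes) paste(AA20[codes + 1L], collapse = "")

# Base-20 code of a single k-mer string; NA if any letter is non-standard.
kmer_code <- function(kmer) {
  c0 <- aa_codes(kmer)
  if (anyNA(c0)) return(NA_real_)
  sum(c0 * 20^(rev(seq_along(c0)) - 1))
}

# Vectorised: n x k matrix of 0..19 codes -> numeric codes (NA rows -> NA).
codes_mat_to_kmer_codes <- function(m) {
  k <- ncol(m)
  out <- numeric(nrow(m))
  for (j in seq_len(k)) out <- out * 20 + m[, j]
  out
}

# Inverse: numeric codes -> n x k matrix of 0..19 digit codes.
kmer_codes_to_mat <- function(codes, k) {
  m <- matrix(0L, nrow = length(codes), ncol = k)
  x <- codes
  for (j in rev(seq_len(k))) {
    m[, j] <- as.integer(x %% 20)
    x <- (x - m[, j]) %/% 20
  }
  m
}

kmer_codes_to_strings <- function(codes, k) {
  if (length(codes) == 0L) return(character(0))
  m <- kmer_codes_to_mat(codes, k)
  apply(m, 1L, function(r) paste(AA20[r + 1L], collapse = ""))
}

# Membership of numeric codes in a sorted numeric set (binary search).
codes_in_set <- function(x, sorted_set) {
  if (length(sorted_set) == 0L || length(x) == 0L) return(rep(FALSE, length(x)))
  i <- findInterval(x, sorted_set)
  res <- i >= 1L & !is.na(x)
  res[res] <- sorted_set[i[res]] == x[res]
  res[is.na(x)] <- FALSE
  res
}
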