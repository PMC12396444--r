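# Proteome k-mer index: exact self-kmer membership for lengths 1..max_len.

#' Read a proteome from a FASTA file
#'
#' Sequences are uppercased on ingest. Rare/ambiguous residue letters
#' (B, J, O, U, Z) are mapped to `X`; `X` and the stop character `*` are
#' retained and handled downstream (k-mer windows never overlap an `X` and
#' never span a `*`).
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  # keep only the first whitespace-delimited word of each header, as is
  # conventional for proteome FASTA identifiers
  names(seqs) <- sub("\\s.*$", "", names(aas))
  seqs
}

normalize_protein <- function(seq) {
  s <- toupper(seq)
  for (r in RARE_TO_X) s <- gsub(r, "X", s, fixed = TRUE)
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X*]"), "", s)
  if (nchar(bad) > 0L) {
    stop("sequence contains characters outside the amino-acid alphabet: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  s
}

#' Build an exact k-mer membership index over a proteome
#'
#' Enumerates every length-k window (k = 1..`max_len`) fully contained in a
#' single protein sequence. Windows containing `X` (or a rare letter mapped
#' to `X`) are excluded, and windows never span a `*` stop character: both
#' split a record into independent segments. Membership is exact (hash-set
#' semantics), not probabilistic.
#'
#' @param proteins Named character vector of protein sequences (or an
#'   `AAStringSet`), e.g. from [read_proteome()]. May be empty.
#' @param max_len Maximum k-mer length to index (>= 1).
#' @return An object of class `kmer_index` with fields `max_len`, per-length
#'   member sets, `n_members` (per-length counts) and `source_digest`.
#' @export
build_kmer_index <- function(proteins, max_len) {
  stopifnot(is.numeric(max_len), length(max_len) == 1L, max_len >= 1)
  max_len <- as.integer(max_len)
  if (inherits(proteins, "AAStringSet")) proteins <- as.character(proteins)
  proteins <- vapply(unname(proteins), normalize_protein, character(1))

  # X-free, stop-free segments; windows live entirely inside one segment
  segs <- unlist(strsplit(proteins, "[X*]+"), use.names = FALSE)
  segs <- segs[nchar(segs) > 0L]
  seg_codes <- lapply(segs, aa_codes)

  sets <- vector("list", max_len)
  for (k in seq_len(max_len)) {
    per_seg <- lapply(seg_codes, function(cv) {
      n <- length(cv)
      if (n < k) return(numeric(0))
      w <- numeric(n - k + 1L)
      for (j in seq_len(k)) w <- w * 20 + cv[j:(n - k + j)]
      w
    })
    sets[[k]] <- sort(unique(as.numeric(unlist(per_seg, use.names = FALSE))))
  }

  structure(
    list(max_len = max_len,
         sets = sets,
         n_members = vapply(sets, length, integer(1)),
         source_digest = rlang::hash(list(names(proteins), unname(proteins),
                                          max_len))),
    class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer membership index (max_len =", x$max_len, ")\n")
  cat("  digest:", x$source_digest, "\n")
  for (k in seq_len(x$max_len)) {
    cat(sprintf("  %2d-mers: %d\n", k, x$n_members[k]))
  }
  invisible(x)
}

#' Query self-kmer membership
#'
#' @param index A `kmer_index`.
#' @param kmers Character vector of k-mers (all lengths <= `index$max_len`;
#'   lengths may be mixed). K-mers containing non-standard letters are never
#'   self.
#' @return Logical vector: is each k-mer a window of the indexed proteome?
#' @export
is_self <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  lens <- nchar(kmers)
  if (any(lens < 1L) || any(lens > index$max_len)) {
    stop("k-mer length outside 1..max_len (", index$max_len,
         "): index misconfigured for this query")
  }
  out <- logical(length(kmers))
  for (k in unique(lens)) {
    idx <- which(lens == k)
    codes <- vapply(kmers[idx], kmer_code, numeric(1), USE.NAMES = FALSE)
    out[idx] <- codes_in_set(codes, index$sets[[k]])
  }
  out
}

#' Extract the member k-mers of one length
#'
#' @param index A `kmer_index`.
#' @param k Length, 1..max_len.
#' @return Character vector of member k-mers (sorted).
#' @export
kmer_members <- function(index, k) {
  stopifnot(k >= 1, k <= index$max_len)
  kmer_codes_to_strings(index$sets[[k]], k)
}

#' Per-length member counts
#'
#' @param index A `kmer_index`.
#' @return A data.frame with columns `length` and `members`.
#' @export
index_summary <- function(index) {
  data.frame(length = seq_len(index$max_len), members = index$n_members)
}

#' Serialize / deserialize a k-mer index
#'
#' The on-disk format is a plain-text listing (header lines, then one k-mer
#' per line per length) that round-trips exactly.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `write_kmer_index` returns `path` invisibly; `read_kmer_index`
#'   returns a `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#epibeam_kmer_index\t1",
               paste0("max_len\t", index$max_len),
               paste0("digest\t", index$source_digest)), con)
  for (k in seq_len(index$max_len)) {
    writeLines(paste0("k\t", k, "\t", index$n_members[k]), con)
    if (index$n_members[k] > 0L) {
      writeLines(kmer_codes_to_strings(index$sets[[k]], k), con)
    }
  }
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#epibeam_kmer_index")) {
    stop("not a k-mer index file: ", path)
  }
  max_len <- as.integer(strsplit(lines[2L], "\t")[[1L]][2L])
  digest <- strsplit(lines[3L], "\t")[[1L]][2L]
  sets <- vector("list", max_len)
  i <- 4L
  for (k in seq_len(max_len)) {
    hdr <- strsplit(lines[i], "\t")[[1L]]
    stopifnot(hdr[1L] == "k", as.integer(hdr[2L]) == k)
    n <- as.integer(hdr[3L])
    i <- i + 1L
    if (n > 0L) {
      kmers <- lines[i:(i + n - 1L)]
      m <- matrix(NA_integer_, nrow = n, ncol = k)
      split_codes <- lapply(kmers, aa_codes)
      for (r in seq_len(n)) m[r, ] <- split_codes[[r]]
      sets[[k]] <- sort(codes_mat_to_kmer_codes(m))
      i <- i + n
    } else {
      sets[[k]] <- numeric(0)
    }
  }
  structure(list(max_len = max_len, sets = sets,
                 n_members = vapply(sets, length, integer(1)),
                 source_digest = digest),
            class = "kmer_index")
}
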