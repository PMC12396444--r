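# Fast approximate MHC-I presentation classifier: one position weight
# matrix (PWM) per allele and peptide length (8-10), with thresholds
# calibrated as empirical background-score quantiles so that a chosen
# fraction of random peptides (2% by convention, mirroring the percentile
# rank cutoff used for presentation calls) is classified presented.

#' Train a position weight matrix from presented peptides
#'
#' Weights are per-position log2 odds of the position-specific residue
#' frequency (with additive pseudocount) over a background frequency:
#' `w[a, p] = log2((count(a at p) + pseudocount) / (n + 20 * pseudocount)
#' / background_freqs[a])`. Scoring is additive over positions.
#'
#' @param presented_peptides Character vector of equal-length peptides
#'   (length k), standard residues only; at least one.
#' @param background_freqs Numeric vector of 20 background residue
#'   frequencies in [aa_alphabet()] order, summing to 1, all > 0.
#'   Default uniform.
#' @param pseudocount Additive pseudocount > 0 (keeps weights finite).
#' @param allele Optional allele name attached to the PWM.
#' @return A `pwm` object (threshold unset, `NA`).
#' @export
train_pwm <- function(presented_peptides, background_freqs = rep(0.05, 20),
                      pseudocount = 0.5, allele = NA_character_) {
  n <- length(presented_peptides)
  if (n < 1L) stop("at least one presented peptide is required")
  k <- nchar(presented_peptides[1L])
  if (any(nchar(presented_peptides) != k)) stop("mixed peptide lengths")
  stopifnot(length(background_freqs) == 20, all(background_freqs > 0),
            abs(sum(background_freqs) - 1) < 1e-8, pseudocount > 0)
  m <- peptide_code_matrix(presented_peptides, k)
  if (anyNA(m)) stop("peptides must use standard residues only")
  w <- matrix(0, nrow = 20L, ncol = k, dimnames = list(AA20, NULL))
  for (p in seq_len(k)) {
    cnt <- tabulate(m[, p] + 1L, nbins = 20L)
    w[, p] <- log2((cnt + pseudocount) / (n + 20 * pseudocount) /
                     background_freqs)
  }
  structure(list(allele = allele, k = k, weights = w,
                 threshold = NA_real_), class = "pwm")
}

# peptides -> n x k matrix of 0..19 codes (NA for non-standard letters)
peptide_code_matrix <- function(peptides, k) {
  n <- length(peptides)
  m <- matrix(NA_integer_, nrow = n, ncol = k)
  u <- utf8ToInt(paste(peptides, collapse = ""))
  ok <- u >= 1L & u <= 127L
  v <- rep(NA_integer_, length(u))
  v[ok] <- .aa_code_lut[u[ok]]
  matrix(v, nrow = n, ncol = k, byrow = TRUE)
}

#' Score peptides under a PWM
#'
#' Additive over positions. Peptides containing non-standard letters
#' (e.g. `X`) score `-Inf` and are therefore never presented.
#'
#' @param pwm A `pwm`.
#' @param peptides Character vector, all of length `pwm$k`.
#' @return Numeric vector of scores.
#' @export
score_peptides <- function(pwm, peptides) {
  if (any(nchar(peptides) != pwm$k)) {
    stop("peptide length must equal pwm$k = ", pwm$k)
  }
  m <- peptide_code_matrix(peptides, pwm$k)
  score_code_matrix(pwm, m)
}

# scores from a precomputed code matrix (NA codes -> -Inf)
score_code_matrix <- function(pwm, m) {
  s <- numeric(nrow(m))
  bad <- rep(FALSE, nrow(m))
  for (p in seq_len(pwm$k)) {
    cp <- m[, p]
    na <- is.na(cp)
    bad <- bad | na
    cp[na] <- 0L
    s <- s + pwm$weights[cbind(cp + 1L, p)]
  }
  s[bad] <- -Inf
  s
}

#' Calibrate a PWM threshold on background peptides
#'
#' Sets the threshold to the nearest-rank empirical
#' `(1 - target_presented_fraction)` quantile of the background scores, so
#' that about `target_presented_fraction` of background peptides score at or
#' above it. Ties at the threshold count as presented.
#'
#' @param pwm A `pwm`.
#' @param background_peptides Character vector of length-`k` peptides;
#'   at least 1000 so the quantile is resolved.
#' @param target_presented_fraction Target fraction in (0, 1); the
#'   conventional presentation cutoff is 0.02.
#' @return The `pwm` with `threshold` set.
#' @export
calibrate_threshold <- function(pwm, background_peptides,
                                target_presented_fraction = 0.02) {
  n <- length(background_peptides)
  stopifnot(target_presented_fraction > 0, target_presented_fraction < 1)
  if (n < 1000L) {
    stop("need >= 1000 background peptides to resolve the quantile (got ",
         n, ")")
  }
  s <- sort(score_peptides(pwm, background_peptides))
  idx <- max(1L, ceiling((1 - target_presented_fraction) * n))
  pwm$threshold <- s[idx]
  pwm
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM: allele=%s k=%d threshold=%s\n", x$allele, x$k,
              format(x$threshold)))
  invisible(x)
}

#' Construct a genotype
#'
#' Up to six MHC-I allele names; duplicates (homozygosity) are allowed but
#' deduplicated for presentation queries.
#'
#' @param alleles Character vector of 1..6 allele names.
#' @return A `genotype` (deduplicated character vector).
#' @export
genotype <- function(alleles) {
  stopifnot(length(alleles) >= 1, length(alleles) <= 6,
            all(nzchar(alleles)))
  structure(unique(alleles), class = "genotype")
}

#' Bundle calibrated PWMs into a presentation model
#'
#' @param pwms List of calibrated `pwm` objects (allele names set,
#'   thresholds set). One PWM per (allele, length) pair.
#' @param lengths_covered Peptide lengths the model must answer for
#'   (default 8:10).
#' @return A `presentation_model`.
#' @export
presentation_model <- function(pwms, lengths_covered = 8:10) {
  stopifnot(length(pwms) >= 1)
  for (p in pwms) {
    stopifnot(inherits(p, "pwm"))
    if (is.na(p$threshold)) stop("all PWMs must be calibrated (threshold set)")
    if (is.na(p$allele)) stop("all PWMs must carry an allele name")
  }
  keys <- vapply(pwms, function(p) paste0(p$allele, "|", p$k), character(1))
  if (anyDuplicated(keys)) stop("duplicate (allele, k) PWM")
  names(pwms) <- keys
  structure(list(pwms = pwms,
                 alleles = unique(vapply(pwms, `[[`, character(1), "allele")),
                 lengths_covered = as.integer(lengths_covered)),
            class = "presentation_model")
}

model_pwm <- function(model, allele, k) {
  p <- model$pwms[[paste0(allele, "|", k)]]
  if (is.null(p)) {
    stop("incomplete presentation model: no PWM for allele ", allele,
         " at length ", k)
  }
  p
}

#' Is a peptide presented by any allele of a genotype?
#'
#' OR-semantics over the (deduplicated) genotype: a peptide is presented
#' iff its PWM score reaches the calibrated threshold for at least one
#' allele's PWM of matching length.
#'
#' @param model A [presentation_model()].
#' @param genotype A [genotype()] (or character vector of allele names).
#' @param peptides Character vector of peptides with lengths in
#'   `model$lengths_covered` (lengths may be mixed).
#' @return Logical vector.
#' @export
is_presented <- function(model, genotype, peptides) {
  alleles <- unique(unclass(genotype))
  lens <- nchar(peptides)
  bad <- setdiff(unique(lens), model$lengths_covered)
  if (length(bad)) {
    stop("peptide length(s) ", paste(bad, collapse = ","),
         " outside lengths covered (", paste(model$lengths_covered,
                                             collapse = ","), ")")
  }
  out <- logical(length(peptides))
  for (k in unique(lens)) {
    sel <- lens == k
    m <- peptide_code_matrix(peptides[sel], k)
    v <- rep(FALSE, sum(sel))
    for (a in alleles) {
      p <- model_pwm(model, a, k)
      v <- v | (score_code_matrix(p, m) >= p$threshold)
    }
    out[sel] <- v
  }
  out
}

#' Presentation profile of one allele over a peptide panel
#'
#' @param model A [presentation_model()].
#' @param allele Allele name.
#' @param panel Character vector of peptides (the shared panel).
#' @return Logical verdict vector over the panel.
#' @export
presentation_profile <- function(model, allele, panel) {
  is_presented(model, genotype(allele), panel)
}

#' Distance between two allele presentation profiles
#'
#' The percentage of panel peptides on which the two verdict vectors
#' disagree (normalized Hamming distance x 100).
#'
#' @param a,b Logical verdict vectors over the same panel.
#' @return Distance in percent, in `[0, 100]`; symmetric.
#' @export
allele_distance <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L) {
    stop("profiles must share one non-empty panel")
  }
  100 * mean(xor(a, b))
}

#' Pairwise allele distance table over a panel
#'
#' @param model A [presentation_model()].
#' @param alleles Character vector of allele names.
#' @param panel Shared peptide panel.
#' @return Symmetric numeric matrix of percent distances.
#' @export
allele_distance_table <- function(model, alleles, panel) {
  profs <- lapply(alleles, function(a) presentation_profile(model, a, panel))
  n <- length(alleles)
  d <- matrix(0, n, n, dimnames = list(alleles, alleles))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) d[i, j] <- d[j, i] <- allele_distance(profs[[i]], profs[[j]])
  }
  d
}

#' Gene prefix of an HLA-style allele name
#'
#' @param allele Allele names such as `"HLA-A*02:01"` (any `<prefix>-<G>*`
#'   shape works, e.g. `"SYN-B*01:01"`).
#' @return Character vector of gene letters (`"A"`, `"B"`, `"C"`).
#' @export
allele_gene <- function(allele) {
  g <- sub("^[^-]*-([A-Z])\\*.*$", "\\1", allele)
  if (any(g == allele)) stop("unparseable allele name(s): ",
                             paste(allele[g == allele], collapse = ", "))
  g
}

#' Select a maximally dissimilar alternative genotype
#'
#' For each gene, picks the two candidate alleles that maximize the minimum
#' presentation-profile distance to any allele of the primary genotype
#' (max-min selection). Ties are broken by lexicographic allele name.
#'
#' @param candidates_by_gene Named list (genes -> character vectors of
#'   candidate allele names), each with >= 2 candidates.
#' @param primary A [genotype()] (or character vector) of primary alleles.
#' @param distances Numeric matrix of percent distances with candidate
#'   alleles in rows and primary alleles in columns (any superset works,
#'   e.g. a full [allele_distance_table()]).
#' @return A [genotype()] of two alleles per gene.
#' @export
select_alternative_genotype <- function(candidates_by_gene, primary,
                                        distances) {
  primary <- unique(unclass(primary))
  chosen <- character(0)
  for (gene in names(candidates_by_gene)) {
    cands <- candidates_by_gene[[gene]]
    if (length(cands) < 2L) stop("need >= 2 candidates for gene ", gene)
    if (!all(cands %in% rownames(distances)) ||
        !all(primary %in% colnames(distances))) {
      stop("distance table must cover every (candidate, primary) pair")
    }
    min_d <- apply(distances[cands, primary, drop = FALSE], 1L, min)
    ord <- order(-min_d, cands)
    chosen <- c(chosen, cands[ord[1:2]])
  }
  genotype(chosen)
}

#' Write / read a PWM as TSV
#'
#' One file per (allele, length): a header line carrying the allele name,
#' k and threshold, then a 20-row by k-column weight table with residue
#' row names. Round-trips exactly at full double precision.
#'
#' @param pwm A `pwm`.
#' @param path File path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` returns a `pwm`.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("#pwm", pwm$allele, pwm$k,
                   formatC(pwm$threshold, digits = 17, format = "g"),
                   sep = "\t"), con)
  writeLines(paste("residue", paste0("p", seq_len(pwm$k), collapse = "\t"),
                   sep = "\t"), con)
  for (i in seq_len(20L)) {
    writeLines(paste(AA20[i],
                     paste(formatC(pwm$weights[i, ], digits = 17,
                                   format = "g"), collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t")[[1L]]
  if (hdr[1L] != "#pwm") stop("not a PWM file: ", path)
  k <- as.integer(hdr[3L])
  w <- matrix(NA_real_, 20L, k, dimnames = list(AA20, NULL))
  for (i in seq_len(20L)) {
    f <- strsplit(lines[2L + i], "\t")[[1L]]
    stopifnot(f[1L] == AA20[i])
    w[i, ] <- as.numeric(f[-1L])
  }
  structure(list(allele = hdr[2L], k = k, weights = w,
                 threshold = as.numeric(hdr[4L])), class = "pwm")
}
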