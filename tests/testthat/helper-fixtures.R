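# Shared fixtures built in code. All seeded; nothing touches the network.

AA <- aa_alphabet()

# tiny two-protein proteome used in hand-derived membership cases
tiny_index <- function(max_len = 3L) {
  build_kmer_index(c(p1 = "ACD", p2 = "CDE"), max_len)
}

# small 4-letter world for brute-force oracles
abcd <- c("A", "C", "D", "E")

abcd_world <- function(seed = 5L, n_proteins = 6L, len = c(20L, 30L),
                       min_self = 4L, max_checked = 6L, factor = 0.9) {
  prot <- generate_proteome(n_proteins, len, alphabet = abcd, seed = seed)
  list(proteome = prot,
       index = build_kmer_index(prot, 10L),
       policy = permissibility_policy(min_self, max_checked, factor))
}

random_peptides <- function(n, k, seed, alphabet = AA) {
  withr::with_seed(seed, {
    m <- matrix(sample(alphabet, n * k, replace = TRUE), nrow = n)
    apply(m, 1L, paste, collapse = "")
  })
}

# calibrated PWM with a manually forced threshold: verdict "always" presents
# every standard peptide, "never" presents none
degenerate_pwm <- function(allele, k, verdict = c("never", "always")) {
  verdict <- match.arg(verdict)
  p <- train_pwm(random_peptides(5L, k, seed = k), allele = allele)
  p$threshold <- if (verdict == "always") -1e9 else 1e9
  p
}

degenerate_model <- function(alleles, verdict = "never", lengths = 8:10) {
  presentation_model(unlist(lapply(alleles, function(a) {
    lapply(lengths, function(k) degenerate_pwm(a, k, verdict))
  }), recursive = FALSE), lengths_covered = lengths)
}

# PWM that presents exactly one peptide (score k at the target, far below
# threshold anywhere else)
single_peptide_pwm <- function(allele, peptide) {
  k <- nchar(peptide)
  p <- train_pwm(peptide, allele = allele)
  w <- matrix(-1e6, 20L, k, dimnames = list(AA, NULL))
  tgt <- strsplit(peptide, "")[[1]]
  for (j in seq_len(k)) w[tgt[j], j] <- 1
  p$weights <- w
  p$threshold <- k
  p
}

# anchored synthetic alleles used across PWM/decoder tests (P2 + C-term)
syn_allele_a <- function(sharpness = 1) {
  allele_spec("SYN-A*01:01", c(2L, -1L), c("L", "V"), sharpness)
}
syn_allele_b <- function(sharpness = 1) {
  allele_spec("SYN-B*01:01", c(2L, -1L), c("E", "K"), sharpness)
}

# train + calibrate a presentation model from allele specs
fit_syn_model <- function(specs, n_train = 3000L, n_bg = 20000L,
                          target = 0.02, seed = 1L) {
  pwms <- list()
  for (i in seq_along(specs)) {
    for (k in 8:10) {
      lab <- generate_synthetic_allele(specs[[i]], k, n_train,
                                       seed = seed + 100L * i + k)
      pwm <- train_pwm(lab$peptides[lab$labels], allele = specs[[i]]$name)
      bg <- random_peptides(n_bg, k, seed = seed + 500L + 10L * i + k)
      pwms[[length(pwms) + 1L]] <- calibrate_threshold(pwm, bg, target)
    }
  }
  presentation_model(pwms)
}

# brute-force re-scan: classes of every window of lengths 1..max_checked
scan_all_windows <- function(sequence, index, model, genotype, policy) {
  L <- nchar(sequence)
  out <- data.frame(kmer = character(0), class = character(0))
  for (k in seq_len(min(policy$max_checked_kmer_len, L))) {
    w <- substring(sequence, 1:(L - k + 1L), k:L)
    out <- rbind(out, data.frame(
      kmer = w, class = classify_kmer(w, index, model, genotype, policy)))
  }
  out
}
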