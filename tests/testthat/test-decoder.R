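make_toy <- function(target = "ACDEAC", conc = 2, blend = 0.3, seed = 2) {
  toy_sequence_model(target, concentration = conc, markov_blend = blend,
                     seed = seed, alphabet = abcd)
}

test_that("lookahead estimate reduces to own log-probability at depth 0", {
  w <- abcd_world(seed = 5)
  toy <- make_toy()
  cfg <- decode_config(w$policy, width = 3, depth = 0, seed = 1)
  ctx <- list(index = w$index, model = NULL, genotype = NULL,
              policy = w$policy, chain = rep(1L, 6), single_chain = TRUE,
              cache = NULL)
  codes <- c(0L, rep(NA_integer_, 5))
  est <- epibeam:::future_logprob(codes, 1, -1.25, 0L, toy, cfg, ctx)
  expect_equal(est, -1.25)
})

test_that("depth-2 lookahead equals the hand-enumerated greedy path", {
  w <- abcd_world(seed = 5)
  toy <- make_toy()
  pol1 <- permissibility_policy(w$policy$min_self_kmer_len,
                                w$policy$max_checked_kmer_len, 1)
  cfg <- decode_config(pol1, width = 3, depth = 2, seed = 1)
  ctx <- list(index = w$index, model = NULL, genotype = NULL,
              policy = pol1, chain = rep(1L, 6), single_chain = TRUE,
              cache = NULL)
  first <- aa_codes("A")
  codes <- c(first, rep(NA_integer_, 5))
  own <- toy$logits(rep(NA_integer_, 6), 1)[first + 1]

  # independent oracle: at each of 2 steps pick the most probable residue
  # whose suffix windows are all permissible, accumulating log-probs
  expected <- own
  cur <- "A"
  for (step in 2:3) {
    lg <- log(toy$prob_table(step, aa_codes(substr(cur, step - 1, step - 1))))
    ok <- vapply(abcd, function(r) {
      kmers <- substring(paste0(cur, r), 1:step, step)
      kmers <- kmers[nchar(kmers) <= pol1$max_checked_kmer_len]
      !any(classify_kmer(kmers, w$index, NULL, NULL, pol1) == "FORBIDDEN")
    }, logical(1))
    lg_ok <- lg[aa_codes(paste(abcd, collapse = "")) + 1][ok]
    best <- abcd[ok][which.max(lg_ok)]
    expected <- expected + max(lg_ok)
    cur <- paste0(cur, best)
  }
  est <- epibeam:::future_logprob(codes, 1, own, 0L, toy, cfg, ctx)
  expect_equal(est, expected)

  # with non_self_prob_factor = 1 a hidden extension is not penalized
  est_h <- epibeam:::future_logprob(codes, 1, own, 3L, toy, cfg, ctx)
  expect_equal(est_h, expected)
})

test_that("beam width 1 is greedy permissible decoding", {
  w <- abcd_world(seed = 5)
  toy <- make_toy()
  cfg1 <- decode_config(w$policy, width = 1, depth = 0, seed = 1)
  res <- decode_design(toy, 6, cfg1, w$index)
  # greedy oracle: extend step by step with the most probable permissible
  cur <- character(0)
  for (p in 1:6) {
    prev <- if (p > 1) aa_codes(cur[p - 1]) else NA_integer_
    lg <- log(toy$prob_table(p, prev))
    ok <- vapply(abcd, function(r) {
      s <- paste(c(cur, r), collapse = "")
      kmers <- substring(s, max(1, p - 5):p, p)
      !any(classify_kmer(kmers, w$index, NULL, NULL, w$policy) == "FORBIDDEN")
    }, logical(1))
    lg_ok <- lg[vapply(abcd, aa_codes, integer(1)) + 1][ok]
    cur <- c(cur, abcd[ok][which.max(lg_ok)])
  }
  expect_equal(res$sequence, paste(cur, collapse = ""))
})

test_that("beams sharing their trailing residues collapse to the best one", {
  w <- abcd_world(seed = 5)
  toy <- make_toy()
  cfg <- decode_config(w$policy, width = 10, depth = 0,
                       dedupe_suffix_len = 2, seed = 1)
  ctx <- list(index = w$index, model = NULL, genotype = NULL,
              policy = w$policy, chain = rep(1L, 6), single_chain = TRUE,
              cache = new.env(parent = emptyenv()))
  # parents differ only at position 1, so candidate permissibility (which
  # looks back min_self - 1 = 3 residues) is identical for both
  b <- epibeam:::new_beam(6)
  b1 <- b; b1$codes[1:4] <- aa_codes("ACDC"); b1$cum_logprob <- -1
  b2 <- b; b2$codes[1:4] <- aa_codes("DCDC"); b2$cum_logprob <- -3
  out <- epibeam:::decode_step(list(b1, b2), 5, toy, cfg, ctx)
  # any surviving pair of beams differs in its last-2 residues
  keys <- vapply(out, function(x) paste(x$codes[4:5], collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  # where both parents offered the same suffix, the higher-probability
  # parent won
  for (kk in keys) {
    surv <- out[[match(kk, keys)]]
    expect_equal(surv$codes[1:2], aa_codes("AC"))
  }
  expect_lte(length(out), cfg$width)
  expect_error(epibeam:::decode_step(list(), 1, toy, cfg, ctx), "empty")
})

test_that("an impossible constraint set triggers flagged fallback", {
  # proteome with a single 1-residue protein: no 2-mer is ever self
  idx <- build_kmer_index(c(p = "A"), 10)
  pol <- permissibility_policy(2, 6, 0.9)
  toy <- make_toy()
  res <- decode_design(toy, 3, decode_config(pol, width = 2, depth = 0),
                       idx)
  expect_true(2L %in% res$beam$fallback_positions)
  expect_equal(res$report$n_fallback, 2L)
  expect_equal(nchar(res$sequence), 3L)
})

test_that("length-1 designs pick the most probable self residue", {
  idx <- build_kmer_index(c(p = "ACDE"), 10)
  toy <- make_toy()
  res <- decode_design(toy, 1, decode_config(permissibility_policy(1, 6),
                                             width = 2, depth = 0), idx)
  pr <- toy$prob_table(1, NA_integer_)
  expect_equal(res$sequence, aa_alphabet()[which.max(pr[1:20])])
})

test_that("a concentrated model recovers its embedded target exactly", {
  target <- "CADECADE"
  prot <- generate_proteome(6, c(20, 30), alphabet = abcd, seed = 8,
                            embed_motifs = rep(target, 3))
  idx <- build_kmer_index(prot, 10)
  toy <- toy_sequence_model(target, concentration = 1e6, markov_blend = 0,
                            seed = 1, alphabet = abcd)
  res <- decode_design(toy, 8, decode_config(permissibility_policy(4, 6),
                                             width = 4), idx)
  expect_equal(res$sequence, target)
})

test_that("decoding equals exhaustive argmax over permissible sequences", {
  for (s in 1:5) {
    w <- abcd_world(seed = 100 + s)
    toy <- make_toy(seed = s)
    enum <- enumerate_permissible_sequences(toy, 6, w$index,
                                            policy = w$policy)
    expect_gt(nrow(enum), 0)
    cfg <- decode_config(w$policy, width = nrow(enum), depth = 0,
                         seed = 1)
    res <- decode_design(toy, 6, cfg, w$index)
    expect_equal(res$sequence, enum$sequence[1])
    expect_equal(res$report$cum_logprob, enum$logprob[1], tolerance = 1e-9)
  }
})

test_that("non-fallback designs re-scan clean under the decode-time model", {
  prot <- generate_proteome(120, c(80, 120), seed = 31)
  idx <- build_kmer_index(prot, 10)
  pm <- fit_syn_model(list(syn_allele_a(), syn_allele_b()),
                      n_train = 1200L, n_bg = 5000L, seed = 32)
  gt <- genotype(c("SYN-A*01:01", "SYN-B*01:01"))
  pol <- permissibility_policy(5, 10, 0.9)
  cfg <- decode_config(pol, width = 8, depth = 6, seed = 3)
  for (d in 1:2) {
    tgt <- random_peptides(1, 40, seed = 40 + d)
    toy <- toy_sequence_model(tgt, concentration = 4, markov_blend = 0.5,
                              seed = d, alphabet = aa_alphabet())
    res <- decode_design(toy, 40, cfg, idx, pm, gt)
    expect_equal(res$report$n_fallback, 0L)
    scan <- scan_all_windows(res$sequence, idx, pm, gt, pol)
    expect_equal(sum(scan$class == "FORBIDDEN"), 0L)
    # incremental hidden accounting equals the batch re-scan
    expect_equal(res$report$hidden_kmer_count,
                 sum(scan$class == "HIDDEN_NONSELF"))
  }
})

test_that("pre-sampled unresolved positions are respected and checked", {
  w <- abcd_world(seed = 5)
  toy <- make_toy()
  cfg <- decode_config(w$policy, width = 4, depth = 0, seed = 7)
  res1 <- decode_design(toy, 6, cfg, w$index, unresolved = c(3L))
  res2 <- decode_design(toy, 6, cfg, w$index, unresolved = c(3L))
  expect_identical(res1$sequence, res2$sequence)  # seeded pre-sampling
  expect_false(is.na(res1$beam$pos_logprob[3]))
  # all windows still verified: no forbidden k-mer unless fallback occurred
  if (res1$report$n_fallback == 0L) {
    scan <- scan_all_windows(res1$sequence, w$index, NULL, NULL, w$policy)
    expect_equal(sum(scan$class == "FORBIDDEN"), 0L)
  }
})

test_that("a stronger hidden-kmer penalty does not increase hidden usage", {
  hidden_total <- function(factor) {
    tot <- 0L
    for (s in 1:4) {
      prot <- generate_proteome(40, c(60, 90), seed = 200 + s)
      idx <- build_kmer_index(prot, 10)
      pol <- permissibility_policy(4, 10, factor)
      toy <- toy_sequence_model(random_peptides(1, 30, seed = 300 + s),
                                concentration = 2, markov_blend = 0.5,
                                seed = s, alphabet = aa_alphabet())
      res <- decode_design(toy, 30, decode_config(pol, width = 6,
                                                  depth = 4, seed = s), idx)
      tot <- tot + res$report$hidden_kmer_count
    }
    tot
  }
  expect_lte(hidden_total(0.3), hidden_total(1))
})

test_that("baseline sampling is seeded, temperature-aware and calibrated", {
  toy <- make_toy()
  expect_identical(baseline_sample(toy, 6, 0.5, seed = 4),
                   baseline_sample(toy, 6, 0.5, seed = 4))
  # tiny temperature = greedy argmax walk over the exposed table
  greedy <- baseline_sample(toy, 6, 1e-9, seed = 1)
  cur <- character(0)
  for (p in 1:6) {
    prev <- if (p > 1) aa_codes(cur[p - 1]) else NA_integer_
    pr <- toy$prob_table(p, prev)
    cur <- c(cur, c(aa_alphabet(), "X")[which.max(pr)])
  }
  expect_equal(greedy, paste(cur, collapse = ""))
  expect_error(baseline_sample(toy, 6, 0), "temperature")

  # temperature-1 draws of a length-1 sequence follow the model multinomial
  toy3 <- toy_sequence_model("A", concentration = 0.5, markov_blend = 0,
                             seed = 2, alphabet = c("A", "C", "D"))
  draws <- vapply(1:4000, function(s) baseline_sample(toy3, 1, 1, seed = s),
                  character(1))
  pr <- toy3$prob_table(1, NA_integer_)
  for (r in c("A", "C", "D")) {
    p <- pr[aa_codes(r) + 1]
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(mean(draws == r) - p), 3 * se + 1e-9)
  }
})
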