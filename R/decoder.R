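# Constrained beam-search decoder. Beams are partial assignments extended
# one position at a time; each of the 21 candidate tokens is admitted only
# if every k-mer window it completes is permissible. Candidates are ranked
# by an estimated "future" log-probability: their own log-probability plus
# a greedy, permissibility-constrained lookahead of `depth` steps, with a
# multiplicative probability penalty (non_self_prob_factor) for extensions
# that lean on hidden non-self k-mers. Beam collapse is prevented by
# keeping only the most likely beam among those sharing the same last few
# residues. The final design is the completed beam with the highest sum of
# per-residue log-probabilities.

#' Decoding configuration
#'
#' @param policy A [permissibility_policy()].
#' @param width Beam width (default 10).
#' @param depth Greedy lookahead depth; default `2 * min_self_kmer_len`.
#' @param dedupe_suffix_len Beams sharing their last this-many residues are
#'   collapsed to the most likely one (default 5).
#' @param seed Integer seed used only for the pre-sampling of unresolved
#'   positions.
#' @param lookahead_floor Log-probability charged per missing lookahead
#'   step when the greedy continuation dead-ends (default `log(1/21)`).
#' @param penalize_immediate Apply the full `non_self_prob_factor^depth`
#'   penalty when the immediate extension introduces hidden non-self
#'   k-mers (default TRUE).
#' @param penalize_lookahead Apply one `non_self_prob_factor` factor per
#'   lookahead step that itself introduces hidden non-self k-mers
#'   (default TRUE).
#' @return A `decode_config`.
#' @export
decode_config <- function(policy = permissibility_policy(), width = 10L,
                          depth = NULL, dedupe_suffix_len = 5L, seed = 1L,
                          lookahead_floor = log(1 / 21),
                          penalize_immediate = TRUE,
                          penalize_lookahead = TRUE) {
  if (is.null(depth)) depth <- 2L * policy$min_self_kmer_len
  stopifnot(width >= 1, depth >= 0)
  structure(list(policy = policy, width = as.integer(width),
                 depth = as.integer(depth),
                 dedupe_suffix_len = as.integer(dedupe_suffix_len),
                 seed = as.integer(seed), lookahead_floor = lookahead_floor,
                 penalize_immediate = isTRUE(penalize_immediate),
                 penalize_lookahead = isTRUE(penalize_lookahead)),
            class = "decode_config")
}

# ---- fast suffix-window permissibility -------------------------------------

# Batch verdict for the 20 standard candidate residues at `pos` given the
# left context in `codes` (0..19; 20 encodes 'X'; NA unfilled). Valid only
# when all checked windows are suffixes ending at pos (pure left-to-right
# within one chain). Returns permissible/hidden for residues 0..19; the
# unknown token is never permissible (its length-1 window is non-self).
suffix_verdict <- function(codes, pos, index, model, genotype, policy,
                           cache = NULL) {
  K <- min(policy$max_checked_kmer_len, pos)
  m <- K - 1L
  tailc <- if (m > 0L) codes[(pos - m):(pos - 1L)] else integer(0)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste0("c", paste(tailc, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  # cc[j + 1] = base-20 code of the last j context letters (NA if any 'X')
  cc <- numeric(m + 1L)
  for (j in seq_len(m)) {
    letter <- tailc[m - j + 1L]
    cc[j + 1L] <- if (is.na(cc[j]) || is.na(letter) || letter >= 20L)
      NA_real_ else letter * 20^(j - 1) + cc[j]
  }
  cand <- 0:19
  permissible <- rep(TRUE, 20L)
  hidden <- integer(20L)
  k_star <- min(policy$min_self_kmer_len, K)
  # substring closure: the k_star-suffix being self implies all shorter
  # suffixes are self, so one membership test covers every short window
  permissible <- codes_in_set(cc[k_star] * 20 + cand, index$sets[[k_star]])
  if (K > policy$min_self_kmer_len) {
    for (k in (policy$min_self_kmer_len + 1L):K) {
      alive <- which(permissible)
      if (length(alive) == 0L) break
      self_k <- codes_in_set(cc[k] * 20 + cand[alive], index$sets[[k]])
      ns <- alive[!self_k]
      if (length(ns) == 0L) next
      if (k %in% 8:10 && !is.null(model)) {
        pepm <- matrix(rep(tailc[(m - k + 2L):m], each = length(ns)),
                       nrow = length(ns), ncol = k - 1L)
        pepm[pepm >= 20L] <- NA_integer_
        pepm <- cbind(pepm, cand[ns])
        pres <- rep(FALSE, length(ns))
        for (a in unique(unclass(genotype))) {
          p <- model_pwm(model, a, k)
          pres <- pres | (score_code_matrix(p, pepm) >= p$threshold)
        }
        permissible[ns[pres]] <- FALSE
        hidden[ns[!pres]] <- hidden[ns[!pres]] + 1L
      } else {
        hidden[ns] <- hidden[ns] + 1L
      }
    }
  }
  res <- list(permissible = permissible, hidden = hidden)
  if (!is.null(cache)) cache[[key]] <- res
  res
}

# Generic verdict via the window enumerator (handles pre-filled positions
# to the right of pos, e.g. pre-sampled unresolved positions).
generic_verdict <- function(codes, pos, index, model, genotype, policy,
                            chain) {
  a <- ifelse(is.na(codes), NA_character_, TOKENS[codes + 1L])
  permissible <- logical(20L)
  hidden <- integer(20L)
  for (c0 in 0:19) {
    v <- extension_verdict(a, pos, TOKENS[c0 + 1L], index, model, genotype,
                           policy, chain)
    permissible[c0 + 1L] <- v$permissible
    hidden[c0 + 1L] <- v$hidden_nonself_count
  }
  list(permissible = permissible, hidden = hidden)
}

candidate_verdict <- function(codes, pos, ctx) {
  K <- ctx$policy$max_checked_kmer_len
  right <- pos + seq_len(K - 1L)
  right <- right[right <= length(codes)]
  fast <- ctx$single_chain && (length(right) == 0L || !any(!is.na(codes[right])))
  if (fast) {
    suffix_verdict(codes, pos, ctx$index, ctx$model, ctx$genotype,
                   ctx$policy, ctx$cache)
  } else {
    generic_verdict(codes, pos, ctx$index, ctx$model, ctx$genotype,
                    ctx$policy, ctx$chain)
  }
}

# ---- lookahead -------------------------------------------------------------

#' Estimated future log-probability of a candidate extension
#'
#' Starting from the candidate's own log-probability, greedily extends for
#' up to `config$depth` further positions using only permissible residues,
#' adding the log-probability of the most probable permissible residue at
#' each step. If the immediate extension introduced hidden non-self k-mers
#' the full `depth * log(non_self_prob_factor)` penalty is added; each
#' lookahead step that itself introduces hidden k-mers adds one further
#' `log(non_self_prob_factor)`. A dead-ended lookahead is truncated,
#' charging `config$lookahead_floor` per missing step.
#'
#' @param codes Integer residue codes with the candidate already placed at
#'   `pos` (internal representation; see [decode_design()] for the
#'   user-facing entry point).
#' @param pos Position of the candidate extension.
#' @param own_logprob The candidate's own log-probability.
#' @param own_hidden Number of hidden non-self k-mers the candidate's own
#'   windows introduced.
#' @param model A `seq_model`.
#' @param config A [decode_config()].
#' @param ctx Internal decode context (index, presentation model, genotype,
#'   policy, cache).
#' @return The penalized lookahead estimate (a log-probability scale
#'   score).
#' @keywords internal
future_logprob <- function(codes, pos, own_logprob, own_hidden, model,
                           config, ctx) {
  factor_log <- log(config$policy$non_self_prob_factor)
  est <- own_logprob
  if (config$penalize_immediate && own_hidden > 0L) {
    est <- est + config$depth * factor_log
  }
  steps <- min(config$depth, length(codes) - pos)
  if (steps <= 0L) return(est)
  cur <- codes
  p <- pos
  for (t in seq_len(steps)) {
    p <- p + 1L
    while (p <= length(cur) && !is.na(cur[p])) p <- p + 1L  # skip pre-filled
    if (p > length(cur)) break
    lg <- model$logits(cur, p)
    v <- candidate_verdict(cur, p, ctx)
    ok <- which(v$permissible)
    if (length(ok) == 0L) {
      est <- est + (steps - t + 1L) * config$lookahead_floor
      break
    }
    j <- ok[which.max(lg[ok])]
    est <- est + lg[j]
    if (config$penalize_lookahead && v$hidden[j] > 0L) {
      est <- est + factor_log
    }
    cur[p] <- j - 1L
  }
  est
}

# ---- beam step -------------------------------------------------------------

new_beam <- function(L, codes = rep(NA_integer_, L)) {
  list(codes = codes, cum_logprob = 0, hidden_kmer_count = 0L,
       fallback_positions = integer(0),
       pos_logprob = rep(NA_real_, L))
}

beam_tail_key <- function(beam, pos, len) {
  filled <- which(!is.na(beam$codes[seq_len(pos)]))
  tail_idx <- utils::tail(filled, len)
  paste(beam$codes[tail_idx], collapse = ",")
}

beam_seq_string <- function(beam) {
  paste(TOKENS[beam$codes[!is.na(beam$codes)] + 1L], collapse = "")
}

#' One beam-search step
#'
#' Enumerates permissible candidate extensions of every beam at `pos`,
#' ranks them all by estimated future log-probability, keeps the top
#' `width`, then collapses beams sharing their last `dedupe_suffix_len`
#' residues to the one with the highest cumulative log-probability. If no
#' candidate of any beam is permissible, every beam is extended with its
#' top-`width` residues by raw log-probability and the position is flagged
#' as a fallback.
#'
#' @param beams Non-empty list of beams (identically filled positions).
#' @param pos Position to fill.
#' @param model A `seq_model`.
#' @param config A [decode_config()].
#' @param ctx Internal decode context.
#' @return List of beams (at most `width`).
#' @keywords internal
decode_step <- function(beams, pos, model, config, ctx) {
  if (length(beams) == 0L) stop("empty beam list")
  n_cand <- 0L
  cand_beam <- integer(0); cand_res <- integer(0)
  cand_own <- numeric(0); cand_hidden <- integer(0); cand_future <- numeric(0)
  logits_by_beam <- vector("list", length(beams))
  for (b in seq_along(beams)) {
    lg <- model$logits(beams[[b]]$codes, pos)
    logits_by_beam[[b]] <- lg
    v <- candidate_verdict(beams[[b]]$codes, pos, ctx)
    for (c0 in which(v$permissible) - 1L) {
      codes2 <- beams[[b]]$codes
      codes2[pos] <- c0
      fut <- future_logprob(codes2, pos, lg[c0 + 1L], v$hidden[c0 + 1L],
                            model, config, ctx)
      n_cand <- n_cand + 1L
      cand_beam[n_cand] <- b; cand_res[n_cand] <- c0
      cand_own[n_cand] <- lg[c0 + 1L]
      cand_hidden[n_cand] <- v$hidden[c0 + 1L]
      cand_future[n_cand] <- fut
    }
  }

  if (n_cand == 0L) {
    # fallback: unconstrained top-width extensions per beam, flagged
    out <- list()
    for (b in seq_along(beams)) {
      lg <- logits_by_beam[[b]]
      top <- order(-lg, seq_along(lg))[seq_len(min(config$width, 21L))]
      for (tok in top) {
        nb <- beams[[b]]
        nb$codes[pos] <- tok - 1L
        nb$cum_logprob <- nb$cum_logprob + lg[tok]
        nb$pos_logprob[pos] <- lg[tok]
        nb$fallback_positions <- c(nb$fallback_positions, pos)
        out[[length(out) + 1L]] <- nb
      }
    }
    cums <- vapply(out, `[[`, numeric(1), "cum_logprob")
    out <- out[order(-cums)][seq_len(min(config$width, length(out)))]
  } else {
    ord <- order(-cand_future, cand_beam, cand_res)
    keep <- ord[seq_len(min(config$width, n_cand))]
    out <- lapply(keep, function(i) {
      nb <- beams[[cand_beam[i]]]
      nb$codes[pos] <- cand_res[i]
      nb$cum_logprob <- nb$cum_logprob + cand_own[i]
      nb$pos_logprob[pos] <- cand_own[i]
      nb$hidden_kmer_count <- nb$hidden_kmer_count + cand_hidden[i]
      nb
    })
  }

  # collapse beams sharing the same trailing residues
  keys <- vapply(out, beam_tail_key, character(1), pos = pos,
                 len = config$dedupe_suffix_len)
  best <- list()
  for (i in seq_along(out)) {
    k <- keys[i]
    cur <- best[[k]]
    if (is.null(cur)) { best[[k]] <- out[[i]]; next }
    if (out[[i]]$cum_logprob > cur$cum_logprob ||
        (out[[i]]$cum_logprob == cur$cum_logprob &&
         beam_seq_string(out[[i]]) < beam_seq_string(cur))) {
      best[[k]] <- out[[i]]
    }
  }
  unname(best[unique(keys)])
}

# ---- decode ----------------------------------------------------------------

#' Design a sequence by constrained beam search
#'
#' Pre-samples any unresolved positions (seeded, unconstrained,
#' temperature-1 sampling from the model, in increasing order), then fills
#' the remaining positions in increasing order with [decode_step()]. The
#' returned design is the completed beam with the highest cumulative
#' log-probability (ties broken lexicographically by sequence).
#'
#' @param model A `seq_model` (e.g. [toy_sequence_model()]), or any list
#'   providing `logits(assignment_codes, position)` over the 21 tokens.
#' @param length Sequence length; defaults to `model$length`.
#' @param config A [decode_config()].
#' @param index A [build_kmer_index()] with
#'   `max_len >= policy$max_checked_kmer_len`.
#' @param pres_model A [presentation_model()] or `NULL` (never-presenting).
#' @param genotype A [genotype()]; required when `pres_model` is given.
#' @param unresolved Integer positions to pre-sample unconstrained (e.g.
#'   template positions with missing coordinates).
#' @param chain Optional integer chain ids (k-mer windows never span
#'   chains).
#' @return A list with `sequence`, `beam` (codes, cumulative log-prob,
#'   hidden k-mer count, fallback positions, per-position log-probs) and
#'   `report` (scalar summary).
#' @export
decode_design <- function(model, length = NULL, config = decode_config(),
                          index, pres_model = NULL, genotype = NULL,
                          unresolved = integer(0), chain = NULL) {
  L <- if (is.null(length)) model$length else as.integer(length)
  stopifnot(L >= 1)
  if (index$max_len < config$policy$max_checked_kmer_len) {
    stop("index max_len (", index$max_len, ") < max_checked_kmer_len (",
         config$policy$max_checked_kmer_len, ")")
  }
  if (is.null(chain)) chain <- rep(1L, L)
  ctx <- list(index = index, model = pres_model, genotype = genotype,
              policy = config$policy, chain = chain,
              single_chain = length(unique(chain)) == 1L,
              cache = new.env(parent = emptyenv()))

  start <- new_beam(L)
  if (length(unresolved) > 0L) {
    unresolved <- sort(unique(as.integer(unresolved)))
    withr::with_seed(config$seed, {
      for (p in unresolved) {
        pr <- exp(model$logits(start$codes, p))
        tok <- sample.int(21L, 1L, prob = pr)
        start$codes[p] <- tok - 1L
        start$cum_logprob <- start$cum_logprob + log(pr[tok])
        start$pos_logprob[p] <- log(pr[tok])
      }
    })
  }

  beams <- list(start)
  for (pos in setdiff(seq_len(L), unresolved)) {
    beams <- decode_step(beams, pos, model, config, ctx)
  }
  cums <- vapply(beams, `[[`, numeric(1), "cum_logprob")
  seqs <- vapply(beams, beam_seq_string, character(1))
  winner <- beams[[order(-cums, seqs)[1L]]]
  list(sequence = beam_seq_string(winner),
       beam = winner,
       report = list(cum_logprob = winner$cum_logprob,
                     hidden_kmer_count = winner$hidden_kmer_count,
                     n_fallback = length(winner$fallback_positions),
                     fallback_positions = winner$fallback_positions,
                     pos_logprob = winner$pos_logprob))
}

#' Unconstrained baseline sampling
#'
#' Standard autoregressive sampling with logits scaled by
#' `1 / temperature`; the comparison baseline for constrained designs.
#' Temperatures below `1e-6` switch to greedy argmax.
#'
#' @param model A `seq_model`.
#' @param length Sequence length; defaults to `model$length`.
#' @param temperature Positive sampling temperature (0.1 is the
#'   conventional baseline setting).
#' @param seed Integer seed; same seed, same sequence.
#' @return The sampled sequence (string over the 21 tokens).
#' @export
baseline_sample <- function(model, length = NULL, temperature = 0.1,
                            seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  L <- if (is.null(length)) model$length else as.integer(length)
  codes <- rep(NA_integer_, L)
  withr::with_seed(seed, {
    for (p in seq_len(L)) {
      lg <- model$logits(codes, p)
      if (temperature < 1e-6) {
        tok <- which.max(lg)
      } else {
        w <- exp((lg - max(lg)) / temperature)
        tok <- sample.int(21L, 1L, prob = w / sum(w))
      }
      codes[p] <- tok - 1L
    }
  })
  paste(TOKENS[codes + 1L], collapse = "")
}

#' Enumerate all permissible sequences (brute force)
#'
#' Exhaustively enumerates sequences of the given length over a restricted
#' alphabet, keeps those whose every window (lengths 1..max checked) is
#' permissible (no `FORBIDDEN` class), and computes each one's exact model
#' log-probability from the model's exposed probability table. Intended as
#' an independent check of the beam search on tiny instances.
#'
#' @param model A `seq_model` exposing `prob_table`.
#' @param length Sequence length (keep `alphabet^length` small).
#' @param index,pres_model,genotype,policy See [classify_kmer()].
#' @param alphabet Restricted alphabet to enumerate over.
#' @return A data.frame of permissible sequences with columns `sequence`,
#'   `logprob`, sorted by decreasing `logprob` then sequence.
#' @export
enumerate_permissible_sequences <- function(model, length, index,
                                            pres_model = NULL,
                                            genotype = NULL,
                                            policy = permissibility_policy(),
                                            alphabet = model$alphabet) {
  L <- as.integer(length)
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), L),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  seqs <- do.call(paste0, grid)
  maxk <- min(policy$max_checked_kmer_len, L)
  ok <- rep(TRUE, length(seqs))
  for (k in seq_len(maxk)) {
    for (s in seq_len(L - k + 1L)) {
      kmers <- substr(seqs, s, s + k - 1L)
      cls <- classify_kmer(unique(kmers), index, pres_model, genotype, policy)
      bad <- unique(kmers)[cls == KMER_FORBIDDEN]
      if (length(bad)) ok <- ok & !(kmers %in% bad)
    }
  }
  seqs <- seqs[ok]
  lp <- vapply(seqs, function(s) {
    cv <- aa_codes(s)
    tot <- 0
    for (p in seq_len(L)) {
      prev <- if (p > 1L) cv[p - 1L] else NA_integer_
      tot <- tot + log(model$prob_table(p, prev)[cv[p] + 1L])
    }
    tot
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(sequence = seqs, logprob = lp)
  out[order(-out$logprob, out$sequence), , drop = FALSE]
}
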