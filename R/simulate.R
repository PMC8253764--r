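#' Sample a sequence from an HMM
#'
#' Ancestral sampling: draw the initial state, then alternate emission and
#' transition draws. Reproducible given the seed.
#'
#' @param m an [action_hmm()] or `hmm_fit`.
#' @param length number of symbols (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param sequence_id,category metadata for the result.
#' @return A [symbol_sequence()].
#' @export
sample_from_hmm <- function(m, length, seed = NULL, sequence_id = "sim",
                            category = "") {
  if (inherits(m, "hmm_fit")) m <- m$model
  stopifnot(inherits(m, "action_hmm"), length >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- m$n_states
  states <- integer(length)
  states[1L] <- sample.int(S, 1L, prob = m$initial)
  if (length > 1L) for (t in 2:length)
    states[t] <- sample.int(S, 1L, prob = m$transition[states[t - 1L], ])
  sym <- vapply(states, function(st)
    sample(m$alphabet, 1L, prob = m$emission[st, ]), "")
  symbol_sequence(sym, sequence_id = sequence_id, category = category)
}

#' @export
simulate.action_hmm <- function(object, nsim = 1, seed = NULL, length = 100,
                                category = "", ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    sample_from_hmm(object, length, seed = NULL,
                    sequence_id = sprintf("sim%d", i), category = category))
}

# A platform-preparation insert: alternating target changes / inversions,
# each followed by a long run (>= 5) of repeated light percussion, coded P.
prep_insert <- function() {
  out <- character(0)
  for (i in seq_len(sample(2:3, 1L))) {
    marker <- if (i %% 2L == 1L) "T" else "I"
    out <- c(out, marker, rep("P", sample(6:12, 1L)))
  }
  out
}

# One flake-removal chunk: a short context of core/tool handling events
# (mostly target changes, stereotyped), optionally a platform-preparation
# insert, one or two percussion strikes, then a flake detachment
# (state-cycle analog: context -> percussion -> flake). Complex sequences
# start with a roughing-out stage: preparation is rare in the first 35% of
# the sequence and concentrates in the later shaping stage, so their early
# text is plain flaking like the simple technology's.
build_sequence <- function(target_len, prep_prob) {
  ctx_codes <- c("T", "G", "H")
  ctx_prob <- c(0.4, 0.3, 0.3)
  sym <- character(0)
  while (length(sym) < target_len) {
    nctx <- if (stats::runif(1) < 0.5) 1L else 2L
    chunk <- sample(ctx_codes, nctx, replace = TRUE, prob = ctx_prob)
    frac <- length(sym) / target_len
    p_eff <- prep_prob * if (frac < 0.45) 0.1 else 1.6
    if (p_eff > 0 && stats::runif(1) < min(p_eff, 1))
      chunk <- c(chunk, prep_insert())
    chunk <- c(chunk, rep("P", sample(1:2, 1L)), "F")
    sym <- c(sym, chunk)
  }
  sym
}

#' Synthetic tool-making corpora
#'
#' Generators that emulate the statistical structure the analysis pipeline
#' assumes, so every stage is testable without external data.
#'
#' `generate_oldowan_like()` builds sequences from repeated flake-removal
#' chunks — a short context of target changes and grip shifts, a percussion
#' run of length 1-2, then a flake detachment — with no long percussion runs
#' (no run ever exceeds 3).
#'
#' `generate_acheulean_like()` uses the same chunks, but with probability
#' `prep_prob` a chunk embeds a platform-preparation insert (alternating
#' target change / inversion markers, each followed by a run of 5-10
#' repeated percussions) before the flake detachment. These long runs add a
#' superordinate level of structure: higher selected HMM order, two
#' oscillating states-of-states, and stronger grammar compression.
#'
#' @param n number of sequences.
#' @param seed integer seed; generation is seed-deterministic.
#' @param lengths `c(min, max)` target symbol counts (uniform-integer);
#'   sequences end at the first chunk boundary past the target. Defaults
#'   80-300 (simple) and 200-800 (complex), reflecting the longer shaping
#'   process of the complex technology.
#' @param prep_prob probability a chunk embeds platform preparation; 0 makes
#'   the complex generator statistically identical to the simple one.
#' @param category category label stored on the sequences.
#' @return List of [symbol_sequence()] objects over the default 7-code
#'   alphabet.
#' @export
generate_oldowan_like <- function(n = 9, seed = 1, lengths = c(80, 300),
                                  category = "Oldowan") {
  stopifnot(n >= 1, lengths[1] <= lengths[2])
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    target <- sample(lengths[1]:lengths[2], 1L)
    symbol_sequence(build_sequence(target, prep_prob = 0),
                    sequence_id = sprintf("%s%02d", tolower(category), i),
                    category = category, alphabet = default_alphabet())
  })
}

#' @rdname generate_oldowan_like
#' @export
generate_acheulean_like <- function(n = 8, seed = 1, prep_prob = 0.5,
                                    lengths = c(200, 800),
                                    category = "Acheulean") {
  stopifnot(n >= 1, prep_prob >= 0, prep_prob <= 1,
            lengths[1] <= lengths[2])
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    target <- sample(lengths[1]:lengths[2], 1L)
    symbol_sequence(build_sequence(target, prep_prob = prep_prob),
                    sequence_id = sprintf("%s%02d", tolower(category), i),
                    category = category, alphabet = default_alphabet())
  })
}
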