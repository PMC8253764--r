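# Shared fixtures and brute-force oracles.

# The worked-example sentence (28 word tokens).
little_cat_tokens <- function() {
  strsplit(paste(
    "the little cat chases the mouse",
    "the little cat catches the mouse",
    "the big cat chases the little cat",
    "the little cat runs away from the big cat"), " ")[[1]]
}

# A well-separated planted 3-state model over the default 7-code alphabet:
# cyclic transitions, near-disjoint emissions.
planted_hmm3 <- function() {
  ab <- default_alphabet()$code
  A <- matrix(c(.1, .8, .1,
                .1, .1, .8,
                .8, .1, .1), 3, 3, byrow = TRUE)
  B <- rbind(c(.45, .45, .025, .025, .025, .0125, .0125),
             c(.02, .02, .45, .45, .02, .02, .02),
             c(.01, .01, .01, .01, .32, .32, .32))
  action_hmm(c(1, 0, 0), A, B, ab)
}

# A random valid HMM, reproducible given the seed.
rand_hmm <- function(S, M, seed) {
  set.seed(seed)
  rdir <- function(n) { g <- stats::rgamma(n, 1) + 1e-3; g / sum(g) }
  A <- t(vapply(seq_len(S), function(i) rdir(S), numeric(S)))
  B <- t(vapply(seq_len(S), function(i) rdir(M), numeric(M)))
  action_hmm(rdir(S), A, B, letters[seq_len(M)])
}

# Exhaustive-path forward probability and Viterbi maximum; obs is 1-based.
all_paths <- function(S, n) {
  as.matrix(expand.grid(rep(list(seq_len(S)), n)))
}

brute_path_prob <- function(m, obs, st) {
  p <- m$initial[st[1]] * m$emission[st[1], obs[1]]
  if (length(obs) > 1)
    for (t in 2:length(obs))
      p <- p * m$transition[st[t - 1], st[t]] * m$emission[st[t], obs[t]]
  p
}

brute_forward <- function(m, obs) {
  paths <- all_paths(m$n_states, length(obs))
  log(sum(apply(paths, 1, function(st) brute_path_prob(m, obs, st))))
}

brute_viterbi <- function(m, obs) {
  paths <- all_paths(m$n_states, length(obs))
  pr <- apply(paths, 1, function(st) brute_path_prob(m, obs, st))
  top <- which(pr == max(pr))
  list(logprob = log(max(pr)),
       paths = lapply(top, function(i) unname(paths[i, ])))
}

# A state_path without running viterbi (for SoS edge cases).
fake_path <- function(states, id = "p", category = "") {
  structure(list(sequence_id = id, category = category,
                 states = as.integer(states),
                 n_states = max(states), logprob = 0),
            class = "state_path")
}

max_run_of <- function(s, code) {
  r <- rle(s$symbols)
  hits <- r$lengths[r$values == code]
  if (length(hits)) max(hits) else 0L
}
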