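#' Multinomial hidden Markov models
#'
#' An `action_hmm` is a discrete-emission HMM over an event alphabet:
#' an initial state distribution, a row-stochastic transition matrix and a
#' row-stochastic emission matrix whose columns follow the alphabet order.
#'
#' @param initial probability vector of length S.
#' @param transition S x S row-stochastic matrix.
#' @param emission S x M row-stochastic matrix, columns in alphabet order.
#' @param alphabet character vector of M tokens, or an [event_alphabet()].
#' @return An object of class `action_hmm`.
#' @export
action_hmm <- function(initial, transition, emission, alphabet) {
  if (inherits(alphabet, "event_alphabet")) alphabet <- alphabet$code
  alphabet <- as.character(alphabet)
  S <- length(initial)
  transition <- as.matrix(transition); emission <- as.matrix(emission)
  stopifnot(S >= 1, nrow(transition) == S, ncol(transition) == S,
            nrow(emission) == S, ncol(emission) == length(alphabet))
  check_stochastic <- function(x, what) {
    if (any(x < 0)) stop(what, " has negative entries")
    rs <- if (is.matrix(x)) rowSums(x) else sum(x)
    if (any(abs(rs - 1) > 1e-9)) stop(what, " rows must sum to 1")
  }
  check_stochastic(initial, "initial distribution")
  check_stochastic(transition, "transition matrix")
  check_stochastic(emission, "emission matrix")
  dimnames(transition) <- list(NULL, NULL)
  dimnames(emission) <- list(NULL, alphabet)
  structure(list(n_states = S, alphabet = alphabet,
                 initial = as.numeric(initial), transition = transition,
                 emission = emission),
            class = "action_hmm")
}

#' @export
print.action_hmm <- function(x, digits = 3, ...) {
  cat(sprintf("<action_hmm: %d states over alphabet [%s]>\n", x$n_states,
              paste(x$alphabet, collapse = " ")))
  cat("initial:\n"); print(round(x$initial, digits))
  cat("transition:\n"); print(round(x$transition, digits))
  cat("emission:\n"); print(round(x$emission, digits))
  invisible(x)
}

# Encode sequences as 0-based integer vectors in the model/alphabet order.
encode_corpus <- function(sequences, tokens) {
  lapply(sequences, function(s) {
    idx <- match(s$symbols, tokens)
    if (anyNA(idx)) {
      bad <- s$symbols[which(is.na(idx))[1L]]
      stop(sprintf("sequence '%s': symbol '%s' not in model alphabet",
                   s$sequence_id, bad))
    }
    idx - 1L
  })
}

# Number of free parameters of an S-state, M-symbol multinomial HMM,
# counting the initial distribution.
hmm_free_params <- function(S, M) {
  S <- as.integer(S); M <- as.integer(M)
  S * (S - 1L) + S * (M - 1L) + (S - 1L)
}

rdirichlet1 <- function(n) { g <- stats::rgamma(n, 1); g / sum(g) }

#' Fit a multinomial HMM by multi-restart Baum-Welch EM
#'
#' EM statistics are summed across all training sequences. Because EM is very
#' sensitive to its initial estimates, the fit is restarted `n_restarts`
#' times from random symmetric-Dirichlet(1) initial conditions (one master
#' seed spawns the per-restart seeds) and the restart with the highest total
#' log-likelihood is returned. Each restart stops when the log-likelihood
#' improves by less than `tol` or after `max_iter` iterations; the
#' per-iteration log-likelihood trace is checked to be non-decreasing.
#'
#' @param sequences a list of [symbol_sequence()] objects sharing an alphabet.
#' @param n_states number of hidden states S (>= 1).
#' @param n_restarts number of random restarts. The study protocol uses 1000;
#'   100 is a practical default for well-separated data.
#' @param seed integer master seed; the fit is reproducible given it.
#' @param alphabet alphabet tokens or [event_alphabet()]; defaults to the
#'   sorted set of symbols observed in the corpus.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `hmm_fit` with elements `model`
#'   ([action_hmm()]), `loglik`, `n_restarts`, `n_free_params`, `converged`,
#'   `seed`, `n_obs`.
#' @export
fit_hmm <- function(sequences, n_states, n_restarts = 100, seed = 1,
                    alphabet = NULL, max_iter = 500, tol = 1e-6) {
  sequences <- as_corpus(sequences)
  if (is.null(alphabet)) {
    tokens <- sort(unique(unlist(lapply(sequences, `[[`, "symbols"))))
  } else if (inherits(alphabet, "event_alphabet")) tokens <- alphabet$code
  else tokens <- as.character(alphabet)
  obs <- encode_corpus(sequences, tokens)
  n_obs <- sum(lengths(obs))
  S <- as.integer(n_states); M <- length(tokens)
  if (S < 1) stop("n_states must be >= 1")
  if (S > n_obs) stop("n_states exceeds the total number of symbols")

  set.seed(seed)
  restart_seeds <- sample.int(2147483646L, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    pi0 <- rdirichlet1(S)
    A0 <- matrix(t(vapply(seq_len(S), function(i) rdirichlet1(S),
                          numeric(S))), S, S)
    B0 <- matrix(t(vapply(seq_len(S), function(i) rdirichlet1(M),
                          numeric(M))), S, M, byrow = (S == 1L || M == 1L))
    if (S == 1) { A0 <- matrix(1, 1, 1); pi0 <- 1 }
    if (M == 1) B0 <- matrix(1, S, 1)
    res <- cpp_baum_welch(obs, pi0, A0, B0, as.integer(max_iter), tol)
    tr <- res$trace
    if (length(tr) > 1 && any(diff(tr) < -1e-6 * (1 + abs(tr[-1]))))
      stop("internal error: EM log-likelihood decreased")
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$restart_seed <- restart_seeds[r]
    }
  }
  model <- action_hmm(best$pi, best$A, best$B, tokens)
  structure(list(model = model, loglik = best$loglik,
                 n_restarts = n_restarts,
                 n_free_params = hmm_free_params(S, M),
                 converged = isTRUE(best$converged), seed = seed,
                 n_obs = n_obs, n_sequences = length(sequences)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<hmm_fit: S=%d, logLik=%.3f, p=%d, n_obs=%d, %d restarts%s>\n",
    x$model$n_states, x$loglik, x$n_free_params, x$n_obs, x$n_restarts,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, nobs = object$n_obs,
            class = "logLik")
}

#' Information criteria for a fitted HMM
#'
#' BIC = -2 logL + p log(n_obs); AIC = -2 logL + 2 p, with p the number of
#' free parameters and n_obs the total number of emitted symbols.
#'
#' @param fit an `hmm_fit`.
#' @param n_obs number of observations; defaults to the total symbol count
#'   of the training corpus.
#' @return Named numeric vector `c(BIC=, AIC=)`.
#' @export
information_criteria <- function(fit, n_obs = fit$n_obs) {
  stopifnot(n_obs >= 1)
  p <- fit$n_free_params
  c(BIC = -2 * fit$loglik + p * log(n_obs),
    AIC = -2 * fit$loglik + 2 * p)
}

#' Scan HMM model orders and select one by BIC
#'
#' Fits an HMM for every candidate number of hidden states and selects the
#' order minimizing BIC (ties broken toward the smaller model).
#'
#' @inheritParams fit_hmm
#' @param states integer vector of candidate state counts (contiguous range).
#' @return An object of class `hmm_scan`: a data frame of per-order fit
#'   metrics in `$rows`, the fitted models in `$fits`, and the selected
#'   order in `$optimal_states`.
#' @export
scan_states <- function(sequences, states = 1:12, n_restarts = 100, seed = 1,
                        alphabet = NULL, max_iter = 500, tol = 1e-6) {
  states <- sort(unique(as.integer(states)))
  if (!length(states)) stop("empty state range")
  set.seed(seed)
  seeds <- sample.int(2147483646L, length(states))
  fits <- vector("list", length(states))
  rows <- data.frame(S = states, loglik = NA_real_, p = NA_integer_,
                     BIC = NA_real_, AIC = NA_real_, converged = NA)
  for (i in seq_along(states)) {
    f <- fit_hmm(sequences, states[i], n_restarts = n_restarts,
                 seed = seeds[i], alphabet = alphabet,
                 max_iter = max_iter, tol = tol)
    ic <- information_criteria(f)
    fits[[i]] <- f
    rows$loglik[i] <- f$loglik; rows$p[i] <- f$n_free_params
    rows$BIC[i] <- ic["BIC"]; rows$AIC[i] <- ic["AIC"]
    rows$converged[i] <- f$converged
  }
  structure(list(rows = rows, fits = stats::setNames(fits, states),
                 optimal_states = states[which.min(rows$BIC)]),
            class = "hmm_scan")
}

#' @export
print.hmm_scan <- function(x, ...) {
  cat(sprintf("<hmm_scan: S in [%d, %d]; BIC minimum at S = %d>\n",
              min(x$rows$S), max(x$rows$S), x$optimal_states))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' @export
plot.hmm_scan <- function(x, ...) {
  plot(x$rows$S, x$rows$BIC, type = "b", pch = 19,
       xlab = "Number of hidden states", ylab = "BIC (less is better)", ...)
  graphics::abline(v = x$optimal_states, lty = 2)
  invisible(x)
}

# Emission floor applied before decoding so finite log-space arithmetic
# survives unseen symbols; errors only if a symbol has zero mass everywhere.
decode_matrices <- function(m, obs, sequence_id = "") {
  B <- m$emission
  for (o in unique(unlist(obs))) {
    if (max(B[, o + 1L]) == 0)
      stop(sprintf(
        "sequence '%s': symbol '%s' has zero emission mass in every state",
        sequence_id, m$alphabet[o + 1L]))
  }
  B[B < 1e-10] <- 1e-10
  B
}

#' Forward-algorithm log-likelihood of a sequence under a model
#'
#' Computed in scaled space so sequences of length 1000+ do not underflow.
#'
#' @param m an [action_hmm()] (or an `hmm_fit`, whose model is used).
#' @param s a [symbol_sequence()] over the model alphabet.
#' @return Log-likelihood (a single number, <= 0).
#' @export
sequence_loglik <- function(m, s) {
  if (inherits(m, "hmm_fit")) m <- m$model
  stopifnot(inherits(m, "action_hmm"), inherits(s, "symbol_sequence"))
  obs <- encode_corpus(list(s), m$alphabet)
  B <- decode_matrices(m, obs, s$sequence_id)
  cpp_loglik(obs, m$initial, m$transition, B)[1L]
}

#' Classify a sequence by cross-model likelihood
#'
#' Evaluates the sequence under each labeled model and returns the label of
#' the highest log-likelihood. An exact tie is flagged, never silently
#' broken.
#'
#' @param models named list of [action_hmm()] (or `hmm_fit`) objects sharing
#'   an alphabet; at least two.
#' @param s a [symbol_sequence()].
#' @return A list with `label` (NA on tie), `tie` flag and the named
#'   `loglik` vector.
#' @export
classify <- function(models, s) {
  if (length(models) < 2 || is.null(names(models)))
    stop("classify needs at least two named models")
  ll <- vapply(models, function(m) sequence_loglik(m, s), 0)
  top <- which(ll == max(ll))
  if (length(top) > 1L)
    list(label = NA_character_, tie = TRUE, loglik = ll)
  else
    list(label = names(models)[top], tie = FALSE, loglik = ll)
}

#' Viterbi decoding
#'
#' Most probable hidden-state path in log space. Ties are broken toward the
#' lower state index at every backtrack step, so a fully uniform model
#' decodes to the constant lowest state.
#'
#' @inheritParams sequence_loglik
#' @return A `state_path`: `sequence_id`, `category`, integer `states` in
#'   1..S (same length as the symbols) and the path log-probability.
#' @export
viterbi <- function(m, s) {
  if (inherits(m, "hmm_fit")) m <- m$model
  stopifnot(inherits(m, "action_hmm"), inherits(s, "symbol_sequence"))
  obs <- encode_corpus(list(s), m$alphabet)
  B <- decode_matrices(m, obs, s$sequence_id)
  res <- cpp_viterbi(obs[[1L]], m$initial, m$transition, B)
  if (!is.finite(res$logprob))
    stop(sprintf("sequence '%s' has probability zero (first impossible position %d)",
                 s$sequence_id, res$first_impossible))
  structure(list(sequence_id = s$sequence_id, category = s$category,
                 states = res$path + 1L, n_states = m$n_states,
                 logprob = res$logprob),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path %s [%s], %d positions, logP=%.3f>\n",
              x$sequence_id, x$category, length(x$states), x$logprob))
  invisible(x)
}

#' Superordinate states-of-states (SoS)
#'
#' Treats decoded hidden-state paths as symbol sequences over the state
#' alphabet and fits a second, 2-state HMM to them (same multi-restart
#' protocol), then decodes each path again. The result is a superordinate
#' segmentation: categories whose behavior oscillates between two regimes
#' (e.g. flaking vs platform preparation) occupy both SoS states, simpler
#' categories remain in one. Paths should be decoded under one shared model;
#' the study protocol decodes both categories under the more complex
#' category's selected model.
#'
#' @param paths list of `state_path` objects from [viterbi()].
#' @param n_restarts,seed,max_iter,tol passed to [fit_hmm()].
#' @return An object of class `sos_result`: `sos_fit` (the 2-state
#'   `hmm_fit`), `sos_paths` (decoded SoS `state_path` per input path),
#'   `occupancy` (category x SoS-state fractions, rows sum to 1), and a
#'   `degenerate` flag set when the input paths carry a single distinct
#'   state.
#' @export
fit_sos <- function(paths, n_restarts = 100, seed = 1, max_iter = 500,
                    tol = 1e-6) {
  stopifnot(length(paths) >= 1,
            all(vapply(paths, inherits, TRUE, "state_path")))
  S <- max(vapply(paths, function(p) max(p$states), 0L))
  tokens <- as.character(seq_len(S))
  seqs <- lapply(paths, function(p)
    symbol_sequence(as.character(p$states), p$sequence_id, p$category))
  degenerate <- length(unique(unlist(lapply(paths, `[[`, "states")))) < 2L
  fit <- fit_hmm(seqs, n_states = 2, n_restarts = n_restarts, seed = seed,
                 alphabet = tokens, max_iter = max_iter, tol = tol)
  sos_paths <- lapply(seqs, function(s) viterbi(fit$model, s))
  cats <- vapply(paths, `[[`, "", "category")
  occ <- t(vapply(unique(cats), function(cc) {
    st <- unlist(lapply(sos_paths[cats == cc], `[[`, "states"))
    tabulate(st, nbins = 2L) / length(st)
  }, numeric(2)))
  colnames(occ) <- c("SoS1", "SoS2")
  structure(list(sos_fit = fit, sos_model = fit$model, sos_paths = sos_paths,
                 occupancy = occ, degenerate = degenerate),
            class = "sos_result")
}

#' @export
print.sos_result <- function(x, ...) {
  cat("<sos_result: 2 superordinate states>\n")
  if (x$degenerate) cat("  (degenerate: constant input state paths)\n")
  cat("occupancy by category:\n")
  print(round(x$occupancy, 4))
  invisible(x)
}

#' Display summary of an HMM with small values suppressed
#'
#' Renders transition edges and emission entries, dropping those below
#' `display_floor` from the display only; the model itself is unchanged.
#'
#' @param m an [action_hmm()] or `hmm_fit`.
#' @param display_floor probability in [0, 1); entries below it are omitted.
#' @return An `hmm_summary`: data frames `transitions` (from, to, prob) and
#'   `emissions` (state, code, prob).
#' @export
summarize_model <- function(m, display_floor = 0.05) {
  if (inherits(m, "hmm_fit")) m <- m$model
  stopifnot(display_floor >= 0, display_floor < 1)
  S <- m$n_states
  tr <- expand.grid(from = seq_len(S), to = seq_len(S))
  tr$prob <- m$transition[cbind(tr$from, tr$to)]
  em <- expand.grid(state = seq_len(S), code = m$alphabet,
                    stringsAsFactors = FALSE)
  em$prob <- m$emission[cbind(em$state, match(em$code, m$alphabet))]
  structure(list(transitions = tr[tr$prob >= display_floor &
                                    tr$prob > 0, , drop = FALSE],
                 emissions = em[em$prob >= display_floor &
                                  em$prob > 0, , drop = FALSE],
                 display_floor = display_floor),
            class = "hmm_summary")
}

#' @export
print.hmm_summary <- function(x, ...) {
  cat(sprintf("<hmm_summary, entries < %.0f%% not displayed>\n",
              100 * x$display_floor))
  cat("transitions:\n"); print(x$transitions, row.names = FALSE)
  cat("emissions:\n"); print(x$emissions, row.names = FALSE)
  invisible(x)
}

#' @export
summary.action_hmm <- function(object, display_floor = 0.05, ...)
  summarize_model(object, display_floor)

#' @export
summary.hmm_fit <- function(object, display_floor = 0.05, ...)
  summarize_model(object$model, display_floor)

#' Corpus-level state occupancy
#'
#' Fraction of Viterbi-decoded positions assigned to each hidden state over
#' a corpus; fractions sum to 1.
#'
#' @param m an [action_hmm()] or `hmm_fit`.
#' @param sequences list of [symbol_sequence()] objects.
#' @return Named numeric vector of per-state fractions.
#' @export
state_occupancy <- function(m, sequences) {
  if (inherits(m, "hmm_fit")) m <- m$model
  sequences <- as_corpus(sequences)
  st <- unlist(lapply(sequences, function(s) viterbi(m, s)$states))
  stats::setNames(tabulate(st, nbins = m$n_states) / length(st),
                  paste0("state", seq_len(m$n_states)))
}

#' Running average of a states-of-states path
#'
#' Centered moving mean of the binary SoS indicator (1 when the path is in
#' the second superordinate state), with truncated windows at the edges.
#'
#' @param p a `state_path` over 2 states (or any path; the indicator is
#'   `states == 2`).
#' @param window odd window width >= 1 and <= path length. Default 9 events:
#'   wide enough to smooth single-event flips while preserving oscillation.
#' @return Numeric series of the same length as the path.
#' @export
running_sos_average <- function(p, window = 9) {
  stopifnot(inherits(p, "state_path"))
  n <- length(p$states)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > n) stop("window exceeds path length")
  ind <- as.numeric(p$states == 2L)
  half <- window %/% 2L
  cs <- c(0, cumsum(ind))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Match states of two emission matrices
#'
#' States of independently fitted HMMs are arbitrarily labeled; comparisons
#' must align them first. Finds the state permutation of `est` minimizing
#' the summed total-variation distance to `ref` (exhaustive for S <= 7,
#' greedy beyond).
#'
#' @param est,ref S x M emission matrices.
#' @return List with `perm` (est row i corresponds to ref row perm[i]...
#'   applied as `est[order(perm), ]` aligning to ref), `tv` per-row
#'   total-variation distances after matching.
#' @export
match_states <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  S <- nrow(est)
  tvmat <- outer(seq_len(S), seq_len(S),
                 Vectorize(function(i, j) 0.5 * sum(abs(est[i, ] - ref[j, ]))))
  if (S <= 7) {
    perms <- permutations_of(S)
    costs <- vapply(perms, function(p) sum(tvmat[cbind(seq_len(S), p)]), 0)
    best <- perms[[which.min(costs)]]
  } else {
    best <- integer(S); taken <- logical(S)
    for (i in order(apply(tvmat, 1, min))) {
      j <- order(tvmat[i, ])[!taken[order(tvmat[i, ])]][1L]
      best[i] <- j; taken[j] <- TRUE
    }
  }
  list(perm = best, tv = tvmat[cbind(seq_len(S), best)])
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

#' Read or write an HMM model file
#'
#' JSON with the alphabet, state count, initial vector and row-major
#' transition/emission matrices at full precision.
#'
#' @param m an [action_hmm()] or `hmm_fit`.
#' @param path file path.
#' @return `read_hmm()` returns an [action_hmm()].
#' @export
write_hmm <- function(m, path) {
  if (inherits(m, "hmm_fit")) m <- m$model
  obj <- list(alphabet = m$alphabet, n_states = m$n_states,
              initial = m$initial,
              transition = as.vector(t(m$transition)),
              emission = as.vector(t(m$emission)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- obj$n_states; M <- length(obj$alphabet)
  action_hmm(obj$initial,
             matrix(obj$transition, S, S, byrow = TRUE),
             matrix(obj$emission, S, M, byrow = TRUE),
             obj$alphabet)
}
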