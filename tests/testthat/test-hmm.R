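test_that("action_hmm validates stochasticity and shapes", {
  expect_error(action_hmm(c(0.5, 0.6), diag(2), matrix(0.5, 2, 2),
                          c("a", "b")), "sum to 1")
  expect_error(action_hmm(c(1.5, -0.5), diag(2), matrix(0.5, 2, 2),
                          c("a", "b")), "negative")
  m <- action_hmm(c(1, 0), diag(2), matrix(0.5, 2, 2), c("a", "b"))
  expect_identical(m$n_states, 2L)
  expect_identical(colnames(m$emission), c("a", "b"))
})

test_that("free parameter count matches the closed form", {
  # S(S-1) transitions + S(M-1) emissions + (S-1) initial
  expect_identical(actiongram:::hmm_free_params(4L, 7L), 39L)
  expect_identical(actiongram:::hmm_free_params(1L, 7L), 6L)
  expect_identical(actiongram:::hmm_free_params(6L, 7L), 71L)
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  for (S in 1:3) {
    m <- rand_hmm(S, 3, seed = 100 + S)
    for (n in c(1L, 4L, 6L)) {
      set.seed(n * S)
      obs <- sample.int(3, n, replace = TRUE)
      s <- symbol_sequence(m$alphabet[obs])
      expect_equal(sequence_loglik(m, s), brute_forward(m, obs),
                   tolerance = 1e-10)
    }
  }
})

test_that("viterbi matches exhaustive maximization and breaks ties low", {
  for (S in 2:3) {
    m <- rand_hmm(S, 3, seed = 200 + S)
    set.seed(S)
    obs <- sample.int(3, 6, replace = TRUE)
    s <- symbol_sequence(m$alphabet[obs])
    got <- viterbi(m, s)
    ref <- brute_viterbi(m, obs)
    expect_equal(got$logprob, ref$logprob, tolerance = 1e-10)
    expect_true(any(vapply(ref$paths, identical, TRUE,
                           as.integer(got$states))))
  }
  # fully uniform model: every path ties; decode must pick state 1 throughout
  u <- action_hmm(c(.5, .5), matrix(.5, 2, 2), matrix(1 / 3, 2, 3),
                  c("a", "b", "c"))
  p <- viterbi(u, symbol_sequence(c("a", "c", "b", "b")))
  expect_identical(p$states, rep(1L, 4))
})

test_that("impossible symbols error; rare ones are floored, not fatal", {
  m <- action_hmm(c(1, 0), matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE),
                  rbind(c(1, 0, 0), c(0, 1, 0)), c("a", "b", "c"))
  expect_error(viterbi(m, symbol_sequence(c("a", "c"), "s9")),
               "zero emission mass in every state")
  # "b" after "a" is fine even though state 1 can't emit it
  expect_identical(viterbi(m, symbol_sequence(c("a", "b")))$states, c(1L, 2L))
})

test_that("a 1-state fit equals the multinomial closed form", {
  s <- symbol_sequence(c("a", "a", "b", "c", "a", "b"))
  f <- fit_hmm(list(s), 1, n_restarts = 3, seed = 1)
  freq <- table(s$symbols) / length(s$symbols)
  expect_equal(f$loglik, sum(table(s$symbols) * log(freq)), tolerance = 1e-8)
  expect_equal(as.numeric(f$model$emission), as.numeric(freq),
               tolerance = 1e-6)
})

test_that("fit_hmm is seed-deterministic and validates inputs", {
  set.seed(42)
  corpus <- lapply(1:3, function(i) sample_from_hmm(planted_hmm3(), 40,
                                                    seed = 400 + i))
  f1 <- fit_hmm(corpus, 2, n_restarts = 5, seed = 7, max_iter = 50,
                tol = 1e-4)
  f2 <- fit_hmm(corpus, 2, n_restarts = 5, seed = 7, max_iter = 50,
                tol = 1e-4)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$model$emission, f2$model$emission)
  expect_identical(f1$n_obs, 120L)
  expect_error(fit_hmm(corpus, 0), "n_states")
  expect_error(fit_hmm(corpus, 1000), "exceeds")
  expect_error(fit_hmm(list(), 1), "empty corpus")
})

test_that("information criteria follow their closed forms", {
  s <- symbol_sequence(rep(c("a", "b"), 10))
  f <- fit_hmm(list(s), 2, n_restarts = 10, seed = 3, max_iter = 100,
               tol = 1e-6)
  ic <- information_criteria(f)
  p <- f$n_free_params
  expect_equal(unname(ic["BIC"]), -2 * f$loglik + p * log(20))
  expect_equal(unname(ic["AIC"]), -2 * f$loglik + 2 * p)
  ll <- logLik(f)
  expect_equal(as.numeric(ll), f$loglik)
  expect_identical(attr(ll, "df"), p)
  expect_identical(attr(ll, "nobs"), f$n_obs)
  expect_error(information_criteria(f, n_obs = 0), "n_obs")
})

test_that("scan_states selects the BIC minimum with ties toward fewer states", {
  set.seed(9)
  corpus <- lapply(1:4, function(i) sample_from_hmm(planted_hmm3(), 80,
                                                    seed = 900 + i))
  sc <- scan_states(corpus, states = 1:4, n_restarts = 30, seed = 2,
                    alphabet = default_alphabet(), max_iter = 100, tol = 1e-4)
  expect_identical(sc$optimal_states,
                   sc$rows$S[which.min(sc$rows$BIC)])
  expect_identical(sc$rows$S, 1:4)
  # best log-likelihood cannot decrease as states are added (nested models)
  expect_true(all(diff(sc$rows$loglik) > -1e-6))
  expect_equal(sc$rows$loglik[3], logLik(sc$fits[["3"]])[1])
})

test_that("classify picks the generating model and flags exact ties", {
  m1 <- planted_hmm3()
  m2 <- action_hmm(1, matrix(1), matrix(1 / 7, 1, 7), default_alphabet())
  s <- sample_from_hmm(m1, 150, seed = 11)
  r <- classify(list(planted = m1, uniform = m2), s)
  expect_identical(r$label, "planted")
  expect_false(r$tie)
  tie <- classify(list(a = m2, b = m2), s)
  expect_true(tie$tie)
  expect_identical(tie$label, NA_character_)
  expect_error(classify(list(m1), s), "two named models")
})

test_that("summarize_model filters the display only", {
  m <- planted_hmm3()
  sm <- summarize_model(m, display_floor = 0.5)
  expect_true(all(sm$transitions$prob >= 0.5))
  expect_true(all(sm$emissions$prob >= 0.5))
  # the model itself is untouched and a 0 floor keeps everything positive
  full <- summarize_model(m, display_floor = 0)
  expect_identical(nrow(full$transitions), 9L)
  expect_equal(sum(full$emissions$prob), 3)
  expect_identical(m$emission, planted_hmm3()$emission)
  expect_s3_class(summary(m), "hmm_summary")
})

test_that("state occupancy fractions sum to one", {
  m <- planted_hmm3()
  corpus <- lapply(1:3, function(i) sample_from_hmm(m, 60, seed = 60 + i))
  occ <- state_occupancy(m, corpus)
  expect_length(occ, 3L)
  expect_equal(sum(occ), 1)
  expect_true(all(occ >= 0))
})

test_that("running_sos_average computes truncated centered means", {
  p <- fake_path(c(1, 2, 1, 2, 1))
  expect_equal(running_sos_average(p, window = 3),
               c(1 / 2, 1 / 3, 2 / 3, 1 / 3, 1 / 2))
  expect_equal(running_sos_average(p, window = 1), c(0, 1, 0, 1, 0))
  expect_equal(running_sos_average(p, window = 5),
               c(1 / 3, 1 / 2, 2 / 5, 1 / 2, 1 / 3))
  expect_error(running_sos_average(p, window = 4), "odd")
  expect_error(running_sos_average(p, window = 7), "exceeds")
})

test_that("fit_sos separates oscillating from constant paths", {
  # two categories of state paths over states {1,2,3}: category X dwells in
  # long alternating blocks of {1} vs {2,3}; category Y stays in state 1
  set.seed(5)
  blocks <- function() unlist(lapply(1:6, function(b)
    if (b %% 2) rep(1L, 10) else sample(2:3, 10, replace = TRUE)))
  paths <- c(lapply(1:3, function(i) fake_path(blocks(), paste0("x", i), "X")),
             lapply(1:3, function(i) fake_path(rep(1L, 60), paste0("y", i),
                                               "Y")))
  sos <- fit_sos(paths, n_restarts = 20, seed = 4, max_iter = 100, tol = 1e-4)
  expect_false(sos$degenerate)
  expect_equal(unname(rowSums(sos$occupancy)), c(1, 1))
  expect_gte(max(sos$occupancy["Y", ]), 0.99)   # constant category: one SoS
  expect_gte(min(sos$occupancy["X", ]), 0.3)    # oscillating: both SoS
  # degenerate input is flagged, not an error
  sd <- fit_sos(lapply(1:2, function(i) fake_path(rep(1L, 2), category = "Z")),
                n_restarts = 2, seed = 1, max_iter = 5, tol = 1e-2)
  expect_true(sd$degenerate)
})

test_that("match_states recovers a planted permutation", {
  B <- planted_hmm3()$emission
  perm <- c(3L, 1L, 2L)
  res <- match_states(B[perm, ], B)
  expect_identical(res$perm, perm)
  expect_equal(res$tv, rep(0, 3))
  expect_equal(max(match_states(B, B)$tv), 0)
})

test_that("HMM model files round-trip exactly", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  m <- planted_hmm3()
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_identical(m2$alphabet, m$alphabet)
  expect_equal(m2$initial, m$initial)
  expect_equal(m2$transition, m$transition)
  expect_equal(m2$emission, m$emission)
})
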