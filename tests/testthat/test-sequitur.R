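test_that("the worked-example sentence yields the canonical grammar", {
  s <- symbol_sequence(little_cat_tokens(), "littlecat", "demo")
  g <- k_sequitur(s, k = 2)
  tab <- summary(g)
  tab <- tab[order(tab$rule), ]
  expect_identical(tab$rule, c("r2", "r3", "r5"))
  expect_identical(tab$expansion,
                   c("the little cat", "the mouse", "the big cat"))
  expect_identical(tab$usage, c(4L, 2L, 2L))
  expect_identical(tab$level, c(2L, 2L, 2L))  # flat bodies after inlining
  root <- actiongram:::element_tokens(g$root[[1]], g$terminals)
  expect_identical(paste(root, collapse = " "),
                   "r2 chases r3 r2 catches r3 r5 chases r2 r2 runs away from r5")
  expect_identical(expand(g)$symbols, s$symbols)
})

test_that("the shipped example sentence file reproduces the same grammar", {
  path <- system.file("extdata", "little_cat.txt", package = "actiongram")
  expect_true(nzchar(path))
  s <- read_symbols(path)[[1]]
  expect_identical(s$sequence_id, "littlecat")
  expect_identical(s$symbols, little_cat_tokens())
  g <- k_sequitur(s, k = 2)
  expect_identical(sort(summary(g)$usage), c(2L, 2L, 4L))
})

test_that("repeated digrams nest into hierarchical rules", {
  g <- k_sequitur(symbol_sequence(rep(c("a", "b"), 8)), k = 2)
  expect_identical(expand(g)$symbols, rep(c("a", "b"), 8))
  expect_identical(sort(as.integer(rule_levels(g))), c(2L, 3L, 4L))
  g2 <- k_sequitur(symbol_sequence(c("a", "b", "a", "b")), k = 2)
  expect_length(g2$rules, 1L)
  expect_identical(unname(g2$usage), 2L)
  expect_length(g2$root[[1]], 2L)
})

test_that("digram counting is non-overlapping and leftmost-greedy", {
  # "aaa" holds a single "aa", so no rule at k = 2; "aaaa" holds two
  g3 <- k_sequitur(symbol_sequence(c("a", "a", "a")), k = 2)
  expect_length(g3$rules, 0L)
  g4 <- k_sequitur(symbol_sequence(c("a", "a", "a", "a")), k = 2)
  expect_length(g4$rules, 1L)
  expect_identical(expand(g4)$symbols, rep("a", 4))
})

test_that("higher k demands more evidence before creating a rule", {
  s <- symbol_sequence(rep(c("a", "b", "c"), 3))
  expect_gt(length(k_sequitur(s, k = 2)$rules), 0L)
  expect_length(k_sequitur(s, k = 4)$rules, 0L)
  expect_error(k_sequitur(s, k = 1), "k must be >= 2")
})

test_that("corpus grammars never span sequence boundaries", {
  seqs <- list(symbol_sequence(c("x", "a"), "s1"),
               symbol_sequence(c("b", "x"), "s2"),
               symbol_sequence(c("x", "a"), "s3"),
               symbol_sequence(c("b", "x"), "s4"))
  g <- fit_corpus(seqs, k = 2)
  exps <- lapply(actiongram:::rule_expansions(g), paste, collapse = " ")
  expect_true("x a" %in% exps)
  expect_true("b x" %in% exps)
  expect_false("a b" %in% exps)   # adjacent only across a boundary
  back <- expand(g)
  expect_identical(back$s2$symbols, c("b", "x"))
  expect_identical(names(back), c("s1", "s2", "s3", "s4"))
})

test_that("induction invariants hold on random strings", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    m <- sample(2:5, 1)
    sym <- sample(letters[1:m], n, replace = TRUE)
    s <- symbol_sequence(sym)
    for (k in c(2, 4, 8)) {
      g <- k_sequitur(s, k = k)
      expect_identical(expand(g)$symbols, sym)
      if (length(g$rules)) {
        expect_true(all(g$usage >= 2L))
        expect_true(all(rule_levels(g) >= 2L))
        # fixpoint: no digram occurs k or more times anywhere
        dg <- actiongram:::count_digrams(c(g$root, unname(g$rules)))
        expect_true(all(dg$count < k))
      }
    }
  }
})

test_that("spurious rules are those used fewer than the threshold", {
  g <- k_sequitur(symbol_sequence(c(rep(c("a", "b"), 2), rep(c("c", "d"), 3),
                                    "x")), k = 2)
  tab <- summary(g)
  ab <- tab$rule[tab$expansion == "a b"]
  cd <- tab$rule[tab$expansion == "c d"]
  expect_identical(spurious_rules(g, min_occurrences = 3), ab)
  expect_identical(spurious_rules(g, min_occurrences = 2), character(0))
  expect_identical(tab$usage[tab$rule == cd], 3L)
})

test_that("exclusive rules are attributed per category and level", {
  A <- symbol_sequence(c(rep(c("m", "n"), 4), rep(c("s", "t"), 2)), "a1", "A")
  A2 <- symbol_sequence(c(rep(c("m", "n"), 3), rep(c("s", "t"), 2)), "a2", "A")
  B <- symbol_sequence(c(rep(c("u", "v"), 4), rep(c("s", "t"), 2)), "b1", "B")
  B2 <- symbol_sequence(c(rep(c("u", "v"), 3), rep(c("s", "t"), 2)), "b2", "B")
  g <- fit_corpus(list(A, A2, B, B2), k = 2)
  ex <- exclusive_rules(g)
  key <- vapply(actiongram:::rule_expansions(g), paste, "", collapse = " ")
  rn <- function(x) paste0("r", names(key)[key == x])
  pr <- ex$per_rule
  expect_identical(pr$exclusive_to[pr$rule == rn("m n")], "A")
  expect_identical(pr$exclusive_to[pr$rule == rn("u v")], "B")
  expect_identical(pr$categories[pr$rule == rn("s t")], "A+B")
  expect_true(is.na(pr$exclusive_to[pr$rule == rn("s t")]))
  expect_true(all(ex$counts$n >= 1))
  expect_setequal(ex$counts$category, c("A", "B"))
})

test_that("entropies match closed forms", {
  expect_equal(shannon_entropy(rep("a", 10)), 0)
  expect_equal(shannon_entropy(c("a", "b")), 1)
  expect_equal(shannon_entropy(c("a", "a", "b", "c")), 1.5)  # (1/2,1/4,1/4)
  expect_equal(shannon_entropy(letters[1:8]), 3)             # uniform log2 M
  expect_equal(normalized_entropy(c("a", "a", "b", "c")), 1.5 / log2(3))
  expect_equal(normalized_entropy(rep("z", 5)), 0)
  expect_equal(normalized_entropy(c("a", "b", "c")), 1)
  expect_error(shannon_entropy(character(0)), "empty")
})

test_that("compression statistics are consistent with the parse", {
  s <- symbol_sequence(rep(c("a", "b"), 8), "s1", "X")
  g <- k_sequitur(s, k = 2)
  cs <- compress_stats(g)
  expect_identical(cs$pre_length, 16L)
  expect_identical(cs$post_length, length(g$root[[1]]))
  expect_equal(cs$ratio, cs$post_length / cs$pre_length)
  expect_lt(cs$ratio, 1)
  expect_equal(cs$entropy_pre, 1)           # equal halves of a, b
  expect_true(all(cs$entropy_pre_norm <= 1 & cs$entropy_post_norm <= 1))
})

test_that("compression regression recovers an exact linear relation", {
  df <- data.frame(pre_length = c(10, 20, 30, 40),
                   post_length = c(5, 10, 15, 20))
  # a perfect fit makes summary.lm warn about its R^2; that is the point here
  reg <- suppressWarnings(compression_regression(df))
  expect_equal(reg$slope, 0.5)
  expect_equal(reg$intercept, 0)
  expect_equal(reg$r_squared, 1)
  expect_equal(reg$rate, 2)
  expect_error(compression_regression(df[1:2, ]), "at least 3")
  df$pre_length <- 10
  expect_error(compression_regression(df), "zero variance")
})

test_that("grammar JSON files round-trip", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  g <- fit_corpus(list(symbol_sequence(rep(c("a", "b"), 4), "s1", "X"),
                       symbol_sequence(c("a", "b", "c"), "s2", "Y")), k = 2)
  write_grammar(g, path)
  g2 <- read_grammar(path)
  expect_identical(format_grammar(g2), format_grammar(g))
  expect_identical(g2$usage, g$usage)
  expect_identical(g2$levels, g$levels)
  expect_identical(expand(g2, "s2")$symbols, c("a", "b", "c"))
})
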