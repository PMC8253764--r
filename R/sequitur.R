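# k-Sequitur grammar induction.
#
# Internal representation: every string (root strings and rule bodies) is an
# integer vector; positive entries index the terminal vocabulary, negative
# entries are rule references (-id). The root is a list of strings, one per
# input sequence, so digrams never span sequence boundaries (equivalent to
# joining with unique non-digram sentinels).

# Count non-overlapping, leftmost-greedy digram occurrences over a list of
# strings. Only equal-symbol pairs can self-overlap ("aaa" counts one "aa"),
# handled by keeping every other pair inside a run. Returns a data frame
# (a, b, count, first) where `first` orders first counted occurrences
# globally for deterministic tie-breaking.
count_digrams <- function(strings) {
  KA <- integer(0); KB <- integer(0); PP <- integer(0)
  offset <- 0L
  for (v in strings) {
    n <- length(v)
    if (n >= 2L) {
      i <- seq_len(n - 1L)
      eq <- v[i] == v[i + 1L]
      if (any(eq)) {
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runidx <- rep(seq_along(r$lengths), r$lengths)
        keep <- !eq | ((i - starts[runidx[i]]) %% 2L == 0L)
      } else keep <- rep(TRUE, n - 1L)
      KA <- c(KA, v[i][keep]); KB <- c(KB, v[i + 1L][keep])
      PP <- c(PP, (i + offset)[keep])
    }
    offset <- offset + length(v) + 1L
  }
  if (!length(KA))
    return(data.frame(a = integer(0), b = integer(0), count = integer(0),
                      first = integer(0)))
  key <- paste0(KA, "|", KB)
  firstpos <- !duplicated(key)
  cnt <- table(key)
  keys1 <- key[firstpos]
  data.frame(a = KA[firstpos], b = KB[firstpos],
             count = as.integer(cnt[keys1]), first = PP[firstpos])
}

# Replace leftmost-greedy non-overlapping occurrences of digram (a,b) by ref.
subst_digram <- function(v, a, b, ref) {
  n <- length(v)
  if (n < 2L) return(v)
  i <- which(v[-n] == a & v[-1L] == b)
  if (!length(i)) return(v)
  if (a == b) {
    keep <- logical(length(i)); last <- -1L
    for (j in seq_along(i))
      if (i[j] > last + 1L) { keep[j] <- TRUE; last <- i[j] }
    i <- i[keep]
  }
  v[i] <- ref
  v[-(i + 1L)]
}

# Replace each occurrence of a rule reference by its body (rule inlining).
inline_ref <- function(v, ref, body) {
  idx <- which(v == ref)
  if (!length(idx)) return(v)
  pieces <- list(); last <- 0L
  for (i in idx) {
    if (last + 1L <= i - 1L) pieces[[length(pieces) + 1L]] <- v[(last + 1L):(i - 1L)]
    pieces[[length(pieces) + 1L]] <- body
    last <- i
  }
  if (last < length(v)) pieces[[length(pieces) + 1L]] <- v[(last + 1L):length(v)]
  unlist(pieces, use.names = FALSE)
}

rule_usage_counts <- function(strings, rules) {
  allv <- unlist(c(strings, unname(rules)), use.names = FALSE)
  us <- stats::setNames(integer(length(rules)), names(rules))
  refs <- allv[allv < 0L]
  if (length(refs)) {
    tt <- table(as.character(-refs))
    hit <- intersect(names(tt), names(us))
    us[hit] <- as.integer(tt[hit])
  }
  us
}

# Core fixpoint induction: create a rule whenever some digram reaches k
# non-overlapping occurrences (most frequent first; ties to the earliest
# first occurrence), substitute it everywhere, enforce rule utility
# (rules referenced < utility times are inlined and deleted), and re-scan
# until no digram count reaches k.
induce_grammar <- function(strings, k, utility = 2L) {
  rules <- list()
  next_id <- 0L
  guard <- 10L * sum(lengths(strings)) + 100L
  repeat {
    guard <- guard - 1L
    if (guard < 0L) stop("grammar induction failed to reach a fixpoint")
    dg <- count_digrams(c(strings, unname(rules)))
    cand <- dg[dg$count >= k, , drop = FALSE]
    if (!nrow(cand)) break
    sel <- cand[order(-cand$count, cand$first)[1L], ]
    a <- sel$a; b <- sel$b
    # reuse an existing rule whose body is exactly this digram
    id <- 0L
    for (nm in names(rules)) {
      bd <- rules[[nm]]
      if (length(bd) == 2L && bd[1L] == a && bd[2L] == b) {
        id <- as.integer(nm); break
      }
    }
    if (id == 0L) {
      next_id <- next_id + 1L
      id <- next_id
      rules[[as.character(id)]] <- c(a, b)
    }
    ref <- -id
    strings <- lapply(strings, subst_digram, a = a, b = b, ref = ref)
    for (nm in names(rules)) if (nm != as.character(id))
      rules[[nm]] <- subst_digram(rules[[nm]], a = a, b = b, ref = ref)
    # rule utility
    repeat {
      us <- rule_usage_counts(strings, rules)
      weak <- names(us)[us < utility]
      if (!length(weak)) break
      nm <- weak[1L]
      body <- rules[[nm]]
      rules[[nm]] <- NULL
      rr <- -as.integer(nm)
      strings <- lapply(strings, inline_ref, ref = rr, body = body)
      rules <- lapply(rules, inline_ref, ref = rr, body = body)
    }
  }
  list(strings = strings, rules = rules)
}

new_kgrammar <- function(strings, rules, terminals, k, sequence_ids,
                         categories) {
  ids <- as.integer(names(rules))
  usage <- rule_usage_counts(strings, rules)
  g <- structure(list(k = k, root = strings, rules = rules,
                      terminals = terminals,
                      usage = stats::setNames(as.integer(usage), names(rules)),
                      sequence_ids = sequence_ids, categories = categories),
                 class = "kgrammar")
  g$levels <- rule_levels(g)
  g
}

#' Induce a context-free grammar with k-Sequitur
#'
#' Sequitur builds a hierarchical, lossless context-free grammar by replacing
#' repeated adjacent symbol pairs (digrams) with rules. The k-Sequitur
#' variant requires a digram to occur k times (non-overlapping,
#' leftmost-greedy, so "aaa" contains one "aa") before a rule is created,
#' making the grammar less sensitive to infrequent pairs; k = 2 reproduces
#' classic Sequitur on its canonical examples. When a digram reaches k
#' occurrences it is substituted everywhere (current and subsequent
#' occurrences), and rule utility is enforced: a rule referenced fewer than
#' `utility` times is inlined and deleted. Induction iterates to a fixpoint:
#' no digram with k or more occurrences survives.
#'
#' @param s a [symbol_sequence()] (any token alphabet; no validation here).
#' @param k digram threshold, >= 2.
#' @param utility minimum references for a rule to survive (default 2, the
#'   classic rule-utility constraint, for all k).
#' @return An object of class `kgrammar`: the threshold `k`, the `root`
#'   parse(s), a rule table with usage counts and hierarchy levels, and the
#'   terminal vocabulary. Rules are named r1, r2, ... in creation order;
#'   gaps mark transient rules deleted by utility.
#' @examples
#' g <- k_sequitur(symbol_sequence(c("a", "b", "a", "b")), k = 2)
#' expand(g)
#' @export
k_sequitur <- function(s, k = 2, utility = 2) {
  fit_corpus(list(s), k = k, utility = utility)
}

#' @describeIn k_sequitur Fit one grammar to a whole corpus in one run:
#'   sequences are kept as separate root strings (so no rule spans a
#'   sequence boundary) and share one global rule set; each sequence's parse
#'   is its root string.
#' @param sequences list of [symbol_sequence()] objects.
#' @export
fit_corpus <- function(sequences, k = 2, utility = 2) {
  sequences <- as_corpus(sequences)
  if (k < 2) stop("k must be >= 2")
  terminals <- unique(unlist(lapply(sequences, `[[`, "symbols")))
  strings <- lapply(sequences, function(s)
    match(s$symbols, terminals))
  res <- induce_grammar(strings, k = as.integer(k),
                        utility = as.integer(utility))
  new_kgrammar(res$strings, res$rules, terminals, as.integer(k),
               vapply(sequences, `[[`, "", "sequence_id"),
               vapply(sequences, `[[`, "", "category"))
}

# Display token of one element.
element_tokens <- function(v, terminals) {
  out <- character(length(v))
  out[v > 0L] <- terminals[v[v > 0L]]
  out[v < 0L] <- paste0("r", -v[v < 0L])
  out
}

# Terminal expansion of every rule, memoized; errors on cycles or dangling
# references.
rule_expansions <- function(g) {
  memo <- list(); visiting <- character(0)
  expand_ref <- function(id) {
    nm <- as.character(id)
    if (!is.null(memo[[nm]])) return(memo[[nm]])
    if (nm %in% visiting) stop("cycle in grammar rule references")
    body <- g$rules[[nm]]
    if (is.null(body)) stop("dangling rule reference r", nm)
    visiting <<- c(visiting, nm)
    out <- expand_string(body)
    visiting <<- setdiff(visiting, nm)
    memo[[nm]] <<- out
    out
  }
  expand_string <- function(v) {
    unlist(lapply(v, function(e)
      if (e > 0L) g$terminals[e] else expand_ref(-e)), use.names = FALSE)
  }
  stats::setNames(lapply(as.integer(names(g$rules)), expand_ref),
                  names(g$rules))
}

#' Expand a grammar back to its input
#'
#' Depth-first expansion of the root parse(s); Sequitur is lossless, so the
#' result equals the original input exactly.
#'
#' @param g a `kgrammar`.
#' @param which optional sequence index or id; default all.
#' @return A [symbol_sequence()] if the grammar covers one sequence (or
#'   `which` selects one), otherwise a list of them.
#' @export
expand <- function(g, which = NULL) {
  stopifnot(inherits(g, "kgrammar"))
  exps <- rule_expansions(g)
  one <- function(i) {
    v <- g$root[[i]]
    sym <- unlist(lapply(v, function(e)
      if (e > 0L) g$terminals[e] else exps[[as.character(-e)]]),
      use.names = FALSE)
    symbol_sequence(sym, g$sequence_ids[i], g$categories[i])
  }
  if (!is.null(which)) {
    if (is.character(which)) which <- match(which, g$sequence_ids)
    return(one(which))
  }
  if (length(g$root) == 1L) return(one(1L))
  stats::setNames(lapply(seq_along(g$root), one), g$sequence_ids)
}

#' Rule hierarchy levels
#'
#' Terminals sit at level 1; a rule's level is 1 plus the maximum level of
#' the elements in its expansion, so rules over terminals only are level 2.
#' The root is not part of the rule table.
#'
#' @param g a `kgrammar`.
#' @return Named integer vector of levels, one per rule.
#' @export
rule_levels <- function(g) {
  stopifnot(inherits(g, "kgrammar"))
  memo <- stats::setNames(rep(NA_integer_, length(g$rules)), names(g$rules))
  visiting <- character(0)
  level_of <- function(nm) {
    if (!is.na(memo[[nm]])) return(memo[[nm]])
    if (nm %in% visiting) stop("cycle in grammar rule references")
    visiting <<- c(visiting, nm)
    body <- g$rules[[nm]]
    lv <- 1L + max(vapply(body, function(e)
      if (e > 0L) 1L else level_of(as.character(-e)), 0L))
    visiting <<- setdiff(visiting, nm)
    memo[[nm]] <<- lv
    lv
  }
  for (nm in names(g$rules)) level_of(nm)
  memo
}

#' Spurious rules
#'
#' Rules referenced fewer than `min_occurrences` times. Classic Sequitur is
#' liable to produce many rules occurring fewer than 3 times on variable
#' behavioral data; this flags them.
#'
#' @param g a `kgrammar`.
#' @param min_occurrences usage threshold (default 3).
#' @return Character vector of rule names (r<id>).
#' @export
spurious_rules <- function(g, min_occurrences = 3) {
  stopifnot(inherits(g, "kgrammar"))
  nm <- names(g$usage)[g$usage < min_occurrences]
  paste0("r", nm, recycle0 = TRUE)
}

#' Category-exclusive rules by hierarchy level
#'
#' For each rule of a corpus grammar, determines the set of categories whose
#' per-sequence parses reference it, by default including indirect use (a
#' rule used inside another rule inherits the contexts of its users). Rules
#' referenced by exactly one category are exclusive to it; counts are
#' reported per category and level.
#'
#' @param g a `kgrammar` from [fit_corpus()].
#' @param direct_only count only rules referenced directly in a parse.
#' @return List with `per_rule` (rule, level, usage, categories,
#'   exclusive_to) and `counts` (category, level, n) for exclusive rules.
#' @export
exclusive_rules <- function(g, direct_only = FALSE) {
  stopifnot(inherits(g, "kgrammar"))
  ids <- names(g$rules)
  # reachable rule set from a string
  closure <- new.env(hash = TRUE)
  reach_rule <- function(nm) {
    got <- closure[[nm]]
    if (!is.null(got)) return(got)
    body <- g$rules[[nm]]
    sub <- as.character(-body[body < 0L])
    out <- unique(c(nm, unlist(lapply(sub, reach_rule))))
    closure[[nm]] <- out
    out
  }
  seq_rules <- lapply(g$root, function(v) {
    direct <- unique(as.character(-v[v < 0L]))
    if (direct_only) direct
    else unique(unlist(lapply(direct, reach_rule)))
  })
  cats <- g$categories
  rule_cats <- lapply(ids, function(nm)
    sort(unique(cats[vapply(seq_rules, function(rr) nm %in% rr, TRUE)])))
  excl <- vapply(rule_cats, function(cc)
    if (length(cc) == 1L) cc else NA_character_, "")
  per_rule <- data.frame(rule = paste0("r", ids, recycle0 = TRUE),
                         level = as.integer(g$levels[ids]),
                         usage = as.integer(g$usage[ids]),
                         categories = vapply(rule_cats, paste, "",
                                             collapse = "+"),
                         exclusive_to = excl, stringsAsFactors = FALSE)
  ex <- per_rule[!is.na(per_rule$exclusive_to), , drop = FALSE]
  counts <- if (nrow(ex)) {
    agg <- stats::aggregate(list(n = ex$rule),
                            by = list(category = ex$exclusive_to,
                                      level = ex$level), FUN = length)
    agg[order(agg$category, agg$level), , drop = FALSE]
  } else data.frame(category = character(0), level = integer(0),
                    n = integer(0))
  list(per_rule = per_rule, counts = counts)
}

#' Shannon entropy of a token string
#'
#' H = -sum f log2 f over the empirical frequencies of the element types
#' present, in bits per element. A constant string has entropy 0; M
#' equiprobable types give log2 M.
#'
#' @param elements character vector of tokens (or a [symbol_sequence()]).
#' @return Bits per element.
#' @export
shannon_entropy <- function(elements) {
  if (inherits(elements, "symbol_sequence")) elements <- elements$symbols
  if (!length(elements)) stop("empty element string")
  f <- table(elements) / length(elements)
  -sum(f * log2(f))
}

#' @describeIn shannon_entropy Entropy divided by the theoretical maximum
#'   log2(number of distinct types present) — the equiprobable case — giving
#'   a unitless value in [0, 1]; a single type is defined as 0.
#' @export
normalized_entropy <- function(elements) {
  if (inherits(elements, "symbol_sequence")) elements <- elements$symbols
  m <- length(unique(elements))
  if (m < 2L) return(0)
  shannon_entropy(elements) / log2(m)
}

#' Per-sequence compression statistics
#'
#' For every sequence parsed by a grammar: pre-compression length (terminal
#' count), post-compression length (elements of its parse string, rules and
#' terminals alike), their ratio, and absolute plus normalized Shannon
#' entropies of the terminal string and the parse string.
#'
#' @param g a `kgrammar`.
#' @return Data frame with one row per sequence: `sequence_id`, `category`,
#'   `pre_length`, `post_length`, `ratio`, `entropy_pre`, `entropy_post`,
#'   `entropy_pre_norm`, `entropy_post_norm`.
#' @export
compress_stats <- function(g) {
  stopifnot(inherits(g, "kgrammar"))
  exps <- rule_expansions(g)
  rows <- lapply(seq_along(g$root), function(i) {
    v <- g$root[[i]]
    pre <- unlist(lapply(v, function(e)
      if (e > 0L) g$terminals[e] else exps[[as.character(-e)]]),
      use.names = FALSE)
    post <- element_tokens(v, g$terminals)
    data.frame(sequence_id = g$sequence_ids[i], category = g$categories[i],
               pre_length = length(pre), post_length = length(post),
               ratio = length(post) / length(pre),
               entropy_pre = shannon_entropy(pre),
               entropy_post = shannon_entropy(post),
               entropy_pre_norm = normalized_entropy(pre),
               entropy_post_norm = normalized_entropy(post),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Corpus compression regression
#'
#' Ordinary least squares of post-compression on pre-compression length
#' across sequences. Within a homogeneous corpus the relation is close to
#' linear; the inverse slope is the corpus compression rate through rule
#' extraction.
#'
#' @param results data frame from [compress_stats()] (needs `pre_length`,
#'   `post_length`; >= 3 rows with varying pre-length).
#' @return Object of class `corpus_compression`: `per_sequence`, `slope`,
#'   `intercept`, `r_squared`, `rate` (= 1/slope).
#' @export
compression_regression <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("pre_length", "post_length") %in% names(results)))
  if (nrow(results) < 3L) stop("need at least 3 sequences")
  if (stats::var(results$pre_length) == 0)
    stop("pre-compression lengths have zero variance")
  fit <- stats::lm(post_length ~ pre_length, data = results)
  slope <- unname(stats::coef(fit)["pre_length"])
  structure(list(per_sequence = results, slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = summary(fit)$r.squared, rate = 1 / slope,
                 lm = fit),
            class = "corpus_compression")
}

#' @export
print.corpus_compression <- function(x, ...) {
  cat(sprintf(
    "<corpus_compression: %d sequences; slope=%.4f, R^2=%.4f, rate=%.2f>\n",
    nrow(x$per_sequence), x$slope, x$r_squared, x$rate))
  invisible(x)
}

#' @export
plot.corpus_compression <- function(x, ...) {
  plot(x$per_sequence$pre_length, x$per_sequence$post_length,
       xlab = "Pre-compression length", ylab = "Post-compression length",
       pch = 19, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Render a grammar as text
#'
#' Mirrors the conventional display: one `Root ->` line per sequence and one
#' line per rule with its terminal expansion and usage count.
#'
#' @param g a `kgrammar`.
#' @param expand_rules show terminal expansions (default) instead of raw
#'   bodies.
#' @return Character vector of lines.
#' @export
format_grammar <- function(g, expand_rules = TRUE) {
  exps <- rule_expansions(g)
  lines <- character(0)
  for (i in seq_along(g$root)) {
    pre <- if (length(g$root) > 1L) sprintf("Root[%s] -> ", g$sequence_ids[i])
    else "Root -> "
    lines <- c(lines, paste0(pre, paste(element_tokens(g$root[[i]],
                                                       g$terminals),
                                        collapse = " ")))
  }
  for (nm in names(g$rules)) {
    body <- if (expand_rules) exps[[nm]]
    else element_tokens(g$rules[[nm]], g$terminals)
    lines <- c(lines, sprintf("r%s -> %s (used %d times)", nm,
                              paste(body, collapse = " "), g$usage[[nm]]))
  }
  lines
}

#' @export
print.kgrammar <- function(x, ...) {
  cat(sprintf("<kgrammar: k=%d, %d sequence(s), %d rules>\n",
              x$k, length(x$root), length(x$rules)))
  writeLines(format_grammar(x))
  invisible(x)
}

#' @export
summary.kgrammar <- function(object, ...) {
  data.frame(rule = paste0("r", names(object$rules)),
             expansion = vapply(rule_expansions(object), paste, "",
                                collapse = " "),
             usage = as.integer(object$usage),
             level = as.integer(object$levels),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read or write a grammar JSON file
#'
#' Serializes k, terminals, per-sequence root parses and the rule table
#' (bodies as display tokens, usage, level).
#'
#' @param g a `kgrammar`.
#' @param path file path.
#' @return `read_grammar()` returns a `kgrammar`.
#' @export
write_grammar <- function(g, path) {
  obj <- list(k = g$k, terminals = g$terminals,
              sequence_ids = g$sequence_ids, categories = g$categories,
              root = lapply(g$root, function(v) as.integer(v)),
              rules = lapply(g$rules, function(v) as.integer(v)),
              usage = as.list(g$usage), levels = as.list(g$levels))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  # no vector simplification: equal-length root strings or rule bodies must
  # not collapse into a matrix
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ints <- function(v) vapply(v, function(e) as.integer(e[[1]]), 0L)
  chrs <- function(v) vapply(v, function(e) as.character(e[[1]]), "")
  new_kgrammar(lapply(obj$root, ints), lapply(obj$rules, ints),
               chrs(obj$terminals), as.integer(obj$k[[1]]),
               chrs(obj$sequence_ids), chrs(obj$categories))
}

# Look up the rule whose terminal expansion matches `tokens`; NA if none.
find_rule_by_expansion <- function(g, tokens) {
  exps <- rule_expansions(g)
  for (nm in names(exps))
    if (length(exps[[nm]]) == length(tokens) && all(exps[[nm]] == tokens))
      return(paste0("r", nm))
  NA_character_
}
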