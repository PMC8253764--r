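#' HMM-based complexity covariate: AIC difference
#'
#' Evaluates one sequence under two pre-fitted HMMs (a complex and a simple
#' reference model, e.g. the corpus-level 6-state and 4-state models) and
#' returns AIC(complex) - AIC(simple), each AIC using that model's own free
#' parameter count. AIC rather than BIC is used because short, variable-
#' length stimulus sequences would otherwise confound sequence length with
#' model likelihood. Decreasing values indicate increasing complexity
#' (complex-model-like structure), predicting a negative correlation with
#' the BOLD response when used as a parametric regressor.
#'
#' @param s a [symbol_sequence()].
#' @param complex_m,simple_m [action_hmm()] or `hmm_fit` objects sharing an
#'   alphabet, fitted on the training corpus (not on `s`).
#' @return AIC difference (complex - simple); antisymmetric under swapping
#'   the models.
#' @export
hmm_covariate <- function(s, complex_m, simple_m) {
  p_of <- function(m) {
    if (inherits(m, "hmm_fit")) return(m$n_free_params)
    hmm_free_params(m$n_states, length(m$alphabet))
  }
  aic <- function(m) -2 * sequence_loglik(m, s) + 2 * p_of(m)
  aic(complex_m) - aic(simple_m)
}

#' CFG-based complexity covariate: compression ratio under a corpus grammar
#'
#' Parses a (typically short stimulus) sequence with the rules of a grammar
#' fitted to the whole corpus, greedily matching the longest rule expansion
#' first, left to right; spans matching no rule remain terminals, so every
#' sequence is parseable and the parse expands back to the input. The ratio
#' of parse length to terminal length is a continuous complexity measure:
#' lower values mean more corpus structure is present in the sequence.
#'
#' @param s a [symbol_sequence()].
#' @param corpus_grammar a `kgrammar` from [fit_corpus()].
#' @return List with `ratio` (parse length / terminal length, in (0, 1]) and
#'   the `parse` (character vector of rule names and terminals).
#' @export
cfg_covariate <- function(s, corpus_grammar) {
  stopifnot(inherits(s, "symbol_sequence"),
            inherits(corpus_grammar, "kgrammar"))
  exps <- rule_expansions(corpus_grammar)
  ord <- order(-lengths(exps))
  exps <- exps[ord]
  rule_names <- paste0("r", names(exps), recycle0 = TRUE)
  sym <- s$symbols
  n <- length(sym)
  parse <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (j in seq_along(exps)) {
      L <- length(exps[[j]])
      if (L < 2L || i + L - 1L > n) next
      if (all(sym[i:(i + L - 1L)] == exps[[j]])) {
        parse <- c(parse, rule_names[j])
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      parse <- c(parse, sym[i])
      i <- i + 1L
    }
  }
  list(ratio = length(parse) / n, parse = parse)
}

#' Complexity covariate table for a stimulus corpus
#'
#' Computes both per-sequence covariates — the AIC difference under two
#' reference HMMs and the compression ratio under a corpus grammar — for a
#' list of sequences. Sequences shorter than `short_flag` symbols are
#' flagged: their AIC is dominated by the parameter penalty.
#'
#' @param sequences list of [symbol_sequence()] objects.
#' @param complex_m,simple_m reference HMMs (see [hmm_covariate()]).
#' @param corpus_grammar corpus `kgrammar` (see [cfg_covariate()]).
#' @param short_flag length below which `short` is set (default 10).
#' @return Data frame: `sequence_id`, `category`, `n_symbols`, `delta_aic`,
#'   `cfg_ratio`, `short`.
#' @export
complexity_covariates <- function(sequences, complex_m, simple_m,
                                  corpus_grammar, short_flag = 10) {
  sequences <- as_corpus(sequences)
  rows <- lapply(sequences, function(s) {
    data.frame(sequence_id = s$sequence_id, category = s$category,
               n_symbols = length(s$symbols),
               delta_aic = hmm_covariate(s, complex_m, simple_m),
               cfg_ratio = cfg_covariate(s, corpus_grammar)$ratio,
               short = length(s$symbols) < short_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a covariate table
#'
#' Writes the covariate table as CSV at full precision, stable column order.
#' Duplicate sequence ids are an error.
#'
#' @param covs data frame from [complexity_covariates()].
#' @param path output CSV path.
#' @export
export_covariates <- function(covs, path) {
  stopifnot(is.data.frame(covs), nrow(covs) >= 1,
            all(c("sequence_id", "category", "delta_aic", "cfg_ratio") %in%
                  names(covs)))
  if (anyDuplicated(covs$sequence_id))
    stop("duplicate sequence_id in covariate table: ",
         covs$sequence_id[duplicated(covs$sequence_id)][1L])
  first <- c("sequence_id", "category", "delta_aic", "cfg_ratio")
  covs <- covs[c(first, setdiff(names(covs), first))]
  utils::write.csv(format(covs, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
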