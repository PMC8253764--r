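# actiongram

Action-grammar extraction from behavioral event sequences.

`actiongram` quantifies the structural complexity of symbolic behavioral
sequences — ethograms of discrete coded events, such as the percussion /
grip-shift / flake-detachment logs of stone tool-making sessions. It asks
whether one behavioral category requires a deeper "action grammar" than
another, using two complementary sequence models:

- **Multinomial hidden Markov models** — multi-restart Baum–Welch EM with a
  compiled core, model-order selection by BIC/AIC, Viterbi decoding,
  cross-model sequence classification, and a hierarchical
  "states-of-states" analysis that fits a second HMM to decoded state paths
  to expose superordinate organization.
- **k-Sequitur context-free grammars** — a lossless, deterministic Sequitur
  variant that requires *k* occurrences of a digram before creating a rule,
  with compression regressions, rule hierarchy levels, spurious and
  category-exclusive rule detection, and pre/post-compression entropies.

From these it derives per-sequence **complexity covariates** (an AIC
difference under two reference HMMs and a grammar compression ratio)
suitable as parametric regressors in neuroimaging analyses, plus
**synthetic-corpus generators** that emulate simple (flake-removal) and
complex (platform-preparation) technologies so the whole pipeline is
testable without external data. A command-line interface (`exec/actiongram`)
exposes the pipeline stages as subcommands.

## Worked example

The canonical Sequitur demonstration sentence, shipped with the package:

```r
library(actiongram)
s <- read_symbols(system.file("extdata", "little_cat.txt",
                              package = "actiongram"))[[1]]
k_sequitur(s, k = 2)
#> <kgrammar: k=2, 1 sequence(s), 3 rules>
#> Root -> r2 chases r3 r2 catches r3 r5 chases r2 r2 runs away from r5
#> r2 -> the little cat (used 4 times)
#> r3 -> the mouse (used 2 times)
#> r5 -> the big cat (used 2 times)
```

Rule names carry gaps (`r1`, `r4` were transient rules inlined by the
utility constraint), and `expand(g)` restores the input exactly.

## Pipeline sketch

```r
# synthetic corpora over the default 7-code tool-making alphabet
old <- generate_oldowan_like(seed = 1)    # no platform preparation
ach <- generate_acheulean_like(seed = 1)  # preparation inserts, longer

# HMM order selection, decoding, states-of-states
sc  <- scan_states(ach, states = 1:8, n_restarts = 50, seed = 1,
                   alphabet = default_alphabet(), max_iter = 100, tol = 1e-4)
m   <- sc$fits[[as.character(sc$optimal_states)]]$model
sos <- fit_sos(lapply(c(old, ach), function(s) viterbi(m, s)), seed = 1)
sos$occupancy    # complex category occupies both superordinate states

# grammar compression
g <- fit_corpus(old, k = 2)
compression_regression(compress_stats(g))
#> <corpus_compression: 9 sequences; slope=..., R^2=..., rate=...>

# per-sequence covariates against two reference models
covs <- complexity_covariates(c(old, ach), complex_m = m,
                              simple_m = fit_hmm(old, 1, seed = 1),
                              corpus_grammar = fit_corpus(c(old, ach), k = 2))
```

Every stochastic step takes a master seed and is exactly reproducible.

## Command line

```sh
exec/actiongram simulate --category acheulean --n 8 --seed 1 --out corpus.txt
exec/actiongram scan --input corpus.txt --min-states 1 --max-states 8 \
    --restarts 100 --seed 1 --out scan.csv
exec/actiongram grammar --input corpus.txt --k 2 --out grammar.txt
```

Subcommands: `simulate`, `fit-hmm`, `scan`, `viterbi`, `sos`, `grammar`,
`compress`, `exclusive`, `covariates`. Flags are `--name value` pairs; a
YAML file given with `--config` supplies defaults that explicit flags
override. Every run writes `<out>.manifest.json` with the version,
arguments and seed. Exit codes: 0 success, 2 validation error, 3 numeric
failure.

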