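#' Symbol sequences
#'
#' A `symbol_sequence` is one coded behavioral sequence: an ordered vector of
#' alphabet tokens plus a sequence id and a category label. It is the
#' universal unit of analysis; all timing has been discarded.
#'
#' @param symbols character vector of alphabet tokens (non-empty).
#' @param sequence_id sequence identifier.
#' @param category category label (e.g. "Oldowan", "Acheulean").
#' @param alphabet optional [event_alphabet()] to validate against (input
#'   codes are mapped through its alias table).
#' @return An object of class `symbol_sequence`.
#' @export
symbol_sequence <- function(symbols, sequence_id = "seq", category = "",
                            alphabet = NULL) {
  symbols <- as.character(symbols)
  if (!length(symbols)) stop("a symbol sequence must be non-empty")
  if (!is.null(alphabet)) symbols <- canonicalize_codes(symbols, alphabet)
  structure(list(sequence_id = as.character(sequence_id),
                 category = as.character(category),
                 symbols = symbols),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence %s [%s], %d symbols>\n",
              x$sequence_id, x$category, length(x$symbols)))
  shown <- paste(utils::head(x$symbols, 40L), collapse = " ")
  if (length(x$symbols) > 40L) shown <- paste(shown, "...")
  cat(" ", shown, "\n")
  invisible(x)
}

#' @export
length.symbol_sequence <- function(x) length(x$symbols)

#' Ethograms
#'
#' An ethogram is the timed event log for one behavioral sequence: an ordered
#' table of (code, onset, duration) records together with a sequence id and
#' category label. Records are kept sorted by onset; ties keep input order.
#'
#' @param records data frame with columns `code`, `onset`, `duration`
#'   (seconds, both >= 0).
#' @param sequence_id sequence identifier.
#' @param category category label.
#' @param alphabet optional [event_alphabet()] for code validation.
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(records, sequence_id = "seq", category = "",
                     alphabet = NULL) {
  stopifnot(is.data.frame(records),
            all(c("code", "onset", "duration") %in% names(records)))
  if (!nrow(records)) stop("an ethogram needs at least one record")
  if (any(records$onset < 0) || any(records$duration < 0))
    stop("onsets and durations must be non-negative")
  if (!is.null(alphabet))
    records$code <- canonicalize_codes(records$code, alphabet)
  if (is.unsorted(records$onset)) {
    warning(sprintf("ethogram '%s': onsets not monotone; records re-sorted",
                    sequence_id))
    records <- records[order(records$onset), , drop = FALSE]  # stable
  }
  rownames(records) <- NULL
  structure(list(sequence_id = as.character(sequence_id),
                 category = as.character(category),
                 records = records[c("code", "onset", "duration")]),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram %s [%s], %d records, %.2f-%.2f s>\n",
              x$sequence_id, x$category, nrow(x$records),
              min(x$records$onset), max(x$records$onset)))
  invisible(x)
}

#' Read and write ethogram event tables
#'
#' The ethogram CSV dialect: comma-separated, UTF-8, "." decimal, header
#' row required with columns `sequence_id`, `category`, `code`, `onset_s`,
#' `duration_s`. One [ethogram()] is returned per distinct `sequence_id`,
#' in order of first appearance.
#'
#' @param path CSV file path.
#' @param alphabet an [event_alphabet()]; unknown codes (after alias
#'   mapping) are an error naming the offending row and code.
#' @return `read_ethogram()`: a named list of [ethogram()] objects.
#' @export
read_ethogram <- function(path, alphabet = default_alphabet()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sequence_id", "category", "code", "onset_s", "duration_s")
  if (!all(need %in% names(df)))
    stop("ethogram CSV must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("empty ethogram file: ", path)
  df$code <- canonicalize_codes(df$code, alphabet,
                                where = seq_len(nrow(df)) + 1L)
  ids <- unique(df$sequence_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$sequence_id == id, , drop = FALSE]
    ethogram(data.frame(code = sub$code, onset = sub$onset_s,
                        duration = sub$duration_s,
                        stringsAsFactors = FALSE),
             sequence_id = id, category = sub$category[1L])
  })
  stats::setNames(out, ids)
}

#' @rdname read_ethogram
#' @param ethograms a list of [ethogram()] objects (or a single one).
#' @export
write_ethogram <- function(ethograms, path) {
  if (inherits(ethograms, "ethogram")) ethograms <- list(ethograms)
  rows <- do.call(rbind, lapply(ethograms, function(e) {
    data.frame(sequence_id = e$sequence_id, category = e$category,
               code = e$records$code, onset_s = e$records$onset,
               duration_s = e$records$duration, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project an ethogram to its symbol sequence
#'
#' Discards timing: the symbols are the record codes in onset order, so the
#' result is a time-scale-invariant representation indexed by sequence
#' position.
#'
#' @param e an [ethogram()].
#' @return A [symbol_sequence()] of the same length as the record table.
#' @export
to_symbols <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  if (!nrow(e$records)) stop("ethogram has no records")
  symbol_sequence(e$records$code, sequence_id = e$sequence_id,
                  category = e$category)
}

#' Collapse runs of one code
#'
#' Replaces every maximal run of consecutive occurrences of `code` by a
#' single occurrence, leaving other symbols untouched. Used as a control to
#' remove long percussion runs (platform preparation) before re-measuring
#' compressibility. Idempotent.
#'
#' @param s a [symbol_sequence()].
#' @param code the token whose runs are collapsed.
#' @return A [symbol_sequence()].
#' @export
collapse_runs <- function(s, code) {
  stopifnot(inherits(s, "symbol_sequence"))
  sym <- s$symbols
  drop <- sym == code & c(FALSE, sym[-length(sym)] == code)
  s$symbols <- sym[!drop]
  s
}

#' Read and write bare symbol files
#'
#' One sequence per line, tokens whitespace-separated, with an optional
#' `id:category:` prefix (two leading fields terminated by colons).
#'
#' @param path file path.
#' @param alphabet optional [event_alphabet()] for validation; `NULL` skips
#'   validation (arbitrary token alphabets, e.g. words).
#' @return `read_symbols()`: a list of [symbol_sequence()] objects.
#' @export
read_symbols <- function(path, alphabet = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty symbol file: ", path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    id <- sprintf("seq%d", i); cat_ <- ""
    m <- regmatches(ln, regexec("^([^ :]+):([^ :]*): *(.*)$", ln))[[1]]
    if (length(m) == 4L) {
      id <- m[2]; cat_ <- m[3]; ln <- m[4]
    }
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    out[[i]] <- symbol_sequence(toks, sequence_id = id, category = cat_,
                                alphabet = alphabet)
  }
  stats::setNames(out, vapply(out, `[[`, "", "sequence_id"))
}

#' @rdname read_symbols
#' @param sequences a list of [symbol_sequence()] objects.
#' @export
write_symbols <- function(sequences, path) {
  if (inherits(sequences, "symbol_sequence")) sequences <- list(sequences)
  lines <- vapply(sequences, function(s) {
    sprintf("%s:%s: %s", s$sequence_id, s$category,
            paste(s$symbols, collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Coerce a single sequence or list thereof to a validated list.
as_corpus <- function(sequences) {
  if (inherits(sequences, "symbol_sequence")) sequences <- list(sequences)
  if (!length(sequences)) stop("empty corpus")
  ok <- vapply(sequences, inherits, TRUE, "symbol_sequence")
  if (!all(ok)) stop("all elements must be symbol_sequence objects")
  sequences
}
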