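#' Event alphabets
#'
#' An event alphabet is the closed, ordered set of terminal codes over which
#' all sequences are defined. Order is meaningful: it fixes the column order
#' of HMM emission matrices. An alphabet may carry an alias table mapping
#' input codes to canonical codes (e.g. a "light percussion" code recorded
#' during annotation but analyzed as plain percussion).
#'
#' @param codes character vector of unique, non-empty tokens (length >= 2).
#' @param labels character vector of human-readable labels, same length.
#' @param descriptions optional character vector of longer descriptions.
#' @param aliases named character vector: names are accepted input codes,
#'   values the canonical code each maps to.
#' @return An object of class `event_alphabet`: a data frame with columns
#'   `code`, `label`, `description` and an `aliases` attribute.
#' @examples
#' ab <- event_alphabet(c("A", "B"), c("ActionA", "ActionB"))
#' default_alphabet()
#' @export
event_alphabet <- function(codes, labels = codes,
                           descriptions = rep("", length(codes)),
                           aliases = character()) {
  codes <- as.character(codes)
  if (length(codes) < 2L) stop("an alphabet needs at least 2 codes")
  if (anyDuplicated(codes)) stop("alphabet codes must be unique")
  if (any(!nzchar(codes))) stop("alphabet codes must be non-empty")
  if (length(labels) != length(codes) || length(descriptions) != length(codes))
    stop("labels and descriptions must match codes in length")
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop("aliases must be a named character vector")
    if (!all(aliases %in% codes))
      stop("alias targets must be alphabet codes")
    if (any(names(aliases) %in% codes))
      stop("an alias may not shadow a canonical code")
  }
  out <- data.frame(code = codes, label = as.character(labels),
                    description = as.character(descriptions),
                    stringsAsFactors = FALSE)
  attr(out, "aliases") <- aliases
  class(out) <- c("event_alphabet", "data.frame")
  out
}

#' @describeIn event_alphabet The default 7-code tool-making alphabet:
#'   P percussion, T target change, G grip shift (core), H grip shift (tool),
#'   I inversion, F flake detach, X tool change. The annotation-only code
#'   L ("light percussion") is aliased to P.
#' @export
default_alphabet <- function() {
  event_alphabet(
    codes = c("P", "T", "G", "H", "I", "F", "X"),
    labels = c("Percussion", "TargetChange", "GripShiftCore", "GripShiftTool",
               "Inversion", "FlakeDetach", "ToolChange"),
    descriptions = c(
      "Striking the core with the percussor",
      "Change in the location of percussion on the core",
      "Repositioning of the hand grasping the core",
      "Repositioning of the hand grasping the percussor",
      "Flipping over the core without otherwise reorienting",
      "Removal of a flake",
      "Exchange of one percussor for another"),
    aliases = c(L = "P"))
}

#' @export
print.event_alphabet <- function(x, ...) {
  cat(sprintf("Event alphabet: %d codes\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-3s %s\n", x$code[i], x$label[i]))
  al <- attr(x, "aliases")
  if (length(al))
    cat("aliases:", paste(names(al), "->", al, collapse = ", "), "\n")
  invisible(x)
}

# Map input codes through the alias table and validate membership.
# `where` labels error messages (e.g. row numbers).
canonicalize_codes <- function(codes, alphabet, where = NULL) {
  stopifnot(inherits(alphabet, "event_alphabet"))
  al <- attr(alphabet, "aliases")
  codes <- as.character(codes)
  if (length(al)) {
    hit <- codes %in% names(al)
    codes[hit] <- unname(al[codes[hit]])
  }
  bad <- !(codes %in% alphabet$code)
  if (any(bad)) {
    idx <- which(bad)[1L]
    loc <- if (!is.null(where)) sprintf(" (row %s)", where[idx]) else ""
    stop(sprintf("unknown event code '%s'%s; not in alphabet [%s]",
                 codes[idx], loc, paste(alphabet$code, collapse = ", ")))
  }
  codes
}

#' Read or write an alphabet file
#'
#' Alphabet files are YAML: a `codes` mapping token -> label, and optional
#' `descriptions` and `aliases` mappings.
#'
#' @param path file path.
#' @return `read_alphabet()` returns an [event_alphabet()].
#' @export
read_alphabet <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$codes)) stop("alphabet file must contain a 'codes' mapping")
  codes <- names(y$codes)
  labels <- unlist(y$codes, use.names = FALSE)
  desc <- if (!is.null(y$descriptions))
    unlist(y$descriptions[codes], use.names = FALSE) else rep("", length(codes))
  desc[is.na(desc)] <- ""
  aliases <- if (!is.null(y$aliases))
    unlist(y$aliases) else character()
  event_alphabet(codes, labels, desc, aliases = aliases)
}

#' @rdname read_alphabet
#' @param alphabet an [event_alphabet()].
#' @export
write_alphabet <- function(alphabet, path) {
  y <- list(codes = as.list(stats::setNames(alphabet$label, alphabet$code)))
  if (any(nzchar(alphabet$description)))
    y$descriptions <- as.list(stats::setNames(alphabet$description,
                                              alphabet$code))
  al <- attr(alphabet, "aliases")
  if (length(al)) y$aliases <- as.list(al)
  yaml::write_yaml(y, path)
  invisible(path)
}
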