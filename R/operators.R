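#' Define an operator and its ordered states
#'
#' An operator is a discrete variable describing the relationship
#' between a user and an entity (e.g. a `view` permission).  It has
#' `n >= 1` ordered states, each written as a one-letter symbol whose
#' case encodes dominance: lower-case is the recessive form, upper-case
#' the dominant form.  The operator responds only to a symbol's position
#' in the order; case matters solely for merge resolution.
#'
#' @param name Operator name.
#' @param states Ordered character vector of state labels
#'   (index 1 first).
#' @param symbols One lower-case letter per state; defaults to
#'   `letters[1:n]`.
#' @return An object of class `s3db_operator`.
#' @examples
#' operator_spec("view", c("all", "self", "none"))
#' @export
operator_spec <- function(name, states,
                          symbols = letters[seq_along(states)]) {
  if (length(states) < 1) {
    s3db_abort("E_CONFIG", "an operator needs at least one state")
  }
  symbols <- as.character(symbols)
  if (length(symbols) != length(states) ||
      any(!grepl("^[a-z]$", symbols)) ||
      anyDuplicated(tolower(symbols))) {
    s3db_abort("E_CONFIG",
               "symbols must be distinct single lower-case letters")
  }
  structure(
    list(name = name, states = as.character(states), symbols = symbols),
    class = "s3db_operator"
  )
}

#' Bundle operators that share one state alphabet
#'
#' State strings may span several operators at once: with `m` operators
#' in the bundle, a string is read as a sequence of m-tuples, the j-th
#' position of each tuple belonging to operator j.  All member operators
#' must use the same ordered symbol alphabet, which is what makes the
#' vectorized migration meaningful.
#'
#' @param ... `s3db_operator` objects (or a single list of them).
#' @return An object of class `s3db_bundle` with fields `operators`,
#'   `m`, and the shared `symbols`.
#' @examples
#' b <- s3db_default_bundle()
#' b$m
#' @export
operator_bundle <- function(...) {
  ops <- list(...)
  if (length(ops) == 1 && !inherits(ops[[1]], "s3db_operator")) {
    ops <- ops[[1]]
  }
  if (length(ops) < 1) {
    s3db_abort("E_CONFIG", "a bundle needs at least one operator")
  }
  for (op in ops) {
    if (!inherits(op, "s3db_operator")) {
      s3db_abort("E_CONFIG", "bundle members must be operator_spec objects")
    }
    if (!identical(op$symbols, ops[[1]]$symbols)) {
      s3db_abort("E_CONFIG",
                 "all operators in a bundle must share one state alphabet")
    }
  }
  structure(
    list(operators = ops,
         m = length(ops),
         symbols = ops[[1]]$symbols,
         names = vapply(ops, function(o) o$name, character(1))),
    class = "s3db_bundle"
  )
}

#' The default View/Edit/Use permission bundle
#'
#' Three permission operators — `view`, `edit`, `use` — each over the
#' same three ordered states `all` > `self` > `none` (index 1 is the
#' most permissive), written with the symbols `a`, `b`, `c`.
#'
#' @param default_decision Decision when no state reaches an entity:
#'   `"deny"` (the default) or `"allow"`.
#' @return An `s3db_bundle` with a `default_decision` field.
#' @export
s3db_default_bundle <- function(default_decision = c("deny", "allow")) {
  default_decision <- match.arg(default_decision)
  states <- c("all", "self", "none")
  b <- operator_bundle(
    operator_spec("view", states),
    operator_spec("edit", states),
    operator_spec("use", states)
  )
  b$default_decision <- default_decision
  b
}

symbol_index <- function(symbols, alphabet) {
  match(tolower(symbols), alphabet)
}

#' Parse and normalize an operator state string
#'
#' Each character is mapped to a state of the bundle's shared alphabet;
#' its case marks the dominant (upper) or recessive (lower) form.
#' Unknown characters are rejected with their position.  The string is
#' then normalized for m-operator migration: an incomplete final
#' m-tuple is completed by borrowing from the position immediately to
#' the left, i.e. the string is right-padded with its last symbol until
#' its length is a multiple of `m`.
#'
#' @param text The state string, e.g. `"abCd"`.
#' @param bundle An `s3db_bundle`.
#' @param normalize Pad to a multiple of the bundle size (default).
#' @return The (normalized) state string.
#' @examples
#' parse_state_string("aB", s3db_default_bundle())  # "aBB"
#' @export
parse_state_string <- function(text, bundle, normalize = TRUE) {
  stopifnot(inherits(bundle, "s3db_bundle"))
  if (!is.character(text) || length(text) != 1 || nchar(text) < 1) {
    s3db_abort("E_PARSE", "a state string must have length >= 1")
  }
  chars <- strsplit(text, "")[[1]]
  idx <- symbol_index(chars, bundle$symbols)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    s3db_abort("E_PARSE", paste0(
      "unknown state symbol '", chars[pos], "' at position ", pos),
      position = pos)
  }
  if (normalize) {
    m <- bundle$m
    while (length(chars) %% m != 0) {
      chars <- c(chars, chars[length(chars)])
    }
  }
  paste(chars, collapse = "")
}

#' Merge a set of assigned states into one effective state
#'
#' Resolution of multiple direct or indirect assignments: if any
#' dominant (upper-case) state is present, the dominant state of
#' minimum index wins; otherwise the recessive (lower-case) state of
#' maximum index wins.  The result keeps its case so that further
#' merges can still distinguish dominance.  The operation is
#' order-independent, associative and idempotent.
#'
#' @param symbols Character vector of one-letter state symbols (a single
#'   multi-character string is split).
#' @param operator An `s3db_operator`, or an `s3db_bundle` (whose shared
#'   alphabet is used).
#' @return The merged one-letter symbol, case preserved.
#' @examples
#' op <- operator_spec("f", c("s1", "s2", "s3"), symbols = c("b", "c", "d"))
#' merge_states(c("b", "c", "d"), op)        # "d" (index 3)
#' merge_states(c("b", "c", "C", "D"), op)   # "C" (index 2)
#' @export
merge_states <- function(symbols, operator) {
  alphabet <- if (inherits(operator, "s3db_bundle")) operator$symbols
              else operator$symbols
  if (length(symbols) == 1 && nchar(symbols) > 1) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  symbols <- unique(symbols)
  if (length(symbols) == 0) {
    s3db_abort("E_MERGE_UNDEFINED", "merge of an empty state set is undefined")
  }
  idx <- symbol_index(symbols, alphabet)
  if (anyNA(idx)) {
    s3db_abort("E_PARSE", paste0(
      "symbols outside the operator alphabet: ",
      paste(symbols[is.na(idx)], collapse = ", ")))
  }
  dominant <- symbols %in% toupper(alphabet) & symbols != tolower(symbols)
  if (any(dominant)) {
    pick <- which(dominant)[which.min(idx[dominant])]
  } else {
    pick <- which.max(idx)
  }
  symbols[pick]
}

#' Index of a state symbol in its operator's order
#'
#' @inheritParams merge_states
#' @param symbol A one-letter state symbol (either case).
#' @return The 1-based state index.
#' @export
state_index <- function(symbol, operator) {
  alphabet <- operator$symbols
  i <- symbol_index(symbol, alphabet)
  if (anyNA(i)) {
    s3db_abort("E_PARSE", paste0("symbol outside the alphabet: ", symbol))
  }
  i
}

#' Migrate a state string one step along a licensed edge
#'
#' With `m` operators migrating simultaneously, the string is first
#' normalized to a whole number of m-tuples by borrowing from the left
#' (right-padding with the last symbol).  A singular per-operator state
#' (normalized length exactly `m`) passes unchanged; a plural state
#' leaves its first m-tuple behind as the source entity's effective
#' state and passes only the remainder on.
#'
#' @param s State string.
#' @param m Number of operators migrating simultaneously (`m >= 1`).
#' @return The migrated state string.
#' @examples
#' migrate_state("a", 3)      # "aaa"
#' migrate_state("abc", 3)    # "abc"
#' migrate_state("abcb", 3)   # "bbb"
#' migrate_state("abcbc", 3)  # "bcc"
#' migrate_state("abCd", 1)   # "bCd"
#' @export
migrate_state <- function(s, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    s3db_abort("E_USAGE", "m must be a positive integer")
  }
  m <- as.integer(m)
  if (!is.character(s) || length(s) != 1 || nchar(s) < 1) {
    s3db_abort("E_USAGE", "cannot migrate an empty state string")
  }
  chars <- strsplit(s, "")[[1]]
  while (length(chars) %% m != 0) {
    chars <- c(chars, chars[length(chars)])
  }
  if (length(chars) == m) {
    return(paste(chars, collapse = ""))
  }
  paste(chars[-seq_len(m)], collapse = "")
}
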