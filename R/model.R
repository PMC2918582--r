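#' The seven S3DB entity kinds
#'
#' The core model types every data element as one of seven entity kinds.
#' The deployment is the root of a store; projects give granularity to
#' collections and rules; collections delimit items; rules describe the
#' domain; statements instantiate rules with observations; users are the
#' subjects of operator assignments.  Kinds carry a canonical order,
#' `[D, P, C, R, I, S, U]` by their initials, which fixes the row/column
#' order of the default transition matrix.
#'
#' @return A tibble with one row per kind: `kind`, `initial`, `ordinal`.
#' @examples
#' s3db_entity_kinds()
#' @export
s3db_entity_kinds <- function() {
  tibble::tibble(
    kind    = c("deployment", "project", "collection", "rule",
                "item", "statement", "user"),
    initial = c("D", "P", "C", "R", "I", "S", "U"),
    ordinal = 1:7
  )
}

#' The twelve S3DB relationship kinds
#'
#' Each relationship kind is a typed edge class with a fixed domain and
#' range among the seven entity kinds.  The first four wire the
#' deployment/project/collection/item backbone; `Rsubject`, `Robject` and
#' `Rpredicate` attach the components of a rule; `Spredicate`, `Ssubject`
#' and `Sobject` attach the components of a statement; `DU` and `UU` wire
#' users.  Edge direction coincides with the direction of operator-state
#' migration from domain to instantiation.
#'
#' @return A tibble with columns `index` (1..12), `relation`,
#'   `domain_kind` and `range_kind`.
#' @examples
#' s3db_relation_kinds()
#' @export
s3db_relation_kinds <- function() {
  tibble::tribble(
    ~index, ~relation,    ~domain_kind, ~range_kind,
    1L,     "DP",         "deployment", "project",
    2L,     "PC",         "project",    "collection",
    3L,     "PR",         "project",    "rule",
    4L,     "CI",         "collection", "item",
    5L,     "Rsubject",   "collection", "rule",
    6L,     "Robject",    "collection", "rule",
    7L,     "Rpredicate", "item",       "rule",
    8L,     "Spredicate", "rule",       "statement",
    9L,     "Ssubject",   "item",       "statement",
    10L,    "Sobject",    "item",       "statement",
    11L,    "DU",         "deployment", "user",
    12L,    "UU",         "user",       "user"
  )
}

kind_initial <- function(kind) {
  k <- s3db_entity_kinds()
  k$initial[match(kind, k$kind)]
}

relation_row <- function(relation) {
  rk <- s3db_relation_kinds()
  i <- match(relation, rk$relation)
  if (is.na(i)) {
    s3db_abort("E_USAGE", paste0("unknown relationship kind: ", relation))
  }
  rk[i, ]
}
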