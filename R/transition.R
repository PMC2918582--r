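#' The default Boolean transition matrix
#'
#' A 7x7 Boolean mask over the canonical entity-kind order
#' `[D, P, C, R, I, S, U]` whose true cells are exactly the
#' (domain, range) pairs of the 12 relationship kinds: D->P, P->C,
#' P->R, C->I, C->R, I->R, R->S, I->S, D->U and U->U — ten type-level
#' edges, two of which (C->R, I->S) are each licensed by two
#' relationship kinds.  State migration between entity instances runs
#' along instance edges whose relationship kind maps to a true cell.
#'
#' Percolation accepts any Boolean matrix in place of this default, so
#' a different core model only needs to supply a different mask.
#'
#' @return A logical matrix of class `s3db_transition_matrix` with
#'   dimnames `[D, P, C, R, I, S, U]` and a `provenance` attribute (a
#'   tibble mapping each true cell to its licensing relationship
#'   indexes).
#' @examples
#' s3db_transition_matrix()["C", "I"]
#' @export
s3db_transition_matrix <- function() {
  kinds <- s3db_entity_kinds()
  rk <- s3db_relation_kinds()
  T_ <- matrix(FALSE, 7, 7,
               dimnames = list(from = kinds$initial, to = kinds$initial))
  prov <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(rk,
        from = kind_initial(.data$domain_kind),
        to   = kind_initial(.data$range_kind)),
      .data$from, .data$to),
    relations = list(.data$index), .groups = "drop")
  for (i in seq_len(nrow(prov))) {
    T_[prov$from[i], prov$to[i]] <- TRUE
  }
  structure(T_, provenance = prov, class = c("s3db_transition_matrix",
                                             "matrix", "array"))
}

#' Tidy view of a transition matrix
#'
#' @param matrix A transition matrix (any logical matrix with entity
#'   initials as dimnames).
#' @return A tibble with one row per true cell: `from`, `to`, and (for
#'   the default matrix) the list-column `relations` of licensing
#'   relationship indexes.
#' @export
transition_edges <- function(matrix = s3db_transition_matrix()) {
  prov <- attr(matrix, "provenance")
  idx <- which(matrix, arr.ind = TRUE)
  out <- tibble::tibble(
    from = rownames(matrix)[idx[, 1]],
    to   = colnames(matrix)[idx[, 2]]
  )
  if (!is.null(prov)) {
    out <- dplyr::left_join(out, prov, by = c("from", "to"))
  }
  dplyr::arrange(out, .data$from, .data$to)
}

#' The instance graph licensed by a transition matrix
#'
#' Projects the store's relation instances through the matrix: an edge
#' `u -> v` exists iff some relation instance `(u, r, v)` has a
#' relationship kind whose (domain, range) cell is true.  This is the
#' graph along which operator states migrate; self-loops can only arise
#' from `UU`.
#'
#' @param store An `s3db_store`.
#' @param matrix A Boolean transition matrix over entity-kind initials.
#' @return A tibble of distinct edges (`from`, `to`).
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo"))
#' instance_graph(store)
#' @export
instance_graph <- function(store, matrix = s3db_transition_matrix()) {
  stopifnot(inherits(store, "s3db_store"))
  rk <- dplyr::mutate(
    s3db_relation_kinds(),
    from_initial = kind_initial(.data$domain_kind),
    to_initial   = kind_initial(.data$range_kind)
  )
  licensed <- rk[mapply(function(f, t) {
    f %in% rownames(matrix) && t %in% colnames(matrix) && matrix[f, t]
  }, rk$from_initial, rk$to_initial), "relation", drop = TRUE]
  edges <- store$relations[store$relations$relation %in% licensed,
                           c("subject", "object")]
  dplyr::distinct(tibble::tibble(from = edges$subject, to = edges$object))
}
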