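#' Check every model invariant of a store
#'
#' Runs the full battery of schema checks: relation endpoints exist,
#' exactly one deployment root, domain/range typing of all 12
#' relationship kinds, rule wiring (Rsubject/Rpredicate/Robject present
#' and correctly typed), statement membership (the subject item belongs
#' to the rule's subject collection; item objects belong to the rule's
#' object collection; object type matches the rule's object type),
#' creator references, and URI uniqueness.  Predicate items that belong
#' to no collection are reported as warnings, not errors.
#'
#' @param store An `s3db_store`.
#' @return A tibble of violations with columns `code`, `severity`
#'   (`"error"` or `"warning"`), `entity` and `detail`; zero rows when
#'   the store is valid.
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo"))
#' validate_store(store)
#' @export
validate_store <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  v <- list()
  add <- function(code, entity, detail, severity = "error") {
    v[[length(v) + 1]] <<- tibble::tibble(
      code = code, severity = severity, entity = entity, detail = detail)
  }
  ents <- store$entities
  rels <- store$relations

  if (anyDuplicated(ents$uri)) {
    for (u in unique(ents$uri[duplicated(ents$uri)])) {
      add("E_DUP_URI", u, "URI appears more than once")
    }
  }
  n_root <- sum(ents$kind == "deployment")
  if (n_root != 1) {
    add("E_DUP_ROOT", store$base_uri,
        paste0("store must have exactly one deployment, found ", n_root))
  }

  missing_creator <- !is.na(ents$creator) &
    !(ents$creator %in% ents$uri[ents$kind == "user"])
  for (i in which(missing_creator)) {
    add("E_NOT_FOUND", ents$uri[i],
        paste0("creator is not a user in the store: ", ents$creator[i]))
  }

  rk <- s3db_relation_kinds()
  for (i in seq_len(nrow(rels))) {
    s <- rels$subject[i]; o <- rels$object[i]; rel <- rels$relation[i]
    rr <- rk[rk$relation == rel, ]
    if (!s %in% ents$uri) {
      add("E_NOT_FOUND", s, paste0("relation subject missing (", rel, ")"))
      next
    }
    if (!o %in% ents$uri) {
      add("E_NOT_FOUND", o, paste0("relation object missing (", rel, ")"))
      next
    }
    s_kind <- ents$kind[match(s, ents$uri)]
    o_kind <- ents$kind[match(o, ents$uri)]
    s_ok <- identical(s_kind, rr$domain_kind) ||
      (rel == "Robject" && identical(s_kind, "external"))
    if (!s_ok) {
      add("E_DOMAIN", s, paste0(
        rel, " (#", rr$index, ") requires a ", rr$domain_kind,
        " subject, found ", s_kind))
    }
    if (!identical(o_kind, rr$range_kind)) {
      add("E_RANGE", o, paste0(
        rel, " (#", rr$index, ") requires a ", rr$range_kind,
        " object, found ", o_kind))
    }
  }

  has_rel <- function(s, rel, o) {
    any(rels$subject == s & rels$relation == rel & rels$object == o)
  }
  for (i in seq_len(nrow(store$rules))) {
    r <- store$rules[i, ]
    if (!has_rel(r$subject_collection, "Rsubject", r$uri)) {
      add("E_NOT_FOUND", r$uri, "rule lacks its Rsubject relation")
    }
    if (!has_rel(r$predicate_item, "Rpredicate", r$uri)) {
      add("E_NOT_FOUND", r$uri, "rule lacks its Rpredicate relation")
    }
    obj <- if (is.na(r$object_collection)) r$object_resource
           else r$object_collection
    if (!has_rel(obj, "Robject", r$uri)) {
      add("E_NOT_FOUND", r$uri, "rule lacks its Robject relation")
    }
    # Predicate items outside any collection are tolerated but flagged.
    pred_memberships <- rels$relation == "CI" & rels$object == r$predicate_item
    if (!any(pred_memberships)) {
      add("W_PREDICATE_NO_COLLECTION", r$predicate_item,
          paste0("predicate item of rule ", r$uri,
                 " belongs to no collection"), severity = "warning")
    }
  }

  for (i in seq_len(nrow(store$statements))) {
    st <- store$statements[i, ]
    j <- match(st$rule, store$rules$uri)
    if (is.na(j)) {
      add("E_NOT_FOUND", st$uri, paste0("statement rule missing: ", st$rule))
      next
    }
    r <- store$rules[j, ]
    if (!has_rel(r$subject_collection, "CI", st$subject_item)) {
      add("E_MEMBERSHIP", st$uri, paste0(
        "statement subject ", st$subject_item,
        " is not a CI-member of ", r$subject_collection))
    }
    if (is.na(r$object_collection)) {
      if (!is.na(st$object_item) || is.na(st$object_literal)) {
        add("E_OBJECT_TYPE", st$uri,
            "opaque-object rule requires a literal statement object")
      }
    } else {
      if (is.na(st$object_item) || !is.na(st$object_literal)) {
        add("E_OBJECT_TYPE", st$uri,
            "collection-object rule requires an item statement object")
      } else if (!has_rel(r$object_collection, "CI", st$object_item)) {
        add("E_MEMBERSHIP", st$uri, paste0(
          "statement object ", st$object_item,
          " is not a CI-member of ", r$object_collection))
      }
    }
  }

  for (i in seq_len(nrow(store$assignments))) {
    a <- store$assignments[i, ]
    if (!a$user %in% ents$uri[ents$kind == "user"]) {
      add("E_NOT_FOUND", a$user, "assignment user missing")
    }
    if (!a$target %in% ents$uri) {
      add("E_NOT_FOUND", a$target, "assignment target missing")
    }
  }

  if (length(v) == 0) {
    tibble::tibble(code = character(), severity = character(),
                   entity = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
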