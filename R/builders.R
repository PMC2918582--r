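#' Convenience builders for the common entity kinds
#'
#' Thin wrappers around [create_entity()] and [assert_relation()] that
#' also wire the backbone edges: a project is `DP`-linked to the
#' deployment, a collection `PC`-linked to its project, an item
#' `CI`-linked to zero or more collections, a user `DU`-linked to the
#' deployment.
#'
#' @param store An `s3db_store`.
#' @param label Optional label.
#' @param project,collections Entity references for the parent project /
#'   member collections.
#' @param creator Optional user reference recorded as creator.
#' @param uri Optional explicit URI.
#' @return The updated store; see [last_uri()].
#' @examples
#' s3db_store("http://example.org/demo") |>
#'   add_project(label = "demo") |>
#'   add_collection("demo", label = "person") |>
#'   add_item(label = "Mary", collections = "person")
#' @export
add_project <- function(store, label = NULL, creator = NULL, uri = NULL) {
  store <- create_entity(store, "project", label = label,
                         creator = creator, uri = uri)
  root <- store$entities$uri[store$entities$kind == "deployment"][1]
  assert_relation(store, root, "DP", store$last_uri)
}

#' @rdname add_project
#' @export
add_collection <- function(store, project, label = NULL, creator = NULL,
                           uri = NULL) {
  p <- resolve_entity(store, project, kind = "project")
  store <- create_entity(store, "collection", label = label,
                         creator = creator, uri = uri)
  assert_relation(store, p, "PC", store$last_uri)
}

#' @rdname add_project
#' @export
add_item <- function(store, label = NULL, collections = character(),
                     creator = NULL, uri = NULL) {
  store <- create_entity(store, "item", label = label,
                         creator = creator, uri = uri)
  item <- store$last_uri
  for (coll in collections) {
    c_uri <- resolve_entity(store, coll, kind = "collection")
    store <- assert_relation(store, c_uri, "CI", item)
  }
  store$last_uri <- item
  store
}

#' @rdname add_project
#' @export
add_user <- function(store, label = NULL, uri = NULL) {
  store <- create_entity(store, "user", label = label, uri = uri)
  root <- store$entities$uri[store$entities$kind == "deployment"][1]
  assert_relation(store, root, "DU", store$last_uri)
}

# Items CI-linked to a collection.
collection_members <- function(store, collection_uri) {
  r <- store$relations
  r$object[r$relation == "CI" & r$subject == collection_uri]
}

#' Describe a piece of the domain as a rule
#'
#' A rule is a dyadic predicate: a subject collection, a predicate item
#' and an object that is either another collection or an opaque foreign
#' resource (for example `foaf:firstName`, or a bare literal name).  The
#' rule itself becomes the predicate of the statements that instantiate
#' it.  Four edges are asserted: `PR` from the project, `Rsubject` from
#' the subject collection, `Rpredicate` from the predicate item, and
#' `Robject` from the object.
#'
#' @param store An `s3db_store`.
#' @param project Reference to the owning project.
#' @param subject_collection Reference to the collection whose items may
#'   subject statements of this rule.
#' @param predicate_item Reference to the item naming the predicate
#'   (e.g. an item labelled "lives in").
#' @param object A collection reference, or — when the reference matches
#'   no collection in the store — an opaque resource name registered as
#'   an external resource; statements of such a rule carry literal
#'   objects.
#' @param label,creator,uri As in [create_entity()].
#' @return The updated store; the rule URI is [last_uri()].
#' @export
add_rule <- function(store, project, subject_collection, predicate_item,
                     object, label = NULL, creator = NULL, uri = NULL) {
  stopifnot(inherits(store, "s3db_store"))
  p <- resolve_entity(store, project, kind = "project")
  subj <- tryCatch(resolve_entity(store, subject_collection),
                   s3db_e_not_found = function(e) NULL)
  if (is.null(subj) || !identical(entity_kind(store, subj), "collection")) {
    s3db_abort("E_DOMAIN", paste0(
      "rule subject must be a collection (relationship Rsubject, #5): ",
      subject_collection))
  }
  pred <- tryCatch(resolve_entity(store, predicate_item),
                   s3db_e_not_found = function(e) NULL)
  if (is.null(pred) || !identical(entity_kind(store, pred), "item")) {
    s3db_abort("E_DOMAIN", paste0(
      "rule predicate must be an item (relationship Rpredicate, #7): ",
      predicate_item))
  }
  obj <- tryCatch(resolve_entity(store, object),
                  s3db_e_not_found = function(e) NULL)
  obj_is_collection <- !is.null(obj) &&
    identical(entity_kind(store, obj), "collection")
  if (!is.null(obj) && !obj_is_collection &&
      !isTRUE(store$entities$external[match(obj, store$entities$uri)])) {
    s3db_abort("E_OBJECT_TYPE", paste0(
      "rule object must be a collection or an opaque resource, not a ",
      entity_kind(store, obj), ": ", object))
  }

  store <- create_entity(store, "rule", label = label,
                         creator = creator, uri = uri)
  rule_uri <- store$last_uri
  store <- assert_relation(store, p, "PR", rule_uri)
  store <- assert_relation(store, subj, "Rsubject", rule_uri)
  store <- assert_relation(store, pred, "Rpredicate", rule_uri)
  if (obj_is_collection) {
    store <- assert_relation(store, obj, "Robject", rule_uri)
    obj_coll <- obj
    obj_res <- NA_character_
  } else {
    store <- register_external(store, if (is.null(obj)) object else obj)
    obj_res <- store$last_uri
    store <- assert_relation(store, obj_res, "Robject", rule_uri)
    obj_coll <- NA_character_
  }
  store$rules <- dplyr::bind_rows(
    store$rules,
    tibble::tibble(uri = rule_uri, subject_collection = subj,
                   predicate_item = pred, object_collection = obj_coll,
                   object_resource = obj_res)
  )
  store$last_uri <- rule_uri
  store
}

#' Instantiate a rule with an observation
#'
#' A statement's predicate is a rule; its subject must be an item of the
#' rule's subject collection.  When the rule's object is a collection
#' the statement object is an item of that collection (pass `object`);
#' when the rule's object is an opaque resource the statement carries a
#' literal value (pass `literal`).  Three edges are asserted:
#' `Ssubject`, `Spredicate` and, for item objects, `Sobject`.
#'
#' @param store An `s3db_store`.
#' @param rule Reference to the predicate rule.
#' @param subject_item Reference to the subject item.
#' @param object Reference to the object item (collection-object rules).
#' @param literal Literal text (opaque-object rules).
#' @param creator,uri As in [create_entity()].
#' @return The updated store; the statement URI is [last_uri()].
#' @export
add_statement <- function(store, rule, subject_item, object = NULL,
                          literal = NULL, creator = NULL, uri = NULL) {
  stopifnot(inherits(store, "s3db_store"))
  rule_uri <- resolve_entity(store, rule, kind = "rule")
  rr <- store$rules[store$rules$uri == rule_uri, ]
  if (nrow(rr) != 1) {
    s3db_abort("E_USAGE", paste0("rule has no rule record: ", rule_uri))
  }
  subj <- resolve_entity(store, subject_item, kind = "item")
  if (!subj %in% collection_members(store, rr$subject_collection)) {
    s3db_abort("E_MEMBERSHIP", paste0(
      "statement subject ", subj, " is not a CI-member of the rule's ",
      "subject collection ", rr$subject_collection))
  }
  has_obj_coll <- !is.na(rr$object_collection)
  if (has_obj_coll) {
    if (is.null(object) || !is.null(literal)) {
      s3db_abort("E_OBJECT_TYPE", paste0(
        "rule ", rule_uri, " has a collection object; the statement ",
        "object must be an item of that collection, not a literal"))
    }
    obj <- resolve_entity(store, object, kind = "item")
    if (!obj %in% collection_members(store, rr$object_collection)) {
      s3db_abort("E_MEMBERSHIP", paste0(
        "statement object ", obj, " is not a CI-member of the rule's ",
        "object collection ", rr$object_collection))
    }
    lit <- NA_character_
  } else {
    if (is.null(literal) || !is.null(object)) {
      s3db_abort("E_OBJECT_TYPE", paste0(
        "rule ", rule_uri, " has an opaque (non-collection) object; ",
        "the statement object must be a literal value"))
    }
    obj <- NA_character_
    lit <- as.character(literal)
  }

  store <- create_entity(store, "statement", creator = creator, uri = uri)
  st_uri <- store$last_uri
  store <- assert_relation(store, subj, "Ssubject", st_uri)
  store <- assert_relation(store, rule_uri, "Spredicate", st_uri)
  if (!is.na(obj)) store <- assert_relation(store, obj, "Sobject", st_uri)
  store$statements <- dplyr::bind_rows(
    store$statements,
    tibble::tibble(uri = st_uri, rule = rule_uri, subject_item = subj,
                   object_item = obj, object_literal = lit)
  )
  store$last_uri <- st_uri
  store
}

#' Edit a rule's opaque object without touching its statements
#'
#' Domain descriptions evolve: the attribute a rule points at (say
#' `foaf:firstName`) may be renamed (say to `"name"`).  Such an edit
#' must not corrupt the data already instantiated, so every dependent
#' statement keeps its URI and its literal object value unchanged.
#' Rules whose object is a collection cannot be re-pointed this way
#' (that would orphan item objects) and raise `E_EDIT_UNSUPPORTED`.
#'
#' @param store An `s3db_store`.
#' @param rule Reference to the rule being edited.
#' @param new_resource The replacement resource name.
#' @return The updated store.
#' @export
update_rule_object <- function(store, rule, new_resource) {
  stopifnot(inherits(store, "s3db_store"))
  rule_uri <- resolve_entity(store, rule, kind = "rule")
  i <- match(rule_uri, store$rules$uri)
  if (is.na(i)) s3db_abort("E_USAGE", paste0("no rule record: ", rule_uri))
  old <- store$rules$object_resource[i]
  if (is.na(old)) {
    s3db_abort("E_EDIT_UNSUPPORTED", paste0(
      "rule ", rule_uri, " has a collection object; re-pointing it is ",
      "not supported"))
  }
  if (identical(old, new_resource)) return(store)
  store <- register_external(store, new_resource)
  new_uri <- store$last_uri
  store$relations <- store$relations[
    !(store$relations$relation == "Robject" &
        store$relations$subject == old &
        store$relations$object == rule_uri), ]
  store <- assert_relation(store, new_uri, "Robject", rule_uri)
  store$rules$object_resource[i] <- new_uri
  # Drop the old external record if nothing references it any more.
  still_used <- old %in% store$relations$subject ||
    old %in% store$relations$object ||
    old %in% store$rules$object_resource
  if (!still_used) {
    store$entities <- store$entities[store$entities$uri != old, ]
  }
  store$last_uri <- rule_uri
  store
}

#' Delete an entity
#'
#' Deletion is refused while dependents exist (relations touching the
#' entity, or rule/statement records referencing it) unless
#' `cascade = TRUE`, in which case dependents are removed transitively:
#' deleting a collection removes the rules it subjects or objects,
#' which removes their statements, and so on.
#'
#' @param store An `s3db_store`.
#' @param entity Reference to the entity to delete.
#' @param cascade Remove dependents transitively instead of refusing.
#' @return The updated store.
#' @export
delete_entity <- function(store, entity, cascade = FALSE) {
  stopifnot(inherits(store, "s3db_store"))
  uri <- resolve_entity(store, entity)
  doomed <- uri
  repeat {
    dep_rules <- store$rules$uri[
      store$rules$subject_collection %in% doomed |
        store$rules$predicate_item %in% doomed |
        store$rules$object_collection %in% doomed |
        store$rules$object_resource %in% doomed]
    dep_stmts <- store$statements$uri[
      store$statements$rule %in% doomed |
        store$statements$subject_item %in% doomed |
        store$statements$object_item %in% doomed]
    grown <- union(doomed, c(dep_rules, dep_stmts))
    if (length(grown) == length(doomed)) break
    doomed <- grown
  }
  rel_hit <- store$relations$subject %in% doomed |
    store$relations$object %in% doomed
  if (!cascade && (length(doomed) > 1 ||
                   sum(rel_hit) > 0 ||
                   uri %in% store$assignments$target)) {
    s3db_abort("E_DEPENDENTS", paste0(
      "entity ", uri, " has dependents; use cascade = TRUE to remove ",
      "them transitively"))
  }
  store$entities   <- store$entities[!store$entities$uri %in% doomed, ]
  store$relations  <- store$relations[!rel_hit, ]
  store$rules      <- store$rules[!store$rules$uri %in% doomed, ]
  store$statements <- store$statements[!store$statements$uri %in% doomed, ]
  store$assignments <- store$assignments[
    !(store$assignments$target %in% doomed |
        store$assignments$user %in% doomed), ]
  store
}
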