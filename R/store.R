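#' Create an empty S3DB store
#'
#' A store is the in-memory representation of one deployment: a set of
#' URI-identified entities, the typed relationships between them, the
#' rule and statement records of the two-tier predication pattern, and
#' the user operator-state assignments.  The deployment root entity is
#' created immediately; every other entity is added with [create_entity()]
#' or the higher-level builders and linked with [assert_relation()].
#'
#' All mutators take the store as their first argument and return the
#' updated store, so a store is built with a pipe chain; the URI of the
#' most recently created entity is available as [last_uri()].
#'
#' @param base_uri Absolute base URI of the deployment; minted entity
#'   URIs are `<base_uri>/<kind initial><counter>`.
#' @param label Optional label for the deployment root.
#' @param random_uris If `TRUE`, minted URIs use a random alphanumeric
#'   suffix instead of the default per-kind sequential counter.
#' @return An object of class `s3db_store`.
#' @examples
#' store <- s3db_store("http://example.org/demo") |>
#'   create_entity("project", label = "demo project")
#' last_uri(store)
#' @export
s3db_store <- function(base_uri, label = NULL, random_uris = FALSE) {
  if (!is.character(base_uri) || length(base_uri) != 1 || !nzchar(base_uri)) {
    s3db_abort("E_USAGE", "base_uri must be a non-empty string")
  }
  base_uri <- sub("/+$", "", base_uri)
  kinds <- s3db_entity_kinds()$kind
  store <- structure(
    list(
      base_uri   = base_uri,
      entities   = tibble::tibble(
        uri = character(), kind = character(), label = character(),
        creator = character(), external = logical()
      ),
      relations  = tibble::tibble(
        subject = character(), relation = character(), object = character()
      ),
      rules      = tibble::tibble(
        uri = character(), subject_collection = character(),
        predicate_item = character(), object_collection = character(),
        object_resource = character()
      ),
      statements = tibble::tibble(
        uri = character(), rule = character(), subject_item = character(),
        object_item = character(), object_literal = character()
      ),
      assignments = tibble::tibble(
        user = character(), target = character(),
        bundle = character(), state = character()
      ),
      counters   = stats::setNames(integer(length(kinds)), kinds),
      settings   = list(random_uris = isTRUE(random_uris)),
      last_uri   = NA_character_
    ),
    class = "s3db_store"
  )
  create_entity(store, "deployment", label = label)
}

#' @export
print.s3db_store <- function(x, ...) {
  counts <- table(factor(x$entities$kind, levels = s3db_entity_kinds()$kind))
  cat("<s3db_store> ", x$base_uri, "\n", sep = "")
  cat("  entities: ", paste0(names(counts), "=", as.integer(counts),
                             collapse = " "), "\n", sep = "")
  n_ext <- sum(x$entities$external)
  if (n_ext > 0) cat("  external resources: ", n_ext, "\n", sep = "")
  cat("  relations: ", nrow(x$relations),
      "  assignments: ", nrow(x$assignments), "\n", sep = "")
  invisible(x)
}

#' Accessors for the tabular contents of a store
#'
#' Each accessor returns the corresponding component as a tibble:
#' entities (`uri`, `kind`, `label`, `creator`, `external`), relation
#' instances (`subject`, `relation`, `object`), rule records, statement
#' records and operator-state assignments.
#'
#' @param store An `s3db_store`.
#' @return A tibble.
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo"))
#' entities(store)
#' relations(store)
#' @export
entities <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$entities
}

#' @rdname entities
#' @export
relations <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$relations
}

#' @rdname entities
#' @export
rules <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$rules
}

#' @rdname entities
#' @export
statements <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$statements
}

#' @rdname entities
#' @export
assignments <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$assignments
}

#' @rdname entities
#' @export
last_uri <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  store$last_uri
}

#' Mint the next entity URI for a kind
#'
#' URIs are minted under the deployment base as
#' `<base>/<kind initial><n>` with a per-kind sequential counter, so a
#' store rebuilt from the same sequence of operations mints identical
#' URIs.  With the store setting `random_uris = TRUE` the suffix is a
#' random alphanumeric string instead.
#'
#' @param store An `s3db_store`.
#' @param kind One of the seven entity kinds.
#' @return The URI string.  Minting is a pure function of the store; the
#'   counter advances when the entity is actually created.
#' @examples
#' mint_uri(s3db_store("http://example.org/demo"), "item")
#' @export
mint_uri <- function(store, kind) {
  stopifnot(inherits(store, "s3db_store"))
  check_kind(kind)
  initial <- kind_initial(kind)
  if (store$settings$random_uris) {
    repeat {
      tag <- paste(sample(c(letters, 0:9), 10, replace = TRUE), collapse = "")
      uri <- paste0(store$base_uri, "/", initial, tag)
      if (!uri %in% store$entities$uri) return(uri)
    }
  }
  n <- store$counters[[kind]] + 1L
  repeat {
    uri <- paste0(store$base_uri, "/", initial, n)
    if (!uri %in% store$entities$uri) return(uri)
    n <- n + 1L
  }
}

check_kind <- function(kind) {
  if (!kind %in% s3db_entity_kinds()$kind) {
    s3db_abort("E_USAGE", paste0("unknown entity kind: ", kind))
  }
  invisible(kind)
}

#' Resolve an entity reference to its URI
#'
#' References may be a full URI, a base-relative local name (the part
#' after `<base>/`), or an entity label (which must be unique in the
#' store).
#'
#' @param store An `s3db_store`.
#' @param ref The reference string.
#' @param kind Optional kind the resolved entity must have.
#' @return The entity URI.
#' @export
resolve_entity <- function(store, ref, kind = NULL) {
  stopifnot(inherits(store, "s3db_store"))
  ents <- store$entities
  uri <- NULL
  if (ref %in% ents$uri) {
    uri <- ref
  } else if (paste0(store$base_uri, "/", ref) %in% ents$uri) {
    uri <- paste0(store$base_uri, "/", ref)
  } else {
    hit <- which(!is.na(ents$label) & ents$label == ref)
    if (length(hit) == 1) uri <- ents$uri[hit]
    if (length(hit) > 1) {
      s3db_abort("E_USAGE", paste0("ambiguous label: ", ref))
    }
  }
  if (is.null(uri)) {
    s3db_abort("E_NOT_FOUND", paste0("no entity matches reference: ", ref))
  }
  if (!is.null(kind)) {
    k <- ents$kind[match(uri, ents$uri)]
    if (!identical(k, kind)) {
      s3db_abort("E_USAGE",
                 paste0(ref, " is a ", k, ", expected a ", kind))
    }
  }
  uri
}

entity_kind <- function(store, uri) {
  store$entities$kind[match(uri, store$entities$uri)]
}

#' Create an entity in a store
#'
#' Adds a new entity of the given kind with a minted (or explicitly
#' supplied) URI.  A store has exactly one deployment: attempting to
#' create a second raises an `E_DUP_ROOT` error.
#'
#' @param store An `s3db_store`.
#' @param kind One of the seven entity kinds.
#' @param label Optional human-readable label.
#' @param creator Optional reference to a user entity recorded as the
#'   creator; this is what gives the `self` permission state its meaning.
#' @param uri Optional explicit URI (must not collide).
#' @param external Internal flag marking a non-minted foreign resource.
#' @return The updated store; the new URI is available via [last_uri()].
#' @export
create_entity <- function(store, kind, label = NULL, creator = NULL,
                          uri = NULL, external = FALSE) {
  stopifnot(inherits(store, "s3db_store"))
  if (!external) check_kind(kind)
  if (!external && kind == "deployment" &&
      any(store$entities$kind == "deployment")) {
    s3db_abort("E_DUP_ROOT",
               "store already has a deployment root entity")
  }
  creator_uri <- NA_character_
  if (!is.null(creator)) {
    creator_uri <- resolve_entity(store, creator, kind = "user")
  }
  if (is.null(uri)) {
    uri <- mint_uri(store, kind)
    store$counters[[kind]] <- store$counters[[kind]] + 1L
  } else {
    if (!external && !grepl("^[a-zA-Z][a-zA-Z0-9+.-]*:", uri)) {
      uri <- paste0(store$base_uri, "/", uri)
    }
    if (uri %in% store$entities$uri) {
      s3db_abort("E_USAGE", paste0("URI already exists: ", uri))
    }
  }
  store$entities <- dplyr::bind_rows(
    store$entities,
    tibble::tibble(uri = uri, kind = kind,
                   label = label %||% NA_character_,
                   creator = creator_uri, external = isTRUE(external))
  )
  store$last_uri <- uri
  store
}

# Register (or find) an external, non-minted resource such as a foreign
# URI or a bare literal name used as a rule object.
register_external <- function(store, resource) {
  hit <- which(store$entities$uri == resource & store$entities$external)
  if (length(hit) == 1) {
    store$last_uri <- resource
    return(store)
  }
  create_entity(store, kind = "external", uri = resource, external = TRUE)
}

#' Assert a typed relationship between two entities
#'
#' The edge is validated against the domain/range of its relationship
#' kind: the subject's entity kind must equal the relationship's domain
#' and the object's its range, otherwise an `E_DOMAIN` / `E_RANGE` error
#' names the violated relationship.  Asserting an existing edge is a
#' no-op (set semantics); no cardinality limits apply.
#'
#' @param store An `s3db_store`.
#' @param subject,object Entity references (URI, local name, or label).
#' @param relation One of the 12 relationship kinds, e.g. `"CI"`.
#' @return The updated store.
#' @examples
#' s3db_store("http://example.org/demo") |>
#'   create_entity("project", label = "P") |>
#'   assert_relation("D1", "DP", "P1")
#' @export
assert_relation <- function(store, subject, relation, object) {
  stopifnot(inherits(store, "s3db_store"))
  rr <- relation_row(relation)
  s <- resolve_entity(store, subject)
  o <- resolve_entity(store, object)
  s_kind <- entity_kind(store, s)
  o_kind <- entity_kind(store, o)
  # A foreign resource may stand in the collection slot of Robject (a
  # rule object need not be a collection).
  s_ok <- identical(s_kind, rr$domain_kind) ||
    (rr$relation == "Robject" && identical(s_kind, "external"))
  if (!s_ok) {
    s3db_abort("E_DOMAIN", paste0(
      "relationship ", rr$relation, " (#", rr$index, ") requires a ",
      rr$domain_kind, " subject; ", s, " is a ", s_kind))
  }
  if (!identical(o_kind, rr$range_kind)) {
    s3db_abort("E_RANGE", paste0(
      "relationship ", rr$relation, " (#", rr$index, ") requires a ",
      rr$range_kind, " object; ", o, " is a ", o_kind))
  }
  new <- tibble::tibble(subject = s, relation = rr$relation, object = o)
  store$relations <- dplyr::distinct(dplyr::bind_rows(store$relations, new))
  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a
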