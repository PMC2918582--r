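#' Parameters for the synthetic store generator
#'
#' Bundles the shape knobs of [generate_random_store()] with
#' validation.  Counts are per entity kind; `membership_density` is the
#' expected number of extra collections each item joins beyond its
#' first; `literal_fraction` is the probability that a rule's object is
#' an opaque resource (literal-valued statements) rather than a
#' collection; `uu_density` is the probability of a directed `UU` link
#' between each ordered pair of users; assignments draw random targets
#' and random state strings of up to `max_tuple_depth` m-tuples.
#'
#' @param n_projects,n_collections,n_items,n_rules,n_statements,n_users
#'   Entity counts (all `>= 0`).
#' @param literal_fraction,membership_density,uu_density Probabilities
#'   in `[0, 1]`.
#' @param n_assignments Number of random operator-state assignments.
#' @param max_tuple_depth Maximum number of m-tuples in one assignment
#'   string.
#' @param dominant_fraction Probability that a sampled symbol is in its
#'   dominant (upper-case) form.
#' @param bundle Operator bundle assignments are written against.
#' @return A validated list of class `s3db_generator_params`.
#' @export
generator_params <- function(n_projects = 1, n_collections = 3,
                             n_items = 8, n_rules = 3, n_statements = 6,
                             n_users = 2, n_assignments = 3,
                             literal_fraction = 0.3,
                             membership_density = 0.3,
                             uu_density = 0,
                             max_tuple_depth = 2,
                             dominant_fraction = 0.3,
                             bundle = s3db_default_bundle()) {
  counts <- c(n_projects = n_projects, n_collections = n_collections,
              n_items = n_items, n_rules = n_rules,
              n_statements = n_statements, n_users = n_users,
              n_assignments = n_assignments)
  if (any(counts < 0)) {
    s3db_abort("E_PARAMS", "entity counts must be >= 0")
  }
  probs <- c(literal_fraction, membership_density, uu_density,
             dominant_fraction)
  if (any(probs < 0 | probs > 1)) {
    s3db_abort("E_PARAMS", "densities and fractions must lie in [0, 1]")
  }
  if (max_tuple_depth < 1) {
    s3db_abort("E_PARAMS", "max_tuple_depth must be >= 1")
  }
  if (n_collections > 0 && n_projects < 1) {
    s3db_abort("E_PARAMS", "collections need at least one project")
  }
  if (n_rules > 0 && (n_collections < 1 || n_items < 1)) {
    s3db_abort("E_PARAMS",
               "rules need at least one collection and one predicate item")
  }
  if (n_statements > 0 && n_rules < 1) {
    s3db_abort("E_PARAMS", "statements need at least one rule")
  }
  if (n_assignments > 0 && n_users < 1) {
    s3db_abort("E_PARAMS", "assignments need at least one user")
  }
  structure(
    list(n_projects = n_projects, n_collections = n_collections,
         n_items = n_items, n_rules = n_rules,
         n_statements = n_statements, n_users = n_users,
         n_assignments = n_assignments,
         literal_fraction = literal_fraction,
         membership_density = membership_density,
         uu_density = uu_density,
         max_tuple_depth = max_tuple_depth,
         dominant_fraction = dominant_fraction,
         bundle = bundle),
    class = "s3db_generator_params"
  )
}

#' Generate a random valid store with random assignments
#'
#' Builds a store of the requested approximate shape whose every
#' invariant holds by construction ([validate_store()] reports no
#' errors): projects under the deployment, collections under random
#' projects, items joining one or more random collections, rules over
#' random subject collections and predicate items (with a configurable
#' fraction of opaque-object rules), statements drawn only from rules
#' whose collections have members, users with optional `UU` links, and
#' well-formed random operator-state assignments.  Output is fully
#' deterministic for a given seed.
#'
#' @param params A [generator_params()] object (or arguments passed on
#'   to it via `...`).
#' @param seed Integer seed; same seed, same store.
#' @param ... Shape arguments forwarded to [generator_params()] when
#'   `params` is not supplied.
#' @return An `s3db_store` (assignments included; see
#'   [assignments()]).
#' @examples
#' store <- generate_random_store(seed = 1, n_items = 5)
#' validate_store(store)
#' @export
generate_random_store <- function(params = NULL, seed = 1, ...) {
  params <- params %||% generator_params(...)
  stopifnot(inherits(params, "s3db_generator_params"))
  withr::with_seed(seed, generate_store_impl(params))
}

generate_store_impl <- function(p) {
  store <- s3db_store("http://example.org/synthetic",
                      label = "synthetic deployment")
  b <- p$bundle
  users <- character(0)
  for (i in seq_len(p$n_users)) {
    store <- add_user(store, label = paste0("user ", i))
    users <- c(users, store$last_uri)
  }
  if (p$uu_density > 0 && length(users) > 1) {
    for (x in users) for (y in setdiff(users, x)) {
      if (stats::runif(1) < p$uu_density) {
        store <- assert_relation(store, x, "UU", y)
      }
    }
  }
  projects <- character(0)
  for (i in seq_len(p$n_projects)) {
    store <- add_project(store, label = paste0("project ", i))
    projects <- c(projects, store$last_uri)
  }
  colls <- character(0)
  for (i in seq_len(p$n_collections)) {
    store <- add_collection(store, sample(projects, 1),
                            label = paste0("collection ", i))
    colls <- c(colls, store$last_uri)
  }
  items <- character(0)
  for (i in seq_len(p$n_items)) {
    memberships <- if (length(colls) > 0) {
      n_extra <- stats::rbinom(1, max(length(colls) - 1, 0),
                               p$membership_density)
      sample(colls, min(1 + n_extra, length(colls)))
    } else character(0)
    store <- add_item(store, label = paste0("item ", i),
                      collections = memberships)
    items <- c(items, store$last_uri)
  }
  rules_ <- character(0)
  for (i in seq_len(p$n_rules)) {
    subj <- sample(colls, 1)
    pred <- sample(items, 1)
    obj <- if (stats::runif(1) < p$literal_fraction || length(colls) == 0) {
      paste0("http://purl.example.org/attr/", i)
    } else {
      sample(colls, 1)
    }
    store <- add_rule(store, sample(projects, 1), subj, pred, obj,
                      label = paste0("rule ", i))
    rules_ <- c(rules_, store$last_uri)
  }
  if (p$n_statements > 0) {
    ok_rule <- function(r) {
      rr <- store$rules[store$rules$uri == r, ]
      length(collection_members(store, rr$subject_collection)) > 0 &&
        (is.na(rr$object_collection) ||
           length(collection_members(store, rr$object_collection)) > 0)
    }
    usable <- rules_[vapply(rules_, ok_rule, logical(1))]
    if (length(usable) == 0) {
      s3db_abort("E_PARAMS", paste0(
        "statements requested but no rule has populated collections; ",
        "increase n_items or membership_density"))
    }
    for (i in seq_len(p$n_statements)) {
      r <- sample(usable, 1)
      rr <- store$rules[store$rules$uri == r, ]
      subj <- sample(collection_members(store, rr$subject_collection), 1)
      if (is.na(rr$object_collection)) {
        store <- add_statement(store, r, subj,
                               literal = paste0("value ", i))
      } else {
        obj <- sample(collection_members(store, rr$object_collection), 1)
        store <- add_statement(store, r, subj, object = obj)
      }
    }
  }
  if (p$n_assignments > 0) {
    targets <- store$entities$uri[!store$entities$external]
    for (i in seq_len(p$n_assignments)) {
      len <- sample(seq_len(p$max_tuple_depth * b$m), 1)
      syms <- sample(b$symbols, len, replace = TRUE)
      dom <- stats::runif(len) < p$dominant_fraction
      syms[dom] <- toupper(syms[dom])
      store <- assign_state(store, sample(users, 1), sample(targets, 1),
                            paste(syms, collapse = ""), bundle = b)
    }
  }
  store
}
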