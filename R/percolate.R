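#' Assign an operator state string to a user/entity pair
#'
#' Realizes the triple `{U f E}`: the user's relationship with the
#' target entity is described by a state string over the bundle's
#' operators.  The string is parsed and normalized (padded to whole
#' m-tuples) at assignment time.  Assigning again for the same
#' user/target adds a further string; all of them are merged during
#' percolation.
#'
#' @param store An `s3db_store`.
#' @param user Reference to a user entity.
#' @param target Reference to any entity in the store.
#' @param state The state string, e.g. `"a"` or `"abCd"`.
#' @param bundle The operator bundle the string is written against.
#' @return The updated store.
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo")) |>
#'   add_user(label = "ann") |>
#'   assign_state("ann", "C_person", "a")
#' assignments(store)
#' @export
assign_state <- function(store, user, target, state,
                         bundle = s3db_default_bundle()) {
  stopifnot(inherits(store, "s3db_store"))
  u <- resolve_entity(store, user, kind = "user")
  t <- resolve_entity(store, target)
  s <- parse_state_string(state, bundle)
  new <- tibble::tibble(user = u, target = t,
                        bundle = bundle_name(bundle), state = s)
  store$assignments <- dplyr::distinct(
    dplyr::bind_rows(store$assignments, new))
  store
}

bundle_name <- function(bundle) {
  paste(bundle$names, collapse = "-")
}

# Propagate a user's assignments across UU links: an assignment made by
# user w reaches, migrated once per UU hop, every user on a UU path
# from w.  Returns the tibble of (target, state) effective for `user`.
uu_effective_assignments <- function(store, user, bundle) {
  asg <- store$assignments
  uu <- store$relations[store$relations$relation == "UU",
                        c("subject", "object")]
  pools <- split(paste(asg$target, asg$state, sep = "\r"), asg$user)
  pools <- lapply(pools, unique)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(uu))) {
      src <- pools[[uu$subject[i]]]
      if (is.null(src)) next
      parts <- strsplit(src, "\r", fixed = TRUE)
      moved <- vapply(parts, function(p) {
        paste(p[1], migrate_state(p[2], bundle$m), sep = "\r")
      }, character(1))
      dst <- uu$object[i]
      grown <- union(pools[[dst]], moved)
      if (length(grown) > length(pools[[dst]] %||% character())) {
        pools[[dst]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mine <- pools[[user]] %||% character()
  parts <- strsplit(mine, "\r", fixed = TRUE)
  tibble::tibble(
    target = vapply(parts, `[`, character(1), 1),
    state  = vapply(parts, `[`, character(1), 2)
  )
}

#' Percolate a user's operator states to a fixed point
#'
#' Initializes a pool of state strings at each directly assigned entity
#' and then migrates every pooled string along every licensed
#' instance-graph edge, repeatedly, until the pools are closed under
#' one more migration step.  Termination is guaranteed because every
#' migrated string is a tuple-suffix of a finite set of assignments,
#' and strings of one m-tuple migrate to themselves; the fixed point is
#' independent of edge processing order.
#'
#' Effective states are not collapsed during iteration: pools keep the
#' full strings so that plural (depth-indexed) states retain their
#' expressivity, and merging is applied when reporting (see
#' [effective_state()]).
#'
#' @param store An `s3db_store`.
#' @param user Reference to the user whose assignments percolate.
#' @param bundle The operator bundle.
#' @param matrix The Boolean transition matrix (default the S3DB one).
#' @param enable_uu If `TRUE`, assignments first migrate between users
#'   along `UU` links (one migration step per hop) before entity
#'   percolation; off by default.
#' @return An object of class `s3db_pool`: a list with `pools` (named
#'   list, entity URI -> character vector of pooled strings), `user`,
#'   `bundle`, `iterations` and `enable_uu`.  Use [tidy()] for a tibble
#'   view and [effective_states()] for merged per-operator states.
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo")) |>
#'   add_user(label = "ann") |>
#'   assign_state("ann", "C_person", "a")
#' pool <- percolate(store, "ann")
#' tidy(pool)
#' @export
percolate <- function(store, user, bundle = s3db_default_bundle(),
                      matrix = s3db_transition_matrix(),
                      enable_uu = FALSE, verbose = FALSE) {
  stopifnot(inherits(store, "s3db_store"))
  u <- resolve_entity(store, user, kind = "user")
  m <- bundle$m

  if (enable_uu) {
    asg <- uu_effective_assignments(store, u, bundle)
  } else {
    asg <- store$assignments[store$assignments$user == u,
                             c("target", "state")]
  }
  pools <- list()
  for (i in seq_len(nrow(asg))) {
    s <- parse_state_string(asg$state[i], bundle)
    pools[[asg$target[i]]] <- union(pools[[asg$target[i]]], s)
  }

  edges <- instance_graph(store, matrix)
  # Entity-level UU edges are handled by the pre-step above (or
  # disabled); drop them here so user-to-user migration is not applied
  # twice.
  user_uris <- store$entities$uri[store$entities$kind == "user"]
  edges <- edges[!(edges$from %in% user_uris & edges$to %in% user_uris), ]

  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      src <- pools[[edges$from[i]]]
      if (is.null(src)) next
      moved <- vapply(src, migrate_state, character(1), m = m,
                      USE.NAMES = FALSE)
      dst <- edges$to[i]
      grown <- union(pools[[dst]], moved)
      if (length(grown) > length(pools[[dst]] %||% character())) {
        pools[[dst]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pools <- lapply(pools, function(p) sort(unique(p)))
  if (verbose) {
    message("percolate: ", nrow(store$entities), " entities, ",
            nrow(edges), " edges, ", iterations, " sweeps, ",
            sum(lengths(pools)), " pooled strings")
  }
  structure(
    list(pools = pools, user = u, bundle = bundle,
         iterations = iterations, enable_uu = isTRUE(enable_uu)),
    class = "s3db_pool"
  )
}

#' @export
print.s3db_pool <- function(x, ...) {
  cat("<s3db_pool> user ", x$user, "\n", sep = "")
  cat("  entities with states: ", length(x$pools),
      "  strings: ", sum(lengths(x$pools)),
      "  sweeps: ", x$iterations, "\n", sep = "")
  invisible(x)
}

#' Effective state of one operator at one entity
#'
#' Collects, over every string pooled at the entity, the symbol at the
#' operator's position in the first m-tuple, and merges the collected
#' set (lowest-index dominant wins, else highest-index recessive).  An
#' empty pool yields `NA` ("unassigned").
#'
#' @param pool An `s3db_pool` from [percolate()].
#' @param entity Entity URI.
#' @param operator Operator name or index within the bundle.
#' @return The merged one-letter state symbol, or `NA_character_`.
#' @export
effective_state <- function(pool, entity, operator = 1) {
  stopifnot(inherits(pool, "s3db_pool"))
  j <- operator_position(pool$bundle, operator)
  strings <- pool$pools[[entity]]
  if (is.null(strings) || length(strings) == 0) return(NA_character_)
  firsts <- vapply(strings, function(s) substr(s, j, j), character(1),
                   USE.NAMES = FALSE)
  merge_states(firsts, pool$bundle$operators[[j]])
}

operator_position <- function(bundle, operator) {
  if (is.numeric(operator)) {
    j <- as.integer(operator)
    if (j < 1 || j > bundle$m) {
      s3db_abort("E_CONFIG", paste0("operator index out of range: ", j))
    }
    return(j)
  }
  j <- match(operator, bundle$names)
  if (is.na(j)) {
    s3db_abort("E_CONFIG", paste0("unknown operator: ", operator))
  }
  j
}

#' Merged effective states for every pooled entity and operator
#'
#' @param pool An `s3db_pool`.
#' @param entities Optional character vector of entity URIs to report
#'   (default: every entity with a non-empty pool).
#' @return A tibble with columns `entity`, `operator`, `symbol`,
#'   `index`, `state` (the label) and `dominant`; entities without any
#'   pooled state report `NA` symbol/index/state ("unassigned").
#' @export
effective_states <- function(pool, entities = NULL) {
  stopifnot(inherits(pool, "s3db_pool"))
  b <- pool$bundle
  entities <- entities %||% names(pool$pools)
  grid <- tidyr::expand_grid(entity = entities, j = seq_len(b$m))
  rows <- purrr::pmap(grid, function(entity, j) {
    sym <- effective_state(pool, entity, j)
    op <- b$operators[[j]]
    if (is.na(sym)) {
      tibble::tibble(entity = entity, operator = op$name,
                     symbol = NA_character_, index = NA_integer_,
                     state = NA_character_, dominant = NA)
    } else {
      i <- state_index(sym, op)
      tibble::tibble(entity = entity, operator = op$name, symbol = sym,
                     index = i, state = op$states[i],
                     dominant = sym != tolower(sym))
    }
  })
  dplyr::bind_rows(rows)
}

#' Resolve an access decision for a user/entity/operator triple
#'
#' Maps the effective state under the default three-state alphabet
#' (`all`, `self`, `none`, indexes 1..3) to a decision: index 1 allows,
#' the last index denies, and any intermediate index is read as `self`
#' — allowed only when the entity's recorded creator is the requesting
#' user.  When no state reaches the entity the bundle's
#' `default_decision` applies (deny unless configured otherwise).
#'
#' @param store The `s3db_store` (consulted for creator metadata).
#' @param pool The user's `s3db_pool` from [percolate()].
#' @param user Reference to the requesting user.
#' @param entity Reference to the entity being accessed.
#' @param operator Operator name, e.g. `"view"`.
#' @return `TRUE` (allow) or `FALSE` (deny).
#' @export
is_allowed <- function(store, pool, user, entity, operator) {
  stopifnot(inherits(store, "s3db_store"), inherits(pool, "s3db_pool"))
  u <- resolve_entity(store, user, kind = "user")
  e <- resolve_entity(store, entity)
  j <- operator_position(pool$bundle, operator)
  sym <- effective_state(pool, e, j)
  if (is.na(sym)) {
    return(identical(pool$bundle$default_decision %||% "deny", "allow"))
  }
  op <- pool$bundle$operators[[j]]
  i <- state_index(sym, op)
  n <- length(op$states)
  if (i == 1) return(TRUE)
  if (i == n && n > 1) return(FALSE)
  creator <- store$entities$creator[match(e, store$entities$uri)]
  isTRUE(!is.na(creator) && creator == u)
}
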