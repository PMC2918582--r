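# Brute-force percolation oracle, independent of the worklist engine:
# enumerates walks by Boolean adjacency-matrix powers.  A string of t
# m-tuples contributes its k-times-migrated form to every entity
# reached by a walk of exact length k (k < t - 1), and its terminal
# one-tuple form to every entity reachable by a walk of length
# >= t - 1 (terminal strings migrate to themselves, so longer walks
# add nothing new).
oracle_pools <- function(store, user, bundle = s3db_default_bundle(),
                         matrix = s3db_transition_matrix()) {
  ents <- entities(store)
  uris <- ents$uri
  edges <- instance_graph(store, matrix)
  user_uris <- ents$uri[ents$kind == "user"]
  edges <- edges[!(edges$from %in% user_uris & edges$to %in% user_uris), ]
  A <- matrix(0L, length(uris), length(uris), dimnames = list(uris, uris))
  for (i in seq_len(nrow(edges))) A[edges$from[i], edges$to[i]] <- 1L

  u <- resolve_entity(store, user)
  asg <- assignments(store)
  asg <- asg[asg$user == u, ]
  m <- bundle$m
  pools <- list()
  addp <- function(us, s) {
    for (x in us) pools[[x]] <<- union(pools[[x]], s)
  }
  forward_closure <- function(v) {
    repeat {
      v2 <- as.integer(((v %*% A) > 0) | (v > 0))
      if (identical(v2, v)) return(v2)
      v <- v2
    }
  }
  for (i in seq_len(nrow(asg))) {
    s <- parse_state_string(asg$state[i], bundle)
    t_tuples <- nchar(s) / m
    v <- as.integer(uris == asg$target[i])
    sk <- s
    for (k in seq_len(t_tuples - 1) - 1) {   # k = 0 .. t-2
      addp(uris[v == 1], sk)
      v <- as.integer((v %*% A) > 0)
      sk <- migrate_state(sk, m)
      if (!any(v == 1)) break
    }
    # terminal one-tuple string spreads over the forward closure
    if (any(v == 1)) addp(uris[forward_closure(v) == 1], sk)
  }
  lapply(pools, function(p) sort(unique(p)))
}

pool_list <- function(pool) lapply(pool$pools, sort)

expect_same_pools <- function(a, b) {
  expect_setequal(as.character(names(a)), as.character(names(b)))
  for (n in names(a)) expect_identical(sort(a[[n]]), sort(b[[n]]))
}

# A small chain store D -> P -> C -> I -> S for depth-semantics tests.
chain_store <- function() {
  s3db_store("http://example.org/chain") |>
    add_user(label = "u") |>
    add_project(label = "p", uri = "P1") |>
    add_collection("P1", label = "c", uri = "C1") |>
    add_collection("P1", label = "obj", uri = "C2") |>
    add_item(label = "i", collections = "C1", uri = "I1") |>
    add_item(label = "o", collections = "C2", uri = "I2") |>
    add_item(label = "pred", uri = "I3") |>
    add_rule("P1", "C1", "I3", "C2", uri = "R1") |>
    add_statement("R1", "I1", object = "I2")
}
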