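one_op <- operator_bundle(operator_spec("view", c("all", "self", "none")))

test_that("a singular state reaches a collection's items and rules", {
  store <- build_mary_fixture(s3db_store("http://example.org/m")) |>
    add_user(label = "ann") |>
    assign_state("ann", "C_person", "a", bundle = one_op)
  pool <- percolate(store, "ann", bundle = one_op)
  p <- pool_list(pool)
  b <- function(x) paste0("http://example.org/m/", x)
  expect_identical(p[[b("C_person")]], "a")
  expect_identical(p[[b("I_Mary")]], "a")
  expect_identical(p[[b("R_people_in_places")]], "a")
  expect_identical(p[[b("R_people_have_names")]], "a")
  # items of the other collection are untouched
  expect_null(p[[b("I_Houston")]])
})

test_that("a plural state leaves its first tuple behind and passes the rest", {
  store <- build_mary_fixture(s3db_store("http://example.org/m")) |>
    add_user(label = "ann") |>
    assign_state("ann", "C_person", "ab", bundle = one_op)
  pool <- percolate(store, "ann", bundle = one_op)
  p <- pool_list(pool)
  b <- function(x) paste0("http://example.org/m/", x)
  expect_identical(p[[b("C_person")]], "ab")
  expect_identical(p[[b("I_Mary")]], "b")
  expect_identical(p[[b("S1")]], "b")
  expect_identical(p[[b("S2")]], "b")
  expect_identical(effective_state(pool, b("C_person"), "view"), "a")
  expect_identical(effective_state(pool, b("I_Mary"), "view"), "b")
})

test_that("percolation with no assignments yields empty pools", {
  store <- build_mary_fixture(s3db_store("http://example.org/m")) |>
    add_user(label = "ann")
  pool <- percolate(store, "ann")
  expect_identical(length(pool$pools), 0L)
  expect_identical(nrow(tidy(pool)), 0L)
  expect_identical(effective_state(pool, "http://example.org/m/I_Mary"),
                   NA_character_)
})

test_that("pooled strings merge by position; empty pools are unassigned", {
  store <- chain_store() |>
    assign_state("u", "I1", "b", bundle = one_op) |>
    assign_state("u", "I1", "c", bundle = one_op) |>
    assign_state("u", "C1", "Cb", bundle = one_op)
  pool <- percolate(store, "u", bundle = one_op)
  i1 <- "http://example.org/chain/I1"
  # pool at I1: own 'b','c' plus migrated 'b' from C1's plural 'Cb'
  expect_setequal(pool$pools[[i1]], c("b", "c"))
  expect_identical(effective_state(pool, i1, "view"), "c")
  # dominant first tuple at the collection
  expect_identical(effective_state(pool, "http://example.org/chain/C1",
                                   "view"), "C")
})

test_that("depth-indexed tuples land at the matching chain depth", {
  # chain D -> P -> C -> I -> S with a three-tuple single-operator state
  store <- chain_store() |>
    assign_state("u", "P1", "abc", bundle = one_op)
  pool <- percolate(store, "u", bundle = one_op)
  b <- function(x) paste0("http://example.org/chain/", x)
  expect_identical(pool_list(pool)[[b("P1")]], "abc")
  expect_setequal(pool$pools[[b("C1")]], "bc")
  expect_setequal(pool$pools[[b("I1")]], "c")
  expect_setequal(pool$pools[[b("S1")]], "c")
  expect_identical(effective_state(pool, b("P1"), 1), "a")
  expect_identical(effective_state(pool, b("C1"), 1), "b")
  expect_identical(effective_state(pool, b("I1"), 1), "c")
})

test_that("multi-operator strings migrate tuple-wise through the store", {
  store <- chain_store() |>
    assign_state("u", "C1", "abcbbb")   # default 3-operator bundle
  pool <- percolate(store, "u")
  b <- function(x) paste0("http://example.org/chain/", x)
  expect_identical(pool$pools[[b("C1")]], "abcbbb")
  expect_identical(pool$pools[[b("I1")]], "bbb")
  eff <- effective_states(pool, entities = b("C1"))
  expect_identical(eff$symbol, c("a", "b", "c"))
  expect_identical(eff$operator, c("view", "edit", "use"))
})

test_that("the fixed point is closed and confluent under edge reordering", {
  for (seed in 1:10) {
    store <- generate_random_store(seed = seed, n_items = 8,
                                   n_statements = 6, n_assignments = 4)
    users <- entities(store)$uri[entities(store)$kind == "user"]
    for (u in users) {
      pool <- percolate(store, u)
      # closure: one more migration sweep adds nothing
      edges <- instance_graph(store)
      for (i in seq_len(nrow(edges))) {
        src <- pool$pools[[edges$from[i]]]
        if (is.null(src)) next
        moved <- vapply(src, migrate_state, character(1), m = 3,
                        USE.NAMES = FALSE)
        expect_true(all(moved %in% pool$pools[[edges$to[i]]]))
      }
      # confluence: reversed and shuffled relation orders agree
      rev_store <- store
      rev_store$relations <- rev_store$relations[rev(seq_len(
        nrow(rev_store$relations))), ]
      shuf_store <- store
      perm <- withr::with_seed(seed + 1000,
                               sample(nrow(store$relations)))
      shuf_store$relations <- shuf_store$relations[perm, ]
      expect_same_pools(pool_list(pool),
                        pool_list(percolate(rev_store, u)))
      expect_same_pools(pool_list(pool),
                        pool_list(percolate(shuf_store, u)))
    }
  }
})

test_that("percolation matches the walk-enumeration oracle", {
  for (seed in 1:25) {
    store <- generate_random_store(seed = seed, n_items = 8,
                                   n_statements = 6, n_assignments = 4,
                                   max_tuple_depth = 3)
    users <- unique(assignments(store)$user)
    for (u in users) {
      expect_same_pools(pool_list(percolate(store, u)),
                        oracle_pools(store, u))
    }
  }
})

test_that("UU links carry assignments between users only when enabled", {
  store <- s3db_store("http://example.org/u") |>
    add_user(label = "ann", uri = "U1") |>
    add_user(label = "bob", uri = "U2") |>
    add_project(uri = "P1") |>
    add_collection("P1", uri = "C1") |>
    add_item(collections = "C1", uri = "I1") |>
    assert_relation("U1", "UU", "U2") |>
    assign_state("U1", "C1", "ab", bundle = one_op)
  # off by default: bob sees nothing
  expect_identical(length(percolate(store, "U2", bundle = one_op)$pools), 0L)
  # enabled: ann's assignment migrates one step to bob
  pool <- percolate(store, "U2", bundle = one_op, enable_uu = TRUE)
  b <- function(x) paste0("http://example.org/u/", x)
  expect_identical(pool$pools[[b("C1")]], "b")
  expect_identical(pool$pools[[b("I1")]], "b")
  # ann's own view is unchanged by the flag
  pa <- percolate(store, "U1", bundle = one_op, enable_uu = TRUE)
  expect_identical(pa$pools[[b("C1")]], "ab")
  # a UU cycle terminates (singular states migrate to themselves)
  store2 <- assert_relation(store, "U2", "UU", "U1")
  expect_identical(
    percolate(store2, "U2", bundle = one_op, enable_uu = TRUE)$pools[[
      b("C1")]], "b")
})

test_that("a dominant local assignment is an exception, not a flood", {
  store <- s3db_store("http://example.org/x") |>
    add_user(label = "ann", uri = "U1") |>
    add_project(uri = "P1") |>
    add_collection("P1", uri = "C1") |>
    add_item(collections = "C1", uri = "I1") |>
    add_item(collections = "C1", uri = "I2") |>
    add_item(collections = "C1", uri = "I3") |>
    assign_state("U1", "C1", "a", bundle = one_op) |>
    assign_state("U1", "I2", "C", bundle = one_op)
  pool <- percolate(store, "U1", bundle = one_op)
  b <- function(x) paste0("http://example.org/x/", x)
  expect_identical(effective_state(pool, b("I1"), 1), "a")
  expect_identical(effective_state(pool, b("I2"), 1), "C")  # dominant wins
  expect_identical(effective_state(pool, b("I3"), 1), "a")
})

test_that("decisions map states to allow/deny with creator-scoped self", {
  store <- s3db_store("http://example.org/x") |>
    add_user(label = "ann", uri = "U1") |>
    add_user(label = "bob", uri = "U2") |>
    add_project(uri = "P1") |>
    add_collection("P1", uri = "C1") |>
    add_item(collections = "C1", uri = "I1", creator = "U1") |>
    add_item(collections = "C1", uri = "I2", creator = "U2")
  b <- function(x) paste0("http://example.org/x/", x)
  bundle <- s3db_default_bundle()
  # index 1 ('all') allows, index 3 ('none') denies
  s1 <- assign_state(store, "U1", "C1", "a", bundle = bundle)
  p1 <- percolate(s1, "U1", bundle = bundle)
  expect_true(is_allowed(s1, p1, "U1", b("I1"), "view"))
  s3 <- assign_state(store, "U1", "C1", "c", bundle = bundle)
  p3 <- percolate(s3, "U1", bundle = bundle)
  expect_false(is_allowed(s3, p3, "U1", b("I1"), "view"))
  # index 2 ('self') allows only the creator
  s2 <- assign_state(store, "U1", "C1", "b", bundle = bundle)
  p2 <- percolate(s2, "U1", bundle = bundle)
  expect_true(is_allowed(s2, p2, "U1", b("I1"), "view"))
  expect_false(is_allowed(s2, p2, "U1", b("I2"), "view"))
  # unassigned falls back to the configured default
  p0 <- percolate(store |> assign_state("U1", "I2", "a", bundle = bundle),
                  "U1", bundle = bundle)
  expect_false(is_allowed(store, p0, "U1", b("I1"), "view"))
  allow_bundle <- s3db_default_bundle(default_decision = "allow")
  pa <- percolate(store |>
                    assign_state("U1", "I2", "a", bundle = allow_bundle),
                  "U1", bundle = allow_bundle)
  expect_true(is_allowed(store, pa, "U1", b("I1"), "view"))
  expect_error(is_allowed(s1, p1, "U1", b("I1"), "launch"),
               class = "s3db_e_config")
})

test_that("pool tidiers report per-string and summary views", {
  store <- chain_store() |> assign_state("u", "C1", "ab", bundle = one_op)
  pool <- percolate(store, "u", bundle = one_op)
  td <- tidy(pool)
  expect_identical(names(td), c("entity", "state"))
  expect_true(all(nchar(td$state) %% 1 == 0))
  gl <- glance(pool)
  expect_identical(gl$m, 1L)
  expect_identical(gl$n_strings, sum(lengths(pool$pools)))
  expect_gte(gl$iterations, 1L)
})
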