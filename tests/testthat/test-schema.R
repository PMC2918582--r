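test_that("the model exposes the 7 kinds and 12 typed relationships", {
  k <- s3db_entity_kinds()
  expect_identical(nrow(k), 7L)
  expect_identical(k$initial, c("D", "P", "C", "R", "I", "S", "U"))
  expect_identical(k$ordinal, 1:7)
  rk <- s3db_relation_kinds()
  expect_identical(nrow(rk), 12L)
  expect_identical(rk$index, 1:12)
  expect_identical(rk$relation[rk$index == 5], "Rsubject")
  expect_identical(rk$domain_kind[rk$relation == "UU"], "user")
  expect_identical(rk$range_kind[rk$relation == "UU"], "user")
})

test_that("URI minting is sequential, collision-free and replayable", {
  store <- s3db_store("http://example.org/x")
  expect_identical(mint_uri(store, "item"), "http://example.org/x/I1")
  store <- create_entity(store, "item")
  expect_identical(last_uri(store), "http://example.org/x/I1")
  store <- create_entity(store, "item")
  expect_false(last_uri(store) == "http://example.org/x/I1")
  # replaying an identical construction sequence mints identical URIs
  build <- function() {
    s3db_store("http://example.org/x") |>
      add_project(label = "p") |>
      add_collection("p", label = "c") |>
      add_item(label = "i", collections = "c")
  }
  expect_identical(entities(build())$uri, entities(build())$uri)
  # random minting never collides and stays inside the base
  r <- s3db_store("http://example.org/r", random_uris = TRUE)
  r <- create_entity(r, "item")
  r <- create_entity(r, "item")
  expect_identical(anyDuplicated(entities(r)$uri), 0L)
})

test_that("a store has exactly one deployment root", {
  store <- s3db_store("http://example.org/x")
  expect_error(create_entity(store, "deployment"), class = "s3db_e_dup_root")
})

test_that("relations enforce Table-style domain/range and are idempotent", {
  store <- s3db_store("http://example.org/x") |>
    add_project(label = "p", uri = "P1") |>
    add_collection("P1", label = "person", uri = "C1") |>
    add_item(label = "Mary", collections = "C1", uri = "I1") |>
    add_user(label = "a", uri = "U1") |>
    add_user(label = "b", uri = "U2")
  # accepted: collection CI item, user UU user
  store <- assert_relation(store, "C1", "CI", "I1")
  store <- assert_relation(store, "U1", "UU", "U2")
  expect_true(any(relations(store)$relation == "UU"))
  # rejected: item in project position
  err <- tryCatch(assert_relation(store, "I1", "PC", "C1"),
                  condition = function(e) e)
  expect_s3_class(err, "s3db_e_domain")
  expect_match(conditionMessage(err), "PC \\(#2\\)")
  expect_error(assert_relation(store, "P1", "PC", "I1"),
               class = "s3db_e_range")
  # idempotence: re-asserting leaves the store bit-identical
  before <- store
  again <- assert_relation(store, "C1", "CI", "I1")
  expect_identical(again, before)
})

test_that("an item may join many collections (many-to-many)", {
  store <- s3db_store("http://example.org/x") |> add_project(uri = "P1")
  for (k in 1:4) {
    store <- add_collection(store, "P1", uri = paste0("C", k))
  }
  store <- add_item(store, label = "shared",
                    collections = paste0("C", 1:4))
  item <- last_uri(store)
  ci <- relations(store)[relations(store)$relation == "CI", ]
  expect_identical(sum(ci$object == item), 4L)
  expect_identical(nrow(validate_store(store)), 0L)
})

test_that("rules wire PR/Rsubject/Rpredicate/Robject and type-check", {
  store <- s3db_store("http://example.org/x") |>
    add_project(uri = "P1") |>
    add_collection("P1", uri = "C_person") |>
    add_collection("P1", uri = "C_place") |>
    add_item(label = "lives in", uri = "I_lives") |>
    add_item(label = "Mary", collections = "C_person", uri = "I_Mary")
  store <- add_rule(store, "P1", "C_person", "I_lives", "C_place")
  r <- rules(store)[1, ]
  expect_identical(r$object_collection, "http://example.org/x/C_place")
  rel <- relations(store)
  for (kind in c("PR", "Rsubject", "Rpredicate", "Robject")) {
    expect_true(any(rel$relation == kind & rel$object == r$uri))
  }
  # opaque (foreign / literal-name) objects register as external
  store <- add_rule(store, "P1", "C_person", "I_lives",
                    "http://xmlns.com/foaf/0.1/firstName")
  r2 <- rules(store)[2, ]
  expect_true(is.na(r2$object_collection))
  ext <- entities(store)[entities(store)$external, ]
  expect_identical(ext$uri, "http://xmlns.com/foaf/0.1/firstName")
  # predicate must be an item; subject must be a collection
  expect_error(add_rule(store, "P1", "C_person", "C_place", "C_place"),
               class = "s3db_e_domain")
  expect_error(add_rule(store, "P1", "I_Mary", "I_lives", "C_place"),
               class = "s3db_e_domain")
})

test_that("statements enforce membership and object type", {
  store <- chain_store()
  st <- statements(store)[1, ]
  expect_identical(st$subject_item, "http://example.org/chain/I1")
  # subject outside the rule's subject collection
  expect_error(add_statement(store, "R1", "I2", object = "I2"),
               class = "s3db_e_membership")
  # object outside the rule's object collection
  store2 <- add_item(store, label = "stray", uri = "I9")
  expect_error(add_statement(store2, "R1", "I1", object = "I9"),
               class = "s3db_e_membership")
  # literal given for a collection-object rule
  expect_error(add_statement(store, "R1", "I1", literal = "x"),
               class = "s3db_e_object_type")
  # item given for an opaque-object rule
  store3 <- add_rule(store, "P1", "C1", "I3", "some:attr")
  lit_rule <- last_uri(store3)
  expect_error(add_statement(store3, lit_rule, "I1", object = "I2"),
               class = "s3db_e_object_type")
  store3 <- add_statement(store3, lit_rule, "I1", literal = "42")
  expect_identical(statements(store3)$object_literal[2], "42")
})

test_that("editing an opaque rule object never disturbs its statements", {
  store <- build_mary_fixture(s3db_store("http://example.org/m"))
  before <- statements(store)
  store2 <- update_rule_object(store, "R_people_have_names", "name")
  expect_identical(statements(store2), before)
  expect_identical(rules(store2)$object_resource[2], "name")
  expect_identical(nrow(validate_store(store2)[
    validate_store(store2)$severity == "error", ]), 0L)
  # identity edit is a no-op
  expect_identical(update_rule_object(store2, "R_people_have_names", "name"),
                   store2)
  # collection-object rules cannot be re-pointed
  expect_error(update_rule_object(store, "R_people_in_places", "x"),
               class = "s3db_e_edit_unsupported")
})

test_that("deletion refuses while dependents exist, cascades on request", {
  store <- chain_store()
  expect_error(delete_entity(store, "C1"), class = "s3db_e_dependents")
  store2 <- delete_entity(store, "C1", cascade = TRUE)
  expect_false("http://example.org/chain/C1" %in% entities(store2)$uri)
  expect_identical(nrow(rules(store2)), 0L)       # rule subjected C1
  expect_identical(nrow(statements(store2)), 0L)  # statement of that rule
  v <- validate_store(store2)
  expect_identical(nrow(v[v$severity == "error", ]), 0L)
  # a leaf deletes without cascade
  store3 <- add_item(store, label = "leaf")
  expect_silent(delete_entity(store3, last_uri(store3)))
})

test_that("validate_store reports constructed breakage with codes", {
  store <- chain_store()
  v0 <- validate_store(store)
  expect_identical(nrow(v0[v0$severity == "error", ]), 0L)
  # the predicate item joined no collection: tolerated, but flagged
  expect_true("W_PREDICATE_NO_COLLECTION" %in% v0$code)
  # silently strip Mary's membership: statement loses its backing
  broken <- store
  broken$relations <- broken$relations[
    !(broken$relations$relation == "CI" &
        broken$relations$object == "http://example.org/chain/I1"), ]
  v <- validate_store(broken)
  expect_true("E_MEMBERSHIP" %in% v$code)
  # relation with a kind mismatch
  broken2 <- store
  broken2$relations <- rbind(broken2$relations,
    tibble::tibble(subject = "http://example.org/chain/I1",
                   relation = "PC",
                   object = "http://example.org/chain/C1"))
  expect_true("E_DOMAIN" %in% validate_store(broken2)$code)
})
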