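#' Build the "Mary lives in Houston" worked example
#'
#' Populates a fresh store (deployment root only) with the canonical
#' two-tier example: a project `P_example`; collections of people and
#' places; items `Mary`, `Houston`, `lives_in` and `has`; the rule
#' "people live in places" (collection object) instantiated by the
#' statement linking Mary to Houston; and the rule "people have names"
#' whose object is the foreign resource `foaf:firstName`, instantiated
#' by a statement carrying the literal `"Mary"`.
#'
#' @param store A fresh `s3db_store` containing only its deployment.
#' @return The populated store.
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo"))
#' statements(store)
#' @export
build_mary_fixture <- function(store) {
  stopifnot(inherits(store, "s3db_store"))
  if (nrow(store$entities) != 1 ||
      store$entities$kind[1] != "deployment") {
    s3db_abort("E_FIXTURE_COLLISION",
               "the fixture must be built on a fresh store (deployment only)")
  }
  store |>
    add_project(label = "example", uri = "P_example") |>
    add_collection("P_example", label = "person", uri = "C_person") |>
    add_collection("P_example", label = "places", uri = "C_places") |>
    add_item(label = "Mary", collections = "C_person", uri = "I_Mary") |>
    add_item(label = "Houston", collections = "C_places",
             uri = "I_Houston") |>
    add_item(label = "lives in", uri = "I_lives_in") |>
    add_item(label = "has", uri = "I_has") |>
    add_rule("P_example", "C_person", "I_lives_in", "C_places",
             label = "people live in places", uri = "R_people_in_places") |>
    add_rule("P_example", "C_person", "I_has",
             "http://xmlns.com/foaf/0.1/firstName",
             label = "people have names", uri = "R_people_have_names") |>
    add_statement("R_people_in_places", "I_Mary", object = "I_Houston") |>
    add_statement("R_people_have_names", "I_Mary", literal = "Mary")
}
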