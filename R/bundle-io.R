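#' Read or write an operator bundle configuration
#'
#' Bundles are configured in YAML (or JSON): a list of operators, each
#' with a name, its ordered state labels and its one-letter symbols,
#' plus the default decision applied when no state reaches an entity.
#' The packaged default configuration
#' (`system.file("extdata", "view-edit-use.yaml", package = "s3db")`)
#' describes the View/Edit/Use permission bundle.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `s3db_bundle`.
#' @examples
#' cfg <- system.file("extdata", "view-edit-use.yaml", package = "s3db")
#' read_operator_bundle(cfg)
#' @export
read_operator_bundle <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$operators) || length(cfg$operators) == 0) {
    s3db_abort("E_CONFIG", "bundle configuration lists no operators")
  }
  ops <- lapply(cfg$operators, function(o) {
    operator_spec(o$name, unlist(o$states),
                  symbols = unlist(o$symbols %||%
                                     letters[seq_along(unlist(o$states))]))
  })
  b <- operator_bundle(ops)
  b$default_decision <- cfg$default_decision %||% "deny"
  if (!b$default_decision %in% c("deny", "allow")) {
    s3db_abort("E_CONFIG", "default_decision must be 'deny' or 'allow'")
  }
  b
}

#' @rdname read_operator_bundle
#' @param bundle An `s3db_bundle` to serialize.
#' @export
write_operator_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "s3db_bundle"))
  cfg <- list(
    operators = lapply(bundle$operators, function(o) {
      list(name = o$name, states = as.list(o$states),
           symbols = as.list(o$symbols))
    }),
    default_decision = bundle$default_decision %||% "deny"
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Dump a store to JSON
#'
#' A plain JSON rendering of the store's tables (entities, relations,
#' rules, statements, assignments) for downstream tooling; this is a
#' report format, not an interchange format — use Turtle for
#' round-tripping.
#'
#' @param store An `s3db_store`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
export_json <- function(store, path = NULL) {
  stopifnot(inherits(store, "s3db_store"))
  x <- list(base_uri = store$base_uri,
            entities = store$entities,
            relations = store$relations,
            rules = store$rules,
            statements = store$statements,
            assignments = store$assignments)
  json <- jsonlite::toJSON(x, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
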