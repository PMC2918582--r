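# Turtle/N3 interchange for s3db stores.
#
# The emitter writes a deliberately narrow dialect — one triple per
# line, @prefix declarations up front, plain or datatyped quoted
# literals — and the reader parses exactly that dialect.  The reified
# style is the normative interchange form: every entity gets an
# rdf:type triple and every relation instance an explicit s3db
# predicate.  The compact style additionally writes each statement as
# one triple whose predicate is its rule URI (the way the worked
# examples are written); compact triples are a derived convenience view
# and are skipped with a warning on import.

S3DB_NS <- "http://www.s3db.org/core#"
FOAF_NS <- "http://xmlns.com/foaf/0.1/"

turtle_prefixes <- function(base_uri) {
  c(
    paste0("@prefix s3db: <", S3DB_NS, "> ."),
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    paste0("@prefix foaf: <", FOAF_NS, "> ."),
    paste0("@prefix : <", base_uri, "/> .")
  )
}

shorten_uri <- function(uri, base_uri) {
  base <- paste0(base_uri, "/")
  ifelse(startsWith(uri, base), paste0(":", substring(uri, nchar(base) + 1)),
  ifelse(startsWith(uri, FOAF_NS),
         paste0("foaf:", substring(uri, nchar(FOAF_NS) + 1)),
         ifelse(grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", uri),
                paste0("<", uri, ">"),
                paste0("<", uri, ">"))))
}

quote_literal <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

#' Serialize a store to Turtle
#'
#' The reified style emits every entity (`rdf:type`, `rdfs:label`,
#' `s3db:createdBy`), every relation instance as an explicit
#' s3db-vocabulary triple, statement literal objects as
#' `s3db:literalObject`, and operator assignments as datatyped
#' `s3db:operator` literals packing `target|bundle|state`.  The compact
#' style additionally writes each statement as one triple whose
#' predicate is the rule URI — `:I_Mary :R_people_in_places :I_Houston`
#' — mirroring how the two-tier pattern reads in N3.
#'
#' @param store An `s3db_store`.
#' @param style `"reified"` (round-trippable, the default) or
#'   `"compact"` (reified plus the derived statement triples).
#' @return A character vector of Turtle lines (class `s3db_turtle`).
#' @seealso [write_turtle()], [import_turtle()]
#' @examples
#' store <- build_mary_fixture(s3db_store("http://example.org/demo"))
#' head(export_turtle(store, style = "compact"))
#' @export
export_turtle <- function(store, style = c("reified", "compact")) {
  stopifnot(inherits(store, "s3db_store"))
  style <- match.arg(style)
  sh <- function(u) shorten_uri(u, store$base_uri)
  lines <- turtle_prefixes(store$base_uri)
  lines <- c(lines, "")

  ents <- store$entities
  for (i in seq_len(nrow(ents))) {
    subj <- sh(ents$uri[i])
    if (ents$external[i]) {
      lines <- c(lines, paste0(subj, " rdf:type rdfs:Resource ."))
    } else {
      lines <- c(lines, paste0(subj, " rdf:type s3db:", ents$kind[i], " ."))
    }
    if (!is.na(ents$label[i])) {
      lines <- c(lines, paste0(subj, " rdfs:label ",
                               quote_literal(ents$label[i]), " ."))
    }
    if (!is.na(ents$creator[i])) {
      lines <- c(lines, paste0(subj, " s3db:createdBy ",
                               sh(ents$creator[i]), " ."))
    }
  }

  rels <- store$relations
  for (i in seq_len(nrow(rels))) {
    lines <- c(lines, paste0(sh(rels$subject[i]), " s3db:",
                             rels$relation[i], " ", sh(rels$object[i]), " ."))
  }

  sts <- store$statements
  for (i in seq_len(nrow(sts))) {
    if (!is.na(sts$object_literal[i])) {
      lines <- c(lines, paste0(sh(sts$uri[i]), " s3db:literalObject ",
                               quote_literal(sts$object_literal[i]), " ."))
    }
  }

  asg <- store$assignments
  for (i in seq_len(nrow(asg))) {
    packed <- paste(asg$target[i], asg$bundle[i], asg$state[i], sep = "|")
    lines <- c(lines, paste0(sh(asg$user[i]), " s3db:operator ",
                             quote_literal(packed), "^^s3db:assignment ."))
  }

  if (style == "compact") {
    lines <- c(lines, "")
    for (i in seq_len(nrow(sts))) {
      obj <- if (!is.na(sts$object_item[i])) sh(sts$object_item[i])
             else quote_literal(sts$object_literal[i])
      lines <- c(lines, paste0(sh(sts$subject_item[i]), " ",
                               sh(sts$rule[i]), " ", obj, " ."))
    }
  }
  structure(lines, class = "s3db_turtle")
}

#' @rdname export_turtle
#' @param path File path to write to.
#' @export
write_turtle <- function(store, path, style = c("reified", "compact")) {
  writeLines(export_turtle(store, style = match.arg(style)), path)
  invisible(path)
}

# --- parsing ---------------------------------------------------------------

parse_turtle_lines <- function(lines) {
  prefixes <- character()
  triples <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line,
        regexec("^@prefix\\s+([A-Za-z0-9_-]*):\\s+<([^>]*)>\\s+\\.$", line))[[1]]
      if (length(m) != 3) {
        s3db_abort("E_PARSE", paste0("bad @prefix at line ", ln, ": ", line))
      }
      prefixes[m[2]] <- m[3]
      next
    }
    m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$",
                                  line))[[1]]
    if (length(m) != 4) {
      s3db_abort("E_PARSE", paste0("unparseable triple at line ", ln,
                                   ": ", line))
    }
    triples[[length(triples) + 1]] <- list(
      subject = m[2], predicate = m[3], object = m[4], line = ln)
  }
  list(prefixes = prefixes, triples = triples)
}

expand_term <- function(term, prefixes) {
  if (startsWith(term, "<") && endsWith(term, ">")) {
    return(list(type = "uri", value = substr(term, 2, nchar(term) - 1)))
  }
  if (startsWith(term, '"')) {
    m <- regmatches(term,
      regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(\\S+))?$', term,
              perl = TRUE))[[1]]
    if (length(m) == 0) {
      s3db_abort("E_PARSE", paste0("bad literal: ", term))
    }
    val <- gsub('\\\\"', '"', m[2])
    val <- gsub("\\\\\\\\", "\\\\", val)
    return(list(type = "literal", value = val,
                datatype = if (nzchar(m[3])) m[3] else NA_character_))
  }
  colon <- regexpr(":", term, fixed = TRUE)
  if (colon > 0) {
    pfx <- substr(term, 1, colon - 1)
    local <- substring(term, colon + 1)
    hit <- which(names(prefixes) == pfx)
    if (length(hit) == 1) {
      return(list(type = "uri", value = paste0(prefixes[hit], local)))
    }
  }
  list(type = "uri", value = term)
}

#' Read a store back from its Turtle serialization
#'
#' Parses the reified s3db dialect emitted by [export_turtle()] and
#' reconstructs the store: entity kinds from `rdf:type`, labels,
#' creators, the 12 relationship kinds (validated against their
#' domain/range — typing violations abort the import listing the
#' offenders), rule and statement records rebuilt from their component
#' relations, literal statement objects and operator assignments.
#' Subjects from foreign namespaces are registered as external
#' resources.  Triples with unknown predicates (including compact-style
#' statement triples) are skipped with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param x Path to a Turtle file, or a character vector of lines.
#' @param strict Error on unknown predicates instead of warning.
#' @param bundle Operator bundle used to re-validate assignment strings.
#' @return An `s3db_store`.
#' @export
import_turtle <- function(x, strict = FALSE,
                          bundle = s3db_default_bundle()) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  doc <- parse_turtle_lines(lines)
  base_pfx <- doc$prefixes[names(doc$prefixes) == ""]
  if (length(base_pfx) != 1) {
    s3db_abort("E_PARSE", "document lacks a base (':') prefix declaration")
  }
  base_uri <- sub("/+$", "", unname(base_pfx))

  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  rdfs_label <- "http://www.w3.org/2000/01/rdf-schema#label"
  rdfs_resource <- "http://www.w3.org/2000/01/rdf-schema#Resource"
  kinds <- s3db_entity_kinds()$kind
  rels12 <- s3db_relation_kinds()$relation

  subj_of <- function(tr) expand_term(tr$subject, doc$prefixes)$value
  pred_of <- function(tr) expand_term(tr$predicate, doc$prefixes)$value

  ents <- tibble::tibble(uri = character(), kind = character(),
                         label = character(), creator = character(),
                         external = logical())
  deferred <- list()   # non-type triples, processed in pass 2
  for (tr in doc$triples) {
    p <- pred_of(tr)
    if (p == rdf_type) {
      obj <- expand_term(tr$object, doc$prefixes)
      s <- subj_of(tr)
      if (obj$value == rdfs_resource) {
        ents <- dplyr::bind_rows(ents, tibble::tibble(
          uri = s, kind = "external", label = NA_character_,
          creator = NA_character_, external = TRUE))
      } else if (startsWith(obj$value, S3DB_NS)) {
        kind <- substring(obj$value, nchar(S3DB_NS) + 1)
        if (!kind %in% kinds) {
          s3db_abort("E_PARSE", paste0("unknown entity kind: ", kind))
        }
        ents <- dplyr::bind_rows(ents, tibble::tibble(
          uri = s, kind = kind, label = NA_character_,
          creator = NA_character_, external = FALSE))
      } else {
        warn_or_stop(strict, paste0("skipping foreign type: ", tr$object))
      }
    } else {
      deferred[[length(deferred) + 1]] <- tr
    }
  }
  ents <- dplyr::distinct(ents)

  store <- structure(
    list(base_uri = base_uri, entities = ents,
         relations = tibble::tibble(subject = character(),
                                    relation = character(),
                                    object = character()),
         rules = tibble::tibble(uri = character(),
                                subject_collection = character(),
                                predicate_item = character(),
                                object_collection = character(),
                                object_resource = character()),
         statements = tibble::tibble(uri = character(), rule = character(),
                                     subject_item = character(),
                                     object_item = character(),
                                     object_literal = character()),
         assignments = tibble::tibble(user = character(),
                                      target = character(),
                                      bundle = character(),
                                      state = character()),
         counters = stats::setNames(integer(length(kinds)), kinds),
         settings = list(random_uris = FALSE),
         last_uri = NA_character_),
    class = "s3db_store")

  literal_objects <- list()
  typing_errors <- character()
  for (tr in deferred) {
    p <- pred_of(tr)
    s <- subj_of(tr)
    obj <- expand_term(tr$object, doc$prefixes)
    if (p == rdfs_label && obj$type == "literal") {
      i <- match(s, store$entities$uri)
      if (!is.na(i)) store$entities$label[i] <- obj$value
      next
    }
    if (p == paste0(S3DB_NS, "createdBy")) {
      i <- match(s, store$entities$uri)
      if (!is.na(i)) store$entities$creator[i] <- obj$value
      next
    }
    if (p == paste0(S3DB_NS, "literalObject") && obj$type == "literal") {
      literal_objects[[s]] <- obj$value
      next
    }
    if (p == paste0(S3DB_NS, "operator") && obj$type == "literal") {
      parts <- strsplit(obj$value, "|", fixed = TRUE)[[1]]
      if (length(parts) != 3) {
        warn_or_stop(strict, paste0("malformed assignment literal: ",
                                    obj$value))
        next
      }
      st <- parse_state_string(parts[3], bundle)
      store$assignments <- dplyr::bind_rows(store$assignments,
        tibble::tibble(user = s, target = parts[1], bundle = parts[2],
                       state = st))
      next
    }
    if (startsWith(p, S3DB_NS) &&
        substring(p, nchar(S3DB_NS) + 1) %in% rels12) {
      rel <- substring(p, nchar(S3DB_NS) + 1)
      # Foreign-namespace subjects become external resources.
      if (!s %in% store$entities$uri) {
        store <- create_entity(store, "external", uri = s, external = TRUE)
        warn_or_stop(FALSE, paste0("registered foreign subject as ",
                                   "external resource: ", s))
      }
      res <- tryCatch(assert_relation(store, s, rel, obj$value),
                      s3db_e_domain = function(e) e,
                      s3db_e_range = function(e) e,
                      s3db_e_not_found = function(e) e)
      if (inherits(res, "condition")) {
        typing_errors <- c(typing_errors, conditionMessage(res))
      } else {
        store <- res
      }
      next
    }
    warn_or_stop(strict, paste0("skipping unknown predicate: ",
                                tr$predicate))
  }
  if (length(typing_errors) > 0) {
    s3db_abort("E_IMPORT", paste0(
      "import found ", length(typing_errors), " typing violation(s):\n",
      paste(typing_errors, collapse = "\n")))
  }

  store <- rebuild_records(store, literal_objects)
  store$counters <- recount_uris(store)
  store
}

warn_or_stop <- function(strict, msg) {
  if (strict) s3db_abort("E_IMPORT", msg) else rlang::warn(msg)
}

# Reconstruct rule and statement records from their component relations.
rebuild_records <- function(store, literal_objects) {
  rels <- store$relations
  pick1 <- function(rel, obj) {
    hits <- rels$subject[rels$relation == rel & rels$object == obj]
    if (length(hits) >= 1) hits[1] else NA_character_
  }
  rule_uris <- store$entities$uri[store$entities$kind == "rule"]
  rule_rows <- lapply(rule_uris, function(r) {
    obj <- pick1("Robject", r)
    is_coll <- !is.na(obj) &&
      identical(entity_kind(store, obj), "collection")
    tibble::tibble(
      uri = r,
      subject_collection = pick1("Rsubject", r),
      predicate_item = pick1("Rpredicate", r),
      object_collection = if (is_coll) obj else NA_character_,
      object_resource = if (is_coll) NA_character_ else obj)
  })
  store$rules <- dplyr::bind_rows(store$rules, rule_rows)

  st_uris <- store$entities$uri[store$entities$kind == "statement"]
  st_rows <- lapply(st_uris, function(s) {
    lit <- literal_objects[[s]]
    tibble::tibble(
      uri = s,
      rule = pick1("Spredicate", s),
      subject_item = pick1("Ssubject", s),
      object_item = pick1("Sobject", s),
      object_literal = if (is.null(lit)) NA_character_ else lit)
  })
  store$statements <- dplyr::bind_rows(store$statements, st_rows)
  store
}

# Continue sequential minting above any imported numeric suffix.
recount_uris <- function(store) {
  kinds <- s3db_entity_kinds()
  counters <- stats::setNames(integer(nrow(kinds)), kinds$kind)
  base <- paste0(store$base_uri, "/")
  local <- store$entities$uri[startsWith(store$entities$uri, base)]
  local <- substring(local, nchar(base) + 1)
  for (i in seq_len(nrow(kinds))) {
    pat <- paste0("^", kinds$initial[i], "([0-9]+)$")
    hits <- regmatches(local, regexec(pat, local))
    ns <- vapply(hits, function(h) {
      if (length(h) == 2) as.integer(h[2]) else NA_integer_
    }, integer(1))
    counters[[kinds$kind[i]]] <-
      if (all(is.na(ns))) 0L else max(ns, na.rm = TRUE)
  }
  counters
}
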