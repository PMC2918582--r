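#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a percolation pool
#'
#' @param x An `s3db_pool` from [percolate()].
#' @param ... Unused.
#' @return A tibble with one row per pooled string: `entity`, `state`.
#' @export
tidy.s3db_pool <- function(x, ...) {
  if (length(x$pools) == 0) {
    return(tibble::tibble(entity = character(), state = character()))
  }
  tibble::tibble(
    entity = rep(names(x$pools), lengths(x$pools)),
    state = unlist(x$pools, use.names = FALSE)
  )
}

#' @rdname tidy.s3db_pool
#' @return For `glance()`: a one-row tibble with `user`, `m`,
#'   `n_entities`, `n_strings`, `iterations`, `enable_uu`.
#' @export
glance.s3db_pool <- function(x, ...) {
  tibble::tibble(
    user = x$user,
    m = x$bundle$m,
    n_entities = length(x$pools),
    n_strings = sum(lengths(x$pools)),
    iterations = x$iterations,
    enable_uu = x$enable_uu
  )
}

#' Tidy a store into its entity table
#'
#' @param x An `s3db_store`.
#' @param ... Unused.
#' @return `tidy()`: the entities tibble with a `local` column (the
#'   base-relative name).  `glance()`: a one-row tibble of counts.
#' @export
tidy.s3db_store <- function(x, ...) {
  base <- paste0(x$base_uri, "/")
  dplyr::mutate(
    x$entities,
    local = ifelse(startsWith(.data$uri, base),
                   substring(.data$uri, nchar(base) + 1), .data$uri)
  )
}

#' @rdname tidy.s3db_store
#' @export
glance.s3db_store <- function(x, ...) {
  kinds <- s3db_entity_kinds()$kind
  counts <- table(factor(x$entities$kind, levels = kinds))
  out <- tibble::as_tibble(as.list(as.integer(counts)),
                           .name_repair = "minimal")
  names(out) <- kinds
  dplyr::mutate(out,
                external = sum(x$entities$external),
                relations = nrow(x$relations),
                assignments = nrow(x$assignments))
}
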