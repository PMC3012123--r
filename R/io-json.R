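#' Save and load the native store document
#'
#' The native persistence format is a single UTF-8 JSON document with one
#' array per record type and stable key ordering, so stores diff cleanly
#' under version control. `read_onto(write_onto(store, path))` is
#' record-for-record identical to `store`.
#'
#' @param store An `onto_store`.
#' @param path File path (or connection for `write_onto`).
#' @return `write_onto` returns `store` invisibly; `read_onto` returns the
#'   store.
#' @export
write_onto <- function(store, path) {
  assert_store(store)
  writeLines(format_onto_json(store), path, useBytes = TRUE)
  invisible(store)
}

format_onto_json <- function(store) {
  doc <- list(
    format = "ontosensu-store/1",
    config = store$config,
    counters = store$counters,
    references = df_rows(store$references),
    concepts = df_rows(store$concepts),
    terms = df_rows(store$terms),
    rel_types = df_rows(store$rel_types),
    relationships = df_rows(store$relationships),
    sensus = df_rows(store$sensus),
    tags = df_rows(store$tags)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", na = "null",
                   pretty = TRUE, digits = NA)
}

# tibble -> list of row-objects; NA -> NULL (serialized as null), list
# columns (referent sets) kept as arrays.
df_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    out <- list()
    for (nm in names(row)) {
      v <- row[[nm]]
      if (is.list(v)) {
        out[[nm]] <- I(v[[1]])
      } else if (length(v) == 1 && is.na(v)) {
        out[nm] <- list(NULL)
      } else {
        out[[nm]] <- v
      }
    }
    out
  })
}

#' @rdname write_onto
#' @export
read_onto <- function(path) {
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      abort_onto(paste0("Malformed store document: ", conditionMessage(e)),
                 "onto_error_parse", parent = e)
    })
  if (!identical(doc$format, "ontosensu-store/1")) {
    abort_onto("Not an ontosensu store document (missing format marker).",
               "onto_error_parse")
  }
  store <- onto_store(
    id_prefix = doc$config$id_prefix %||% "HAO",
    keywords = unlist(doc$config$keywords) %||% default_keywords()
  )
  store$counters <- rebuild_counters(doc$counters)
  store$references <- rows_df(doc$references, list(
    ref_id = "c", citation = "c", year = "i", authors = "c"))
  store$concepts <- rows_df(doc$concepts, list(
    uid = "c", public_id = "c", status = "c", genus = "c", differentia = "c"))
  store$terms <- rows_df(doc$terms, list(
    uid = "c", text = "c", language = "c"))
  store$rel_types <- rows_df(doc$rel_types, list(
    name = "c", is_transitive = "l", is_hierarchy = "l"))
  store$relationships <- rows_df(doc$relationships, list(
    rel_id = "c", subject = "c", rel_type = "c", object = "c"))
  store$sensus <- rows_df(doc$sensus, list(
    sensu_id = "c", term = "c", referent = "L", reference = "c",
    order_rank = "i", obo_label = "l"))
  store$tags <- rows_df(doc$tags, list(
    tag_id = "c", target = "c", keyword = "c", note = "c",
    reference = "c", figure_uri = "c"))
  store
}

rebuild_counters <- function(counters) {
  if (is.null(counters)) return(list())
  out <- lapply(counters, function(v) {
    if (is.list(v)) lapply(v, as.integer) else as.integer(v)
  })
  out
}

rows_df <- function(rows, schema) {
  cast <- list(
    c = function(v) if (is.null(v)) NA_character_ else as.character(v),
    i = function(v) if (is.null(v)) NA_integer_ else as.integer(v),
    l = function(v) if (is.null(v)) NA else as.logical(v)
  )
  cols <- lapply(names(schema), function(nm) {
    kind <- schema[[nm]]
    if (kind == "L") {
      lapply(rows, function(r) as.character(unlist(r[[nm]])))
    } else {
      vapply(rows, function(r) cast[[kind]](r[[nm]]),
             cast[[kind]](NULL))
    }
  })
  names(cols) <- names(schema)
  if (length(rows) == 0) {
    empty <- list(c = character(), i = integer(), l = logical(), L = list())
    cols <- lapply(schema, function(kind) empty[[kind]])
  }
  tibble::as_tibble(cols)
}
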