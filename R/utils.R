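# Internal helpers shared across modules.

# Canonical key for a referent concept set: member uids sorted and joined.
# Referent equality throughout the package is exact set equality on this key.
referent_key <- function(uids) {
  paste(sort(unique(uids)), collapse = "+")
}

referent_keys <- function(referent_list) {
  vapply(referent_list, referent_key, character(1))
}

# Subset-or-superset test for two referent keys (nested-homonym flag).
referents_nested <- function(a, b) {
  sa <- strsplit(a, "+", fixed = TRUE)[[1]]
  sb <- strsplit(b, "+", fixed = TRUE)[[1]]
  all(sa %in% sb) || all(sb %in% sa)
}

abort_onto <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "onto_error"), ...)
}

`%||%` <- rlang::`%||%`

# scalar NA-safe coalesce for optional character fields
chr1 <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) NA_character_
  else as.character(x)[1]
}

int1 <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) NA_integer_
  else as.integer(x)[1]
}

assert_store <- function(store, arg = "store") {
  if (!inherits(store, "onto_store")) {
    abort_onto(sprintf("`%s` must be an onto_store object.", arg),
               "onto_error_type")
  }
  invisible(store)
}

# Resolve a term given either its uid or its (unique) label text.
resolve_term_uid <- function(store, term) {
  terms <- store$terms
  if (term %in% terms$uid) return(term)
  hits <- terms$uid[terms$text == term]
  if (length(hits) == 1) return(hits)
  if (length(hits) > 1) {
    abort_onto(sprintf("Term text '%s' is ambiguous across languages; use a uid (%s).",
                       term, paste(hits, collapse = ", ")),
               "onto_error_lookup")
  }
  abort_onto(sprintf("Unknown term '%s'.", term), "onto_error_lookup")
}

resolve_concept_uid <- function(store, concept) {
  cc <- store$concepts
  if (concept %in% cc$uid) return(concept)
  hits <- cc$uid[!is.na(cc$public_id) & cc$public_id == concept]
  if (length(hits) == 1) return(hits)
  abort_onto(sprintf("Unknown concept '%s'.", concept), "onto_error_lookup")
}

# All uids usable as tag targets, across record tables.
all_record_ids <- function(store) {
  c(store$concepts$uid, store$terms$uid, store$sensus$sensu_id,
    store$relationships$rel_id, store$references$ref_id, store$tags$tag_id)
}

uid_prefixes <- c(concept = "c", term = "t", reference = "ref",
                  sensu = "s", relationship = "rel", tag = "tag")

new_uid <- function(store, kind) {
  n <- store$counters[[kind]] %||% 0L
  list(uid = paste0(uid_prefixes[[kind]], n + 1L), n = n + 1L)
}
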