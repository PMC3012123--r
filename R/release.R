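#' Release a candidate concept
#'
#' A candidate concept becomes part of the public ontology once it is
#' suitably documented: it must carry a genus-differentia definition, be
#' associated with at least one label via a sensu whose referent is exactly
#' this concept, and have at least one `is_a` relationship to another
#' concept. Release assigns the next unused 7-digit zero-padded serial under
#' `id_prefix` (e.g. `HAO:0000312`); allocation is strictly increasing and
#' gap-free within a store session.
#'
#' @param store An `onto_store`.
#' @param concept Concept uid.
#' @param id_prefix Namespace prefix; defaults to the store configuration.
#' @return The updated store, with the concept released.
#' @export
release_concept <- function(store, concept, id_prefix = NULL) {
  assert_store(store)
  id_prefix <- id_prefix %||% store$config$id_prefix
  concept <- resolve_concept_uid(store, concept)
  row <- store$concepts[store$concepts$uid == concept, ]
  if (row$status == "released") {
    abort_onto(sprintf("Concept '%s' is already released (%s).",
                       concept, row$public_id), "onto_error_release")
  }
  failed <- character()
  if (is.na(row$genus) || is.na(row$differentia)) {
    failed <- c(failed, "genus-differentia definition missing")
  }
  keys <- referent_keys(store$sensus$referent)
  if (!any(keys == concept)) {
    failed <- c(failed, "no sensu links a label to exactly this concept")
  }
  isa <- store$relationships$rel_type == "is_a" &
    store$relationships$subject == concept
  if (!any(isa)) {
    failed <- c(failed, "no is_a relationship to a parent concept")
  }
  if (length(failed)) {
    abort_onto(
      sprintf("Concept '%s' cannot be released: %s.",
              concept, paste(failed, collapse = "; ")),
      "onto_error_release", failed_checks = failed)
  }
  serial <- next_serial(store, id_prefix)
  store$counters$serial <- store$counters$serial %||% list()
  store$counters$serial[[id_prefix]] <- serial
  store$concepts$status[store$concepts$uid == concept] <- "released"
  store$concepts$public_id[store$concepts$uid == concept] <-
    sprintf("%s:%07d", id_prefix, serial)
  store
}

next_serial <- function(store, id_prefix) {
  counted <- store$counters$serial[[id_prefix]] %||% 0L
  pat <- paste0("^", id_prefix, ":[0-9]{7}$")
  ids <- store$concepts$public_id
  used <- ids[!is.na(ids) & grepl(pat, ids)]
  existing <- if (length(used)) max(as.integer(sub(".*:", "", used))) else 0L
  max(counted, existing) + 1L
}
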