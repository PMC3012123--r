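#' Create an empty ontology store
#'
#' An `onto_store` is the in-memory curation database: one tibble per record
#' type (concepts, terms, references, relationship types, relationships,
#' sensus, tags) plus configuration. Concepts are anatomical classes with an
#' optional public identifier and a genus-differentia definition; terms are
#' bare language-tagged labels; a *sensu* is the triple (reference, referent
#' concept set, term) recording how a publication used a label, and is the
#' unit from which synonymy and homonymy are inferred.
#'
#' All `add_*()` verbs take the store first and return the updated store, so
#' curation steps chain with the pipe. Every mutation is validated against
#' the store invariants (identifier uniqueness, hierarchy acyclicity,
#' controlled tag vocabulary) at insertion time.
#'
#' @param id_prefix Default namespace prefix for public identifiers assigned
#'   at release, e.g. `"HAO"`.
#' @param keywords Controlled vocabulary for [add_tag()] keywords.
#' @return An object of class `onto_store`.
#' @examples
#' store <- onto_store() |>
#'   add_concept(uid = "leg") |>
#'   add_term("leg")
#' store
#' @export
onto_store <- function(id_prefix = "HAO", keywords = default_keywords()) {
  structure(
    list(
      concepts = tibble::tibble(
        uid = character(), public_id = character(), status = character(),
        genus = character(), differentia = character()
      ),
      terms = tibble::tibble(
        uid = character(), text = character(), language = character()
      ),
      references = tibble::tibble(
        ref_id = character(), citation = character(),
        year = integer(), authors = character()
      ),
      rel_types = tibble::tibble(
        name = c("is_a", "part_of", "attaches_to"),
        is_transitive = c(TRUE, TRUE, FALSE),
        is_hierarchy = c(TRUE, TRUE, FALSE)
      ),
      relationships = tibble::tibble(
        rel_id = character(), subject = character(),
        rel_type = character(), object = character()
      ),
      sensus = tibble::tibble(
        sensu_id = character(), term = character(),
        referent = list(), reference = character(),
        order_rank = integer(), obo_label = logical()
      ),
      tags = tibble::tibble(
        tag_id = character(), target = character(), keyword = character(),
        note = character(), reference = character(), figure_uri = character()
      ),
      config = list(id_prefix = id_prefix, keywords = keywords),
      counters = list()
    ),
    class = "onto_store"
  )
}

#' Default tag keyword vocabulary
#'
#' The configurable controlled vocabulary from which tag keywords are drawn:
#' cross-references, workflow states and annotation kinds typical of
#' collaborative ontology curation.
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  c("xref", "alternative_definition", "quarantined", "needs_review",
    "questionable_definition", "external_candidate", "note")
}

#' @export
print.onto_store <- function(x, ...) {
  cat("<onto_store> prefix:", x$config$id_prefix, "\n")
  cat(sprintf(
    "  %d concepts (%d released), %d terms, %d references, %d relationships, %d sensus, %d tags\n",
    nrow(x$concepts), sum(x$concepts$status == "released"), nrow(x$terms),
    nrow(x$references), nrow(x$relationships), nrow(x$sensus), nrow(x$tags)
  ))
  invisible(x)
}

bump <- function(store, kind, uid = NULL) {
  if (is.null(uid)) {
    g <- new_uid(store, kind)
    store$counters[[kind]] <- g$n
    list(store = store, uid = g$uid)
  } else {
    list(store = store, uid = as.character(uid))
  }
}

check_uid_free <- function(store, uid) {
  if (uid %in% all_record_ids(store)) {
    abort_onto(sprintf("Identifier '%s' is already in use.", uid),
               "onto_error_duplicate")
  }
}

#' Add a bibliographic reference
#'
#' @param store An `onto_store`.
#' @param citation Free-text citation.
#' @param year,authors Optional metadata.
#' @param ref_id Optional explicit identifier (auto-generated otherwise).
#' @return The updated store.
#' @export
add_reference <- function(store, citation, year = NULL, authors = NULL,
                          ref_id = NULL) {
  assert_store(store)
  b <- bump(store, "reference", ref_id)
  store <- b$store
  check_uid_free(store, b$uid)
  store$references <- dplyr::bind_rows(
    store$references,
    tibble::tibble(ref_id = b$uid, citation = as.character(citation),
                   year = int1(year), authors = chr1(authors))
  )
  store
}

#' Add an anatomical concept
#'
#' Concepts normally enter the store as candidates (status `"candidate"`)
#' and gain a public identifier through [release_concept()]. A concept may be
#' created directly as released -- the route used for pre-defined upper
#' (root) classes -- in which case a `public_id` and definition must be
#' supplied up front.
#'
#' @param store An `onto_store`.
#' @param uid Optional explicit internal identifier.
#' @param genus uid of the parent concept in the genus-differentia
#'   definition ("a *genus* that *differentia*").
#' @param differentia Free-text differentia.
#' @param status `"candidate"` (default) or `"released"`.
#' @param public_id Public identifier (`PREFIX:NNNNNNN`); required when
#'   creating a released concept, otherwise assigned at release.
#' @return The updated store.
#' @export
add_concept <- function(store, uid = NULL, genus = NULL, differentia = NULL,
                        status = c("candidate", "released"), public_id = NULL) {
  assert_store(store)
  status <- match.arg(status)
  b <- bump(store, "concept", uid)
  store <- b$store
  check_uid_free(store, b$uid)
  genus <- chr1(genus)
  public_id <- chr1(public_id)
  if (!is.na(genus) && !genus %in% store$concepts$uid) {
    abort_onto(sprintf("Genus concept '%s' not found.", genus),
               "onto_error_lookup")
  }
  if (!is.na(public_id)) check_public_id(store, public_id)
  if (status == "released") {
    if (is.na(public_id) || is.null(differentia)) {
      abort_onto(
        "A concept created as released needs a public_id and a definition.",
        "onto_error_invariant")
    }
  }
  store$concepts <- dplyr::bind_rows(
    store$concepts,
    tibble::tibble(uid = b$uid, public_id = public_id, status = status,
                   genus = genus, differentia = chr1(differentia))
  )
  store
}

check_public_id <- function(store, public_id) {
  if (!grepl("^[A-Za-z_]+:[0-9]{7}$", public_id)) {
    abort_onto(sprintf(
      "public_id '%s' does not match PREFIX:NNNNNNN (7-digit serial).",
      public_id), "onto_error_invariant")
  }
  if (public_id %in% store$concepts$public_id) {
    abort_onto(sprintf("public_id '%s' is already assigned.", public_id),
               "onto_error_duplicate")
  }
}

#' Add a term (label)
#'
#' A term is a bare language-tagged label; it carries no concept linkage
#' itself -- usage is recorded separately via [add_sensu()].
#'
#' @param store An `onto_store`.
#' @param text Label text.
#' @param language ISO language code.
#' @param uid Optional explicit internal identifier.
#' @return The updated store.
#' @export
add_term <- function(store, text, language = "en", uid = NULL) {
  assert_store(store)
  b <- bump(store, "term", uid)
  store <- b$store
  check_uid_free(store, b$uid)
  if (any(store$terms$text == text & store$terms$language == language)) {
    abort_onto(sprintf("Term ('%s', %s) already exists.", text, language),
               "onto_error_duplicate")
  }
  store$terms <- dplyr::bind_rows(
    store$terms,
    tibble::tibble(uid = b$uid, text = as.character(text),
                   language = as.character(language))
  )
  store
}

#' Add a relationship type
#'
#' Built-ins `is_a` and `part_of` (transitive hierarchy relations) and
#' `attaches_to` (non-hierarchy) are present in every store; further types
#' can be declared here. Hierarchy relations participate in acyclicity
#' checking and in property propagation.
#'
#' @param store An `onto_store`.
#' @param name Relation name.
#' @param is_transitive,is_hierarchy Logical flags.
#' @return The updated store.
#' @export
add_rel_type <- function(store, name, is_transitive = FALSE,
                         is_hierarchy = FALSE) {
  assert_store(store)
  if (name %in% store$rel_types$name) {
    abort_onto(sprintf("Relationship type '%s' already exists.", name),
               "onto_error_duplicate")
  }
  store$rel_types <- dplyr::bind_rows(
    store$rel_types,
    tibble::tibble(name = name, is_transitive = isTRUE(is_transitive),
                   is_hierarchy = isTRUE(is_hierarchy))
  )
  store
}

hierarchy_types <- function(store) {
  store$rel_types$name[store$rel_types$is_hierarchy]
}

hierarchy_edges <- function(store) {
  dplyr::filter(store$relationships,
                .data$rel_type %in% hierarchy_types(store))
}

# Path (vector of concept uids) from `from` to `to` over hierarchy edges,
# or NULL. Used to report the offending path when an insertion would close
# a cycle.
hierarchy_path <- function(store, from, to) {
  edges <- hierarchy_edges(store)
  if (nrow(edges) == 0) return(NULL)
  g <- igraph::graph_from_data_frame(
    edges[, c("subject", "object")], directed = TRUE,
    vertices = store$concepts$uid)
  if (!from %in% store$concepts$uid || !to %in% store$concepts$uid) return(NULL)
  p <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, mode = "out"))
  v <- p$vpath[[1]]
  if (length(v) == 0) NULL else names(v)
}

#' Add a typed relationship between concepts
#'
#' Hierarchy relations (is_a, part_of by default) must keep the concept
#' graph a DAG: self-loops and edges that would close a directed cycle are
#' rejected, the latter with the offending path in the error message.
#'
#' @param store An `onto_store`.
#' @param subject,object Concept uids (subject relates to object, e.g.
#'   femur `part_of` leg).
#' @param rel_type Relationship type name.
#' @return The updated store.
#' @export
add_relationship <- function(store, subject, rel_type, object) {
  assert_store(store)
  if (!rel_type %in% store$rel_types$name) {
    abort_onto(sprintf("Unknown relationship type '%s'.", rel_type),
               "onto_error_lookup")
  }
  subject <- resolve_concept_uid(store, subject)
  object <- resolve_concept_uid(store, object)
  is_hier <- rel_type %in% hierarchy_types(store)
  if (is_hier && subject == object) {
    abort_onto(sprintf("Self-loop '%s %s %s' rejected for hierarchy relation.",
                       subject, rel_type, object), "onto_error_cycle")
  }
  dup <- store$relationships$subject == subject &
    store$relationships$rel_type == rel_type &
    store$relationships$object == object
  if (any(dup)) {
    abort_onto("Duplicate relationship triple.", "onto_error_duplicate")
  }
  if (is_hier) {
    path <- hierarchy_path(store, object, subject)
    if (!is.null(path)) {
      abort_onto(
        sprintf("Relationship %s -> %s would create a cycle: %s -> %s.",
                subject, object, paste(path, collapse = " -> "), object),
        "onto_error_cycle", path = c(path, object))
    }
  }
  b <- bump(store, "relationship")
  store <- b$store
  store$relationships <- dplyr::bind_rows(
    store$relationships,
    tibble::tibble(rel_id = b$uid, subject = subject,
                   rel_type = rel_type, object = object)
  )
  store
}

#' Record a sensu (term usage)
#'
#' A sensu states that `reference` used `term` for the concept set
#' `referent`. Referents are usually a single concept; multi-concept
#' referents encode composite usages where a publication applied one label
#' to a combination of structures. Synonymy and homonymy are inferred from
#' the sensu table, see [synonyms_of()], [homonyms()], [acts_of_synonymy()].
#'
#' @param store An `onto_store`.
#' @param term Term uid or label text.
#' @param referent Character vector of concept uids (non-empty).
#' @param reference Reference id.
#' @param order_rank Preference rank among sensus sharing this referent
#'   (lower = preferred); defaults to one past the current maximum.
#' @param obo_label Flag the label used for this concept in OBO exports; at
#'   most one sensu per concept (singleton referent) may carry it.
#' @return The updated store.
#' @export
add_sensu <- function(store, term, referent, reference, order_rank = NULL,
                      obo_label = FALSE) {
  assert_store(store)
  term <- resolve_term_uid(store, term)
  if (length(referent) == 0) {
    abort_onto("Sensu referent must be a non-empty concept set.",
               "onto_error_invariant")
  }
  referent <- vapply(referent, resolve_concept_uid, character(1),
                     store = store, USE.NAMES = FALSE)
  referent <- sort(unique(referent))
  if (!reference %in% store$references$ref_id) {
    abort_onto(sprintf("Unknown reference '%s'.", reference),
               "onto_error_lookup")
  }
  key <- referent_key(referent)
  keys <- referent_keys(store$sensus$referent)
  if (any(store$sensus$term == term & keys == key &
            store$sensus$reference == reference)) {
    abort_onto("Duplicate (term, referent, reference) sensu.",
               "onto_error_duplicate")
  }
  if (isTRUE(obo_label) && length(referent) == 1 &&
        any(store$sensus$obo_label & keys == key)) {
    abort_onto(sprintf(
      "Concept '%s' already has an OBO-label sensu (labels are 1:1 in OBO exports).",
      referent), "onto_error_invariant")
  }
  if (is.null(order_rank)) {
    existing <- store$sensus$order_rank[keys == key]
    order_rank <- if (length(existing)) max(existing) + 1L else 1L
  }
  b <- bump(store, "sensu")
  store <- b$store
  store$sensus <- dplyr::bind_rows(
    store$sensus,
    tibble::tibble(sensu_id = b$uid, term = term, referent = list(referent),
                   reference = reference, order_rank = as.integer(order_rank),
                   obo_label = isTRUE(obo_label))
  )
  store
}

#' Attach a tag to any record
#'
#' Tags are keyword-bearing annotations drawn from the store's controlled
#' vocabulary (see [default_keywords()]); they carry workflow state,
#' cross-references ("xref") or free-text notes, optionally backed by a
#' reference or figure URI.
#'
#' @param store An `onto_store`.
#' @param target uid of any record (concept, term, sensu, relationship,
#'   reference, tag).
#' @param keyword Keyword from the configured vocabulary.
#' @param note,reference,figure_uri Optional payload.
#' @return The updated store.
#' @export
add_tag <- function(store, target, keyword, note = NULL, reference = NULL,
                    figure_uri = NULL) {
  assert_store(store)
  if (!keyword %in% store$config$keywords) {
    abort_onto(sprintf(
      "Keyword '%s' is not in the configured vocabulary (%s).",
      keyword, paste(store$config$keywords, collapse = ", ")),
      "onto_error_vocabulary")
  }
  if (!target %in% all_record_ids(store)) {
    abort_onto(sprintf("Tag target '%s' does not exist.", target),
               "onto_error_lookup")
  }
  reference <- chr1(reference)
  if (!is.na(reference) && !reference %in% store$references$ref_id) {
    abort_onto(sprintf("Unknown reference '%s'.", reference),
               "onto_error_lookup")
  }
  b <- bump(store, "tag")
  store <- b$store
  store$tags <- dplyr::bind_rows(
    store$tags,
    tibble::tibble(tag_id = b$uid, target = target, keyword = keyword,
                   note = chr1(note), reference = reference,
                   figure_uri = chr1(figure_uri))
  )
  store
}
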