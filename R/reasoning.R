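#' Ancestors and descendants over transitive hierarchy relations
#'
#' `ancestors()` returns every concept reachable from `concept` by one or
#' more edges, following the subject-to-object direction (e.g. femur
#' `part_of` leg: leg is an ancestor of femur) over the selected relation
#' types; mixed chains across the selected types are allowed.
#' `descendants()` is the reverse query. Only transitive hierarchy relations
#' may be selected.
#'
#' @param store An `onto_store`.
#' @param concept Concept uid or public id.
#' @param rel_types Relation type names; defaults to all transitive
#'   hierarchy relations in the store (is_a and part_of in a fresh store).
#' @return A character vector of concept uids (sorted; `concept` excluded).
#' @examples
#' store <- build_fixture("leg_example")
#' ancestors(store, "femur")
#' @export
ancestors <- function(store, concept, rel_types = NULL) {
  reachable(store, concept, rel_types, mode = "out")
}

#' @rdname ancestors
#' @export
descendants <- function(store, concept, rel_types = NULL) {
  reachable(store, concept, rel_types, mode = "in")
}

transitive_hierarchy_types <- function(store) {
  rt <- store$rel_types
  rt$name[rt$is_transitive & rt$is_hierarchy]
}

check_rel_types <- function(store, rel_types) {
  if (is.null(rel_types)) return(transitive_hierarchy_types(store))
  rt <- store$rel_types
  for (r in rel_types) {
    i <- match(r, rt$name)
    if (is.na(i) || !rt$is_transitive[i] || !rt$is_hierarchy[i]) {
      abort_onto(sprintf(
        "Relation '%s' is not a transitive hierarchy relation; reasoning over it is unsupported.",
        r), "onto_error_unsupported_relation")
    }
  }
  rel_types
}

reachable <- function(store, concept, rel_types, mode) {
  assert_store(store)
  concept <- resolve_concept_uid(store, concept)
  rel_types <- check_rel_types(store, rel_types)
  edges <- store$relationships[store$relationships$rel_type %in% rel_types, ]
  if (nrow(edges) == 0) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("subject", "object")],
                                     directed = TRUE,
                                     vertices = store$concepts$uid)
  hits <- igraph::subcomponent(g, concept, mode = mode)
  sort(setdiff(names(hits), concept))
}

#' Propagate a property down the hierarchy
#'
#' Encodes the core ontology inference: a quality asserted of a class (say,
#' "legs are yellow") is inherited by every concept whose is_a/part_of chain
#' reaches that class -- its subclasses (fore leg is_a leg) and its parts
#' (femur part_of leg). Returns the asserted assertion plus one inferred
#' assertion per such concept, each carrying the witnessing relationship
#' chain. Propagation is downward only; nothing flows from part to whole.
#'
#' @param store An `onto_store`.
#' @param concept Concept uid or public id carrying the asserted property.
#' @param property Text label of the quality (e.g. `"yellow"`).
#' @param rel_types Relation types to propagate over; defaults to all
#'   transitive hierarchy relations.
#' @return A tibble: `concept`, `property`, `provenance`
#'   (`"asserted"`/`"inferred"`), `via` (list column of relationship-id
#'   chains from the concept up to the asserted concept; empty for the
#'   asserted row).
#' @examples
#' store <- build_fixture("leg_example")
#' propagate_property(store, "leg", "yellow")
#' @export
propagate_property <- function(store, concept, property, rel_types = NULL) {
  assert_store(store)
  concept <- resolve_concept_uid(store, concept)
  rel_types <- check_rel_types(store, rel_types)
  edges <- store$relationships[store$relationships$rel_type %in% rel_types, ]

  # BFS from `concept` over reversed edges, keeping one witnessing edge per
  # discovered node; chains are rebuilt by walking the parent pointers.
  parent_edge <- character()
  frontier <- concept
  seen <- concept
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      inc <- edges[edges$object == v, ]
      inc <- inc[order(inc$subject), ]
      for (j in seq_len(nrow(inc))) {
        child <- inc$subject[j]
        if (!child %in% seen) {
          parent_edge[child] <- inc$rel_id[j]
          seen <- c(seen, child)
          nxt <- c(nxt, child)
        }
      }
    }
    frontier <- nxt
  }
  inferred <- sort(setdiff(seen, concept))
  edge_by_id <- stats::setNames(seq_len(nrow(edges)), edges$rel_id)
  chain_for <- function(node) {
    chain <- character()
    while (node != concept) {
      rid <- parent_edge[[node]]
      chain <- c(chain, rid)
      node <- edges$object[edge_by_id[[rid]]]
    }
    chain
  }
  tibble::tibble(
    concept = c(concept, inferred),
    property = property,
    provenance = c("asserted", rep("inferred", length(inferred))),
    via = c(list(character()), lapply(inferred, chain_for))
  )
}
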