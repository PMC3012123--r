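#' Export the released hierarchy as a Newick tree
#'
#' Flattens the concept DAG over the selected hierarchy relations
#' (child-to-parent edges) into a tree for visualization in standard Newick
#' viewers. A concept with several parents is duplicated under each parent,
#' with a numeric suffix (`_2`, `_3`, ...) disambiguating the copies. Labels
#' are the preferred labels, sanitized for Newick (spaces to underscores;
#' parentheses, commas, colons, quotes and semicolons stripped). With
#' `annotate = TRUE` each node carries a bracketed comment
#' `[&labels=N]` giving the number of unique labels (distinct terms linked
#' to the concept via sensus) -- the annotation viewers such as FigTree use
#' to colour the hierarchy.
#'
#' @param store An `onto_store`.
#' @param annotate Attach unique-label-count comments.
#' @param rel_types Relation types defining the hierarchy; default all
#'   hierarchy relations (is_a and part_of). Pass `"is_a"` for the pure
#'   subsumption tree.
#' @param forest Allow multiple roots, emitted as children of an artificial
#'   blank root; by default multiple roots are an error.
#' @return Newick text (single string ending in `;`). Only released
#'   concepts are included; children at each node are ordered by label.
#' @examples
#' export_newick(build_fixture("leg_example"))
#' @export
export_newick <- function(store, annotate = FALSE, rel_types = NULL,
                          forest = FALSE) {
  assert_store(store)
  rel_types <- rel_types %||% hierarchy_types(store)
  released <- store$concepts$uid[store$concepts$status == "released"]
  if (length(released) == 0) {
    abort_onto("No released concepts to export.", "onto_error_export")
  }
  edges <- store$relationships[
    store$relationships$rel_type %in% rel_types &
      store$relationships$subject %in% released &
      store$relationships$object %in% released, ]
  g <- igraph::graph_from_data_frame(edges[, c("subject", "object")],
                                     directed = TRUE, vertices = released)
  if (!igraph::is_dag(g)) {
    abort_onto("Hierarchy contains a cycle; cannot export a tree.",
               "onto_error_cycle")
  }
  roots <- setdiff(released, unique(edges$subject))
  if (length(roots) > 1 && !forest) {
    abort_onto(sprintf(
      "Multiple hierarchy roots (%s); use forest = TRUE to export anyway.",
      paste(roots, collapse = ", ")), "onto_error_multi_root")
  }

  label <- vapply(released, function(uid) {
    txt <- tryCatch(preferred_label(store, uid)$text,
                    onto_error_no_label = function(e) uid)
    sanitize_newick(txt)
  }, character(1))
  n_labels <- if (annotate) {
    vapply(released, function(uid) {
      hit <- vapply(store$sensus$referent, function(s) uid %in% s, logical(1))
      length(unique(store$sensus$term[hit]))
    }, integer(1))
  }

  seen <- new.env(parent = emptyenv())
  node_text <- function(uid) {
    k <- (get0(uid, envir = seen, ifnotfound = 0L)) + 1L
    assign(uid, k, envir = seen)
    lab <- if (k == 1) label[[uid]] else paste0(label[[uid]], "_", k)
    if (annotate) paste0(lab, "[&labels=", n_labels[[uid]], "]") else lab
  }
  children_of <- function(uid) {
    kids <- unique(edges$subject[edges$object == uid])
    kids[order(label[kids], kids)]
  }
  render <- function(uid) {
    kids <- children_of(uid)
    if (length(kids) == 0) return(node_text(uid))
    paste0("(", paste(vapply(kids, render, character(1)), collapse = ","),
           ")", node_text(uid))
  }
  roots <- roots[order(label[roots], roots)]
  body <- if (length(roots) == 1) render(roots) else {
    paste0("(", paste(vapply(roots, render, character(1)), collapse = ","), ")")
  }
  paste0(body, ";")
}

sanitize_newick <- function(x) {
  x <- gsub("[[:space:]]+", "_", x)
  gsub("[(),:;'\"\\[\\]]", "", x, perl = TRUE)
}
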