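#' Validate an ontology store
#'
#' Runs the consistency checks applied before an OBO release and returns a
#' report tibble (one row per finding). A clean store yields zero rows.
#'
#' Checks, with severity:
#' * `public_id_unique` (error) -- no two concepts share a public id.
#' * `public_id_pattern` (error) -- public ids match `PREFIX:NNNNNNN`.
#' * `released_defined` (error) -- released concepts carry a
#'   genus-differentia definition and a public id. The unique hierarchy root
#'   is exempt from the genus requirement (its definition cannot reference a
#'   parent) but still needs definition text.
#' * `dangling_reference` (error) -- relationships, sensus and tags only
#'   point at existing records.
#' * `hierarchy_acyclic` (error) -- the is_a/part_of graph is a DAG.
#' * `term_unique` (error) -- (text, language) unique among terms.
#' * `obo_label_unique` (error) -- at most one OBO-label sensu per concept.
#' * `keyword_vocabulary` (error) -- tag keywords belong to the vocabulary.
#' * `released_no_parent` (warning) -- a released non-root concept without
#'   any outgoing hierarchy relationship.
#' * `released_to_candidate` (warning) -- a released concept related to a
#'   candidate object.
#'
#' @param store An `onto_store`.
#' @return A tibble with columns `check`, `severity`, `record`, `message`.
#' @export
validate_onto <- function(store) {
  assert_store(store)
  f <- list()
  add <- function(check, severity, record, message) {
    tibble::tibble(check = check, severity = severity,
                   record = record, message = message)
  }

  cc <- store$concepts
  pid <- cc$public_id[!is.na(cc$public_id)]
  dup <- unique(pid[duplicated(pid)])
  for (d in dup) {
    f[[length(f) + 1]] <- add("public_id_unique", "error", d,
                              sprintf("public_id '%s' assigned to %d concepts",
                                      d, sum(pid == d)))
  }
  bad <- pid[!grepl("^[A-Za-z_]+:[0-9]{7}$", pid)]
  for (b in bad) {
    f[[length(f) + 1]] <- add("public_id_pattern", "error", b,
                              sprintf("public_id '%s' is not PREFIX:NNNNNNN", b))
  }

  rel <- cc[cc$status == "released", ]
  # root exemption considers released concepts only: candidates are allowed
  # to float unattached while being drafted
  roots <- intersect(hierarchy_roots(store), rel$uid)
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    missing <- character()
    if (is.na(r$genus) && !(r$uid %in% roots && length(roots) == 1)) {
      missing <- c(missing, "genus")
    }
    if (is.na(r$differentia)) missing <- c(missing, "differentia")
    if (is.na(r$public_id)) missing <- c(missing, "public_id")
    if (length(missing)) {
      f[[length(f) + 1]] <- add(
        "released_defined", "error", r$uid,
        sprintf("released concept '%s' missing: %s",
                r$uid, paste(missing, collapse = ", ")))
    }
  }

  # dangling references
  rr <- store$relationships
  for (i in seq_len(nrow(rr))) {
    gone <- setdiff(c(rr$subject[i], rr$object[i]), cc$uid)
    if (length(gone) || !rr$rel_type[i] %in% store$rel_types$name) {
      f[[length(f) + 1]] <- add(
        "dangling_reference", "error", rr$rel_id[i],
        sprintf("relationship '%s' points at missing record(s): %s",
                rr$rel_id[i], paste(gone, collapse = ", ")))
    }
  }
  ss <- store$sensus
  for (i in seq_len(nrow(ss))) {
    gone <- character()
    if (!ss$term[i] %in% store$terms$uid) gone <- c(gone, ss$term[i])
    gone <- c(gone, setdiff(ss$referent[[i]], cc$uid))
    if (!ss$reference[i] %in% store$references$ref_id) {
      gone <- c(gone, ss$reference[i])
    }
    if (length(gone)) {
      f[[length(f) + 1]] <- add(
        "dangling_reference", "error", ss$sensu_id[i],
        sprintf("sensu '%s' points at missing record(s): %s",
                ss$sensu_id[i], paste(gone, collapse = ", ")))
    }
  }
  tt <- store$tags
  ids <- all_record_ids(store)
  for (i in seq_len(nrow(tt))) {
    if (!tt$target[i] %in% ids) {
      f[[length(f) + 1]] <- add(
        "dangling_reference", "error", tt$tag_id[i],
        sprintf("tag '%s' targets missing record '%s'",
                tt$tag_id[i], tt$target[i]))
    }
    if (!tt$keyword[i] %in% store$config$keywords) {
      f[[length(f) + 1]] <- add(
        "keyword_vocabulary", "error", tt$tag_id[i],
        sprintf("tag '%s' keyword '%s' not in vocabulary",
                tt$tag_id[i], tt$keyword[i]))
    }
  }

  # acyclicity
  edges <- hierarchy_edges(store)
  edges <- edges[edges$subject %in% cc$uid & edges$object %in% cc$uid, ]
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("subject", "object")],
                                       directed = TRUE,
                                       vertices = cc$uid)
    if (!igraph::is_dag(g)) {
      f[[length(f) + 1]] <- add("hierarchy_acyclic", "error", NA_character_,
                                "hierarchy relation graph contains a cycle")
    }
  }

  key <- paste(store$terms$text, store$terms$language, sep = "\r")
  for (d in unique(key[duplicated(key)])) {
    f[[length(f) + 1]] <- add(
      "term_unique", "error", strsplit(d, "\r")[[1]][1],
      sprintf("duplicate term text/language: %s", sub("\r", " / ", d)))
  }

  # OBO-label 1:1
  lab <- ss[ss$obo_label & lengths(ss$referent) == 1, ]
  if (nrow(lab)) {
    tgt <- vapply(lab$referent, `[[`, character(1), 1)
    for (d in unique(tgt[duplicated(tgt)])) {
      f[[length(f) + 1]] <- add(
        "obo_label_unique", "error", d,
        sprintf("concept '%s' has multiple OBO-label sensus", d))
    }
  }

  # warnings: released structure
  with_parent <- unique(edges$subject)
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    if (!r$uid %in% with_parent && !(r$uid %in% roots && length(roots) == 1)) {
      f[[length(f) + 1]] <- add(
        "released_no_parent", "warning", r$uid,
        sprintf("released concept '%s' has no hierarchy parent", r$uid))
    }
  }
  status <- stats::setNames(cc$status, cc$uid)
  for (i in seq_len(nrow(rr))) {
    if (identical(unname(status[rr$subject[i]]), "released") &&
          identical(unname(status[rr$object[i]]), "candidate")) {
      f[[length(f) + 1]] <- add(
        "released_to_candidate", "warning", rr$rel_id[i],
        sprintf("released '%s' relates to candidate '%s'",
                rr$subject[i], rr$object[i]))
    }
  }

  if (length(f)) dplyr::bind_rows(f) else
    tibble::tibble(check = character(), severity = character(),
                   record = character(), message = character())
}

# Concepts with no outgoing hierarchy edge ("roots" of the DAG). On a
# well-formed store exactly one: the top-level class the ontology is rooted
# with.
hierarchy_roots <- function(store) {
  edges <- hierarchy_edges(store)
  setdiff(store$concepts$uid, unique(edges$subject))
}
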