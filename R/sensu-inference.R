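#' Synonyms of a term
#'
#' Two terms are synonyms when some referent concept set is shared -- with
#' exact set equality -- between a sensu of one and a sensu of the other.
#' The relation is symmetric and, at a fixed referent set, an equivalence
#' relation on the terms carrying a sensu to that referent. Synonymy is
#' computed across references: any two sensus suffice, they need not cite
#' the same publication. Inference is language-agnostic: labels in different
#' languages applied to the same referent are synonyms.
#'
#' @param store An `onto_store`.
#' @param term Term uid or label text.
#' @return A tibble of synonymous terms (`uid`, `text`, `language`), sorted
#'   by text then uid.
#' @examples
#' store <- build_fixture("phallobase")
#' synonyms_of(store, "phallobase")$text
#' @export
synonyms_of <- function(store, term) {
  assert_store(store)
  term <- resolve_term_uid(store, term)
  keys <- referent_keys(store$sensus$referent)
  mine <- unique(keys[store$sensus$term == term])
  others <- unique(store$sensus$term[keys %in% mine &
                                       store$sensus$term != term])
  out <- store$terms[store$terms$uid %in% others,
                     c("uid", "text", "language")]
  dplyr::arrange(out, .data$text, .data$uid)
}

#' Homonym report
#'
#' A term is homonymous when its sensus reference two or more distinct
#' referent concept sets -- a single label applied to incompatible
#' structures across the literature. Distinctness is exact set inequality;
#' overlapping-but-unequal composite referents count as distinct. The
#' `has_nested` flag marks terms whose referent sets include a
#' subset/superset pair, so downstream users can filter usages that may be
#' refinements rather than true conflicts.
#'
#' @param store An `onto_store`.
#' @return A tibble with one row per homonymous term: `term` (uid), `text`,
#'   `n_referents`, `referents` (list of concept-uid sets),
#'   `supporting_sensus` (list of sensu ids), `has_nested`. Sorted by text
#'   then uid; terms with fewer than two referent sets are absent.
#' @examples
#' store <- build_fixture("paramere")
#' homonyms(store)
#' @export
homonyms <- function(store) {
  assert_store(store)
  ss <- store$sensus
  empty <- tibble::tibble(
    term = character(), text = character(), n_referents = integer(),
    referents = list(), supporting_sensus = list(), has_nested = logical())
  if (nrow(ss) == 0) {
    return(structure(empty, class = c("onto_homonyms", class(empty))))
  }
  keys <- referent_keys(ss$referent)
  rows <- ss |>
    dplyr::mutate(key = keys) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_referents = dplyr::n_distinct(.data$key),
      referents = list(.data$referent[!duplicated(.data$key)][
        order(unique(.data$key))]),
      supporting_sensus = list(sort(.data$sensu_id)),
      keyset = list(sort(unique(.data$key))),
      .groups = "drop") |>
    dplyr::filter(.data$n_referents >= 2L)
  if (nrow(rows) == 0) {
    return(structure(empty, class = c("onto_homonyms", class(empty))))
  }
  rows$has_nested <- vapply(rows$keyset, function(ks) {
    pairs <- utils::combn(ks, 2, simplify = FALSE)
    any(vapply(pairs, function(p) referents_nested(p[1], p[2]), logical(1)))
  }, logical(1))
  rows <- dplyr::left_join(rows, store$terms[, c("uid", "text")],
                           by = c(term = "uid"))
  out <- rows[order(rows$text, rows$term),
              c("term", "text", "n_referents", "referents",
                "supporting_sensus", "has_nested")]
  structure(out, class = c("onto_homonyms", class(empty)))
}

#' Acts of synonymy
#'
#' An act of synonymy is a single publication linking two or more distinct
#' terms to the same referent concept set, thereby asserting their
#' equivalence: one act per (reference, referent) pair with at least two
#' terms.
#'
#' @param store An `onto_store`.
#' @return A tibble: `reference`, `referent` (list of concept uids),
#'   `terms` (list of term uids), `term_texts` (list), `n_terms`; sorted by
#'   reference then referent key.
#' @examples
#' store <- build_fixture("sensu_demo")
#' acts_of_synonymy(store)
#' @export
acts_of_synonymy <- function(store) {
  assert_store(store)
  ss <- store$sensus
  empty <- tibble::tibble(reference = character(), referent = list(),
                          terms = list(), term_texts = list(),
                          n_terms = integer())
  if (nrow(ss) == 0) return(empty)
  label <- stats::setNames(store$terms$text, store$terms$uid)
  keys <- referent_keys(ss$referent)
  out <- ss |>
    dplyr::mutate(key = keys) |>
    dplyr::group_by(.data$reference, .data$key) |>
    dplyr::summarise(
      referent = list(.data$referent[[1]]),
      terms = list(sort(unique(.data$term))),
      n_terms = dplyr::n_distinct(.data$term),
      .groups = "drop") |>
    dplyr::filter(.data$n_terms >= 2L) |>
    dplyr::arrange(.data$reference, .data$key)
  out$term_texts <- lapply(out$terms, function(t) unname(label[t]))
  out[, c("reference", "referent", "terms", "term_texts", "n_terms")]
}

#' Preferred label of a concept
#'
#' Sensus can be ordered per concept to indicate a preferred label; a
#' sensu flagged `obo_label` overrides the ordering (it is the 1:1 label
#' used in OBO exports). Only sensus whose referent is exactly the single
#' concept are considered. Rank ties break on the lowest term uid so output
#' is deterministic.
#'
#' @param store An `onto_store`.
#' @param concept Concept uid or public id.
#' @return A one-row tibble (`uid`, `text`, `language`) for the preferred
#'   term.
#' @export
preferred_label <- function(store, concept) {
  assert_store(store)
  concept <- resolve_concept_uid(store, concept)
  keys <- referent_keys(store$sensus$referent)
  ss <- store$sensus[keys == concept, ]
  if (nrow(ss) == 0) {
    abort_onto(sprintf("Concept '%s' has no single-referent sensu, hence no label.",
                       concept), "onto_error_no_label")
  }
  ss <- ss[order(!ss$obo_label, ss$order_rank, ss$term), ]
  store$terms[store$terms$uid == ss$term[1], c("uid", "text", "language")]
}

#' Format sensu-inference reports as tab-separated tables
#'
#' Referent concept sets are rendered with members semicolon-joined within a
#' set and sets pipe-joined; concepts are shown by public id where assigned,
#' uid otherwise.
#'
#' @param store The `onto_store` the report came from (for id resolution).
#' @param report A tibble from [homonyms()] or [acts_of_synonymy()].
#' @return A character vector of TSV lines (header first).
#' @export
report_tsv <- function(store, report) {
  assert_store(store)
  shown <- stats::setNames(
    ifelse(is.na(store$concepts$public_id), store$concepts$uid,
           store$concepts$public_id),
    store$concepts$uid)
  set_str <- function(s) paste(sort(unname(shown[s])), collapse = ";")
  if ("n_referents" %in% names(report)) {
    body <- vapply(seq_len(nrow(report)), function(i) {
      paste(report$text[i],
            paste(vapply(report$referents[[i]], set_str, character(1)),
                  collapse = "|"),
            paste(report$supporting_sensus[[i]], collapse = ";"),
            sep = "\t")
    }, character(1))
    c("term\treferents\tsupporting_sensus", body)
  } else {
    body <- vapply(seq_len(nrow(report)), function(i) {
      paste(report$reference[i], set_str(report$referent[[i]]),
            paste(report$term_texts[[i]], collapse = ";"),
            sep = "\t")
    }, character(1))
    c("reference\treferent\tterms", body)
  }
}
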