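#' Ontology census statistics
#'
#' One-row summary of an ontology store in the style of cross-ontology
#' comparison tables: concept and term counts, percentage of concepts with a
#' genus-differentia definition, the distribution of concepts by the number
#' of relationships they are the subject of (bins 0, 1, 2, 3, >3 -- the
#' customary table starts at 1; the 0 bin is added so the bins conserve the
#' concept total), and the numbers of terms participating in synonymy and
#' homonymy.
#'
#' @param store An `onto_store`.
#' @param hierarchy_only Count only hierarchy relations (is_a/part_of) in
#'   the distribution instead of all relation types.
#' @return A one-row tibble of class `onto_census`: `n_concepts`,
#'   `n_defined`, `pct_defined`, `rel_0`, `rel_1`, `rel_2`, `rel_3`,
#'   `rel_gt3`, `n_terms`, `n_sensus`, `n_synonym_terms`, `n_homonym_terms`.
#' @examples
#' census(build_fixture("leg_example"))
#' @export
census <- function(store, hierarchy_only = FALSE) {
  assert_store(store)
  cc <- store$concepts
  rr <- store$relationships
  if (hierarchy_only) {
    rr <- rr[rr$rel_type %in% hierarchy_types(store), ]
  }
  counts <- table(factor(rr$subject, levels = cc$uid))
  bin <- cut(as.integer(counts), breaks = c(-1, 0, 1, 2, 3, Inf),
             labels = c("rel_0", "rel_1", "rel_2", "rel_3", "rel_gt3"))
  bins <- table(bin)

  n_concepts <- nrow(cc)
  n_defined <- sum(!is.na(cc$genus) & !is.na(cc$differentia))
  keys <- referent_keys(store$sensus$referent)
  syn_terms <- store$sensus |>
    dplyr::mutate(key = keys) |>
    dplyr::distinct(.data$term, .data$key) |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n() >= 2L)
  out <- tibble::tibble(
    n_concepts = n_concepts,
    n_defined = n_defined,
    pct_defined = if (n_concepts) 100 * n_defined / n_concepts else 0,
    rel_0 = as.integer(bins[["rel_0"]]),
    rel_1 = as.integer(bins[["rel_1"]]),
    rel_2 = as.integer(bins[["rel_2"]]),
    rel_3 = as.integer(bins[["rel_3"]]),
    rel_gt3 = as.integer(bins[["rel_gt3"]]),
    n_terms = nrow(store$terms),
    n_sensus = nrow(store$sensus),
    n_synonym_terms = dplyr::n_distinct(syn_terms$term),
    n_homonym_terms = nrow(homonyms(store))
  )
  structure(out, class = c("onto_census", class(out)))
}

#' Render a census as TSV or JSON
#'
#' The TSV variant follows the customary comparison-table column order
#' (concepts, defined with percentage, then the relationship-distribution
#' bins 1, 2, 3, >3), with the added 0 bin and the term/sensu/synonymy
#' counts appended.
#'
#' @param x An `onto_census` row from [census()].
#' @param format `"tsv"` or `"json"`.
#' @return Character vector (TSV lines) or JSON string.
#' @export
census_render <- function(x, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(as.list(x), auto_unbox = TRUE, digits = NA))
  }
  header <- c("n_concepts", "n_defined", "pct_defined",
              "rel_1", "rel_2", "rel_3", "rel_gt3", "rel_0",
              "n_terms", "n_sensus", "n_synonym_terms", "n_homonym_terms")
  vals <- vapply(header, function(h) format(x[[h]], trim = TRUE), character(1))
  c(paste(header, collapse = "\t"), paste(vals, collapse = "\t"))
}
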