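#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a store into a concept table
#'
#' One row per concept with its preferred label (NA when no single-referent
#' sensu exists yet) and subject-side relationship count -- the table a
#' curator scans for gaps.
#'
#' @param x An `onto_store`.
#' @param ... Unused.
#' @return A tibble: `uid`, `public_id`, `status`, `label`, `n_relationships`.
#' @method tidy onto_store
#' @export
tidy.onto_store <- function(x, ...) {
  lab <- vapply(x$concepts$uid, function(uid) {
    tryCatch(preferred_label(x, uid)$text,
             onto_error_no_label = function(e) NA_character_)
  }, character(1))
  nrel <- table(factor(x$relationships$subject, levels = x$concepts$uid))
  tibble::tibble(
    uid = x$concepts$uid,
    public_id = x$concepts$public_id,
    status = x$concepts$status,
    label = unname(lab),
    n_relationships = as.integer(nrel)
  )
}

#' Glance at a store
#'
#' One-row census summary; see [census()].
#' @param x An `onto_store`.
#' @param ... Unused.
#' @method glance onto_store
#' @export
glance.onto_store <- function(x, ...) {
  census(x)
}

#' Plot the relationship distribution of a census
#'
#' Bar chart of concepts binned by their subject-side relationship count,
#' the at-a-glance complexity profile used when comparing ontologies.
#'
#' @param object An `onto_census` from [census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot onto_census
#' @export
autoplot.onto_census <- function(object, ...) {
  bins <- tibble::tibble(
    bin = factor(c("0", "1", "2", "3", ">3"),
                 levels = c("0", "1", "2", "3", ">3")),
    concepts = c(object$rel_0, object$rel_1, object$rel_2, object$rel_3,
                 object$rel_gt3)
  )
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$concepts)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relationships (as subject)", y = "concepts",
                  title = "Relationship distribution") +
    ggplot2::theme_minimal()
}

#' Plot homonym severity
#'
#' One bar per homonymous term, height = number of distinct referent
#' concept sets; nested-referent terms are highlighted since those may be
#' refinements rather than conflicts.
#'
#' @param object An `onto_homonyms` report from [homonyms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot onto_homonyms
#' @export
autoplot.onto_homonyms <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$text, -.data$n_referents),
    y = .data$n_referents, fill = .data$has_nested)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "term", y = "distinct referent sets",
                  fill = "nested referents",
                  title = "Homonymous terms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot text annotation coverage
#'
#' Matched spans along the character axis of the proofed text; ambiguous
#' (homonymous) matches are coloured separately.
#'
#' @param object An `onto_annotations` tibble from [proof()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot onto_annotations
#' @export
autoplot.onto_annotations <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$y <- seq_len(nrow(df))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end, y = .data$y, yend = .data$y,
      colour = .data$ambiguous), linewidth = 3) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = .data$y,
      label = .data$term_text), vjust = -1, size = 3) +
    ggplot2::labs(x = "character offset", y = NULL,
                  title = "Ontology matches in text") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
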