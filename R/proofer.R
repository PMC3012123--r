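#' Proof free text against the ontology lexicon
#'
#' Marks up a text block (a taxonomic description, character statement,
#' identification key...) with matches to the ontology's term lexicon:
#' case-insensitive, word-boundary, leftmost-longest matching, with
#' multi-word terms matched as phrases. Annotations never overlap; a longer
#' phrase wins over any term matching a prefix of it ("fore leg" beats
#' "leg"). Homonymous terms are flagged `ambiguous` with every referent
#' concept set listed, so a reader can see the competing usages.
#'
#' Tokenization splits on whitespace and punctuation but keeps internal
#' hyphens (anatomical terms are frequently hyphenated); multi-word phrases
#' may only span plain whitespace. Optional naive plural folding strips a
#' trailing "s"/"es" from text tokens when comparing; it is off by default
#' -- exact matching is the conservative choice for curation.
#'
#' @param text A single string.
#' @param store An `onto_store` with at least one term.
#' @param plural_folding Fold naive English plurals when matching.
#' @param released_only Restrict the lexicon to terms linked by sensu to at
#'   least one released concept.
#' @return A tibble of class `onto_annotations`, sorted by `start`:
#'   `start`, `end` (0-based, half-open character offsets), `matched_text`,
#'   `term` (uid), `term_text`, `referents` (list of referent concept sets),
#'   `ambiguous`.
#' @examples
#' store <- build_fixture("leg_example")
#' proof("The fore leg and the femur are yellow.", store)
#' @export
proof <- function(text, store, plural_folding = FALSE, released_only = FALSE) {
  assert_store(store)
  stopifnot(length(text) == 1)
  lex <- proof_lexicon(store, released_only)
  ann0 <- tibble::tibble(start = integer(), end = integer(),
                         matched_text = character(), term = character(),
                         term_text = character(), referents = list(),
                         ambiguous = logical())
  if (nrow(lex) == 0) {
    rlang::warn("Ontology lexicon is empty; nothing to match.",
                class = "onto_warning_empty_lexicon")
    return(structure(ann0, class = c("onto_annotations", class(ann0))))
  }
  toks <- tokenize(text)
  if (nrow(toks) == 0) {
    return(structure(ann0, class = c("onto_annotations", class(ann0))))
  }
  max_len <- max(lex$n_tokens)
  out <- list()
  i <- 1L
  while (i <= nrow(toks)) {
    matched <- FALSE
    for (len in seq(min(max_len, nrow(toks) - i + 1L), 1L)) {
      # phrases may only span clean (whitespace-only) gaps
      if (len > 1 && !all(toks$clean_gap[i:(i + len - 2L)])) next
      phrase_toks <- toks$lower[i:(i + len - 1L)]
      hit <- match_lexicon(lex, phrase_toks, plural_folding)
      if (!is.na(hit)) {
        t_uid <- lex$uid[hit]
        ref_sets <- store$sensus$referent[store$sensus$term == t_uid]
        ref_sets <- ref_sets[!duplicated(referent_keys(ref_sets))]
        ref_sets <- ref_sets[order(referent_keys(ref_sets))]
        s0 <- toks$start[i]; e0 <- toks$end[i + len - 1L]
        out[[length(out) + 1]] <- tibble::tibble(
          start = s0, end = e0,
          matched_text = substr(text, s0 + 1L, e0),
          term = t_uid, term_text = lex$text[hit],
          referents = list(ref_sets),
          ambiguous = length(ref_sets) > 1)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  res <- if (length(out)) dplyr::bind_rows(out) else ann0
  structure(res, class = c("onto_annotations", class(res)))
}

proof_lexicon <- function(store, released_only = FALSE) {
  terms <- store$terms
  if (released_only) {
    released <- store$concepts$uid[store$concepts$status == "released"]
    linked <- vapply(seq_len(nrow(store$sensus)), function(i) {
      any(store$sensus$referent[[i]] %in% released)
    }, logical(1))
    keep <- unique(store$sensus$term[linked])
    terms <- terms[terms$uid %in% keep, ]
  }
  toks <- lapply(tolower(terms$text), function(t) {
    tokenize(t)$lower
  })
  tibble::tibble(uid = terms$uid, text = terms$text, tokens = toks,
                 n_tokens = lengths(toks))[lengths(toks) > 0, ]
}

# first lexicon row whose token sequence matches, preferring exact over
# plural-folded comparison; NA when none.
match_lexicon <- function(lex, phrase_toks, plural_folding) {
  n <- length(phrase_toks)
  cand <- which(lex$n_tokens == n)
  for (j in cand) {
    if (identical(lex$tokens[[j]], phrase_toks)) return(j)
  }
  if (plural_folding) {
    folded <- vapply(phrase_toks, fold_plural, character(1))
    for (j in cand) {
      lt <- lex$tokens[[j]]
      ok <- all(lt == phrase_toks | lt == folded)
      if (ok) return(j)
    }
  }
  NA_integer_
}

fold_plural <- function(tok) {
  if (grepl("es$", tok) && nchar(tok) > 3) return(sub("es$", "", tok))
  if (grepl("s$", tok) && nchar(tok) > 2) return(sub("s$", "", tok))
  tok
}

# Tokens with 0-based half-open offsets; internal hyphens kept inside a
# token; clean_gap[i] says tokens i and i+1 are separated by whitespace only.
tokenize <- function(text) {
  m <- gregexpr("[[:alnum:]]+(-[[:alnum:]]+)*", text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), lower = character(),
                          start = integer(), end = integer(),
                          clean_gap = logical()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  token <- substring(text, starts, starts + lens - 1)
  start0 <- starts - 1L
  end0 <- start0 + lens
  gap <- vapply(seq_len(length(token) - 1), function(i) {
    between <- substr(text, end0[i] + 1L, start0[i + 1])
    grepl("^[[:space:]]*$", between)
  }, logical(1))
  tibble::tibble(token = token, lower = tolower(token),
                 start = start0, end = as.integer(end0),
                 clean_gap = c(gap, NA))
}

#' Render proof annotations as hyperlinked HTML or TSV
#'
#' HTML output wraps every matched span in an anchor whose target is
#' `uri_template` with `{id}` replaced by the public id (uid when
#' unreleased) of the annotation's referent concepts -- composite referents
#' join members with `+`, ambiguous terms link to their first referent set.
#' TSV output gives one row per annotation; referent sets join members with
#' `;` and sets with `|`.
#'
#' @param text The text the annotations were computed on.
#' @param annotations Output of [proof()] on the same text.
#' @param format `"html"` or `"tsv"`.
#' @param store The store (to resolve public ids); required for both formats.
#' @param uri_template URI with an `{id}` placeholder.
#' @return A single string (html) or character vector of TSV lines.
#' @export
render_annotations <- function(text, annotations, format = c("html", "tsv"),
                               store = NULL,
                               uri_template = "https://example.org/{id}") {
  format <- match.arg(format)
  n <- nchar(text)
  if (nrow(annotations) > 0 &&
        (any(annotations$start < 0) || any(annotations$end > n) ||
           any(annotations$start >= annotations$end))) {
    abort_onto("Annotation offsets are inconsistent with the text.",
               "onto_error_consistency")
  }
  shown <- if (!is.null(store)) {
    stats::setNames(
      ifelse(is.na(store$concepts$public_id), store$concepts$uid,
             store$concepts$public_id),
      store$concepts$uid)
  } else {
    character()
  }
  id_of <- function(set) {
    paste(vapply(set, function(u) {
      v <- unname(shown[u])
      if (length(v) == 0 || is.na(v)) u else v
    }, character(1), USE.NAMES = FALSE), collapse = "+")
  }
  if (format == "tsv") {
    header <- "start\tend\ttext\tterm\treferents\tambiguous"
    if (nrow(annotations) == 0) return(header)
    rows <- vapply(seq_len(nrow(annotations)), function(i) {
      refs <- paste(vapply(annotations$referents[[i]], id_of, character(1)),
                    collapse = "|")
      paste(annotations$start[i], annotations$end[i],
            annotations$matched_text[i], annotations$term_text[i],
            refs, tolower(annotations$ambiguous[i]), sep = "\t")
    }, character(1))
    return(c(header, rows))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  if (nrow(annotations) == 0) return(esc(text))
  ann <- annotations[order(annotations$start), ]
  pieces <- character()
  pos <- 0L
  for (i in seq_len(nrow(ann))) {
    pieces <- c(pieces, esc(substr(text, pos + 1L, ann$start[i])))
    target <- gsub("{id}", id_of(ann$referents[[i]][[1]]), uri_template,
                   fixed = TRUE)
    pieces <- c(pieces, sprintf('<a href="%s">%s</a>', target,
                                esc(ann$matched_text[i])))
    pos <- ann$end[i]
  }
  pieces <- c(pieces, esc(substr(text, pos + 1L, n)))
  paste(pieces, collapse = "")
}

#' Extract candidate terms from text
#'
#' Supports the semi-automatic harvesting of new lexicon entries: all word
#' n-grams (up to `max_ngram` tokens, spanning whitespace-only gaps) that do
#' not match an existing term, do not contain a stop word, and do not
#' overlap a span already annotated by [proof()], lowercased and ranked by
#' frequency (descending) then alphabetically.
#'
#' @param text A single string.
#' @param store An `onto_store` (its terms define what is already known).
#' @param max_ngram Longest n-gram to consider (>= 1).
#' @param stopwords Stop-word list; defaults to the built-in English list,
#'   override with your own vector (e.g. read from a file).
#' @return A tibble: `text`, `frequency`, `contexts` (list of snippets
#'   around the first occurrences).
#' @examples
#' store <- build_fixture("leg_example")
#' extract_candidates("the gonostyle and the volsella", store)
#' @export
extract_candidates <- function(text, store, max_ngram = 3,
                               stopwords = onto_stopwords()) {
  assert_store(store)
  stopifnot(max_ngram >= 1)
  toks <- tokenize(text)
  if (nrow(toks) == 0) {
    return(tibble::tibble(text = character(), frequency = integer(),
                          contexts = list()))
  }
  ann <- if (nrow(store$terms)) {
    suppressWarnings(proof(text, store))
  } else {
    tibble::tibble(start = integer(), end = integer())
  }
  covered <- vapply(seq_len(nrow(toks)), function(i) {
    any(ann$start < toks$end[i] & ann$end > toks$start[i])
  }, logical(1))
  known <- unique(vapply(tolower(store$terms$text), function(t) {
    paste(tokenize(t)$lower, collapse = " ")
  }, character(1), USE.NAMES = FALSE))
  grams <- list()
  for (i in seq_len(nrow(toks))) {
    for (len in seq_len(min(max_ngram, nrow(toks) - i + 1L))) {
      j <- i + len - 1L
      if (any(covered[i:j])) next
      if (len > 1 && !all(toks$clean_gap[i:(j - 1L)])) next
      words <- toks$lower[i:j]
      if (any(words %in% stopwords)) next
      if (all(grepl("^[0-9]+$", words))) next
      gram <- paste(words, collapse = " ")
      if (gram %in% known) next
      grams[[length(grams) + 1]] <- list(
        gram = gram, start = toks$start[i], end = toks$end[j])
    }
  }
  if (length(grams) == 0) {
    return(tibble::tibble(text = character(), frequency = integer(),
                          contexts = list()))
  }
  gtxt <- vapply(grams, `[[`, character(1), "gram")
  tab <- table(gtxt)
  snippet <- function(g) {
    occ <- grams[gtxt == g]
    occ <- occ[seq_len(min(3, length(occ)))]
    vapply(occ, function(o) {
      s <- max(0L, o$start - 20L); e <- min(nchar(text), o$end + 20L)
      substr(text, s + 1L, e)
    }, character(1))
  }
  out <- tibble::tibble(
    text = names(tab),
    frequency = as.integer(tab),
    contexts = lapply(names(tab), snippet)
  )
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$text)
}

#' Built-in English stop-word list
#' @return Character vector.
#' @export
onto_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "from",
    "has", "have", "in", "into", "is", "it", "its", "more", "most", "not",
    "of", "on", "or", "so", "than", "that", "the", "their", "then", "there",
    "these", "this", "to", "was", "were", "which", "with", "without", "when",
    "where", "while", "will", "we", "can", "may", "each", "very", "such",
    "also", "been", "being", "both", "other", "some", "only", "its")
}
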