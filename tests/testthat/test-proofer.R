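test_that("plural folding lets 'legs' match the term 'leg'", {
  store <- build_fixture("leg_example")
  ann <- proof("legs are yellow", store, plural_folding = TRUE)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$matched_text, "legs")
  expect_equal(ann$term_text, "leg")
  expect_equal(ann$start, 0)
  expect_equal(ann$end, 4)
  # folding is off by default: exact matching only
  expect_equal(nrow(proof("legs are yellow", store)), 0)
})

test_that("leftmost-longest: a phrase beats its own substring", {
  store <- build_fixture("leg_example")
  ann <- proof("fore leg and leg", store)
  expect_equal(ann$term_text, c("fore leg", "leg"))
  expect_equal(ann$matched_text, c("fore leg", "leg"))
  expect_equal(ann$start, c(0, 13))
  # matching is case-insensitive at word boundaries
  ann2 <- proof("The Fore Leg; the FEMUR.", store)
  expect_equal(ann2$term_text, c("fore leg", "femur"))
})

test_that("text with no lexicon words yields no annotations", {
  store <- build_fixture("leg_example")
  expect_equal(nrow(proof("mandible and clypeus", store)), 0)
  expect_warning(proof("anything", onto_store() |> add_concept(uid = "c")),
                 class = "onto_warning_empty_lexicon")
})

test_that("homonymous matches are flagged ambiguous with all referent sets", {
  store <- build_fixture("paramere")
  ann <- proof("the paramere is curved", store)
  expect_equal(nrow(ann), 1)
  expect_true(ann$ambiguous)
  expect_length(ann$referents[[1]], 5)
})

test_that("annotations never overlap and gaps+matches reconstruct the text", {
  store <- build_fixture("leg_example")
  text <- "The fore leg bears a femur; each leg and fore leg is yellow."
  ann <- proof(text, store)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$end[-nrow(ann)] <= ann$start[-1]))
  # reconstruct
  pieces <- character()
  pos <- 0L
  for (i in seq_len(nrow(ann))) {
    pieces <- c(pieces, substr(text, pos + 1, ann$start[i]),
                ann$matched_text[i])
    pos <- ann$end[i]
  }
  pieces <- c(pieces, substr(text, pos + 1, nchar(text)))
  expect_equal(paste(pieces, collapse = ""), text)
})

test_that("matching agrees with the exhaustive enumeration oracle", {
  store <- build_fixture("leg_example") |>
    add_term("hind leg") |>
    add_term("femoral depression")
  lex <- store$terms$text
  texts <- c(
    "The hind leg and the fore leg differ; the femur of the hind leg is wide.",
    "femoral depression absent; leg, fore leg, hind-leg and legs vary.",
    "Fore leg. femur!femur leg... femoral depression, depression femoral.",
    paste(rep("leg femur fore leg hind leg femoral depression word", 12),
          collapse = " ")
  )
  for (tx in texts) {
    for (fold in c(FALSE, TRUE)) {
      ann <- proof(tx, store, plural_folding = fold)
      want <- oracle_proof(tx, lex, plural_folding = fold)
      expect_equal(ann$start, want$start, info = tx)
      expect_equal(ann$end, want$end, info = tx)
    }
  }
})

test_that("adding a term never decreases annotated characters", {
  text <- "the fore leg bears one femur and one tibia"
  s1 <- build_fixture("leg_example")
  a1 <- proof(text, s1)
  s2 <- add_term(s1, "tibia")
  a2 <- proof(text, s2)
  expect_gte(sum(a2$end - a2$start), sum(a1$end - a1$start))
})

test_that("released-only lexicon excludes candidate-only labels", {
  store <- build_fixture("leg_example") |>
    add_concept(uid = "cand") |>
    add_term("petiole") |>
    add_sensu("petiole", "cand", "ref_fix")
  expect_equal(nrow(proof("the petiole", store)), 1)
  expect_equal(nrow(proof("the petiole", store, released_only = TRUE)), 0)
})

test_that("html rendering wraps matches in anchors from the URI template", {
  store <- build_fixture("leg_example")
  text <- "the femur & the fore leg"
  ann <- proof(text, store)
  html <- render_annotations(text, ann, "html", store,
                             uri_template = "https://example/{id}")
  expect_match(html, '<a href="https://example/HAO:0000004">femur</a>',
               fixed = TRUE)
  expect_match(html, '<a href="https://example/HAO:0000003">fore leg</a>',
               fixed = TRUE)
  expect_match(html, "&amp;", fixed = TRUE)
  # zero annotations: text returned verbatim (escaped)
  expect_equal(render_annotations("no matches", ann[0, ], "html", store),
               "no matches")
})

test_that("tsv rendering gives one row per annotation and guards offsets", {
  store <- build_fixture("paramere")
  text <- "one paramere here"
  ann <- proof(text, store)
  tsv <- render_annotations(text, ann, "tsv", store)
  expect_length(tsv, 2)
  fields <- strsplit(tsv[2], "\t")[[1]]
  expect_equal(fields[3], "paramere")
  expect_equal(fields[6], "true")
  sets <- strsplit(fields[5], "|", fixed = TRUE)[[1]]
  expect_length(sets, 5)
  expect_equal(render_annotations("x", ann[0, ], "tsv", store),
               "start\tend\ttext\tterm\treferents\tambiguous")
  bad <- ann
  bad$end <- nchar(text) + 10L
  expect_error(render_annotations(text, bad, "tsv", store),
               class = "onto_error_consistency")
})

test_that("candidate extraction counts unknown n-grams and skips known terms", {
  store <- build_fixture("leg_example")
  cand <- extract_candidates("the gonostyle and the gonostyle", store)
  expect_equal(cand$text[1], "gonostyle")
  expect_equal(cand$frequency[1], 2)
  # text of only existing terms and stop words yields nothing
  none <- extract_candidates("the leg and the femur", store)
  expect_equal(nrow(none), 0)
  # candidates never overlap accepted annotation spans
  text <- "fore leg volsella; the volsella of the fore leg"
  ann <- proof(text, store)
  cand2 <- extract_candidates(text, store)
  expect_false(any(grepl("leg|fore", cand2$text)))
  expect_true("volsella" %in% cand2$text)
})

test_that("stop-word list is overridable and max_ngram respected", {
  store <- onto_store() |> add_concept(uid = "c")
  cand <- extract_candidates("alpha beta gamma", store, max_ngram = 2,
                             stopwords = "beta")
  expect_true(all(lengths(strsplit(cand$text, " ")) <= 2))
  expect_false(any(grepl("beta", cand$text)))
  expect_true(all(c("alpha", "gamma") %in% cand$text))
})
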