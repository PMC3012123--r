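test_that("terms sharing a referent are synonyms (minimal demo wiring)", {
  store <- build_fixture("sensu_demo")
  expect_setequal(synonyms_of(store, "T1")$uid, c("T2", "T3"))
  expect_setequal(synonyms_of(store, "T2")$uid, c("T1", "T3"))
  # symmetry: b in synonyms_of(a) <=> a in synonyms_of(b)
  for (a in c("T1", "T2", "T3")) {
    for (b in setdiff(c("T1", "T2", "T3"), a)) {
      expect_equal(b %in% synonyms_of(store, a)$uid,
                   a %in% synonyms_of(store, b)$uid)
    }
  }
})

test_that("two labels recorded against one concept are synonyms", {
  store <- build_fixture("phallobase")
  expect_equal(synonyms_of(store, "phallobase")$text, "gonocoxite IX")
  expect_equal(synonyms_of(store, "gonocoxite IX")$text, "phallobase")
})

test_that("a term with a single unique referent has no synonyms", {
  store <- make_small_store() |> add_sensu("alpha", "a", "r1")
  expect_equal(nrow(synonyms_of(store, "alpha")), 0)
  expect_error(synonyms_of(store, "no such term"),
               class = "onto_error_lookup")
})

test_that("homonym detection: demo term T3 refers to two concepts", {
  store <- build_fixture("sensu_demo")
  hom <- homonyms(store)
  expect_equal(hom$term, "T3")
  expect_equal(hom$n_referents, 2)
  expect_setequal(unlist(hom$referents[[1]]), c("C1", "C2"))
  expect_equal(nrow(homonyms(onto_store())), 0)
})

test_that("the paramere fixture shows five incompatible referent sets", {
  store <- build_fixture("paramere")
  hom <- homonyms(store)
  expect_equal(nrow(hom), 1)
  expect_equal(hom$text, "paramere")
  expect_equal(hom$n_referents, 5)
  # two of the five sets are composites; overlap does not merge them
  sizes <- sort(lengths(hom$referents[[1]]))
  expect_equal(sizes, c(1, 1, 1, 2, 3))
  expect_true(hom$has_nested)  # {389,1084} is nested in {707,389,1084}
})

test_that("acts of synonymy: one act per reference linking >= 2 terms to a referent", {
  store <- build_fixture("sensu_demo")
  acts <- acts_of_synonymy(store)
  expect_equal(nrow(acts), 1)
  expect_equal(acts$reference, "R1")
  expect_equal(acts$referent[[1]], "C1")
  expect_setequal(acts$terms[[1]], c("T2", "T3"))
  # one sensu per reference -> no acts
  expect_equal(nrow(acts_of_synonymy(build_fixture("paramere"))), 0)
})

test_that("synonym pairs, homonyms and acts match exhaustive brute-force oracles", {
  for (seed in c(3, 11, 27)) {
    store <- build_fixture("random", n_concepts = 25, n_terms = 18,
                           n_sensus = 90, n_refs = 6, seed = seed)
    # synonym pairs via synonyms_of on each term
    got_pairs <- character()
    for (t in unique(store$sensus$term)) {
      for (s in synonyms_of(store, t)$uid) {
        got_pairs <- c(got_pairs, paste(sort(c(t, s)), collapse = "|"))
      }
    }
    expect_equal(sort(unique(got_pairs)), oracle_synonym_pairs(store))

    hom <- homonyms(store)
    expect_equal(hom$term, oracle_homonym_terms(store))

    acts <- acts_of_synonymy(store)
    expected <- oracle_acts(store)
    expect_equal(nrow(acts), length(expected))
    for (i in seq_along(expected)) {
      expect_equal(acts$reference[i], expected[[i]]$reference)
      expect_equal(paste(sort(acts$referent[[i]]), collapse = "+"),
                   expected[[i]]$key)
      expect_equal(acts$terms[[i]], expected[[i]]$terms)
    }
  }
})

test_that("synonymy at a fixed referent partitions terms (equivalence relation)", {
  store <- build_fixture("random", n_concepts = 15, n_terms = 12,
                         n_sensus = 60, n_refs = 5, seed = 99)
  keys <- vapply(store$sensus$referent, function(s)
    paste(sort(s), collapse = "+"), character(1))
  for (k in unique(keys)) {
    members <- sort(unique(store$sensus$term[keys == k]))
    if (length(members) < 2) next
    # every pair of terms sharing referent k must be mutual synonyms
    for (a in members) {
      syn_a <- synonyms_of(store, a)$uid
      expect_true(all(setdiff(members, a) %in% syn_a))
    }
  }
})

test_that("inference is insensitive to sensu insertion order", {
  build <- function(order) {
    store <- onto_store() |>
      add_reference("R", ref_id = "R1") |>
      add_concept(uid = "C1") |> add_concept(uid = "C2") |>
      add_term("T1", uid = "T1") |> add_term("T2", uid = "T2") |>
      add_term("T3", uid = "T3")
    specs <- list(list("T1", "C1"), list("T2", "C1"),
                  list("T3", "C1"), list("T3", "C2"))[order]
    for (sp in specs) store <- add_sensu(store, sp[[1]], sp[[2]], "R1")
    store
  }
  a <- build(1:4)
  b <- build(4:1)
  expect_equal(homonyms(a)[, c("term", "n_referents")],
               homonyms(b)[, c("term", "n_referents")])
  expect_equal(synonyms_of(a, "T1")$uid, synonyms_of(b, "T1")$uid)
})

test_that("preferred label: obo flag overrides rank, rank ties break on term uid", {
  base <- onto_store() |>
    add_reference("R", ref_id = "R1") |>
    add_concept(uid = "c") |>
    add_term("first", uid = "t1") |>
    add_term("second", uid = "t2")

  one <- add_sensu(base, "t1", "c", "R1")
  expect_equal(preferred_label(one, "c")$text, "first")

  ranked <- base |>
    add_sensu("t1", "c", "R1", order_rank = 2L) |>
    add_sensu("t2", "c", "R1", order_rank = 1L)
  expect_equal(preferred_label(ranked, "c")$text, "second")

  flagged <- base |>
    add_sensu("t2", "c", "R1", order_rank = 1L) |>
    add_sensu("t1", "c", "R1", order_rank = 2L, obo_label = TRUE)
  expect_equal(preferred_label(flagged, "c")$text, "first")

  tied <- base |>
    add_sensu("t2", "c", "R1", order_rank = 1L) |>
    add_sensu("t1", "c", "R1", order_rank = 1L)
  expect_equal(preferred_label(tied, "c")$uid, "t1")

  expect_error(preferred_label(base, "c"), class = "onto_error_no_label")
})

test_that("reports render as TSV with semicolon/pipe joined referent sets", {
  store <- build_fixture("paramere")
  tsv <- report_tsv(store, homonyms(store))
  expect_equal(tsv[1], "term\treferents\tsupporting_sensus")
  fields <- strsplit(tsv[2], "\t")[[1]]
  expect_equal(fields[1], "paramere")
  sets <- strsplit(fields[2], "|", fixed = TRUE)[[1]]
  expect_length(sets, 5)
  expect_true(any(grepl("HAO:0000389;HAO:0001084",
                        gsub(" ", "", sets), fixed = TRUE)))
})
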