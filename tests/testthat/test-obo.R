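fixed_date <- "01:01:2026 00:00"

test_that("leg fixture exports four stanzas that the package parser reads back", {
  store <- build_fixture("leg_example")
  doc <- export_obo(store, date = fixed_date)
  expect_equal(length(gregexpr("\\[Term\\]", doc)[[1]]), 4)
  expect_match(doc, "format-version: 1.2", fixed = TRUE)
  expect_match(doc, "def: \"A leg that is attached to the prothorax.\"",
               fixed = TRUE)
  back <- import_obo(doc)
  expect_equal(nrow(back$concepts), 4)
  expect_true(all(back$concepts$status == "released"))
})

test_that("a store with no released concepts exports a header-only document", {
  store <- build_fixture("sensu_demo")
  doc <- export_obo(store, date = fixed_date)
  expect_false(grepl("[Term]", doc, fixed = TRUE))
  expect_match(doc, "^format-version: 1.2")
  expect_equal(nrow(import_obo(doc)$concepts), 0)
})

test_that("non-preferred labels of a shared class are emitted as synonyms", {
  store <- build_fixture("phallobase") |>
    add_concept(uid = "root", differentia = "top-level class",
                status = "released", public_id = "HAO:0000001") |>
    add_term("genitalia root") |>
    add_sensu("genitalia root", "root", "R1", obo_label = TRUE) |>
    add_relationship("c_phallobase", "is_a", "root")
  store$concepts$genus[store$concepts$uid == "c_phallobase"] <- "root"
  store <- release_concept(store, "c_phallobase")
  doc <- export_obo(store, date = fixed_date)
  # rank-1 sensu "phallobase" is the name; "gonocoxite IX" a synonym
  expect_match(doc, "name: phallobase", fixed = TRUE)
  expect_match(doc, 'synonym: "gonocoxite IX" EXACT [R1]', fixed = TRUE)
})

test_that("export is deterministic and refuses invalid stores", {
  store <- build_fixture("paramere")
  expect_identical(export_obo(store, date = fixed_date),
                   export_obo(store, date = fixed_date))
  broken <- store
  broken$sensus$referent[[2]] <- "ghost"
  expect_error(export_obo(broken, date = fixed_date),
               class = "onto_error_validation")
})

test_that("round-trip preserves the released projection", {
  store <- build_fixture("paramere")
  doc <- export_obo(store, date = fixed_date)
  back <- import_obo(doc)
  expect_equal(sum(back$concepts$status == "released"), 5)
  expect_setequal(back$concepts$public_id, store$concepts$public_id)
  # preferred labels survive
  for (uid in store$concepts$uid) {
    pid <- store$concepts$public_id[store$concepts$uid == uid]
    expect_equal(preferred_label(back, pid)$text,
                 preferred_label(store, uid)$text)
  }
  # relationships survive (by public id)
  pid_of <- stats::setNames(store$concepts$public_id, store$concepts$uid)
  orig <- sort(paste(pid_of[store$relationships$subject],
                     store$relationships$rel_type,
                     pid_of[store$relationships$object]))
  got <- sort(paste(back$relationships$subject,
                    back$relationships$rel_type,
                    back$relationships$object))
  expect_equal(got, orig)
  # second export of the reimport contains the same stanza ids
  doc2 <- export_obo(back, date = fixed_date)
  ids <- function(d) sort(regmatches(d, gregexpr("id: [A-Z:0-9]+", d))[[1]])
  expect_equal(ids(doc2), ids(doc))
})

test_that("composite usages export as RELATED synonyms on member concepts", {
  doc <- export_obo(build_fixture("paramere"), date = fixed_date)
  related <- grep("RELATED", strsplit(doc, "\n")[[1]], value = TRUE)
  # the two composite referents cover three member concepts; each member
  # stanza carries one RELATED synonym line (references merged)
  expect_true(all(grepl('synonym: "paramere" RELATED', related)))
  expect_equal(length(related), 3)
})

test_that("malformed stanzas and dangling targets are reported", {
  expect_error(import_obo(c("format-version: 1.2", "", "[Term]",
                            "id: HAO:0000001")),
               class = "onto_error_parse")
  doc <- paste(c("format-version: 1.2", "", "[Term]", "id: HAO:0000001",
                 "name: thing", "is_a: HAO:9999999"), collapse = "\n")
  expect_warning(back <- import_obo(doc), class = "onto_warning_dangling")
  expect_equal(nrow(back$relationships), 0)
})
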