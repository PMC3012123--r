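test_that("leg fixture exports the expected tree shape", {
  nwk <- export_newick(build_fixture("leg_example"))
  expect_equal(nwk, "((femur,fore_leg)leg)anatomical_entity;")
})

test_that("a single released concept exports as a bare root", {
  store <- onto_store() |>
    add_reference("r", ref_id = "r1") |>
    add_concept(uid = "root", differentia = "top", status = "released",
                public_id = "HAO:0000001") |>
    add_term("whole organism") |>
    add_sensu("whole organism", "root", "r1", obo_label = TRUE)
  expect_equal(export_newick(store), "whole_organism;")
})

test_that("newick output parses in ape and matches the hierarchy adjacency", {
  skip_if_not_installed("ape")
  store <- build_fixture("leg_example")
  tree <- ape::read.tree(text = export_newick(store))
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("femur", "fore_leg"))
  expect_setequal(tree$node.label, c("anatomical_entity", "leg"))
  # random released is_a hierarchy: parent-child pairs in the tree equal
  # the is_a adjacency
  store2 <- onto_store() |> add_reference("r", ref_id = "r1")
  store2 <- add_concept(store2, uid = "n1", differentia = "top",
                        status = "released", public_id = "HAO:0000001")
  store2 <- add_term(store2, "node 1") |>
    add_sensu("node 1", "n1", "r1", obo_label = TRUE)
  set.seed(4)
  for (i in 2:12) {
    uid <- sprintf("n%d", i)
    parent <- sprintf("n%d", sample(i - 1, 1))
    store2 <- store2 |>
      add_concept(uid = uid, genus = parent,
                  differentia = sprintf("is node %d", i)) |>
      add_term(sprintf("node %d", i)) |>
      add_sensu(sprintf("node %d", i), uid, "r1", obo_label = TRUE) |>
      add_relationship(uid, "is_a", parent) |>
      release_concept(uid)
  }
  nwk <- export_newick(store2, rel_types = "is_a")
  tree2 <- ape::read.tree(text = nwk)
  lab <- function(x) sub("_", " ", x)
  ntip <- length(tree2$tip.label)
  got_edges <- apply(tree2$edge, 1, function(e) {
    child <- if (e[2] <= ntip) tree2$tip.label[e[2]]
    else tree2$node.label[e[2] - ntip]
    parent <- tree2$node.label[e[1] - ntip]
    paste(lab(child), "->", lab(parent))
  })
  want_edges <- paste(
    vapply(store2$relationships$subject,
           function(u) preferred_label(store2, u)$text, character(1)),
    "->",
    vapply(store2$relationships$object,
           function(u) preferred_label(store2, u)$text, character(1)))
  expect_setequal(got_edges, want_edges)
})

test_that("multi-parent concepts are duplicated under each parent", {
  store <- build_fixture("leg_example") |>
    add_concept(uid = "mid_leg", genus = "leg",
                differentia = "is attached to the mesothorax",
                status = "candidate") |>
    add_term("mid leg") |>
    add_sensu("mid leg", "mid_leg", "ref_fix") |>
    add_relationship("mid_leg", "is_a", "leg") |>
    release_concept("mid_leg") |>
    add_relationship("femur", "part_of", "mid_leg")
  nwk <- export_newick(store)
  expect_equal(length(gregexpr("femur", nwk)[[1]]), 2)
  expect_match(nwk, "femur_2", fixed = TRUE)
  skip_if_not_installed("ape")
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("annotation counts unique labels per concept", {
  store <- build_fixture("leg_example") |>
    add_term("hind femur") |>
    add_sensu("hind femur", "femur", "ref_fix")
  nwk <- export_newick(store, annotate = TRUE)
  expect_match(nwk, "femur[&labels=2]", fixed = TRUE)
  expect_match(nwk, "leg[&labels=1]", fixed = TRUE)
  # bracketed comments strip to a standard-parseable tree
  skip_if_not_installed("ape")
  plain <- gsub("\\[[^]]*\\]", "", nwk)
  expect_s3_class(ape::read.tree(text = plain), "phylo")
})

test_that("multiple roots error unless forest export is requested", {
  store <- onto_store() |>
    add_reference("r", ref_id = "r1") |>
    add_concept(uid = "a", differentia = "d", status = "released",
                public_id = "HAO:0000001") |>
    add_term("alpha") |> add_sensu("alpha", "a", "r1", obo_label = TRUE) |>
    add_concept(uid = "b", differentia = "d", status = "released",
                public_id = "HAO:0000002") |>
    add_term("beta") |> add_sensu("beta", "b", "r1", obo_label = TRUE)
  expect_error(export_newick(store), class = "onto_error_multi_root")
  expect_equal(export_newick(store, forest = TRUE), "(alpha,beta);")
})
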