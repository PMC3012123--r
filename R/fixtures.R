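#' Build worked-example and random ontology stores
#'
#' Self-contained stores used throughout the documentation and tests; no
#' external data is needed. Available fixtures:
#'
#' * `"leg_example"` -- the classic reasoning example: concepts root, leg,
#'   fore leg and femur with `fore_leg is_a leg`, `femur part_of leg`,
#'   `leg is_a root`; all released, each with a labelled sensu. Asserting
#'   "legs are yellow" on this store lets [propagate_property()] infer the
#'   colour of the fore leg (via is_a) and of the femur (via part_of).
#' * `"paramere"` -- the homonymy worked example: one term "paramere" whose
#'   five sensus, from five different publications, point at five mutually
#'   incompatible referent sets over the genital concepts with public ids
#'   HAO:0000707, HAO:0000395, HAO:0000389 and HAO:0001084 -- three
#'   singletons and two composites (389+1084 and 707+389+1084). Member
#'   concept labels are invented placeholders; the original structure names
#'   exist only as image overlays.
#' * `"sensu_demo"` -- the minimal inference demo: terms T1, T2, T3,
#'   concepts C1, C2, references R1-R3, wired so that T1, T2, T3 are
#'   synonyms (all reference C1), T3 is homonymous (C1 and C2), and R1 is an
#'   act of synonymy (it links both T2 and T3 to C1).
#' * `"phallobase"` -- one concept with two sensus citing the same
#'   publication for "phallobase" and "gonocoxite IX": the two labels are
#'   synonyms.
#' * `"random"` -- a seeded random ontology: `n_concepts` candidates whose
#'   hierarchy edges run only from later to earlier creation order (acyclic
#'   by construction, edge probability `edge_prob`, relation type drawn from
#'   is_a/part_of), a term pool, and `n_sensus` random sensus (10% composite
#'   two-concept referents) over `n_refs` references.
#'
#' Every fixture passes [validate_onto()] with zero error findings.
#'
#' @param name Fixture name.
#' @param n_concepts,edge_prob,n_sensus,n_terms,n_refs,seed Parameters for
#'   `"random"`.
#' @return An `onto_store`.
#' @examples
#' homonyms(build_fixture("paramere"))$n_referents
#' @export
build_fixture <- function(name = c("leg_example", "paramere", "sensu_demo",
                                   "phallobase", "random"),
                          n_concepts = 50, edge_prob = 0.08, n_sensus = 120,
                          n_terms = 60, n_refs = 12, seed = 1L) {
  name <- match.arg(name)
  switch(name,
         leg_example = fixture_leg(),
         paramere = fixture_paramere(),
         sensu_demo = fixture_sensu_demo(),
         phallobase = fixture_phallobase(),
         random = fixture_random(n_concepts, edge_prob, n_sensus,
                                 n_terms, n_refs, seed))
}

# released concept + term + obo-label sensu in one step
released_concept <- function(store, uid, label, public_id, genus = NULL,
                             differentia = "is a distinct anatomical entity",
                             reference = "ref_fix") {
  store <- add_concept(store, uid = uid, genus = genus,
                       differentia = differentia, status = "released",
                       public_id = public_id)
  store <- add_term(store, label, uid = paste0("t_", uid))
  add_sensu(store, paste0("t_", uid), uid, reference, obo_label = TRUE)
}

fixture_leg <- function() {
  onto_store() |>
    add_reference("Fixture glossary reference", ref_id = "ref_fix") |>
    released_concept("root", "anatomical entity", "HAO:0000001",
                     differentia = "An entity that is part of the anatomy of an organism.") |>
    released_concept("leg", "leg", "HAO:0000002", genus = "root",
                     differentia = "is a segmented locomotory appendage") |>
    released_concept("fore_leg", "fore leg", "HAO:0000003", genus = "leg",
                     differentia = "is attached to the prothorax") |>
    released_concept("femur", "femur", "HAO:0000004", genus = "root",
                     differentia = "is the third segment of the leg") |>
    add_relationship("leg", "is_a", "root") |>
    add_relationship("fore_leg", "is_a", "leg") |>
    add_relationship("femur", "part_of", "leg")
}

fixture_paramere <- function() {
  store <- onto_store() |>
    add_reference("Usage source A", ref_id = "R1") |>
    add_reference("Usage source B", ref_id = "R2") |>
    add_reference("Usage source C", ref_id = "R3") |>
    add_reference("Usage source D", ref_id = "R4") |>
    add_reference("Usage source E", ref_id = "R5") |>
    add_reference("Fixture glossary reference", ref_id = "ref_fix") |>
    released_concept("root", "male genitalia", "HAO:0000312",
                     differentia = "An anatomical cluster comprising the external male reproductive structures.")
  # placeholder labels: the real structure names are image overlays
  store <- store |>
    released_concept("c707", "genital structure A", "HAO:0000707",
                     genus = "root", differentia = "is genital sclerite A") |>
    released_concept("c395", "genital structure B", "HAO:0000395",
                     genus = "root", differentia = "is genital sclerite B") |>
    released_concept("c389", "genital structure C", "HAO:0000389",
                     genus = "root", differentia = "is genital sclerite C") |>
    released_concept("c1084", "genital structure D", "HAO:0001084",
                     genus = "root", differentia = "is genital sclerite D") |>
    add_relationship("c707", "is_a", "root") |>
    add_relationship("c395", "is_a", "root") |>
    add_relationship("c389", "is_a", "root") |>
    add_relationship("c1084", "is_a", "root") |>
    add_term("paramere", uid = "t_paramere")
  # five incompatible usages: three singleton referents, two composites
  store |>
    add_sensu("t_paramere", "c707", "R1") |>
    add_sensu("t_paramere", "c395", "R2") |>
    add_sensu("t_paramere", "c389", "R3") |>
    add_sensu("t_paramere", c("c389", "c1084"), "R4") |>
    add_sensu("t_paramere", c("c707", "c389", "c1084"), "R5")
}

fixture_sensu_demo <- function() {
  onto_store() |>
    add_reference("Publication one", ref_id = "R1") |>
    add_reference("Publication two", ref_id = "R2") |>
    add_reference("Publication three", ref_id = "R3") |>
    add_concept(uid = "C1") |>
    add_concept(uid = "C2") |>
    add_term("T1", uid = "T1") |>
    add_term("T2", uid = "T2") |>
    add_term("T3", uid = "T3") |>
    add_sensu("T1", "C1", "R2") |>
    add_sensu("T2", "C1", "R1") |>
    add_sensu("T3", "C1", "R1") |>
    add_sensu("T3", "C2", "R3")
}

fixture_phallobase <- function() {
  onto_store() |>
    add_reference("Genitalia monograph", ref_id = "R1") |>
    add_concept(uid = "c_phallobase",
                differentia = "is the basal part of the aedeagus") |>
    add_term("phallobase") |>
    add_term("gonocoxite IX") |>
    add_sensu("phallobase", "c_phallobase", "R1") |>
    add_sensu("gonocoxite IX", "c_phallobase", "R1")
}

fixture_random <- function(n_concepts, edge_prob, n_sensus, n_terms,
                           n_refs, seed) {
  set.seed(seed)
  store <- onto_store()
  for (r in seq_len(n_refs)) {
    store <- add_reference(store, sprintf("Random reference %d", r),
                           ref_id = sprintf("R%d", r))
  }
  for (i in seq_len(n_concepts)) {
    store <- add_concept(store, uid = sprintf("c%03d", i))
  }
  # acyclic by construction: edges only from later to earlier concepts
  for (i in seq_len(n_concepts)[-1]) {
    for (j in seq_len(i - 1)) {
      if (stats::runif(1) < edge_prob) {
        rel <- sample(c("is_a", "part_of"), 1)
        store <- add_relationship(store, sprintf("c%03d", i), rel,
                                  sprintf("c%03d", j))
      }
    }
  }
  for (t in seq_len(n_terms)) {
    store <- add_term(store, sprintf("term %03d", t), uid = sprintf("t%03d", t))
  }
  tries <- 0L
  added <- 0L
  while (added < n_sensus && tries < n_sensus * 20L) {
    tries <- tries + 1L
    term <- sprintf("t%03d", sample.int(n_terms, 1))
    k <- if (stats::runif(1) < 0.1) 2L else 1L
    referent <- sprintf("c%03d", sample.int(n_concepts, k))
    ref <- sprintf("R%d", sample.int(n_refs, 1))
    ok <- tryCatch({
      store <- add_sensu(store, term, referent, ref)
      TRUE
    }, onto_error_duplicate = function(e) FALSE)
    if (ok) added <- added + 1L
  }
  store
}
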