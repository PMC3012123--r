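#' Export the released ontology as OBO 1.2
#'
#' Serializes one `[Term]` stanza per released concept, sorted by public id,
#' so identical stores yield byte-identical documents (for a fixed `date`).
#' Candidates are excluded. Each stanza carries the preferred label as
#' `name`, the rendered genus-differentia definition ("A <genus label> that
#' <differentia>.") with the supporting reference ids as definition
#' cross-references, other labels as `synonym` lines (scope EXACT when the
#' synonym's sensu referent is exactly this concept, RELATED when the label
#' reaches the concept only through a composite multi-concept referent),
#' `xref` lines from tags with keyword "xref", and `is_a` /
#' `relationship` lines restricted to released targets so every id
#' mentioned in the document is defined in it.
#'
#' @param store An `onto_store`; must pass [validate_onto()] with no
#'   error-severity findings, and every released concept must have a
#'   preferred label.
#' @param date Header timestamp (`dd:mm:yyyy HH:MM`); defaults to the
#'   current time. Fix it to make output reproducible across runs.
#' @return The OBO document as a single string.
#' @examples
#' cat(export_obo(build_fixture("leg_example"), date = "01:01:2026 00:00"))
#' @export
export_obo <- function(store, date = format(Sys.time(), "%d:%m:%Y %H:%M")) {
  assert_store(store)
  findings <- validate_onto(store)
  if (any(findings$severity == "error")) {
    abort_onto(paste0(
      "Store fails validation; fix error findings before export:\n",
      paste(findings$message[findings$severity == "error"], collapse = "\n")),
      "onto_error_validation", findings = findings)
  }
  cc <- store$concepts[store$concepts$status == "released", ]
  prefix <- store$config$id_prefix
  header <- c(
    "format-version: 1.2",
    paste0("date: ", date),
    paste0("default-namespace: ", tolower(prefix))
  )
  if (nrow(cc) == 0) return(paste0(paste(header, collapse = "\n"), "\n"))

  cc <- cc[order(cc$public_id), ]
  released <- cc$uid
  pid <- stats::setNames(cc$public_id, cc$uid)
  keys <- referent_keys(store$sensus$referent)
  label_of <- function(uid) {
    tryCatch(preferred_label(store, uid),
             onto_error_no_label = function(e) {
               abort_onto(sprintf(
                 "Released concept '%s' (%s) has no preferred label; cannot export.",
                 uid, pid[[uid]]), "onto_error_export", parent = e)
             })
  }
  pref <- lapply(released, label_of)
  names(pref) <- released
  labels <- vapply(pref, `[[`, character(1), "text")

  stanza <- function(uid) {
    row <- cc[cc$uid == uid, ]
    lines <- c("[Term]", paste0("id: ", pid[[uid]]),
               paste0("name: ", labels[[uid]]))
    # definition: "A <genus label> that <differentia>." (root: text only)
    if (!is.na(row$differentia)) {
      def <- if (!is.na(row$genus) && row$genus %in% names(labels)) {
        sprintf("A %s that %s.", labels[[row$genus]], row$differentia)
      } else if (!is.na(row$genus)) {
        sprintf("A %s that %s.", row$genus, row$differentia)
      } else {
        row$differentia
      }
      refs <- sort(unique(store$sensus$reference[keys == uid]))
      lines <- c(lines, sprintf('def: "%s" [%s]', def,
                                paste(refs, collapse = ", ")))
    }
    # synonyms
    pref_uid <- pref[[uid]]$uid
    exact <- store$sensus[keys == uid & store$sensus$term != pref_uid, ]
    syn_lines <- character()
    for (t in sort(unique(exact$term))) {
      txt <- store$terms$text[store$terms$uid == t]
      refs <- sort(unique(exact$reference[exact$term == t]))
      syn_lines <- c(syn_lines, sprintf('synonym: "%s" EXACT [%s]', txt,
                                        paste(refs, collapse = ", ")))
    }
    comp <- store$sensus[lengths(store$sensus$referent) > 1, ]
    comp <- comp[vapply(comp$referent, function(s) uid %in% s, logical(1)), ]
    for (t in sort(unique(comp$term))) {
      txt <- store$terms$text[store$terms$uid == t]
      refs <- sort(unique(comp$reference[comp$term == t]))
      syn_lines <- c(syn_lines, sprintf(
        'synonym: "%s" RELATED [%s] ! composite referent', txt,
        paste(refs, collapse = ", ")))
    }
    lines <- c(lines, sort(syn_lines))
    # xrefs
    xr <- store$tags[store$tags$target == uid &
                       store$tags$keyword == "xref", ]
    xrn <- xr$note[!is.na(xr$note)]
    if (length(xrn)) lines <- c(lines, sort(paste0("xref: ", xrn)))
    # relationships to released targets only
    rr <- store$relationships[store$relationships$subject == uid &
                                store$relationships$object %in% released, ]
    isa <- rr[rr$rel_type == "is_a", ]
    isa <- isa[order(pid[isa$object]), ]
    lines <- c(lines, sprintf("is_a: %s ! %s", pid[isa$object],
                              labels[isa$object]))
    oth <- rr[rr$rel_type != "is_a", ]
    oth <- oth[order(oth$rel_type, pid[oth$object]), ]
    lines <- c(lines, sprintf("relationship: %s %s ! %s", oth$rel_type,
                              pid[oth$object], labels[oth$object]))
    paste(lines, collapse = "\n")
  }
  stanzas <- vapply(cc$uid, stanza, character(1))
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(stanzas, collapse = "\n\n"), "\n")
}

#' @rdname export_obo
#' @param path Output file path.
#' @export
write_obo <- function(store, path, date = format(Sys.time(), "%d:%m:%Y %H:%M")) {
  writeLines(sub("\n$", "", export_obo(store, date = date)), path,
             useBytes = TRUE)
  invisible(store)
}

#' Import an OBO 1.2 document
#'
#' Parses `[Term]` stanzas into a store of released concepts: names become
#' OBO-label sensus, synonym lines become sensus citing their dbxref
#' references (or a synthetic "obo_import" reference when none is given),
#' and is_a/relationship lines become relationships. The genus is taken from
#' the first is_a parent and the differentia recovered from the rendered
#' definition where it matches "A ... that ...". Full sensu provenance and
#' composite referent membership are lossy by design: RELATED synonyms are
#' recorded as plain terms tagged on the concept, not reconstructed into
#' multi-concept referents.
#'
#' @param x OBO document text (single string or lines) or a file path.
#' @return An `onto_store`.
#' @export
import_obo <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
  }
  # split header / stanzas
  stanza_starts <- grep("^\\[", lines)
  header <- lines[seq_len(if (length(stanza_starts)) stanza_starts[1] - 1 else length(lines))]
  ns <- sub("^default-namespace: *", "",
            grep("^default-namespace:", header, value = TRUE))
  prefix <- if (length(ns)) toupper(ns[1]) else "HAO"
  store <- onto_store(id_prefix = prefix)

  terms <- list()
  for (i in seq_along(stanza_starts)) {
    from <- stanza_starts[i]
    to <- if (i < length(stanza_starts)) stanza_starts[i + 1] - 1 else length(lines)
    if (trimws(lines[from]) != "[Term]") next
    body <- lines[(from + 1):to]
    body <- body[nzchar(trimws(body))]
    st <- parse_stanza(body, from)
    terms[[length(terms) + 1]] <- st
  }
  if (length(terms) == 0) return(store)

  ids <- vapply(terms, `[[`, character(1), "id")
  # references first
  all_refs <- sort(unique(unlist(lapply(terms, function(s) {
    c(s$def_refs, unlist(lapply(s$synonyms, `[[`, "refs")))
  }))))
  for (r in all_refs) store <- add_reference(store, citation = r, ref_id = r)
  if (!"obo_import" %in% store$references$ref_id) {
    store <- add_reference(store, citation = "imported OBO document",
                           ref_id = "obo_import")
  }
  # concepts (two passes: create, then set genus/relationships)
  for (s in terms) {
    diff_txt <- s$def %||% sprintf("imported class %s", s$id)
    m <- regmatches(diff_txt,
                    regexec("^A .+ that (.+)\\.$", diff_txt))[[1]]
    if (length(m) == 2) diff_txt <- m[2]
    store <- add_concept(store, uid = s$id, differentia = diff_txt,
                         status = "released", public_id = s$id)
  }
  for (s in terms) {
    parents <- s$is_a[s$is_a %in% ids]
    for (p in setdiff(s$is_a, ids)) {
      rlang::warn(sprintf("Stanza %s: dangling is_a target '%s' dropped.",
                          s$id, p), class = "onto_warning_dangling")
    }
    if (length(parents)) {
      store$concepts$genus[store$concepts$uid == s$id] <- parents[1]
    }
    for (p in parents) store <- add_relationship(store, s$id, "is_a", p)
    for (r in s$relationships) {
      if (!r$target %in% ids) {
        rlang::warn(sprintf(
          "Stanza %s: dangling %s target '%s' dropped.", s$id, r$type,
          r$target), class = "onto_warning_dangling")
        next
      }
      if (!r$type %in% store$rel_types$name) {
        store <- add_rel_type(store, r$type)
      }
      store <- add_relationship(store, s$id, r$type, r$target)
    }
  }
  # labels and synonyms as sensus
  for (s in terms) {
    if (!any(store$terms$text == s$name)) store <- add_term(store, s$name)
    ref0 <- if (length(s$def_refs)) s$def_refs[1] else "obo_import"
    store <- add_sensu(store, s$name, s$id, ref0, order_rank = 1L,
                       obo_label = TRUE)
    for (sy in s$synonyms) {
      if (sy$scope != "EXACT") next
      if (!any(store$terms$text == sy$text)) store <- add_term(store, sy$text)
      refs <- if (length(sy$refs)) sy$refs else "obo_import"
      for (r in refs) {
        keys <- referent_keys(store$sensus$referent)
        t_uid <- store$terms$uid[store$terms$text == sy$text][1]
        dupe <- any(store$sensus$term == t_uid & keys == s$id &
                      store$sensus$reference == r)
        if (!dupe) store <- add_sensu(store, sy$text, s$id, r)
      }
    }
  }
  store
}

parse_stanza <- function(body, line0) {
  st <- list(id = NULL, name = NULL, def = NULL, def_refs = character(),
             synonyms = list(), is_a = character(), relationships = list())
  for (k in seq_along(body)) {
    line <- trimws(body[k])
    m <- regmatches(line, regexec("^([a-z_-]+): *(.*)$", line))[[1]]
    if (length(m) != 3) {
      abort_onto(sprintf("Malformed OBO line %d: '%s'", line0 + k, line),
                 "onto_error_parse")
    }
    key <- m[2]; val <- m[3]
    val <- sub(" *!.*$", "", val)  # strip trailing comment
    if (key == "id") st$id <- val
    else if (key == "name") st$name <- val
    else if (key == "def") {
      q <- regmatches(val, regexec('^"(.*)" *(\\[(.*)\\])?$', val))[[1]]
      if (length(q) < 2) {
        abort_onto(sprintf("Malformed def at line %d", line0 + k),
                   "onto_error_parse")
      }
      st$def <- q[2]
      if (length(q) >= 4 && nzchar(q[4])) {
        st$def_refs <- trimws(strsplit(q[4], ",")[[1]])
      }
    } else if (key == "synonym") {
      q <- regmatches(val, regexec(
        '^"(.*)" +([A-Z]+) *(\\[(.*)\\])?$', val))[[1]]
      if (length(q) < 3) {
        abort_onto(sprintf("Malformed synonym at line %d", line0 + k),
                   "onto_error_parse")
      }
      refs <- if (length(q) >= 5 && nzchar(q[5])) {
        trimws(strsplit(q[5], ",")[[1]])
      } else character()
      st$synonyms[[length(st$synonyms) + 1]] <-
        list(text = q[2], scope = q[3], refs = refs)
    } else if (key == "is_a") {
      st$is_a <- c(st$is_a, trimws(val))
    } else if (key == "relationship") {
      parts <- strsplit(trimws(val), " +")[[1]]
      if (length(parts) < 2) {
        abort_onto(sprintf("Malformed relationship at line %d", line0 + k),
                   "onto_error_parse")
      }
      st$relationships[[length(st$relationships) + 1]] <-
        list(type = parts[1], target = parts[2])
    }
    # other keys (xref, comment, ...) tolerated and skipped
  }
  if (is.null(st$id) || is.null(st$name)) {
    abort_onto(sprintf("Stanza at line %d lacks id or name.", line0),
               "onto_error_parse")
  }
  st
}
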