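# Independent brute-force oracles, deliberately written without reusing any
# package internals: plain loops and recursion only.

# Depth-first cycle detection on an edge data frame (subject -> object).
oracle_has_cycle <- function(edges, nodes) {
  colour <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 white 1 grey 2 black
  visit <- function(v) {
    colour[v] <<- 1L
    for (w in edges$object[edges$subject == v]) {
      if (colour[w] == 1L) return(TRUE)
      if (colour[w] == 0L && visit(w)) return(TRUE)
    }
    colour[v] <<- 2L
    FALSE
  }
  for (v in nodes) {
    if (colour[v] == 0L && visit(v)) return(TRUE)
  }
  FALSE
}

# Breadth-first reachability (excluding the start node) over given edges.
oracle_reachable <- function(edges, from, forward = TRUE) {
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      step <- if (forward) edges$object[edges$subject == v]
      else edges$subject[edges$object == v]
      for (w in step) {
        if (!w %in% c(seen, from)) {
          seen <- c(seen, w)
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  sort(seen)
}

oracle_key <- function(s) paste(sort(unique(s)), collapse = "+")

# Exhaustive pairwise synonym pairs: unordered term pairs sharing an exact
# referent set between some pair of sensus.
oracle_synonym_pairs <- function(store) {
  ss <- store$sensus
  pairs <- character()
  n <- nrow(ss)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (ss$term[i] == ss$term[j]) next
      if (oracle_key(ss$referent[[i]]) == oracle_key(ss$referent[[j]])) {
        pairs <- c(pairs, paste(sort(c(ss$term[i], ss$term[j])),
                                collapse = "|"))
      }
    }
  }
  sort(unique(pairs))
}

# Terms whose sensus carry >= 2 distinct referent sets.
oracle_homonym_terms <- function(store) {
  ss <- store$sensus
  out <- character()
  for (t in unique(ss$term)) {
    keys <- unique(vapply(ss$referent[ss$term == t], oracle_key, character(1)))
    if (length(keys) >= 2) out <- c(out, t)
  }
  sort(out)
}

# Triple-nested enumeration of acts of synonymy: (reference, referent) pairs
# with >= 2 distinct terms.
oracle_acts <- function(store) {
  ss <- store$sensus
  acts <- list()
  for (r in unique(ss$reference)) {
    sub <- ss[ss$reference == r, ]
    for (k in unique(vapply(sub$referent, oracle_key, character(1)))) {
      terms <- character()
      for (i in seq_len(nrow(sub))) {
        if (oracle_key(sub$referent[[i]]) == k) terms <- c(terms, sub$term[i])
      }
      terms <- sort(unique(terms))
      if (length(terms) >= 2) {
        acts[[length(acts) + 1]] <- list(reference = r, key = k, terms = terms)
      }
    }
  }
  acts[order(vapply(acts, function(a) paste(a$reference, a$key), character(1)))]
}

# Exhaustive leftmost-longest phrase matcher: enumerate every candidate
# match (any lexicon entry at any token position), then select scanning
# left-to-right preferring longer matches, skipping overlaps.
oracle_proof <- function(text, term_texts, plural_folding = FALSE) {
  tok_pat <- "[[:alnum:]]+(-[[:alnum:]]+)*"
  m <- gregexpr(tok_pat, text)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  toks <- tolower(substring(text, starts + 1L, ends))
  fold <- function(w) {
    if (plural_folding) {
      if (nchar(w) > 3 && grepl("es$", w)) return(sub("es$", "", w))
      if (nchar(w) > 2 && grepl("s$", w)) return(sub("s$", "", w))
    }
    w
  }
  lex <- lapply(tolower(term_texts), function(t) {
    mm <- gregexpr(tok_pat, t)[[1]]
    if (mm[1] == -1) character() else
      substring(t, as.integer(mm), as.integer(mm) + attr(mm, "match.length") - 1L)
  })
  clean_gap <- function(i) { # gap between token i and i+1 whitespace-only
    grepl("^[[:space:]]*$", substr(text, ends[i] + 1L, starts[i + 1]))
  }
  cand <- list()
  for (i in seq_along(toks)) {
    for (l in seq_along(lex)) {
      n <- length(lex[[l]])
      if (n == 0 || i + n - 1L > length(toks)) next
      if (n > 1 && !all(vapply(i:(i + n - 2L), clean_gap, logical(1)))) next
      window <- toks[i:(i + n - 1L)]
      ok <- all(window == lex[[l]] | vapply(window, fold, character(1)) == lex[[l]])
      if (ok) {
        cand[[length(cand) + 1]] <- list(tok = i, n = n,
                                         start = starts[i],
                                         end = ends[i + n - 1L])
      }
    }
  }
  sel <- list()
  i <- 1L
  while (i <= length(toks)) {
    here <- Filter(function(c) c$tok == i, cand)
    if (length(here)) {
      best <- here[[which.max(vapply(here, `[[`, integer(1), "n"))]]
      sel[[length(sel) + 1]] <- best
      i <- i + best$n
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = vapply(sel, `[[`, integer(1), "start"),
             end = vapply(sel, `[[`, integer(1), "end"))
}

# small well-formed store used by several suites
make_small_store <- function() {
  onto_store() |>
    add_reference("Ref one", ref_id = "r1") |>
    add_reference("Ref two", ref_id = "r2") |>
    add_concept(uid = "a") |>
    add_concept(uid = "b") |>
    add_concept(uid = "c") |>
    add_term("alpha") |>
    add_term("beta") |>
    add_relationship("b", "is_a", "a") |>
    add_relationship("c", "part_of", "b")
}
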