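#' Parse an OBO 1.2 flat file into a concept scheme
#'
#' Only `[Term]` stanzas are interpreted, and within them only the `id`,
#' `name`, `namespace`, `is_a` and `is_obsolete` tags. Obsolete terms are
#' excluded together with any `is_a` edge touching them; all other
#' relationship types are ignored. The surviving `is_a` edges are oriented
#' child-to-parent and must form a DAG — a cycle aborts with one offending
#' cycle spelled out.
#'
#' @param path File path, connection, or character vector of lines.
#' @return A `concept_scheme`: a list with tibbles `terms`
#'   (`id`, `name`, `namespace`) and `edges` (`child`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- if (is.character(path) && length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (inherits(path, "connection")) readLines(path, warn = FALSE) else path

  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  for (i in seq_along(stanza_starts)) {
    if (lines[stanza_starts[i]] != "[Term]") next
    from <- stanza_starts[i] + 1L
    to <- if (i < length(stanza_starts)) stanza_starts[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    tag_val <- function(tag) {
      hits <- body[startsWith(body, paste0(tag, ": "))]
      vals <- substring(hits, nchar(tag) + 3L)
      sub("\\s*!.*$", "", vals)  # trailing OBO comments
    }
    id <- tag_val("id")
    if (length(id) == 0) next
    terms[[length(terms) + 1L]] <- list(
      id = id[1],
      name = if (length(tag_val("name")) > 0) tag_val("name")[1] else NA_character_,
      namespace = if (length(tag_val("namespace")) > 0) tag_val("namespace")[1]
                  else NA_character_,
      parents = sub("\\s.*$", "", tag_val("is_a")),
      obsolete = any(tolower(tag_val("is_obsolete")) == "true")
    )
  }
  if (length(terms) == 0) {
    return(new_concept_scheme(
      tibble(id = character(), name = character(), namespace = character()),
      tibble(child = character(), parent = character())
    ))
  }
  ids <- map_chr(terms, "id")
  bad <- !grepl("^GO:[0-9]{7}$", ids)
  if (any(bad)) abort(paste0("not a GO accession: ", ids[bad][1]))
  obsolete <- map_lgl(terms, "obsolete")
  live <- ids[!obsolete]
  term_tbl <- tibble(
    id = live,
    name = map_chr(terms, "name")[!obsolete],
    namespace = map_chr(terms, "namespace")[!obsolete]
  )
  edges <- bind_rows(map(terms[!obsolete], function(t) {
    if (length(t$parents) == 0) return(NULL)
    tibble(child = t$id, parent = t$parents)
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character())
  } else {
    edges <- distinct(edges[edges$parent %in% live, ])
    if (any(edges$child == edges$parent)) {
      abort(paste0("term is its own parent: ",
                   edges$child[edges$child == edges$parent][1]))
    }
  }
  check_acyclic(term_tbl$id, edges)
  new_concept_scheme(term_tbl, edges)
}

new_concept_scheme <- function(terms, edges) {
  structure(list(terms = terms, edges = edges), class = "concept_scheme")
}

#' @export
print.concept_scheme <- function(x, ...) {
  cat("# Concept scheme:", nrow(x$terms), "terms,", nrow(x$edges),
      "broader edges\n")
  invisible(x)
}

# Kahn's algorithm; on failure walk parent links among the residual nodes
# to spell out one cycle.
check_acyclic <- function(ids, edges) {
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  children_of <- split(edges$parent, edges$child)  # child -> parents
  parents_count <- table(edges$child)
  out <- setNames(integer(length(ids)), ids)  # edges leaving child upward
  out[names(parents_count)] <- as.integer(parents_count)
  # Kahn over the child->parent digraph: repeatedly remove nodes with no
  # incoming edge (i.e. nodes that are nobody's parent)
  remaining <- edges
  active <- ids
  repeat {
    is_parent <- active %in% remaining$parent
    leaves <- active[!is_parent]
    if (length(leaves) == length(active)) break
    if (length(leaves) == 0) {
      # every remaining node has a child: walking parent -> child must
      # revisit a node, exposing one cycle
      node <- remaining$parent[1]
      path <- node
      repeat {
        nxt <- remaining$child[remaining$parent == node][1]
        if (nxt %in% path) {
          cyc <- rev(c(path[which(path == nxt):length(path)], nxt))
          abort(paste0("is_a cycle detected: ", paste(cyc, collapse = " -> ")))
        }
        path <- c(path, nxt)
        node <- nxt
      }
    }
    remaining <- remaining[!remaining$child %in% leaves, ]
    active <- active[is_parent]
    if (nrow(remaining) == 0) break
  }
  invisible(TRUE)
}

#' Convert a concept scheme to a SKOS RDF graph
#'
#' Every term becomes a `skos:Concept` node under the legacy GO namespace
#' (`go:GO_0006915` style), annotated with its name as `dc:title`; every
#' `is_a` edge becomes a `skos:broader` triple from child to parent.
#' Modelling the hierarchy as instance-level broader links (rather than
#' class subsumption) is what lets annotation propagation run as a simple
#' property chain.
#'
#' @param scheme A `concept_scheme` from [read_obo()].
#' @param vocab Vocabulary.
#' @return An `rdf_graph`.
#' @export
obo_to_skos <- function(scheme, vocab = rdf_vocabulary()) {
  stopifnot(inherits(scheme, "concept_scheme"))
  if (nrow(scheme$terms) == 0) return(rdf_graph())
  iri <- go_uri(scheme$terms$id)
  named <- !is.na(scheme$terms$name)
  g <- bind_rows(
    triple_iri(iri, vocab$rdf_type, vocab$concept),
    triple_lit(iri[named], vocab$dc_title, scheme$terms$name[named]),
    if (nrow(scheme$edges) > 0) {
      triple_iri(go_uri(scheme$edges$child), vocab$broader,
                 go_uri(scheme$edges$parent))
    }
  )
  rdf_graph(g)
}

#' Proper ancestors of a term in a concept scheme
#'
#' Transitive (non-reflexive) closure of the broader edges starting from
#' `term`.
#'
#' @param scheme A `concept_scheme`.
#' @param term GO accession present in the scheme.
#' @return Character vector of ancestor GO accessions (possibly empty).
#' @export
go_ancestors <- function(scheme, term) {
  stopifnot(inherits(scheme, "concept_scheme"))
  if (!term %in% scheme$terms$id) abort(paste0("unknown term: ", term))
  parents_of <- split(scheme$edges$parent, scheme$edges$child)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Read a GAF 2.x gene-association file
#'
#' Comment lines starting with `!` are skipped. Only the symbol (column
#' 3), qualifier (4), GO id (5), evidence code (7) and aspect (9) are
#' retained.
#'
#' @param path File path, connection, or character vector of lines.
#' @return Tibble with columns `symbol`, `qualifier`, `go_id`,
#'   `evidence_code`, `aspect`.
#' @export
read_gaf <- function(path) {
  lines <- if (is.character(path) && length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (inherits(path, "connection")) readLines(path, warn = FALSE) else path
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(symbol = character(), qualifier = character(),
                  go_id = character(), evidence_code = character(),
                  aspect = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9)
  if (length(short) > 0) {
    abort(sprintf("GAF row with fewer than 9 columns at data line %d", short[1]))
  }
  out <- tibble(
    symbol = map_chr(fields, 3),
    qualifier = map_chr(fields, 4),
    go_id = map_chr(fields, 5),
    evidence_code = map_chr(fields, 7),
    aspect = map_chr(fields, 9)
  )
  bad <- !out$aspect %in% c("P", "F", "C")
  if (any(bad)) {
    abort(sprintf("invalid GAF aspect '%s' at data line %d",
                  out$aspect[bad][1], which(bad)[1]))
  }
  out
}

#' Read a gene-symbol to RefSeq mapping table
#'
#' @param path TSV with two columns (symbol, RefSeq accession), one pair
#'   per row, no header.
#' @return Tibble with columns `symbol`, `refseq`; a symbol may map to
#'   several accessions.
#' @export
read_symbol_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("symbol", "refseq"),
                        col_types = "cc", progress = FALSE)
  if (any(is.na(df$refseq) | df$refseq == "")) {
    abort("symbol map contains an empty RefSeq accession")
  }
  distinct(as_tibble(df))
}

#' RDF property for a GAF aspect
#'
#' Biological-process annotations are linked with `participates_in`,
#' molecular functions with `has_function`, and cellular components with
#' `part_of`.
#'
#' @param aspect `"P"`, `"F"` or `"C"`.
#' @param vocab Vocabulary.
#' @return IRI string.
#' @export
aspect_property <- function(aspect, vocab = rdf_vocabulary()) {
  if (length(aspect) != 1 || !aspect %in% c("P", "F", "C")) {
    abort(paste0("unknown GAF aspect: ", paste(aspect, collapse = ",")))
  }
  switch(aspect, P = vocab$participates_in, F = vocab$has_function,
         C = vocab$part_of)
}

#' Convert GAF annotations to RDF over RefSeq transcript nodes
#'
#' Gene symbols are expanded to all their RefSeq accessions; each kept
#' record emits the transcript typing triple and one annotation triple
#' using the aspect's property. `NOT`-qualified records are dropped.
#' Records whose symbol has no RefSeq mapping or whose GO id is not in the
#' scheme are skipped and summarised in one message.
#'
#' @param gaf Tibble from [read_gaf()].
#' @param symbol_map Tibble from [read_symbol_map()].
#' @param scheme `concept_scheme` whose terms gate the annotations.
#' @param vocab Vocabulary.
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (none by default).
#' @return An `rdf_graph`.
#' @export
annotations_to_rdf <- function(gaf, symbol_map, scheme,
                               vocab = rdf_vocabulary(),
                               exclude_evidence = character(0)) {
  stopifnot(inherits(scheme, "concept_scheme"))
  gaf <- as_tibble(gaf)
  if (nrow(gaf) == 0) return(rdf_graph())
  keep <- !grepl("\\bNOT\\b", gaf$qualifier) &
    !gaf$evidence_code %in% exclude_evidence
  gaf <- gaf[keep, ]
  known_term <- gaf$go_id %in% scheme$terms$id
  mapped <- gaf$symbol %in% symbol_map$symbol
  n_skip <- sum(!known_term | !mapped)
  if (n_skip > 0) {
    message(sprintf("annotations_to_rdf: skipped %d record(s) (%d unmapped symbol, %d unknown GO id)",
                    n_skip, sum(!mapped), sum(!known_term)))
  }
  gaf <- gaf[known_term & mapped, ]
  if (nrow(gaf) == 0) return(rdf_graph())
  expanded <- inner_join(gaf, symbol_map, by = "symbol",
                         relationship = "many-to-many")
  gene <- refseq_uri(expanded$refseq)
  prop <- vapply(expanded$aspect, aspect_property, character(1), vocab = vocab,
                 USE.NAMES = FALSE)
  rdf_graph(bind_rows(
    triple_iri(unique(gene), vocab$rdf_type, vocab$transcript_class),
    triple_iri(gene, prop, go_uri(expanded$go_id))
  ))
}
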