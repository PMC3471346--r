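#' RDF graphs as tibbles of triples
#'
#' A graph is a tibble with one row per triple and columns `subject`,
#' `predicate`, `object`, `object_type` (`"iri"` or `"literal"`) and
#' `datatype` (a datatype IRI for typed literals, `NA` otherwise). Set
#' semantics hold: constructing a graph deduplicates rows, so adding a
#' triple twice leaves the size unchanged. Nodes are identified purely by
#' IRI string equality, which is what makes graph merging a union.
#'
#' @param triples A data frame with the five columns above; `object_type`
#'   and `datatype` may be omitted, in which case all objects are taken to
#'   be IRIs.
#' @return A tibble of class `rdf_graph`.
#' @examples
#' g <- rdf_graph(tibble::tibble(
#'   subject = "http://example.org/a",
#'   predicate = "http://example.org/p",
#'   object = "http://example.org/b"
#' ))
#' nrow(g)
#' @export
rdf_graph <- function(triples = NULL) {
  if (is.null(triples)) {
    triples <- tibble(
      subject = character(), predicate = character(), object = character(),
      object_type = character(), datatype = character()
    )
  }
  triples <- as_tibble(triples)
  if (!all(c("subject", "predicate", "object") %in% names(triples))) {
    abort("a graph needs subject, predicate and object columns")
  }
  if (!"object_type" %in% names(triples)) {
    triples$object_type <- rep("iri", nrow(triples))
  }
  if (!"datatype" %in% names(triples)) {
    triples$datatype <- rep(NA_character_, nrow(triples))
  }
  triples <- triples[, c("subject", "predicate", "object", "object_type", "datatype")]
  triples$datatype <- as.character(triples$datatype)
  if (any(!triples$object_type %in% c("iri", "literal"))) {
    abort("object_type must be 'iri' or 'literal'")
  }
  out <- distinct(triples)
  class(out) <- c("rdf_graph", class(tibble()))
  out
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("# RDF graph:", nrow(x), "triples\n")
  NextMethod()
}

# Row helpers -----------------------------------------------------------

triple_iri <- function(s, p, o) {
  tibble(subject = s, predicate = p, object = o,
         object_type = "iri", datatype = NA_character_)
}

triple_lit <- function(s, p, o, datatype = NA_character_) {
  tibble(subject = s, predicate = p, object = as.character(o),
         object_type = "literal", datatype = datatype)
}

# Canonical lexical form for doubles: round-trips exactly through as.numeric.
format_double <- function(x) {
  sprintf("%.17g", x)
}

triple_num <- function(s, p, x) {
  triple_lit(s, p, format_double(x), xsd_double())
}

#' Merge RDF graphs by set union
#'
#' Nodes with identical IRIs unify automatically, so merging the
#' observation, GO-annotation and transcription-factor models joins them on
#' their shared RefSeq transcript URIs. The union is commutative,
#' associative and idempotent; inputs are not modified.
#'
#' @param ... Graphs (or a single list of graphs).
#' @return The union graph.
#' @examples
#' rdf_merge(rdf_graph(), rdf_graph())
#' @export
rdf_merge <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is.data.frame(gs[[1]])) {
    gs <- gs[[1]]
  }
  if (length(gs) == 0) return(rdf_graph())
  rdf_graph(bind_rows(gs))
}

#' Test two graphs for triple-set equality
#'
#' @param a,b Graphs.
#' @return `TRUE` when both contain exactly the same set of triples.
#' @export
rdf_equal <- function(a, b) {
  a <- rdf_graph(a); b <- rdf_graph(b)
  nrow(a) == nrow(b) && nrow(anti_join(a, b,
    by = c("subject", "predicate", "object", "object_type", "datatype"))) == 0
}

# Subjects of a graph restricted to a node set.
subgraph_by_subject <- function(graph, subjects) {
  rdf_graph(graph[graph$subject %in% subjects, ])
}
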