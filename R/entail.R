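# Forward-chaining materialisation of the two property-chain rule sets.
# Both entailments are Horn rules, so chaining to fixpoint is semantically
# equivalent to running a DL reasoner over the corresponding OWL 2 property
# chain axioms, and both functions are monotone and idempotent.

#' Propagate GO annotations up the broader hierarchy
#'
#' Materialises, to fixpoint, the rule family: for each annotation
#' property p in \{participates_in, has_function, part_of\}, if
#' `(gene, p, term)` and `(term, broader, ancestor)` then
#' `(gene, p, ancestor)`. A gene annotated to apoptosis thus also
#' participates in cell death and in biological process. Propagation never
#' crosses properties: a `participates_in` annotation only ever yields
#' `participates_in` triples.
#'
#' @param graph Graph containing annotation and `skos:broader` triples.
#' @param vocab Vocabulary.
#' @return The input graph plus all entailed annotation triples.
#' @export
entail_go <- function(graph, vocab = rdf_vocabulary()) {
  graph <- rdf_graph(graph)
  props <- c(vocab$participates_in, vocab$has_function, vocab$part_of)
  broader <- graph[graph$predicate == vocab$broader & graph$object_type == "iri",
                   c("subject", "object")]
  names(broader) <- c("term", "ancestor")
  if (nrow(broader) == 0) return(graph)
  known <- graph[graph$predicate %in% props & graph$object_type == "iri",
                 c("subject", "predicate", "object")]
  frontier <- known
  acc <- known
  while (nrow(frontier) > 0) {
    derived <- inner_join(frontier, broader, by = c(object = "term"),
                          relationship = "many-to-many")
    if (nrow(derived) == 0) break
    derived <- distinct(tibble(subject = derived$subject,
                               predicate = derived$predicate,
                               object = derived$ancestor))
    frontier <- anti_join(derived, acc,
                          by = c("subject", "predicate", "object"))
    acc <- bind_rows(acc, frontier)
  }
  new_triples <- anti_join(acc, known, by = c("subject", "predicate", "object"))
  rdf_graph(bind_rows(graph, mutate(new_triples, object_type = "iri",
                                    datatype = NA_character_)))
}

#' Materialise the transcription-factor coregulation closure
#'
#' Two rule sets run to fixpoint. First, if a factor `corresponds_to` a
#' gene g1 and `regulates` a gene g2, then `(g1, coregulates, g2)`.
#' Second, `indirectly_coregulates` connects every pair of genes joined by
#' a coregulates path of length at least two — the full sphere of
#' influence when `indirect_depth = "inf"` (reachability closure, cycles
#' included), or only the single chain step (paths of length exactly two)
#' when `indirect_depth = "2"`.
#'
#' Cycles in the network can entail self-edges (a gene coregulating
#' itself); with `allow_self = FALSE` derived self-edges are suppressed
#' from the output. Suppression is applied after the closure is computed,
#' so reachability through a cycle is unaffected.
#'
#' @param graph Graph containing `corresponds_to` and `regulates` triples.
#' @param vocab Vocabulary.
#' @param allow_self Keep derived self-edges (default `TRUE`: the DL
#'   entailment over a cycle does produce them).
#' @param indirect_depth `"inf"` (default) or `"2"`.
#' @return The input graph plus derived `coregulates` and
#'   `indirectly_coregulates` triples.
#' @export
entail_tf <- function(graph, vocab = rdf_vocabulary(), allow_self = TRUE,
                      indirect_depth = c("inf", "2")) {
  indirect_depth <- match.arg(as.character(indirect_depth), c("inf", "2"))
  graph <- rdf_graph(graph)
  corr <- graph[graph$predicate == vocab$corresponds_to, c("subject", "object")]
  names(corr) <- c("tf", "gene")
  reg <- graph[graph$predicate == vocab$regulates, c("subject", "object")]
  names(reg) <- c("tf", "target")
  coreg <- distinct(inner_join(corr, reg, by = "tf",
                               relationship = "many-to-many")[, c("gene", "target")])
  # corresponds_to is materialised in both directions; only the rows whose
  # "tf" really is a factor join against regulates, so the rule is safe.
  indirect <- if (nrow(coreg) == 0) {
    coreg
  } else if (indirect_depth == "2") {
    distinct(inner_join(coreg, coreg, by = c(target = "gene"),
                        relationship = "many-to-many") %>%
               select(gene = "gene", target = "target.y"))
  } else {
    closure_two_plus(coreg)
  }
  if (!allow_self) {
    coreg <- coreg[coreg$gene != coreg$target, ]
    indirect <- indirect[indirect$gene != indirect$target, ]
  }
  derived <- bind_rows(
    if (nrow(coreg) > 0) triple_iri(coreg$gene, vocab$coregulates, coreg$target),
    if (nrow(indirect) > 0) triple_iri(indirect$gene,
                                       vocab$indirectly_coregulates,
                                       indirect$target)
  )
  rdf_graph(bind_rows(graph, derived))
}

# Pairs (u, v) joined by an edge path of length >= 2, via iterated join to
# fixpoint (R <- R union R.E starting from E.E).
closure_two_plus <- function(edges) {
  step <- function(r) {
    distinct(inner_join(r, edges, by = c(target = "gene"),
                        relationship = "many-to-many") %>%
               select(gene = "gene", target = "target.y"))
  }
  acc <- step(edges)
  frontier <- acc
  while (nrow(frontier) > 0) {
    nxt <- anti_join(step(frontier), acc, by = c("gene", "target"))
    acc <- bind_rows(acc, nxt)
    frontier <- nxt
  }
  acc
}
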