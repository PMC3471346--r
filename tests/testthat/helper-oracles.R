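# Independent oracle implementations used to validate the entailment and
# query machinery. Everything here is plain base-R set/matrix code with no
# calls into the code paths under test.

# proper ancestors of every node in a child->parent edge list, by boolean
# matrix powers
oracle_ancestor_sets <- function(nodes, child, parent) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(child) > 0) adj[cbind(child, parent)] <- TRUE
  acc <- adj
  p <- adj
  repeat {
    p <- (p %*% adj) > 0
    nxt <- acc | p
    if (all(nxt == acc)) break
    acc <- nxt
  }
  lapply(setNames(nodes, nodes), function(v) sort(nodes[acc[v, ]]))
}

# pairs reachable by directed paths of length >= min_len
oracle_reachable_pairs <- function(nodes, from, to, min_len = 1L) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(from) > 0) adj[cbind(from, to)] <- TRUE
  acc <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  p <- diag(n) == 1
  for (len in seq_len(n)) {
    p <- (p %*% adj) > 0
    if (len >= min_len) acc <- acc | p
  }
  which_idx <- which(acc, arr.ind = TRUE)
  if (nrow(which_idx) == 0) {
    return(tibble::tibble(from = character(), to = character()))
  }
  out <- tibble::tibble(from = nodes[which_idx[, 1]], to = nodes[which_idx[, 2]])
  out[order(out$from, out$to, method = "radix"), ]
}

# exhaustive Fisher p-values by enumerating all tables with the observed
# margins; probabilities from log binomial coefficients, not dhyper
oracle_fisher <- function(a, b, c, d, sided) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(n, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  if (sided == "greater") {
    sum(probs[support >= a])
  } else {
    min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
  }
}

# random small RDF graph for algebraic property tests
random_graph <- function(n, seed) {
  withr::with_seed(seed, {
    subj <- paste0("http://example.org/s", sample(5, n, replace = TRUE))
    pred <- paste0("http://example.org/p", sample(3, n, replace = TRUE))
    lit <- runif(n) < 0.4
    obj <- ifelse(lit, as.character(round(runif(n), 3)),
                  paste0("http://example.org/o", sample(5, n, replace = TRUE)))
    rdf_graph(tibble::tibble(
      subject = subj, predicate = pred, object = obj,
      object_type = ifelse(lit, "literal", "iri"),
      datatype = ifelse(lit, "http://www.w3.org/2001/XMLSchema#double",
                        NA_character_)
    ))
  })
}

# extract (subject, predicate, object) annotation triples for a property
annotation_pairs <- function(graph, prop) {
  rows <- graph[graph$predicate == prop, c("subject", "object")]
  rows[order(rows$subject, rows$object, method = "radix"), ]
}

# random rooted DAG in concept_scheme shape plus random annotations,
# for entailment property tests
random_annotation_setup <- function(seed, max_terms = 30, max_genes = 40) {
  withr::with_seed(seed, {
    n_terms <- sample(3:max_terms, 1)
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    child <- character(0); parent <- character(0)
    for (i in 2:n_terms) {
      k <- sample(1:min(2, i - 1), 1)
      ps <- sample(ids[seq_len(i - 1)], k)
      child <- c(child, rep(ids[i], k)); parent <- c(parent, ps)
    }
    n_genes <- sample(1:max_genes, 1)
    genes <- sprintf("NM_%06d", seq_len(n_genes))
    n_ann <- sample(1:(2 * n_genes), 1)
    ann <- tibble::tibble(
      gene = sample(genes, n_ann, replace = TRUE),
      aspect = sample(c("P", "F", "C"), n_ann, replace = TRUE),
      term = sample(ids, n_ann, replace = TRUE)
    )
    list(ids = ids, child = child, parent = parent, genes = genes, ann = ann)
  })
}

# random TF tables (long format) whose coregulation networks may contain
# self-loops and cycles
random_tf_graph <- function(seed, max_genes = 20, max_tfs = 6) {
  withr::with_seed(seed, {
    n_genes <- sample(3:max_genes, 1)
    genes <- sprintf("NM_%06d", seq_len(n_genes))
    n_tfs <- sample(1:max_tfs, 1)
    rows <- lapply(seq_len(n_tfs), function(i) {
      expressing <- sample(genes, 1)  # self-loops arise when also regulated
      regulated <- sample(genes, sample(seq_len(min(4, n_genes)), 1))
      tibble::tibble(tf = paste0("TF", i),
                     role = c("expresses", rep("regulates", length(regulated))),
                     gene = c(expressing, regulated))
    })
    dplyr::bind_rows(rows)
  })
}

# sorted subject/object pairs for one predicate
coreg_pairs <- function(graph, prop) {
  rows <- graph[graph$predicate == prop, c("subject", "object")]
  rows <- rows[order(rows$subject, rows$object, method = "radix"), ]
  as.data.frame(rows, optional = TRUE)
}

# helper to build the annotation graph for a random setup
annotation_graph_from_setup <- function(setup, vocab = rdf_vocabulary()) {
  prop <- c(P = vocab$participates_in, F = vocab$has_function,
            C = vocab$part_of)
  rdf_graph(dplyr::bind_rows(
    tibble::tibble(subject = go_uri(setup$child), predicate = vocab$broader,
                   object = go_uri(setup$parent),
                   object_type = "iri", datatype = NA_character_),
    tibble::tibble(subject = refseq_uri(setup$ann$gene),
                   predicate = unname(prop[setup$ann$aspect]),
                   object = go_uri(setup$ann$term),
                   object_type = "iri", datatype = NA_character_)
  ))
}
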