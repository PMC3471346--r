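chain_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0008219", "name: cell death",
    "namespace: biological_process", "is_a: GO:0008150 ! biological_process", "",
    "[Term]", "id: GO:0006915", "name: apoptosis",
    "namespace: biological_process", "is_a: GO:0008219 ! cell death")
}

test_that("OBO parsing keeps live terms and is_a edges only", {
  empty <- read_obo(c("format-version: 1.2", "[Typedef]", "id: part_of"))
  expect_equal(nrow(empty$terms), 0)

  scheme <- read_obo(chain_obo())
  expect_equal(nrow(scheme$terms), 3)
  expect_equal(nrow(scheme$edges), 2)
  expect_true(all(c("GO:0006915", "GO:0008219") %in% scheme$edges$child))

  obsolete <- read_obo(c(chain_obo(), "",
                         "[Term]", "id: GO:0000005", "name: gone",
                         "namespace: biological_process",
                         "is_a: GO:0008150", "is_obsolete: true"))
  expect_false("GO:0000005" %in% obsolete$terms$id)
  expect_false("GO:0000005" %in% obsolete$edges$child)

  cyclic <- c("[Term]", "id: GO:0000001", "name: a", "is_a: GO:0000002", "",
              "[Term]", "id: GO:0000002", "name: b", "is_a: GO:0000001")
  expect_error(read_obo(cyclic), "cycle")
})

test_that("SKOS conversion emits typed concepts and broader edges", {
  v <- rdf_vocabulary()
  expect_equal(nrow(obo_to_skos(read_obo(character(0)), v)), 0)
  g <- obo_to_skos(read_obo(chain_obo()), v)
  concepts <- g$subject[g$predicate == v$rdf_type & g$object == v$concept]
  expect_length(unique(concepts), 3)
  broader <- g[g$predicate == v$broader, ]
  expect_equal(nrow(broader), 2)
  expect_true(go_uri("GO:0006915") %in% broader$subject)
  expect_match(go_uri("GO:0006915"), "GO#0006915$")
})

test_that("aspects map to the three relation-ontology properties", {
  v <- rdf_vocabulary()
  expect_identical(aspect_property("P", v), v$participates_in)
  expect_identical(aspect_property("F", v), v$has_function)
  expect_identical(aspect_property("C", v), v$part_of)
  expect_error(aspect_property("X", v), "aspect")
})

gaf_line <- function(symbol, go_id, aspect = "P", qualifier = "") {
  paste("DB", symbol, symbol, qualifier, go_id, "REF:1", "IEA", "", aspect,
        "", "", "transcript", "taxon:9606", "20120101", "DB", "", "",
        sep = "\t")
}

test_that("GAF records convert to annotation triples with symbol expansion", {
  v <- rdf_vocabulary()
  scheme <- read_obo(chain_obo())
  symmap <- read_symbol_map(I("TP53\tNM_000546\nDUP\tNM_000100\nDUP\tNM_000101"))

  gaf <- read_gaf(c("!gaf-version: 2.1", gaf_line("TP53", "GO:0006915")))
  g <- annotations_to_rdf(gaf, symmap, scheme, v)
  expect_true(any(g$subject == refseq_uri("NM_000546") &
                    g$predicate == v$participates_in &
                    g$object == go_uri("GO:0006915")))

  not_gaf <- read_gaf(gaf_line("TP53", "GO:0006915", qualifier = "NOT"))
  expect_equal(nrow(annotations_to_rdf(not_gaf, symmap, scheme, v)), 0)

  dup_gaf <- read_gaf(gaf_line("DUP", "GO:0008219"))
  g2 <- annotations_to_rdf(dup_gaf, symmap, scheme, v)
  ann2 <- g2[g2$predicate == v$participates_in, ]
  expect_equal(nrow(ann2), 2)

  unknown <- read_gaf(c(gaf_line("NOPE", "GO:0006915"),
                        gaf_line("TP53", "GO:9999999")))
  expect_message(g3 <- annotations_to_rdf(unknown, symmap, scheme, v),
                 "skipped 2")
  expect_equal(nrow(g3), 0)
})

test_that("ancestor queries match the matrix reachability oracle", {
  scheme <- read_obo(chain_obo())
  expect_equal(go_ancestors(scheme, "GO:0008150"), character(0))
  expect_equal(go_ancestors(scheme, "GO:0006915"),
               sort(c("GO:0008219", "GO:0008150")))
  expect_error(go_ancestors(scheme, "GO:1111111"), "unknown")

  for (seed in 1:25) {
    setup <- random_annotation_setup(seed)
    scheme_r <- semweave:::new_concept_scheme(
      tibble::tibble(id = setup$ids, name = setup$ids, namespace = "bp"),
      tibble::tibble(child = setup$child, parent = setup$parent)
    )
    oracle <- oracle_ancestor_sets(setup$ids, setup$child, setup$parent)
    for (t in sample(setup$ids, min(5, length(setup$ids)))) {
      expect_equal(go_ancestors(scheme_r, t), oracle[[t]])
    }
  }
})

test_that("annotation propagation follows the chain example", {
  v <- rdf_vocabulary()
  g <- rdf_merge(
    obo_to_skos(read_obo(chain_obo()), v),
    annotations_to_rdf(read_gaf(gaf_line("TP53", "GO:0006915")),
                       read_symbol_map(I("TP53\tNM_000546")),
                       read_obo(chain_obo()), v)
  )
  e <- entail_go(g, v)
  gene <- refseq_uri("NM_000546")
  for (term in c("GO:0006915", "GO:0008219", "GO:0008150")) {
    expect_true(any(e$subject == gene & e$predicate == v$participates_in &
                      e$object == go_uri(term)))
  }
  # no broader triples -> unchanged
  ann_only <- rdf_graph(tibble::tibble(
    subject = gene, predicate = v$participates_in,
    object = go_uri("GO:0006915")))
  expect_true(rdf_equal(entail_go(ann_only, v), ann_only))
})

test_that("entailment equals the ancestor oracle on random DAGs", {
  v <- rdf_vocabulary()
  prop <- c(P = v$participates_in, F = v$has_function, C = v$part_of)
  for (seed in 1:40) {
    setup <- random_annotation_setup(seed + 100)
    g <- annotation_graph_from_setup(setup, v)
    e <- entail_go(g, v)
    oracle <- oracle_ancestor_sets(setup$ids, setup$child, setup$parent)
    expected <- dplyr::distinct(dplyr::bind_rows(lapply(
      seq_len(nrow(setup$ann)), function(i) {
        terms <- c(setup$ann$term[i], oracle[[setup$ann$term[i]]])
        tibble::tibble(subject = refseq_uri(setup$ann$gene[i]),
                       predicate = unname(prop[setup$ann$aspect[i]]),
                       object = go_uri(terms))
      })))
    for (p in prop) {
      got <- annotation_pairs(e, p)
      want <- expected[expected$predicate == p, c("subject", "object")]
      want <- want[order(want$subject, want$object, method = "radix"), ]
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
    # idempotence and monotonicity
    expect_true(rdf_equal(entail_go(e, v), e))
    expect_equal(nrow(dplyr::anti_join(g, e,
      by = c("subject", "predicate", "object", "object_type", "datatype"))), 0)
  }
})

test_that("propagation never crosses aspects", {
  v <- rdf_vocabulary()
  g <- rdf_graph(dplyr::bind_rows(
    tibble::tibble(subject = go_uri("GO:0000002"), predicate = v$broader,
                   object = go_uri("GO:0000001")),
    tibble::tibble(subject = refseq_uri("NM_000001"),
                   predicate = v$participates_in,
                   object = go_uri("GO:0000002"))
  ))
  e <- entail_go(g, v)
  expect_equal(sum(e$predicate == v$has_function), 0)
  expect_equal(sum(e$predicate == v$part_of), 0)
  expect_equal(sum(e$predicate == v$participates_in), 2)
})
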