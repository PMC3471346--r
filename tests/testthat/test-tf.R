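tf_lines <- function(rows) c("tf_id\trole\trefseq", rows)

test_that("TF tables aggregate per factor with set semantics", {
  empty <- read_tf_table(I("tf_id\trole\trefseq"))
  expect_equal(nrow(empty), 0)

  recs <- read_tf_table(I(paste(tf_lines(c(
    "TF1\texpresses\tNM_000001",
    "TF1\tregulates\tNM_000002",
    "TF1\tregulates\tNM_000003",
    "TF1\tregulates\tNM_000003"
  )), collapse = "\n")))
  expect_equal(nrow(recs), 1)
  expect_equal(recs$expressing_genes[[1]], "NM_000001")
  expect_equal(recs$regulated_genes[[1]], c("NM_000002", "NM_000003"))

  expect_error(read_tf_table(I(paste(tf_lines("TF1\tbinds\tNM_000001"),
                                     collapse = "\n"))),
               "line 2")
})

test_that("TF RDF uses both corresponds_to directions and TF->gene regulates", {
  v <- rdf_vocabulary()
  expect_equal(nrow(tf_to_rdf(read_tf_table(I("tf_id\trole\trefseq")), v)), 0)
  recs <- read_tf_table(I(paste(tf_lines(c(
    "V$HEN1_01\texpresses\tNM_000001",
    "V$HEN1_01\tregulates\tNM_000002"
  )), collapse = "\n")))
  g <- tf_to_rdf(recs, v)
  tf <- semweave:::tf_uri("V$HEN1_01")
  g1 <- refseq_uri("NM_000001")
  # printed-query direction: ?rep k:corresponds_to ?tf
  expect_true(any(g$subject == g1 & g$predicate == v$corresponds_to &
                    g$object == tf))
  # prose direction: factor corresponds_to expressing gene
  expect_true(any(g$subject == tf & g$predicate == v$corresponds_to &
                    g$object == g1))
  expect_true(any(g$subject == tf & g$predicate == v$regulates &
                    g$object == refseq_uri("NM_000002")))
  # '$' must be percent-encoded in the factor IRI
  expect_false(grepl("\\$", tf))
})

test_that("the coregulation chain derives both property levels", {
  v <- rdf_vocabulary()
  recs <- read_tf_table(I(paste(tf_lines(c(
    "TF1\texpresses\tNM_000001",
    "TF1\tregulates\tNM_000002",
    "TF2\texpresses\tNM_000002",
    "TF2\tregulates\tNM_000003"
  )), collapse = "\n")))
  e <- entail_tf(tf_to_rdf(recs, v), v)
  g1 <- refseq_uri("NM_000001"); g2 <- refseq_uri("NM_000002")
  g3 <- refseq_uri("NM_000003")
  expect_true(any(e$subject == g1 & e$predicate == v$coregulates &
                    e$object == g2))
  expect_true(any(e$subject == g2 & e$predicate == v$coregulates &
                    e$object == g3))
  expect_true(any(e$subject == g1 & e$predicate == v$indirectly_coregulates &
                    e$object == g3))

  # no regulates triples -> no derived triples
  only_corr <- rdf_graph(tibble::tibble(
    subject = semweave:::tf_uri("TF1"), predicate = v$corresponds_to,
    object = g1))
  e2 <- entail_tf(only_corr, v)
  expect_equal(sum(e2$predicate %in% c(v$coregulates,
                                       v$indirectly_coregulates)), 0)
})

test_that("TF closure equals the matrix reachability oracle with cycles", {
  v <- rdf_vocabulary()
  for (seed in 1:40) {
    rows <- random_tf_graph(seed)
    recs <- read_tf_table(I(paste(c("tf_id\trole\trefseq",
                                    paste(rows$tf, rows$role, rows$gene,
                                          sep = "\t")), collapse = "\n")))
    base <- tf_to_rdf(recs, v)
    # independent join oracle for coregulates
    expr <- rows[rows$role == "expresses", c("tf", "gene")]
    reg <- rows[rows$role == "regulates", c("tf", "gene")]
    joined <- merge(expr, reg, by = "tf")
    coreg_oracle <- unique(tibble::tibble(from = refseq_uri(joined$gene.x),
                                          to = refseq_uri(joined$gene.y)))
    nodes <- sort(unique(c(coreg_oracle$from, coreg_oracle$to)))
    for (depth in c("inf", "2")) {
      for (allow_self in c(TRUE, FALSE)) {
        e <- entail_tf(base, v, allow_self = allow_self, indirect_depth = depth)
        got_coreg <- coreg_pairs(e, v$coregulates)
        want_coreg <- coreg_oracle[order(coreg_oracle$from, coreg_oracle$to,
                                         method = "radix"), ]
        if (!allow_self) {
          want_coreg <- want_coreg[want_coreg$from != want_coreg$to, ]
        }
        expect_equal(got_coreg$subject, want_coreg$from)
        expect_equal(got_coreg$object, want_coreg$to)

        min_len <- 2L
        want_ind <- if (depth == "2") {
          two <- merge(coreg_oracle, coreg_oracle, by.x = "to", by.y = "from")
          unique(tibble::tibble(from = two$from, to = two$to.y))
        } else {
          oracle_reachable_pairs(nodes, coreg_oracle$from, coreg_oracle$to,
                                 min_len = min_len)
        }
        if (!allow_self) want_ind <- want_ind[want_ind$from != want_ind$to, ]
        want_ind <- want_ind[order(want_ind$from, want_ind$to,
                                   method = "radix"), ]
        got_ind <- coreg_pairs(e, v$indirectly_coregulates)
        expect_equal(got_ind$subject, want_ind$from)
        expect_equal(got_ind$object, want_ind$to)

        # idempotence and monotonicity
        expect_true(rdf_equal(entail_tf(e, v, allow_self = allow_self,
                                        indirect_depth = depth), e))
        expect_equal(nrow(dplyr::anti_join(base, e,
          by = c("subject", "predicate", "object", "object_type",
                 "datatype"))), 0)
        if (!allow_self) {
          derived <- e[e$predicate %in% c(v$coregulates,
                                          v$indirectly_coregulates), ]
          expect_equal(sum(derived$subject == derived$object), 0)
        }
      }
    }
  }
})

test_that("a three-gene regulatory ring closes onto itself", {
  v <- rdf_vocabulary()
  recs <- read_tf_table(I(paste(tf_lines(c(
    "TF1\texpresses\tNM_000001", "TF1\tregulates\tNM_000002",
    "TF2\texpresses\tNM_000002", "TF2\tregulates\tNM_000003",
    "TF3\texpresses\tNM_000003", "TF3\tregulates\tNM_000001"
  )), collapse = "\n")))
  e <- entail_tf(tf_to_rdf(recs, v), v, allow_self = TRUE)
  genes <- refseq_uri(sprintf("NM_%06d", 1:3))
  ind <- e[e$predicate == v$indirectly_coregulates, ]
  for (u in genes) for (w in genes) {
    expect_true(any(ind$subject == u & ind$object == w))
  }
  e2 <- entail_tf(tf_to_rdf(recs, v), v, allow_self = FALSE)
  ind2 <- e2[e2$predicate == v$indirectly_coregulates, ]
  expect_equal(sum(ind2$subject == ind2$object), 0)
})
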