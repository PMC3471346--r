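# Hand-planted merged graph: three apoptosis genes (one via a child term
# only), two proliferation genes, one background gene; S1 passes all five
# signal genes, S2 passes a single apoptosis gene.
planted_graph <- function() {
  v <- rdf_vocabulary()
  obo <- c(
    "[Term]", "id: GO:0008150", "name: biological_process", "",
    "[Term]", "id: GO:0006915", "name: apoptosis", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0008283", "name: cell proliferation",
    "is_a: GO:0008150", "",
    "[Term]", "id: GO:0000010", "name: apoptotic subprocess",
    "is_a: GO:0006915")
  scheme <- read_obo(obo)
  genes <- c(A1 = "NM_000001", A2 = "NM_000002", A3 = "NM_000003",
             P1 = "NM_000004", P2 = "NM_000005", B1 = "NM_000006")
  ann <- tibble::tibble(
    subject = refseq_uri(genes[c("A1", "A2", "A3", "P1", "P2")]),
    predicate = v$participates_in,
    object = go_uri(c("GO:0006915", "GO:0006915", "GO:0000010",
                      "GO:0008283", "GO:0008283"))
  )
  pass <- function(samp, gene, meth, ratio) tibble::tibble(
    dataset_title = c("Methylation Relative", "AZA Pre-Post Treatment Ratios"),
    sample_title = samp, reporter_id = gene, value = c(meth, ratio))
  obs <- dplyr::bind_rows(
    unname(lapply(genes[1:5], function(g) pass("S1", g, 4, 2))),
    pass("S1", genes[["B1"]], 1, 0.5),
    pass("S2", genes[["A1"]], 5, 3),
    unname(lapply(genes[2:6], function(g) pass("S2", g, 0.5, 0.3)))
  )
  g <- rdf_merge(observations_to_rdf(obs), obo_to_skos(scheme, v),
                 rdf_graph(ann))
  entail_go(g, v)
}

test_that("pathway counts match the planted fixture, with entailment", {
  g <- planted_graph()
  out <- pathway_contrast_counts(g, "GO:0006915", "GO:0008283")
  expect_equal(out$sample_title, c("S1", "S2"))
  expect_equal(out$count_a, c(3L, 1L))  # A3 counted only via entailment
  expect_equal(out$count_b, c(2L, 0L))
  expect_equal(out$ratio, c(1.5, 0))

  strict <- pathway_contrast_counts(g, "GO:0006915", "GO:0008283",
                                    mode = "strict")
  expect_equal(strict$sample_title, "S1")

  # the child-term gene disappears without entailment
  raw <- planted_graph()
  raw <- rdf_graph(raw[!(raw$predicate == rdf_vocabulary()$participates_in &
                           raw$object == go_uri("GO:0008150")), ])
  no_ent <- raw[!(raw$predicate == rdf_vocabulary()$participates_in &
                    raw$subject == refseq_uri("NM_000003") &
                    raw$object == go_uri("GO:0006915")), ]
  out2 <- pathway_contrast_counts(rdf_graph(no_ent), "GO:0006915",
                                  "GO:0008283")
  expect_equal(out2$count_a, c(2L, 1L))
})

test_that("empty graphs and missing datasets are handled explicitly", {
  expect_equal(nrow(pathway_contrast_counts(rdf_graph(), "GO:0006915",
                                            "GO:0008283")), 0)
  rows <- tibble::tibble(dataset_title = "Methylation Relative",
                         sample_title = "S1", reporter_id = "NM_000001",
                         value = 3)
  g <- observations_to_rdf(rows)
  expect_error(pathway_contrast_counts(g, "GO:0006915", "GO:0008283"),
               "AZA Pre-Post Treatment Ratios")
})

test_that("TF candidates recover exactly the planted passing gene", {
  v <- rdf_vocabulary()
  rows <- dplyr::bind_rows(
    tibble::tibble(dataset_title = "Methylation Relative",
                   sample_title = "S1",
                   reporter_id = c("NM_000001", "NM_000002"),
                   value = c(4, 1)),
    tibble::tibble(dataset_title = "AZA Pre-Post Treatment Ratios",
                   sample_title = "S1",
                   reporter_id = c("NM_000001", "NM_000002"),
                   value = c(2, 3))
  )
  tf <- read_tf_table(I(paste(c("tf_id\trole\trefseq",
                                "V$X_01\texpresses\tNM_000001",
                                "V$X_01\texpresses\tNM_000002"),
                              collapse = "\n")))
  g <- rdf_merge(observations_to_rdf(rows), tf_to_rdf(tf, v))
  out <- tf_candidates(g)
  expect_equal(nrow(out), 1)  # NM_000002 fails the methylation filter
  expect_equal(out$reporter, refseq_uri("NM_000001"))
  expect_equal(out$sample_title, "S1")
  expect_equal(out$methylation_value, 4)
  expect_equal(out$ratio_value, 2)
})

# 20 genes observed in the ratio dataset for S1; the factor directly
# regulates 10; 4 of those are high, 2 non-regulated are high.
enrichment_graph <- function() {
  v <- rdf_vocabulary()
  genes <- sprintf("NM_%06d", 1:20)
  high <- c(genes[1:4], genes[11:12])
  ratio <- ifelse(genes %in% high, 3, 0.5)
  rows <- dplyr::bind_rows(
    tibble::tibble(dataset_title = "AZA Pre-Post Treatment Ratios",
                   sample_title = "S1", reporter_id = genes, value = ratio),
    tibble::tibble(dataset_title = "Methylation Relative",
                   sample_title = "S1", reporter_id = genes, value = 1)
  )
  tf_rows <- c("tf_id\trole\trefseq", "V$E_01\texpresses\tNM_000099",
               paste0("V$E_01\tregulates\t", genes[1:10]))
  g <- rdf_merge(observations_to_rdf(rows),
                 tf_to_rdf(read_tf_table(I(paste(tf_rows, collapse = "\n")))))
  entail_tf(g)
}

test_that("TF enrichment counts and Fisher p match the enumeration oracle", {
  g <- enrichment_graph()
  out <- tf_regulated_high_counts(g, "V$E_01")
  expect_equal(out$high_regulated_count, 4L)
  expect_equal(out$total_high_count, 6L)
  expect_equal(out$p_value, oracle_fisher(4, 6, 2, 8, "greater"),
               tolerance = 1e-12)

  expect_error(tf_regulated_high_counts(g, "V$MISSING_01"), "not in graph")

  # a factor regulating nothing observed: zero count, p = 1
  v <- rdf_vocabulary()
  g2 <- rdf_merge(g, rdf_graph(tibble::tibble(
    subject = semweave:::tf_uri("V$NONE_01"), predicate = v$regulates,
    object = refseq_uri("NM_000500"))))
  out2 <- tf_regulated_high_counts(g2, "V$NONE_01")
  expect_equal(out2$high_regulated_count, 0L)
  expect_equal(out2$p_value, 1)
})

test_that("influence sets include the coregulation closure when asked", {
  v <- rdf_vocabulary()
  # factor A is expressed by E1 and regulates R1; factor B expressed by R1
  # regulates R2, so R2 is in A's indirect sphere of influence
  tf_rows <- c("tf_id\trole\trefseq",
               "A\texpresses\tNM_000001", "A\tregulates\tNM_000002",
               "B\texpresses\tNM_000002", "B\tregulates\tNM_000003")
  genes <- sprintf("NM_%06d", 1:3)
  rows <- dplyr::bind_rows(
    tibble::tibble(dataset_title = "AZA Pre-Post Treatment Ratios",
                   sample_title = "S1", reporter_id = genes, value = 3),
    tibble::tibble(dataset_title = "Methylation Relative",
                   sample_title = "S1", reporter_id = genes, value = 1)
  )
  g <- entail_tf(rdf_merge(
    observations_to_rdf(rows),
    tf_to_rdf(read_tf_table(I(paste(tf_rows, collapse = "\n"))))), v)
  infl <- tf_regulated_high_counts(g, "A", relation = "influence")
  direct <- tf_regulated_high_counts(g, "A", relation = "direct")
  expect_equal(infl$high_regulated_count, 2L)   # R1 and R2
  expect_equal(direct$high_regulated_count, 1L) # R1 only
})

test_that("pathway composition of the influence set matches the plant", {
  v <- rdf_vocabulary()
  genes <- sprintf("NM_%06d", 1:6)
  ann <- tibble::tibble(
    subject = refseq_uri(genes[1:5]), predicate = v$participates_in,
    object = go_uri(c(rep("GO:0006915", 3), rep("GO:0008283", 2)))
  )
  rows <- dplyr::bind_rows(
    tibble::tibble(dataset_title = "AZA Pre-Post Treatment Ratios",
                   sample_title = "S1", reporter_id = genes, value = 3),
    tibble::tibble(dataset_title = "Methylation Relative",
                   sample_title = "S1", reporter_id = genes, value = 1)
  )
  tf_rows <- c("tf_id\trole\trefseq", "A\texpresses\tNM_000099",
               paste0("A\tregulates\t", genes))
  g <- entail_tf(rdf_merge(
    observations_to_rdf(rows), rdf_graph(ann),
    tf_to_rdf(read_tf_table(I(paste(tf_rows, collapse = "\n"))))), v)
  out <- tf_pathway_ratio(g, "A", "GO:0006915", "GO:0008283")
  expect_equal(out$count_a, 3L)
  expect_equal(out$count_b, 2L)
  expect_equal(out$ratio, 1.5)

  # nothing high -> zero row
  thr0 <- threshold_config(high_expression_min = 10)
  out0 <- tf_pathway_ratio(g, "A", "GO:0006915", "GO:0008283", thr = thr0)
  expect_equal(out0$count_a, 0L)
  expect_equal(out0$ratio, 0)
})

test_that("all analysis counts are non-increasing in every threshold", {
  cfg <- synthetic_config(seed = 21, n_terms = 14, n_genes = 60, n_tfs = 4,
                          n_samples = 3, background_hit_rate = 0.2)
  study <- simulate_study(cfg)
  g <- semantic_model_from_study(study)
  tf1 <- study$tf$records$tf_id[1]
  withr::with_seed(99, thresholds <- sort(runif(6, 0, 4)))
  prev_counts <- NULL
  for (t in thresholds) {
    thr <- threshold_config(methylation_min = t, expression_ratio_min = t,
                            tf_expression_ratio_min = t,
                            high_expression_min = t)
    pc <- pathway_contrast_counts(g, "GO:0006915", "GO:0008283", thr)
    en <- tf_regulated_high_counts(g, tf1, thr)
    cand <- nrow(tf_candidates(g, thr))
    counts <- c(sum(pc$count_a), sum(pc$count_b),
                sum(en$high_regulated_count), sum(en$total_high_count), cand)
    if (!is.null(prev_counts)) expect_true(all(counts <= prev_counts))
    prev_counts <- counts
  }
})

test_that("result types expose tidy, glance and autoplot methods", {
  g <- planted_graph()
  pc <- pathway_contrast_counts(g, "GO:0006915", "GO:0008283")
  expect_s3_class(tidy(pc), "tbl_df")
  expect_equal(glance(pc)$n_samples, 2)
  expect_s3_class(autoplot(pc), "ggplot")

  en <- tf_regulated_high_counts(enrichment_graph(), "V$E_01")
  td <- tidy(en)
  expect_true(all(c("estimate", "p.value") %in% names(td)))
  expect_equal(glance(en)$n_samples, 1)
  expect_s3_class(autoplot(en), "ggplot")
})
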