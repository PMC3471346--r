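#' Threshold configuration for the sensitivity analyses
#'
#' The defaults are the cutoffs used by the stored case-study queries:
#' genes count as methylated when relative methylation exceeds 2, as
#' responding when the post/pre expression ratio exceeds 1 (0.5 in the
#' transcription-factor candidate query), and as highly expressed when the
#' ratio exceeds `high_expression_min`. All comparisons are strict, like
#' the queries' `FILTER (... > ...)` operators.
#'
#' @param methylation_min Relative methylation cutoff.
#' @param expression_ratio_min Post/pre ratio cutoff for the pathway query.
#' @param tf_expression_ratio_min Ratio cutoff for the TF-candidate query.
#' @param high_expression_min Ratio cutoff defining "highly expressed".
#' @param methylation_dataset_title,ratio_dataset_title Dataset `dc:title`
#'   values naming the two observation datasets.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(methylation_min = 2,
                             expression_ratio_min = 1,
                             tf_expression_ratio_min = 0.5,
                             high_expression_min = 1,
                             methylation_dataset_title = "Methylation Relative",
                             ratio_dataset_title = "AZA Pre-Post Treatment Ratios") {
  cutoffs <- c(methylation_min, expression_ratio_min,
               tf_expression_ratio_min, high_expression_min)
  if (any(!is.finite(cutoffs))) abort("thresholds must be finite")
  structure(list(
    methylation_min = methylation_min,
    expression_ratio_min = expression_ratio_min,
    tf_expression_ratio_min = tf_expression_ratio_min,
    high_expression_min = high_expression_min,
    methylation_dataset_title = methylation_dataset_title,
    ratio_dataset_title = ratio_dataset_title
  ), class = "threshold_config")
}

# Graph extraction helpers ----------------------------------------------

# Flatten the observation portion of a (possibly merged) graph back to a
# tidy table: one row per observation with its dataset title, sample title,
# reporter IRI and numeric value.
graph_observations <- function(graph, vocab = rdf_vocabulary()) {
  titles <- graph[graph$predicate == vocab$dc_title &
                  graph$object_type == "literal", c("subject", "object")]
  names(titles) <- c("node", "title")
  typed <- function(class_iri) {
    graph$subject[graph$predicate == vocab$rdf_type & graph$object == class_iri]
  }
  samples <- typed(vocab$cell_culture)
  vals <- graph[graph$predicate == vocab$has_measurement_value,
                c("subject", "object")]
  obs <- tibble(obs = vals$subject, value = as.numeric(vals$object))
  part <- graph[graph$predicate == vocab$part_of & graph$object_type == "iri",
                c("subject", "object")]
  names(part) <- c("obs", "ds")
  about <- graph[graph$predicate == vocab$is_about, c("subject", "object")]
  names(about) <- c("obs", "node")
  obs %>%
    inner_join(part, by = "obs") %>%
    inner_join(rename(titles, ds = "node", dataset_title = "title"), by = "ds") %>%
    inner_join(about[about$node %in% samples, ] %>% rename(sample = "node"),
               by = "obs") %>%
    inner_join(rename(titles, sample = "node", sample_title = "title"),
               by = "sample") %>%
    inner_join(about[!about$node %in% samples, ] %>% rename(gene = "node"),
               by = "obs") %>%
    select("obs", "dataset_title", "sample_title", "gene", "value")
}

graph_sample_titles <- function(graph, vocab = rdf_vocabulary()) {
  samples <- graph$subject[graph$predicate == vocab$rdf_type &
                           graph$object == vocab$cell_culture]
  sort(unique(graph$object[graph$subject %in% samples &
                           graph$predicate == vocab$dc_title]))
}

check_dataset_present <- function(graph, titles, vocab) {
  ds_nodes <- graph$subject[graph$predicate == vocab$rdf_type &
                            graph$object == vocab$data_set_class]
  have <- graph$object[graph$subject %in% ds_nodes &
                       graph$predicate == vocab$dc_title]
  missing <- setdiff(titles, have)
  if (length(missing) > 0) {
    abort(paste0("dataset not present in graph: ", missing[1]))
  }
}

resolve_term_iri <- function(term) {
  if (grepl("^GO:[0-9]{7}$", term)) go_uri(term) else term
}

resolve_tf_iri <- function(tf) {
  if (grepl("^https?://", tf)) tf else tf_uri(tf)
}

# Genes annotated (post-entailment) to a term via participates_in.
genes_annotated_to <- function(graph, term_iri, vocab) {
  unique(graph$subject[graph$predicate == vocab$participates_in &
                       graph$object == term_iri])
}

# Per-sample gene sets passing a value threshold in one dataset.
passing_set <- function(obs_tbl, dataset_title, cutoff) {
  hits <- obs_tbl[obs_tbl$dataset_title == dataset_title &
                  obs_tbl$value > cutoff, c("sample_title", "gene")]
  distinct(hits)
}

# The transcription factor's sphere of influence: direct targets, plus the
# coregulates / indirectly_coregulates targets of every gene expressing it.
tf_influence_set <- function(graph, tf_iri, vocab,
                             relation = c("influence", "direct")) {
  relation <- match.arg(relation)
  direct <- graph$object[graph$subject == tf_iri &
                         graph$predicate == vocab$regulates]
  if (relation == "direct") return(unique(direct))
  expressing <- graph$object[graph$subject == tf_iri &
                             graph$predicate == vocab$corresponds_to]
  via <- graph$object[graph$subject %in% expressing &
                      graph$predicate %in% c(vocab$coregulates,
                                             vocab$indirectly_coregulates)]
  unique(c(direct, via))
}

# Analyses ---------------------------------------------------------------

#' Per-sample pathway contrast counts
#'
#' For every sample, counts the genes passing both filters (methylation
#' above `methylation_min` in the methylation dataset and expression ratio
#' above `expression_ratio_min` in the ratio dataset) that are annotated —
#' after entailment — to `term_a` (e.g. apoptosis) and to `term_b` (e.g.
#' cell proliferation), and reports their ratio. This is the set-logic
#' counterpart of the stored pathway SPARQL query.
#'
#' @param graph Merged, entailed graph.
#' @param term_a,term_b GO accessions (`"GO:0006915"`) or full term IRIs.
#' @param thr A [threshold_config()].
#' @param mode `"report"` (default) lists every sample, reporting 0 counts
#'   and a 0 ratio where nothing passes; `"strict"` reproduces the SPARQL
#'   inner-join behaviour, dropping samples where either count is zero.
#' @param vocab Vocabulary.
#' @return Tibble of class `pathway_counts` with columns `sample_title`,
#'   `count_a`, `count_b`, `ratio`, ordered by sample title.
#' @export
pathway_contrast_counts <- function(graph, term_a, term_b,
                                    thr = threshold_config(),
                                    mode = c("report", "strict"),
                                    vocab = rdf_vocabulary()) {
  mode <- match.arg(mode)
  graph <- rdf_graph(graph)
  obs_tbl <- graph_observations(graph, vocab)
  samples <- graph_sample_titles(graph, vocab)
  if (length(samples) == 0) {
    out <- tibble(sample_title = character(), count_a = integer(),
                  count_b = integer(), ratio = numeric())
    class(out) <- c("pathway_counts", class(out))
    return(out)
  }
  check_dataset_present(graph, c(thr$methylation_dataset_title,
                                 thr$ratio_dataset_title), vocab)
  pass <- inner_join(
    passing_set(obs_tbl, thr$methylation_dataset_title, thr$methylation_min),
    passing_set(obs_tbl, thr$ratio_dataset_title, thr$expression_ratio_min),
    by = c("sample_title", "gene")
  )
  ann_a <- genes_annotated_to(graph, resolve_term_iri(term_a), vocab)
  ann_b <- genes_annotated_to(graph, resolve_term_iri(term_b), vocab)
  counts <- pass %>%
    group_by(.data$sample_title) %>%
    summarise(count_a = sum(unique(.data$gene) %in% ann_a),
              count_b = sum(unique(.data$gene) %in% ann_b),
              .groups = "drop")
  out <- left_join(tibble(sample_title = samples), counts, by = "sample_title")
  out$count_a[is.na(out$count_a)] <- 0L
  out$count_b[is.na(out$count_b)] <- 0L
  out$ratio <- ifelse(out$count_b == 0, 0, out$count_a / out$count_b)
  if (mode == "strict") {
    out <- out[out$count_a >= 1 & out$count_b >= 1, , drop = FALSE]
  }
  out <- out[order(out$sample_title, method = "radix"), ]
  out <- as_tibble(out)
  class(out) <- c("pathway_counts", class(out))
  out
}

#' Methylated, re-expressed genes that express a transcription factor
#'
#' Finds every (gene, factor, sample) combination where the gene expresses
#' the factor (`corresponds_to`), its methylation exceeds
#' `methylation_min`, and its post/pre expression ratio exceeds
#' `tf_expression_ratio_min`. Set-logic counterpart of the stored
#' TF-candidate SPARQL query.
#'
#' @inheritParams pathway_contrast_counts
#' @return Tibble with columns `reporter` (RefSeq IRI), `tf` (factor IRI),
#'   `sample_title`, `methylation_value`, `ratio_value`.
#' @export
tf_candidates <- function(graph, thr = threshold_config(),
                          vocab = rdf_vocabulary()) {
  graph <- rdf_graph(graph)
  obs_tbl <- graph_observations(graph, vocab)
  check_dataset_present(graph, c(thr$methylation_dataset_title,
                                 thr$ratio_dataset_title), vocab)
  transcripts <- graph$subject[graph$predicate == vocab$rdf_type &
                               graph$object == vocab$transcript_class]
  corr <- graph[graph$predicate == vocab$corresponds_to &
                graph$subject %in% transcripts, c("subject", "object")]
  names(corr) <- c("gene", "tf")
  meth <- obs_tbl[obs_tbl$dataset_title == thr$methylation_dataset_title &
                  obs_tbl$value > thr$methylation_min, ]
  ratio <- obs_tbl[obs_tbl$dataset_title == thr$ratio_dataset_title &
                   obs_tbl$value > thr$tf_expression_ratio_min, ]
  out <- meth %>%
    select("sample_title", "gene", methylation_value = "value") %>%
    inner_join(select(ratio, "sample_title", "gene", ratio_value = "value"),
               by = c("sample_title", "gene")) %>%
    inner_join(corr, by = "gene", relationship = "many-to-many") %>%
    distinct() %>%
    select(reporter = "gene", "tf", "sample_title",
           "methylation_value", "ratio_value")
  out[order(out$sample_title, out$reporter, out$tf, method = "radix"), ]
}

#' Highly expressed genes regulated by a transcription factor, per sample
#'
#' For each sample observed in the ratio dataset, counts the highly
#' expressed genes (ratio above `high_expression_min`) falling inside the
#' factor's sphere of influence, and scores the enrichment with a
#' one-sided Fisher exact test over the genes observed in that sample.
#'
#' @inheritParams pathway_contrast_counts
#' @param tf Factor identifier (e.g. `"V$HEN1_01"`) or full factor IRI.
#' @param relation `"influence"` (default) counts direct targets together
#'   with the coregulates / indirectly-coregulates closure of the genes
#'   expressing the factor; `"direct"` restricts to direct targets.
#' @return Tibble of class `tf_enrichment` with columns `sample_title`,
#'   `tf`, `high_regulated_count`, `total_high_count`, `p_value`.
#' @export
tf_regulated_high_counts <- function(graph, tf, thr = threshold_config(),
                                     relation = c("influence", "direct"),
                                     vocab = rdf_vocabulary()) {
  relation <- match.arg(relation)
  graph <- rdf_graph(graph)
  tf_iri <- resolve_tf_iri(tf)
  if (!any(graph$subject == tf_iri | graph$object == tf_iri)) {
    abort(paste0("transcription factor not in graph: ", tf))
  }
  check_dataset_present(graph, thr$ratio_dataset_title, vocab)
  obs_tbl <- graph_observations(graph, vocab)
  ratio_obs <- obs_tbl[obs_tbl$dataset_title == thr$ratio_dataset_title, ]
  influence <- tf_influence_set(graph, tf_iri, vocab, relation)
  out <- ratio_obs %>%
    group_by(.data$sample_title) %>%
    summarise(
      high_regulated_count =
        length(unique(.data$gene[.data$value > thr$high_expression_min &
                                   .data$gene %in% influence])),
      total_high_count =
        length(unique(.data$gene[.data$value > thr$high_expression_min])),
      n_regulated_observed = length(unique(.data$gene[.data$gene %in% influence])),
      n_observed = length(unique(.data$gene)),
      .groups = "drop"
    )
  out$p_value <- purrr::pmap_dbl(out, function(high_regulated_count,
                                               total_high_count,
                                               n_regulated_observed,
                                               n_observed, ...) {
    a <- high_regulated_count
    b <- n_regulated_observed - a
    cc <- total_high_count - a
    d <- n_observed - a - b - cc
    fisher_exact(a, b, cc, d, sided = "greater")
  })
  out <- out %>%
    mutate(tf = tf) %>%
    select("sample_title", "tf", "high_regulated_count", "total_high_count",
           "p_value")
  out <- out[order(out$sample_title, method = "radix"), ]
  class(out) <- c("tf_enrichment", class(out))
  out
}

#' Pathway composition of a factor's highly expressed influence set
#'
#' Among each sample's highly expressed genes that lie in the factor's
#' sphere of influence, counts those annotated (after entailment) to
#' `term_a` versus `term_b` and reports the ratio (0 when the `term_b`
#' count is 0).
#'
#' @inheritParams tf_regulated_high_counts
#' @param term_a,term_b GO accessions or term IRIs.
#' @return Tibble with columns `sample_title`, `tf`, `count_a`, `count_b`,
#'   `ratio`.
#' @export
tf_pathway_ratio <- function(graph, tf, term_a, term_b,
                             thr = threshold_config(),
                             relation = c("influence", "direct"),
                             vocab = rdf_vocabulary()) {
  relation <- match.arg(relation)
  graph <- rdf_graph(graph)
  tf_iri <- resolve_tf_iri(tf)
  if (!any(graph$subject == tf_iri | graph$object == tf_iri)) {
    abort(paste0("transcription factor not in graph: ", tf))
  }
  check_dataset_present(graph, thr$ratio_dataset_title, vocab)
  obs_tbl <- graph_observations(graph, vocab)
  high <- passing_set(obs_tbl, thr$ratio_dataset_title, thr$high_expression_min)
  influence <- tf_influence_set(graph, tf_iri, vocab, relation)
  ann_a <- genes_annotated_to(graph, resolve_term_iri(term_a), vocab)
  ann_b <- genes_annotated_to(graph, resolve_term_iri(term_b), vocab)
  samples <- sort(unique(obs_tbl$sample_title[obs_tbl$dataset_title ==
                                                thr$ratio_dataset_title]))
  high_inf <- high[high$gene %in% influence, ]
  counts <- high_inf %>%
    group_by(.data$sample_title) %>%
    summarise(count_a = sum(unique(.data$gene) %in% ann_a),
              count_b = sum(unique(.data$gene) %in% ann_b),
              .groups = "drop")
  out <- left_join(tibble(sample_title = samples), counts, by = "sample_title")
  out$count_a[is.na(out$count_a)] <- 0L
  out$count_b[is.na(out$count_b)] <- 0L
  out$tf <- tf
  out$ratio <- ifelse(out$count_b == 0, 0, out$count_a / out$count_b)
  out[order(out$sample_title, method = "radix"),
      c("sample_title", "tf", "count_a", "count_b", "ratio")]
}
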