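#' Read a transcription-factor table
#'
#' The table is long-format TSV with a header and three columns: `tf_id`,
#' `role` (`expresses` or `regulates`) and `refseq`. Rows are aggregated
#' per transcription factor into its set of expressing genes (genes whose
#' transcript encodes the factor) and its set of regulated genes.
#'
#' @param path File path, connection, or character vector of lines.
#' @return Tibble with one row per factor: `tf_id`, list-columns
#'   `expressing_genes` and `regulated_genes` of RefSeq accessions.
#' @export
read_tf_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  required <- c("tf_id", "role", "refseq")
  if (!all(required %in% names(df))) {
    abort(paste0("TF table needs columns: ", paste(required, collapse = ", ")))
  }
  bad <- which(!df$role %in% c("expresses", "regulates"))
  if (length(bad) > 0) {
    abort(sprintf("unknown role '%s' at line %d", df$role[bad[1]], bad[1] + 1L))
  }
  if (nrow(df) == 0) {
    return(tibble(tf_id = character(), expressing_genes = list(),
                  regulated_genes = list()))
  }
  df %>%
    group_by(.data$tf_id) %>%
    summarise(
      expressing_genes = list(sort(unique(.data$refseq[.data$role == "expresses"]))),
      regulated_genes = list(sort(unique(.data$refseq[.data$role == "regulates"]))),
      .groups = "drop"
    )
}

tf_uri <- function(tf_id) paste0(NS$k, "tf/", iri_encode(tf_id))

#' Map transcription-factor records to RDF
#'
#' Factors get IRIs in the `k:` namespace (ids percent-encoded, so motif
#' names like `V$HEN1_01` survive IRI syntax). `corresponds_to` is
#' materialised in both directions between a factor and each gene that
#' expresses it, so chains phrased factor-to-gene and queries phrased
#' gene-to-factor both hold. `regulates` runs factor-to-target. All gene
#' nodes are typed as SO transcripts under their Bio2RDF RefSeq IRIs.
#'
#' @param records Tibble from [read_tf_table()].
#' @param vocab Vocabulary.
#' @return An `rdf_graph`.
#' @export
tf_to_rdf <- function(records, vocab = rdf_vocabulary()) {
  records <- as_tibble(records)
  if (nrow(records) == 0) return(rdf_graph())
  expr <- tidyr::unnest(records[, c("tf_id", "expressing_genes")],
                        "expressing_genes")
  reg <- tidyr::unnest(records[, c("tf_id", "regulated_genes")],
                       "regulated_genes")
  genes <- unique(c(expr$expressing_genes, reg$regulated_genes))
  g <- bind_rows(
    if (nrow(expr) > 0) bind_rows(
      triple_iri(tf_uri(expr$tf_id), vocab$corresponds_to,
                 refseq_uri(expr$expressing_genes)),
      triple_iri(refseq_uri(expr$expressing_genes), vocab$corresponds_to,
                 tf_uri(expr$tf_id))
    ),
    if (nrow(reg) > 0) triple_iri(tf_uri(reg$tf_id), vocab$regulates,
                                  refseq_uri(reg$regulated_genes)),
    if (length(genes) > 0) triple_iri(refseq_uri(genes), vocab$rdf_type,
                                      vocab$transcript_class)
  )
  rdf_graph(g)
}
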