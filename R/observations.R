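#' Read a quantitative observation table
#'
#' Observations are per-sample, per-reporter measurements carrying their
#' dataset provenance, e.g. relative promoter methylation or post/pre
#' treatment expression ratios. The TSV must have a header naming at least
#' `dataset`, `sample`, `reporter_id` and `value`; `reporter_title`,
#' `measure` and `unit` are optional.
#'
#' @param path File path, connection, or character vector of lines.
#' @return A tibble with columns `dataset_title`, `sample_title`,
#'   `reporter_id`, `reporter_title`, `value`, `measure_quality`,
#'   `unit_label`, in file order.
#' @export
read_observation_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("dataset", "sample", "reporter_id", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("observation table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(value) | !is.finite(value))
  if (length(bad) > 0) {
    abort(sprintf("unparseable value '%s' at line %d", df$value[bad[1]],
                  bad[1] + 1L))  # +1 for the header row
  }
  empty_key <- which(is.na(df$dataset) | df$dataset == "" |
                     is.na(df$sample) | df$sample == "" |
                     is.na(df$reporter_id) | df$reporter_id == "")
  if (length(empty_key) > 0) {
    abort(sprintf("empty dataset/sample/reporter_id at line %d",
                  empty_key[1] + 1L))
  }
  opt <- function(col) if (col %in% names(df)) dplyr::coalesce(df[[col]], "") else
    rep("", nrow(df))
  tibble(
    dataset_title = df$dataset,
    sample_title = df$sample,
    reporter_id = df$reporter_id,
    reporter_title = opt("reporter_title"),
    value = value,
    measure_quality = opt("measure"),
    unit_label = opt("unit")
  )
}

#' Bio2RDF-style IRI for a RefSeq accession
#'
#' The RefSeq transcript IRI is the merge key between the observation, GO
#' annotation and transcription-factor models: every module emits exactly
#' this IRI for a given accession. Version suffixes (`NM_000546.3`) are
#' stripped so transcripts join across sources regardless of release.
#'
#' @param accession Character vector of RefSeq accessions.
#' @return IRI strings of the form `http://bio2rdf.org/refseq:<accession>`.
#' @examples
#' refseq_uri("NM_000546")
#' @export
refseq_uri <- function(accession) {
  if (any(is.na(accession) | accession == "")) {
    abort("empty RefSeq accession")
  }
  acc <- sub("\\.[0-9]+$", "", accession)
  paste0("http://bio2rdf.org/refseq:", acc)
}

observation_uri <- function(dataset_title, sample_title, reporter_id,
                            measure_quality) {
  paste0(NS$k, "observation/",
         iri_encode(dataset_title), "/", iri_encode(sample_title), "/",
         iri_encode(reporter_id), "/", iri_encode(measure_quality))
}

dataset_uri <- function(title) paste0(NS$k, "dataset/", iri_encode(title))
sample_uri <- function(title) paste0(NS$k, "sample/", iri_encode(title))

#' Map observation records to RDF
#'
#' Each observation becomes a measurement-datum node carrying its numeric
#' value (`has measurement value`), its dataset membership (`part of`), and
#' two `is about` links — one to the sample (an OBI cell culture) and one
#' to the reporter (an SO transcript identified by its Bio2RDF RefSeq IRI).
#' Dataset and sample nodes are shared across records with the same title,
#' and carry Dublin Core titles so stored SPARQL queries can select them.
#'
#' @param records Tibble as returned by [read_observation_table()].
#' @param vocab Vocabulary from [rdf_vocabulary()].
#' @return An `rdf_graph`.
#' @export
observations_to_rdf <- function(records, vocab = rdf_vocabulary()) {
  records <- as_tibble(records)
  if (nrow(records) == 0) return(rdf_graph())
  stopifnot(all(c("dataset_title", "sample_title", "reporter_id", "value") %in%
                  names(records)))
  for (col in c("reporter_title", "measure_quality", "unit_label")) {
    if (!col %in% names(records)) records[[col]] <- ""
  }
  # one value per (dataset, sample, reporter): last row wins
  key <- paste(records$dataset_title, records$sample_title,
               records$reporter_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warn(sprintf("%d duplicate (dataset, sample, reporter) row(s); keeping the last",
                 n_dup))
    records <- records[!duplicated(key, fromLast = TRUE), ]
  }

  obs <- observation_uri(records$dataset_title, records$sample_title,
                         records$reporter_id, records$measure_quality)
  ds <- dataset_uri(records$dataset_title)
  smp <- sample_uri(records$sample_title)
  rep_iri <- refseq_uri(records$reporter_id)

  per_obs <- bind_rows(
    triple_iri(obs, vocab$rdf_type, vocab$measurement_datum_class),
    triple_num(obs, vocab$has_measurement_value, records$value),
    triple_iri(obs, vocab$part_of, ds),
    triple_iri(obs, vocab$is_about, smp),
    triple_iri(obs, vocab$is_about, rep_iri)
  )
  has_measure <- records$measure_quality != ""
  has_unit <- records$unit_label != ""
  optional <- bind_rows(
    triple_lit(obs[has_measure], vocab$is_quality_measurement_of,
               records$measure_quality[has_measure]),
    triple_lit(obs[has_unit], vocab$has_measurement_unit_label,
               records$unit_label[has_unit])
  )

  ds_meta <- distinct(tibble(iri = ds, title = records$dataset_title))
  smp_meta <- distinct(tibble(iri = smp, title = records$sample_title))
  rep_meta <- distinct(tibble(iri = rep_iri, id = records$reporter_id,
                              title = records$reporter_title))
  shared <- bind_rows(
    triple_iri(ds_meta$iri, vocab$rdf_type, vocab$data_set_class),
    triple_lit(ds_meta$iri, vocab$dc_title, ds_meta$title),
    triple_iri(smp_meta$iri, vocab$rdf_type, vocab$cell_culture),
    triple_lit(smp_meta$iri, vocab$dc_title, smp_meta$title),
    triple_iri(rep_meta$iri, vocab$rdf_type, vocab$transcript_class),
    triple_lit(rep_meta$iri, vocab$dc_identifier, rep_meta$id),
    triple_lit(rep_meta$iri[rep_meta$title != ""], vocab$dc_title,
               rep_meta$title[rep_meta$title != ""])
  )
  rdf_graph(bind_rows(per_obs, optional, shared))
}

#' Extract the per-sample subgraph of an observation graph
#'
#' Mirrors a SPARQL `DESCRIBE ?rep ?obs ?data ?samp` query: selects every
#' observation that `is about` the sample with the given title, then
#' returns all triples whose subject is one of those observations, their
#' datasets, their reporters, or the sample node itself. An unknown sample
#' title yields an empty graph.
#'
#' @param graph A graph produced by [observations_to_rdf()] (possibly
#'   merged with other models).
#' @param sample_title Sample `dc:title`, e.g. `"YUMAC"`.
#' @param vocab Vocabulary.
#' @return An `rdf_graph` subgraph.
#' @export
describe_sample <- function(graph, sample_title, vocab = rdf_vocabulary()) {
  graph <- rdf_graph(graph)
  samp <- graph$subject[graph$predicate == vocab$dc_title &
                        graph$object == sample_title &
                        graph$object_type == "literal"]
  samp <- intersect(samp, graph$subject[graph$predicate == vocab$rdf_type &
                                        graph$object == vocab$cell_culture])
  if (length(samp) == 0) return(rdf_graph())
  obs <- graph$subject[graph$predicate == vocab$is_about &
                       graph$object %in% samp]
  obs_rows <- graph[graph$subject %in% obs, ]
  ds <- obs_rows$object[obs_rows$predicate == vocab$part_of]
  reps <- setdiff(obs_rows$object[obs_rows$predicate == vocab$is_about], samp)
  subgraph_by_subject(graph, unique(c(obs, ds, reps, samp)))
}
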