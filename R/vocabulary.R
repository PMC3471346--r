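# Namespace roots. The legacy ro/go/k namespaces are kept so that queries
# written against the original endpoints run unmodified; purl.obolibrary is
# the modern OBO PURL root used for IAO/OBI/SO numeric ids.
NS <- list(
  obo  = "http://purl.obolibrary.org/obo/",
  ro   = "http://www.obofoundry.org/ro/ro.owl#",
  go   = "http://purl.org/obo/owl/GO#",
  k    = "http://krauthammerlab.med.yale.edu/",
  skos = "http://www.w3.org/2004/02/skos/core#",
  dc   = "http://purl.org/dc/elements/1.1/",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

#' The fixed vocabulary of IRIs used by the semantic models
#'
#' Returns the named set of IRIs with which observations, Gene Ontology
#' annotations and transcription-factor networks are expressed. Terms with
#' well-known numeric identifiers (IAO, OBI, SO) use their canonical OBO
#' PURLs; relation-ontology properties live in the legacy `ro.owl#` namespace
#' and GO concepts in the legacy `purl.org/obo/owl/GO#` namespace, so that
#' SPARQL queries written against the original endpoints run unchanged.
#'
#' @return A named list of IRI strings. Notable members:
#'   `is_about` (IAO_0000136), `has_measurement_value` (IAO_0000004),
#'   `cell_culture` (OBI_0100060), `measurement_datum_class` (IAO_0000109),
#'   `data_set_class` (IAO_0000100), `transcript_class` (SO_0000673),
#'   `part_of`, `participates_in`, `has_function` (ro namespace),
#'   `broader`, `concept` (SKOS), `corresponds_to`, `regulates`,
#'   `coregulates`, `indirectly_coregulates` (k namespace),
#'   `dc_title`, `dc_identifier`, `rdf_type`.
#' @examples
#' v <- rdf_vocabulary()
#' v$is_about
#' @export
rdf_vocabulary <- function() {
  list(
    is_about                   = paste0(NS$obo, "IAO_0000136"),
    has_measurement_value      = paste0(NS$obo, "IAO_0000004"),
    is_quality_measurement_of  = paste0(NS$obo, "IAO_0000221"),
    has_measurement_unit_label = paste0(NS$obo, "IAO_0000039"),
    measurement_datum_class    = paste0(NS$obo, "IAO_0000109"),
    data_set_class             = paste0(NS$obo, "IAO_0000100"),
    cell_culture               = paste0(NS$obo, "OBI_0100060"),
    transcript_class           = paste0(NS$obo, "SO_0000673"),
    part_of                    = paste0(NS$ro, "part_of"),
    participates_in            = paste0(NS$ro, "participates_in"),
    has_function               = paste0(NS$ro, "has_function"),
    broader                    = paste0(NS$skos, "broader"),
    concept                    = paste0(NS$skos, "Concept"),
    corresponds_to             = paste0(NS$k, "corresponds_to"),
    regulates                  = paste0(NS$k, "regulates"),
    coregulates                = paste0(NS$k, "coregulates"),
    indirectly_coregulates     = paste0(NS$k, "indirectly_coregulates"),
    dc_title                   = paste0(NS$dc, "title"),
    dc_identifier              = paste0(NS$dc, "identifier"),
    rdf_type                   = paste0(NS$rdf, "type")
  )
}

#' IRI for a GO term in the legacy GO namespace
#'
#' The local part is the bare seven-digit accession, so that queries
#' written with the `go:` prefix (`go:0006915` for apoptosis) match the
#' concept nodes directly.
#'
#' @param go_id GO accession such as `"GO:0006915"`.
#' @return IRI string, e.g. `"http://purl.org/obo/owl/GO#0006915"`.
#' @examples
#' go_uri("GO:0006915")
#' @export
go_uri <- function(go_id) {
  stopifnot(is.character(go_id))
  bad <- !grepl("^GO:[0-9]{7}$", go_id)
  if (any(bad)) {
    abort(paste0("not a GO accession: ", go_id[bad][1]))
  }
  paste0(NS$go, sub("^GO:", "", go_id))
}

xsd_double <- function() paste0(NS$xsd, "double")
xsd_string <- function() paste0(NS$xsd, "string")

# Percent-encode a string for use as an IRI path segment. Strings made of
# unreserved characters pass through untouched; the rest are encoded once
# per unique value.
iri_encode <- function(x) {
  out <- x
  needs <- grepl("[^A-Za-z0-9_.~-]", x)
  if (any(needs)) {
    ux <- unique(x[needs])
    enc <- vapply(ux, function(s) URLencode(s, reserved = TRUE), character(1),
                  USE.NAMES = FALSE)
    out[needs] <- enc[match(x[needs], ux)]
  }
  out
}
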