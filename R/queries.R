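#' Stored case-study SPARQL queries
#'
#' Returns the text of one of the queries shipped with the package:
#' `"pathway-contrast"` (per-sample counts of methylated, re-expressed
#' apoptosis vs cell-proliferation genes), `"tf-candidates"` (methylated,
#' re-expressed genes that express a transcription factor), or
#' `"describe-sample"` (the per-sample extraction query; its
#' `{{SAMPLE}}` placeholder is filled from the `sample` argument).
#'
#' @param name Query name.
#' @param sample Sample title substituted into the describe query.
#' @return Query text as a single string, ready for [run_sparql()].
#' @export
stored_query <- function(name = c("pathway-contrast", "tf-candidates",
                                  "describe-sample"),
                         sample = NULL) {
  name <- match.arg(name)
  path <- system.file("sparql", paste0(name, ".rq"), package = "semweave",
                      mustWork = TRUE)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (name == "describe-sample") {
    if (is.null(sample)) abort("describe-sample needs a sample title")
    text <- sub("{{SAMPLE}}", sample, text, fixed = TRUE)
  }
  text
}
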