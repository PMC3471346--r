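#' Write an RDF graph to Turtle or N-Triples
#'
#' The Turtle writer abbreviates IRIs with the package's namespace prefixes
#' where the local part is a safe prefixed-name; everything else is written
#' as a full IRI. One triple per line; no blank nodes (the models never use
#' them).
#'
#' @param graph An `rdf_graph`.
#' @param path File path or connection; use `NULL` to return the document
#'   as a character vector of lines.
#' @param format `"turtle"` or `"ntriples"`.
#' @return Invisibly, the lines written (visibly when `path` is `NULL`).
#' @export
write_rdf <- function(graph, path = NULL, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  graph <- rdf_graph(graph)
  lines <- if (format == "turtle") turtle_lines(graph) else ntriples_lines(graph)
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Read an RDF graph from Turtle or N-Triples
#'
#' @param path File path, connection, or a character vector of document
#'   lines.
#' @param format `"turtle"` or `"ntriples"`.
#' @return An `rdf_graph`. Malformed input aborts with the offending line
#'   number.
#' @export
read_rdf <- function(path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  lines <- if (is.character(path) && length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (inherits(path, "connection")) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  if (format == "turtle") parse_turtle(lines) else parse_ntriples(lines)
}

# Writers ---------------------------------------------------------------

term_to_ntriples <- function(value, object_type, datatype) {
  ifelse(object_type == "iri",
    paste0("<", value, ">"),
    paste0("\"", escape_string(value), "\"",
           ifelse(is.na(datatype), "", paste0("^^<", datatype, ">"))))
}

ntriples_lines <- function(graph) {
  if (nrow(graph) == 0) return(character(0))
  paste0("<", graph$subject, "> <", graph$predicate, "> ",
         term_to_ntriples(graph$object, graph$object_type, graph$datatype),
         " .")
}

# Abbreviate an IRI against the package prefixes when the remainder is a
# safe local name (letters/digits/underscore/hyphen/percent, non-empty).
abbreviate_iri <- function(iri) {
  if (length(iri) == 0) return(character(0))
  for (p in names(NS)) {
    ns <- NS[[p]]
    hit <- startsWith(iri, ns)
    local <- substr(iri, nchar(ns) + 1, nchar(iri))
    ok <- hit & grepl("^[A-Za-z0-9_%-]+$", local)
    iri <- ifelse(ok, paste0(p, ":", local), iri)
  }
  iri
}

turtle_iri <- function(value) {
  abbr <- abbreviate_iri(value)
  ifelse(abbr != value, abbr, paste0("<", value, ">"))
}

turtle_term <- function(value, object_type, datatype) {
  out <- character(length(value))
  is_iri <- object_type == "iri"
  out[is_iri] <- turtle_iri(value[is_iri])
  lit <- !is_iri
  if (any(lit)) {
    dt <- datatype[lit]
    out[lit] <- paste0("\"", escape_string(value[lit]), "\"",
                       ifelse(is.na(dt), "", paste0("^^", turtle_iri(dt))))
  }
  out
}

turtle_lines <- function(graph) {
  header <- paste0("@prefix ", names(NS), ": <", unlist(NS), "> .")
  if (nrow(graph) == 0) return(header)
  body <- paste(
    turtle_term(graph$subject, "iri", NA_character_),
    turtle_term(graph$predicate, "iri", NA_character_),
    turtle_term(graph$object, graph$object_type, graph$datatype),
    "."
  )
  c(header, "", body)
}

# Parsers ---------------------------------------------------------------

parse_ntriples <- function(lines) {
  cur <- token_cursor(tokenize_rdf(lines))
  acc <- list()
  while (!tk_done(cur)) {
    s <- tk_expect(cur, type = "iriref")
    p <- tk_expect(cur, type = "iriref")
    o <- parse_object_token(cur, prefixes = list())
    tk_expect(cur, value = ".")
    acc[[length(acc) + 1L]] <- tibble(
      subject = strip_angle(s$value), predicate = strip_angle(p$value),
      object = o$value, object_type = o$type, datatype = o$datatype
    )
  }
  if (length(acc) == 0) return(rdf_graph())
  rdf_graph(bind_rows(acc))
}

parse_turtle <- function(lines) {
  cur <- token_cursor(tokenize_rdf(lines))
  prefixes <- list()
  acc <- list()
  while (!tk_done(cur)) {
    if (tk_peek_is(cur, type = "directive")) {
      d <- tk_next(cur)
      if (d$value == "@base") abort(sprintf("line %d: @base not supported", d$line))
      pn <- tk_expect(cur, type = "pname")
      iri <- tk_expect(cur, type = "iriref")
      tk_expect(cur, value = ".")
      prefixes[[sub(":$", "", pn$value)]] <- strip_angle(iri$value)
      next
    }
    s <- parse_iri_token(cur, prefixes)
    repeat {
      p <- parse_predicate_token(cur, prefixes)
      repeat {
        o <- parse_object_token(cur, prefixes)
        acc[[length(acc) + 1L]] <- tibble(
          subject = s, predicate = p, object = o$value,
          object_type = o$type, datatype = o$datatype
        )
        if (tk_peek_is(cur, value = ",")) { tk_next(cur); next }
        break
      }
      if (tk_peek_is(cur, value = ";")) {
        tk_next(cur)
        # allow trailing ';' before '.'
        if (tk_peek_is(cur, value = ".")) break
        next
      }
      break
    }
    tk_expect(cur, value = ".")
  }
  if (length(acc) == 0) return(rdf_graph())
  rdf_graph(bind_rows(acc))
}

strip_angle <- function(v) substr(v, 2, nchar(v) - 1)

parse_iri_token <- function(cur, prefixes) {
  t <- tk_next(cur)
  if (t$type == "iriref") return(strip_angle(t$value))
  if (t$type == "pname") return(resolve_pname(t$value, prefixes, t$line))
  abort(sprintf("line %d: expected an IRI, found '%s'", t$line, t$value))
}

parse_predicate_token <- function(cur, prefixes) {
  if (tk_peek_is(cur, value = "a", type = "name")) {
    tk_next(cur)
    return(rdf_vocabulary()$rdf_type)
  }
  parse_iri_token(cur, prefixes)
}

parse_object_token <- function(cur, prefixes) {
  t <- tk_next(cur)
  if (t$type == "iriref") {
    return(list(value = strip_angle(t$value), type = "iri",
                datatype = NA_character_))
  }
  if (t$type == "pname") {
    return(list(value = resolve_pname(t$value, prefixes, t$line),
                type = "iri", datatype = NA_character_))
  }
  if (t$type == "string") {
    lex <- unescape_string(t$value)
    dt <- NA_character_
    if (tk_peek_is(cur, value = "^^")) {
      tk_next(cur)
      dt <- parse_iri_token(cur, prefixes)
    }
    return(list(value = lex, type = "literal", datatype = dt))
  }
  if (t$type == "number") {
    dt <- if (grepl("[.eE]", t$value)) xsd_double() else
      paste0(NS$xsd, "integer")
    return(list(value = t$value, type = "literal", datatype = dt))
  }
  abort(sprintf("line %d: expected an object term, found '%s'", t$line, t$value))
}
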