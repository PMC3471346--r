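# Shared tokenizer for the Turtle/N-Triples readers and the SPARQL parser.
# One alternation regex scans the document; anything left over that is not
# whitespace is a syntax error reported with its line number.

TOKEN_REGEX <- paste0(
  "#[^\n]*",                                       # comment
  "|<[^<>\"\\s{}|^`\\\\]*>",                       # IRIREF
  "|\"(?:\\\\.|[^\"\\\\\n])*\"",                   # double-quoted string
  "|'(?:\\\\.|[^'\\\\\n])*'",                      # single-quoted string
  "|\\?[A-Za-z_][A-Za-z0-9_]*",                    # SPARQL variable
  "|@prefix|@base",                                # Turtle directives
  "|[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",     # numeric literal
  "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_.%-]*", # prefixed name
  "|[A-Za-z_][A-Za-z0-9_]*",                       # bare name / keyword
  "|\\^\\^|>=|<=|!=",                              # multi-char operators
  "|[{}().,;*/+=<>-]"                              # punctuation
)

tokenize_rdf <- function(text) {
  text <- paste(text, collapse = "\n")
  mm <- gregexpr(TOKEN_REGEX, text, perl = TRUE)
  m <- mm[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (length(starts) == 1 && starts == -1) {
    starts <- integer(0); lens <- integer(0)
  }
  # coverage check: everything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (j in seq_along(starts)) {
    covered[seq.int(starts[j], length.out = lens[j])] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stray <- which(!covered & !grepl("^\\s$", chars))
  if (length(stray) > 0) {
    line <- sum(chars[seq_len(stray[1])] == "\n") + 1
    abort(sprintf("syntax error at line %d: unexpected character '%s'",
                  line, chars[stray[1]]))
  }
  vals <- regmatches(text, mm)[[1]]
  if (length(vals) == 0) {
    return(tibble(type = character(), value = character(), line = integer()))
  }
  newline_pos <- which(chars == "\n")
  lines <- findInterval(starts, newline_pos) + 1L
  type <- vapply(vals, classify_token, character(1), USE.NAMES = FALSE)
  keep <- type != "comment"
  tibble(type = type[keep], value = vals[keep], line = lines[keep])
}

classify_token <- function(v) {
  c1 <- substr(v, 1, 1)
  if (c1 == "#") return("comment")
  if (c1 == "<" && nchar(v) > 1 && substr(v, nchar(v), nchar(v)) == ">") {
    return("iriref")
  }
  if (c1 == "\"" || c1 == "'") return("string")
  if (c1 == "?") return("var")
  if (v %in% c("@prefix", "@base")) return("directive")
  if (grepl("^[0-9]", v)) return("number")
  if (grepl(":", v, fixed = TRUE)) return("pname")
  if (grepl("^[A-Za-z_]", v)) return("name")
  "punct"
}

unescape_string <- function(v) {
  body <- substr(v, 2, nchar(v) - 1)
  body <- gsub("\\\\t", "\t", body)
  body <- gsub("\\\\n", "\n", body)
  body <- gsub("\\\\r", "\r", body)
  body <- gsub("\\\\\"", "\"", body)
  body <- gsub("\\\\'", "'", body)
  gsub("\\\\\\\\", "\\\\", body)
}

escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# Cursor over a token tibble -------------------------------------------

token_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

tk_done <- function(cur) cur$i > nrow(cur$tokens)

tk_peek <- function(cur, offset = 0L) {
  j <- cur$i + offset
  if (j > nrow(cur$tokens)) return(NULL)
  as.list(cur$tokens[j, ])
}

tk_next <- function(cur) {
  t <- tk_peek(cur)
  if (is.null(t)) abort("unexpected end of input")
  cur$i <- cur$i + 1L
  t
}

tk_expect <- function(cur, value = NULL, type = NULL) {
  t <- tk_next(cur)
  if (!is.null(value) && !identical(toupper(t$value), toupper(value))) {
    abort(sprintf("line %d: expected '%s' but found '%s'",
                  t$line, value, t$value))
  }
  if (!is.null(type) && t$type != type) {
    abort(sprintf("line %d: expected %s but found '%s'", t$line, type, t$value))
  }
  t
}

tk_peek_is <- function(cur, value = NULL, type = NULL) {
  t <- tk_peek(cur)
  if (is.null(t)) return(FALSE)
  ok <- TRUE
  if (!is.null(value)) ok <- ok && identical(toupper(t$value), toupper(value))
  if (!is.null(type)) ok <- ok && t$type == type
  ok
}

resolve_pname <- function(value, prefixes, line = NA) {
  parts <- regmatches(value, regexec("^([^:]*):(.*)$", value))[[1]]
  prefix <- parts[2]; local <- parts[3]
  if (!prefix %in% names(prefixes)) {
    abort(sprintf("line %s: undeclared prefix '%s:'", line, prefix))
  }
  paste0(prefixes[[prefix]], local)
}
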