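# A SPARQL 1.1 subset engine: SELECT / DESCRIBE, basic graph patterns,
# FILTER with comparisons and arithmetic, DISTINCT, COUNT / COUNT(DISTINCT)
# aggregates, GROUP BY and ORDER BY. That is exactly the fragment the
# stored case-study queries exercise; solution semantics follow the
# standard (bag of bindings, inner-join BGP evaluation, filters as
# effective-boolean-value row restrictions).

SPARQL_KEYWORDS <- c("SELECT", "DESCRIBE", "WHERE", "FILTER", "PREFIX",
                     "DISTINCT", "COUNT", "AS", "GROUP", "ORDER", "BY",
                     "ASC", "DESC")

# Parsing ---------------------------------------------------------------

parse_sparql <- function(query) {
  cur <- token_cursor(tokenize_rdf(query))
  prefixes <- list()
  while (tk_peek_is(cur, value = "PREFIX")) {
    tk_next(cur)
    pn <- tk_expect(cur, type = "pname")
    iri <- tk_expect(cur, type = "iriref")
    prefixes[[sub(":$", "", pn$value)]] <- strip_angle(iri$value)
  }
  form <- tk_next(cur)
  if (form$type != "name" ||
      !toupper(form$value) %in% c("SELECT", "DESCRIBE")) {
    abort(sprintf("line %d: expected SELECT or DESCRIBE, found '%s'",
                  form$line, form$value))
  }
  q <- list(prefixes = prefixes, distinct = FALSE, projections = list(),
            describe_vars = character(0), patterns = list(), filters = list(),
            group_by = character(0), order_by = list())
  q$type <- tolower(form$value)
  if (q$type == "select") {
    if (tk_peek_is(cur, value = "DISTINCT")) { tk_next(cur); q$distinct <- TRUE }
    repeat {
      if (tk_peek_is(cur, value = "WHERE") || tk_peek_is(cur, value = "{")) break
      if (tk_peek_is(cur, type = "var")) {
        v <- tk_next(cur)
        q$projections[[length(q$projections) + 1L]] <-
          list(kind = "var", var = substring(v$value, 2), name = substring(v$value, 2))
      } else if (tk_peek_is(cur, value = "(")) {
        tk_next(cur)
        expr <- parse_sparql_expr(cur, prefixes)
        tk_expect(cur, value = "AS")
        v <- tk_expect(cur, type = "var")
        tk_expect(cur, value = ")")
        q$projections[[length(q$projections) + 1L]] <-
          list(kind = "expr", expr = expr, name = substring(v$value, 2))
      } else {
        t <- tk_peek(cur)
        abort(sprintf("line %d: unexpected token '%s' in SELECT clause",
                      t$line, t$value))
      }
    }
    if (length(q$projections) == 0) abort("empty SELECT clause")
  } else {
    while (tk_peek_is(cur, type = "var")) {
      q$describe_vars <- c(q$describe_vars, substring(tk_next(cur)$value, 2))
    }
    if (length(q$describe_vars) == 0) abort("DESCRIBE needs at least one variable")
  }
  if (tk_peek_is(cur, value = "WHERE")) tk_next(cur)
  tk_expect(cur, value = "{")
  repeat {
    if (tk_peek_is(cur, value = "}")) { tk_next(cur); break }
    if (tk_peek_is(cur, value = "FILTER")) {
      tk_next(cur)
      tk_expect(cur, value = "(")
      q$filters[[length(q$filters) + 1L]] <- parse_sparql_expr(cur, prefixes)
      tk_expect(cur, value = ")")
      if (tk_peek_is(cur, value = ".")) tk_next(cur)
      next
    }
    s <- parse_pattern_term(cur, prefixes, position = "subject")
    p <- parse_pattern_term(cur, prefixes, position = "predicate")
    o <- parse_pattern_term(cur, prefixes, position = "object")
    q$patterns[[length(q$patterns) + 1L]] <- list(s = s, p = p, o = o)
    if (tk_peek_is(cur, value = ".")) tk_next(cur)
  }
  # solution modifiers
  while (!tk_done(cur)) {
    kw <- tk_next(cur)
    if (toupper(kw$value) == "GROUP") {
      tk_expect(cur, value = "BY")
      while (tk_peek_is(cur, type = "var")) {
        q$group_by <- c(q$group_by, substring(tk_next(cur)$value, 2))
      }
    } else if (toupper(kw$value) == "ORDER") {
      tk_expect(cur, value = "BY")
      repeat {
        if (tk_peek_is(cur, type = "var")) {
          q$order_by[[length(q$order_by) + 1L]] <-
            list(var = substring(tk_next(cur)$value, 2), desc = FALSE)
        } else if (tk_peek_is(cur, value = "ASC") || tk_peek_is(cur, value = "DESC")) {
          dir <- toupper(tk_next(cur)$value)
          tk_expect(cur, value = "(")
          v <- tk_expect(cur, type = "var")
          tk_expect(cur, value = ")")
          q$order_by[[length(q$order_by) + 1L]] <-
            list(var = substring(v$value, 2), desc = dir == "DESC")
        } else break
      }
    } else {
      abort(sprintf("line %d: unexpected token '%s' after group pattern",
                    kw$line, kw$value))
    }
  }
  q
}

parse_pattern_term <- function(cur, prefixes, position) {
  t <- tk_next(cur)
  if (t$type == "var") return(list(kind = "var", var = substring(t$value, 2)))
  if (t$type == "iriref") return(list(kind = "iri", value = strip_angle(t$value)))
  if (t$type == "pname") {
    return(list(kind = "iri", value = resolve_pname(t$value, prefixes, t$line)))
  }
  if (t$type == "name" && t$value == "a" && position == "predicate") {
    return(list(kind = "iri", value = rdf_vocabulary()$rdf_type))
  }
  if (position != "predicate" && t$type == "string") {
    dt <- NA_character_
    if (tk_peek_is(cur, value = "^^")) {
      tk_next(cur)
      dt <- parse_iri_token(cur, prefixes)
    }
    return(list(kind = "literal", value = unescape_string(t$value), datatype = dt))
  }
  if (position == "object" && t$type == "number") {
    dt <- if (grepl("[.eE]", t$value)) xsd_double() else paste0(NS$xsd, "integer")
    return(list(kind = "literal", value = t$value, datatype = dt))
  }
  abort(sprintf("line %d: unexpected %s term '%s'", t$line, position, t$value))
}

# expression := additive (comparison additive)?
parse_sparql_expr <- function(cur, prefixes) {
  lhs <- parse_additive(cur, prefixes)
  if (tk_peek_is(cur, type = "punct") &&
      tk_peek(cur)$value %in% c(">", "<", ">=", "<=", "=", "!=")) {
    op <- tk_next(cur)$value
    rhs <- parse_additive(cur, prefixes)
    return(list(op = "cmp", fn = op, lhs = lhs, rhs = rhs))
  }
  lhs
}

parse_additive <- function(cur, prefixes) {
  lhs <- parse_multiplicative(cur, prefixes)
  while (tk_peek_is(cur, type = "punct") && tk_peek(cur)$value %in% c("+", "-")) {
    op <- tk_next(cur)$value
    rhs <- parse_multiplicative(cur, prefixes)
    lhs <- list(op = "arith", fn = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_multiplicative <- function(cur, prefixes) {
  lhs <- parse_primary(cur, prefixes)
  while (tk_peek_is(cur, type = "punct") && tk_peek(cur)$value %in% c("*", "/")) {
    op <- tk_next(cur)$value
    rhs <- parse_primary(cur, prefixes)
    lhs <- list(op = "arith", fn = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_primary <- function(cur, prefixes) {
  t <- tk_peek(cur)
  if (is.null(t)) abort("unexpected end of expression")
  if (t$type == "punct" && t$value == "(") {
    tk_next(cur)
    e <- parse_sparql_expr(cur, prefixes)
    tk_expect(cur, value = ")")
    return(e)
  }
  if (t$type == "name" && toupper(t$value) == "COUNT") {
    tk_next(cur)
    tk_expect(cur, value = "(")
    dist <- FALSE
    if (tk_peek_is(cur, value = "DISTINCT")) { tk_next(cur); dist <- TRUE }
    v <- tk_expect(cur, type = "var")
    tk_expect(cur, value = ")")
    return(list(op = "count", distinct = dist, var = substring(v$value, 2)))
  }
  if (t$type == "var") {
    tk_next(cur)
    return(list(op = "var", name = substring(t$value, 2)))
  }
  if (t$type == "number") {
    tk_next(cur)
    return(list(op = "num", value = as.numeric(t$value)))
  }
  if (t$type == "string") {
    tk_next(cur)
    return(list(op = "str", value = unescape_string(t$value)))
  }
  if (t$type %in% c("iriref", "pname")) {
    return(list(op = "iri", value = parse_iri_token(cur, prefixes)))
  }
  abort(sprintf("line %d: unexpected token '%s' in expression", t$line, t$value))
}

# Term encoding ---------------------------------------------------------
# During evaluation every RDF term is a single string key (its N-Triples
# form) so joins and DISTINCT are plain string operations.

term_key <- function(value, object_type, datatype) {
  n <- length(value)
  if (n == 0) return(character(0))
  object_type <- rep_len(object_type, n)
  datatype <- rep_len(datatype, n)
  ifelse(object_type == "iri", paste0("<", value, ">"),
         paste0("\"", escape_string(value), "\"",
                ifelse(is.na(datatype), "", paste0("^^<", datatype, ">"))))
}

pattern_term_key <- function(term) {
  if (term$kind == "iri") return(term_key(term$value, "iri", NA_character_))
  term_key(term$value, "literal", term$datatype)
}

key_is_iri <- function(key) startsWith(key, "<")

key_display <- function(key) {
  out <- key
  iri <- key_is_iri(key) & !is.na(key)
  out[iri] <- substr(key[iri], 2, nchar(key[iri]) - 1)
  lit <- !iri & !is.na(key)
  out[lit] <- vapply(key[lit], function(k) {
    unescape_string(sub("\\^\\^<[^>]*>$", "", k))
  }, character(1), USE.NAMES = FALSE)
  out
}

xsd_numeric_types <- function() {
  paste0(NS$xsd, c("double", "float", "decimal", "integer", "int", "long"))
}

key_numeric <- function(key) {
  out <- rep(NA_real_, length(key))
  lit <- !is.na(key) & !key_is_iri(key)
  if (!any(lit)) return(out)
  dt <- rep(NA_character_, length(key))
  has_dt <- lit & grepl("\\^\\^<[^>]*>$", key)
  dt[has_dt] <- sub("^.*\\^\\^<([^>]*)>$", "\\1", key[has_dt])
  lex <- key_display(key)
  ok <- lit & (is.na(dt) | dt %in% xsd_numeric_types())
  out[ok] <- suppressWarnings(as.numeric(lex[ok]))
  out
}

encode_graph <- function(graph) {
  tibble(
    s_key = term_key(graph$subject, "iri", NA_character_),
    p_key = term_key(graph$predicate, "iri", NA_character_),
    o_key = term_key(graph$object, graph$object_type, graph$datatype)
  )
}

# BGP evaluation --------------------------------------------------------

match_pattern <- function(enc, pat) {
  df <- enc
  if (pat$s$kind != "var") df <- df[df$s_key == pattern_term_key(pat$s), ]
  if (pat$p$kind != "var") df <- df[df$p_key == pattern_term_key(pat$p), ]
  if (pat$o$kind != "var") df <- df[df$o_key == pattern_term_key(pat$o), ]
  slots <- list(s_key = pat$s, p_key = pat$p, o_key = pat$o)
  vars <- list()
  for (col in names(slots)) {
    term <- slots[[col]]
    if (term$kind != "var") next
    if (term$var %in% names(vars)) {
      df <- df[df[[col]] == df[[vars[[term$var]]]], ]  # repeated variable
    } else {
      vars[[term$var]] <- col
    }
  }
  out <- df[, unlist(vars), drop = FALSE]
  names(out) <- names(vars)
  distinct_rows <- out  # keep bag semantics: same var set may repeat
  distinct_rows
}

join_solutions <- function(a, b) {
  if (ncol(a) == 0) {
    if (nrow(a) == 0) return(b[0, , drop = FALSE])
    return(b)
  }
  if (ncol(b) == 0) {
    if (nrow(b) == 0) return(a[0, , drop = FALSE])
    return(a)
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) return(cross_join(a, b))
  inner_join(a, b, by = shared, relationship = "many-to-many")
}

eval_bgp <- function(enc, patterns) {
  if (length(patterns) == 0) return(tibble(.rows = 1))
  sol <- match_pattern(enc, patterns[[1]])
  for (pat in patterns[-1]) {
    sol <- join_solutions(sol, match_pattern(enc, pat))
    if (nrow(sol) == 0) {
      # still need the full variable set for projection
      remaining_vars <- unlist(lapply(patterns, function(p) {
        vs <- c(); for (t in p) if (t$kind == "var") vs <- c(vs, t$var); vs
      }))
      for (v in setdiff(unique(remaining_vars), names(sol))) {
        sol[[v]] <- character(0)
      }
      return(sol)
    }
  }
  sol
}

# Row-wise (non-aggregate) expression evaluation; returns a numeric,
# character or logical vector aligned with sol rows.
eval_expr_rows <- function(expr, sol) {
  switch(expr$op,
    var = sol[[expr$name]],
    num = rep(expr$value, nrow(sol)),
    str = rep(term_key(expr$value, "literal", NA_character_), nrow(sol)),
    iri = rep(term_key(expr$value, "iri", NA_character_), nrow(sol)),
    cmp = {
      lhs <- eval_expr_rows(expr$lhs, sol)
      rhs <- eval_expr_rows(expr$rhs, sol)
      compare_values(expr$fn, lhs, rhs)
    },
    arith = {
      lhs <- to_numeric(eval_expr_rows(expr$lhs, sol))
      rhs <- to_numeric(eval_expr_rows(expr$rhs, sol))
      switch(expr$fn, "+" = lhs + rhs, "-" = lhs - rhs,
             "*" = lhs * rhs, "/" = lhs / rhs)
    },
    count = abort("aggregate used outside a group context")
  )
}

to_numeric <- function(x) {
  if (is.numeric(x)) return(x)
  key_numeric(x)
}

compare_values <- function(fn, lhs, rhs) {
  ln <- to_numeric(lhs); rn <- to_numeric(rhs)
  num_ok <- !is.na(ln) & !is.na(rn)
  out <- logical(length(num_ok))
  out[num_ok] <- switch(fn,
    ">" = ln[num_ok] > rn[num_ok], "<" = ln[num_ok] < rn[num_ok],
    ">=" = ln[num_ok] >= rn[num_ok], "<=" = ln[num_ok] <= rn[num_ok],
    "=" = ln[num_ok] == rn[num_ok], "!=" = ln[num_ok] != rn[num_ok])
  if (fn %in% c("=", "!=")) {
    # fall back to term equality for non-numeric operands
    str_cmp <- !num_ok & !is.na(lhs) & !is.na(rhs)
    eq <- as.character(lhs)[str_cmp] == as.character(rhs)[str_cmp]
    out[str_cmp] <- if (fn == "=") eq else !eq
  }
  out
}

# Aggregate expression evaluation over one group.
eval_expr_group <- function(expr, group_df) {
  switch(expr$op,
    count = {
      vals <- group_df[[expr$var]]
      vals <- vals[!is.na(vals)]
      if (expr$distinct) length(unique(vals)) else length(vals)
    },
    var = {
      v <- unique(group_df[[expr$name]])
      if (length(v) != 1) abort(paste0("variable ?", expr$name,
                                       " is not constant within a group"))
      v
    },
    num = expr$value,
    str = term_key(expr$value, "literal", NA_character_),
    iri = term_key(expr$value, "iri", NA_character_),
    cmp = abort("comparison not supported in SELECT expressions"),
    arith = {
      lhs <- to_numeric_scalar(eval_expr_group(expr$lhs, group_df))
      rhs <- to_numeric_scalar(eval_expr_group(expr$rhs, group_df))
      switch(expr$fn, "+" = lhs + rhs, "-" = lhs - rhs,
             "*" = lhs * rhs, "/" = lhs / rhs)
    }
  )
}

to_numeric_scalar <- function(x) {
  if (is.numeric(x)) return(x)
  key_numeric(x)
}

has_aggregate <- function(expr) {
  if (!is.list(expr)) return(FALSE)
  if (identical(expr$op, "count")) return(TRUE)
  any(vapply(expr[c("lhs", "rhs")], function(e) {
    !is.null(e) && has_aggregate(e)
  }, logical(1)))
}

# Decode a column of term keys for output: numeric literal columns become
# numeric, everything else its display form.
decode_column <- function(x) {
  if (is.numeric(x)) return(x)
  nums <- key_numeric(x)
  if (length(x) > 0 && all(!is.na(nums) | is.na(x))) return(nums)
  key_display(x)
}

#' Run a SPARQL query over an RDF graph
#'
#' Supports the SPARQL 1.1 fragment used by the stored case-study queries:
#' `SELECT` (with `DISTINCT`, expression projections, `COUNT` /
#' `COUNT(DISTINCT)` aggregates, `GROUP BY`, `ORDER BY`) and `DESCRIBE`,
#' over basic graph patterns with `FILTER` comparisons and arithmetic.
#' Parse errors report the offending line.
#'
#' @param graph An `rdf_graph`.
#' @param query Query text (single string or character vector of lines).
#' @return For `SELECT`, a tibble with one column per projected variable
#'   (IRIs as strings, numeric literals and aggregates as numbers). For
#'   `DESCRIBE`, an `rdf_graph` containing every triple whose subject is a
#'   binding of a described variable.
#' @export
run_sparql <- function(graph, query) {
  graph <- rdf_graph(graph)
  q <- parse_sparql(paste(query, collapse = "\n"))
  enc <- encode_graph(graph)
  sol <- eval_bgp(enc, q$patterns)
  for (f in q$filters) {
    if (nrow(sol) == 0) break
    keep <- eval_expr_rows(f, sol)
    keep[is.na(keep)] <- FALSE
    sol <- sol[keep, , drop = FALSE]
  }
  if (q$type == "describe") {
    keys <- unique(unlist(sol[intersect(q$describe_vars, names(sol))],
                          use.names = FALSE))
    nodes <- key_display(keys[!is.na(keys) & key_is_iri(keys)])
    return(subgraph_by_subject(graph, nodes))
  }
  aggregated <- length(q$group_by) > 0 ||
    any(vapply(q$projections, function(p) p$kind == "expr" &&
                 has_aggregate(p$expr), logical(1)))
  if (aggregated) {
    out <- eval_aggregated(q, sol)
  } else {
    out <- tibble(.rows = nrow(sol))
    for (p in q$projections) {
      out[[p$name]] <- if (p$kind == "var") sol[[p$var]] else
        eval_expr_rows(p$expr, sol)
    }
  }
  out <- as_tibble(lapply(out, decode_column))
  if (q$distinct) out <- distinct(out)
  if (length(q$order_by) > 0) {
    keys <- lapply(q$order_by, function(o) {
      v <- out[[o$var]]
      if (o$desc && is.numeric(v)) -v else if (o$desc) -xtfrm(v) else v
    })
    ord <- do.call(order, c(keys, list(method = "radix")))
    out <- out[ord, , drop = FALSE]
  }
  out
}

eval_aggregated <- function(q, sol) {
  if (length(q$group_by) > 0) {
    missing_gv <- setdiff(q$group_by, names(sol))
    for (v in missing_gv) sol[[v]] <- NA_character_
    group_key <- do.call(paste, c(sol[q$group_by], sep = "\r"))
  } else {
    group_key <- rep("", nrow(sol))
  }
  groups <- if (nrow(sol) == 0 && length(q$group_by) > 0) {
    list()
  } else if (nrow(sol) == 0) {
    list(sol)  # implicit single group, aggregates over the empty bag
  } else {
    unname(split(sol, group_key))
  }
  rows <- lapply(groups, function(gdf) {
    vals <- lapply(q$projections, function(p) {
      if (p$kind == "var") {
        if (!p$var %in% q$group_by) {
          abort(paste0("variable ?", p$var, " must appear in GROUP BY"))
        }
        gdf[[p$var]][1]
      } else {
        eval_expr_group(p$expr, gdf)
      }
    })
    setNames(vals, vapply(q$projections, function(p) p$name, character(1)))
  })
  if (length(rows) == 0) {
    out <- tibble(.rows = 0)
    for (p in q$projections) out[[p$name]] <- character(0)
    return(out)
  }
  bind_rows(lapply(rows, as_tibble))
}
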