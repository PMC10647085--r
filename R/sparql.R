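# SPARQL query engine.
#
# Implements the core of SPARQL 1.1 SELECT/ASK over the embedded store:
# PREFIX declarations, basic graph patterns with joins, FILTER expressions
# (comparisons, && || !, BOUND, STRSTARTS), OPTIONAL groups, DISTINCT, and
# transitive property paths p* / p+ on a fixed predicate. This covers the
# query shapes the analysis agents construct; unsupported syntax fails with
# the position of the offending token.

SEP <- "\x1f"
enc_term <- function(type, value) {
  if (!length(value)) return(character(0))
  paste(type, value, sep = SEP)
}
dec_type <- function(x) sub("\x1f.*$", "", x)
dec_value <- function(x) sub("^[^\x1f]*\x1f", "", x)

sparql_tokenize <- function(q) {
  toks <- list()
  i <- 1L
  n <- nchar(q)
  push <- function(kind, text, pos) {
    toks[[length(toks) + 1L]] <<- list(kind = kind, text = text, pos = pos)
  }
  while (i <= n) {
    ch <- substr(q, i, i)
    rest <- substr(q, i, n)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { i <- i + attr(regexpr("^[^\n]*", rest), "match.length"); next }
    if (ch == "<") {
      m <- regexpr("^<[^<>\"{}|^`\\\\ ]*>", rest)
      if (m == -1L) stop_sparql("unterminated IRI", i)
      push("iri", substr(rest, 2L, attr(m, "match.length") - 1L), i)
      i <- i + attr(m, "match.length"); next
    }
    if (ch == "?" || ch == "$") {
      m <- regexpr("^[?$][A-Za-z_][A-Za-z0-9_]*", rest)
      if (m == -1L) stop_sparql("bad variable name", i)
      push("var", substr(rest, 2L, attr(m, "match.length")), i)
      i <- i + attr(m, "match.length"); next
    }
    if (ch == "\"") {
      j <- i + 1L
      val <- ""
      while (j <= n) {
        cj <- substr(q, j, j)
        if (cj == "\\" && j < n) { val <- paste0(val, substr(q, j, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        val <- paste0(val, cj); j <- j + 1L
      }
      if (j > n) stop_sparql("unterminated string literal", i)
      push("string", unescape_literal(val), i)
      i <- j + 1L; next
    }
    m <- regexpr("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", rest)
    if (m == 1L && attr(m, "match.length") > 0L) {
      push("number", substr(rest, 1L, attr(m, "match.length")), i)
      i <- i + attr(m, "match.length"); next
    }
    two <- substr(q, i, min(n, i + 1L))
    if (two %in% c("&&", "||", "<=", ">=", "!=", "^^")) {
      push("op", two, i); i <- i + 2L; next
    }
    if (ch %in% c("{", "}", "(", ")", ".", ",", ";", "*", "+", "=", "<", ">", "!")) {
      push("op", ch, i); i <- i + 1L; next
    }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_-]*(:[A-Za-z0-9_.-]*)?", rest)
    if (m == 1L) {
      txt <- substr(rest, 1L, attr(m, "match.length"))
      push(if (grepl(":", txt)) "pname" else "ident", txt, i)
      i <- i + attr(m, "match.length"); next
    }
    stop_sparql(sprintf("unexpected character %s", dQuote(ch)), i)
  }
  toks
}

stop_sparql <- function(msg, pos) {
  stop(sprintf("SPARQL syntax error at character %d: %s", pos, msg),
       call. = FALSE)
}

# recursive-descent parser state: environment with tokens and cursor
sp_state <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks
  e$i <- 1L
  e
}
sp_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
sp_next <- function(st) { t <- sp_peek(st); st$i <- st$i + 1L; t }
sp_expect <- function(st, kind, text = NULL) {
  t <- sp_peek(st)
  if (is.null(t) || t$kind != kind || (!is.null(text) && !identical(toupper(t$text), toupper(text)))) {
    pos <- if (is.null(t)) nchar_end(st) else t$pos
    stop_sparql(sprintf("expected %s", text %||% kind), pos)
  }
  sp_next(st)
}
nchar_end <- function(st) {
  if (length(st$toks)) st$toks[[length(st$toks)]]$pos + 1L else 1L
}
sp_is_kw <- function(t, kw) !is.null(t) && t$kind == "ident" && toupper(t$text) == kw

DEFAULT_SPARQL_PREFIXES <- function() {
  c(rdf = RDF, rdfs = RDFS, skos = SKOS, xsd = XSD, os = OS,
    oskg = kg_namespace())
}

resolve_pname <- function(txt, prefixes, pos) {
  parts <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_-]*):(.*)$", txt))[[1]]
  if (!length(parts) || !(parts[2] %in% names(prefixes))) {
    stop_sparql(sprintf("unknown prefix in %s", dQuote(txt)), pos)
  }
  paste0(prefixes[[parts[2]]], parts[3])
}

parse_term <- function(st, prefixes) {
  t <- sp_next(st)
  if (is.null(t)) stop_sparql("unexpected end of query", nchar_end(st))
  switch(t$kind,
    var = list(kind = "var", name = t$text),
    iri = list(kind = "iri", value = t$text),
    pname = list(kind = "iri", value = resolve_pname(t$text, prefixes, t$pos)),
    string = {
      nt <- sp_peek(st)
      dt <- NULL
      if (!is.null(nt) && nt$kind == "op" && nt$text == "^^") {
        sp_next(st)
        dtt <- sp_next(st)
        dt <- if (dtt$kind == "iri") dtt$value else resolve_pname(dtt$text, prefixes, dtt$pos)
      }
      ty <- if (is.null(dt)) "string" else {
        hit <- names(XSD_OF_TYPE)[match(local_name(dt), XSD_OF_TYPE)]
        if (is.na(hit)) "string" else hit
      }
      list(kind = "literal", value = t$text, type = ty)
    },
    number = list(kind = "literal", value = t$text,
                  type = if (grepl("[.eE]", t$text)) "decimal" else "integer"),
    ident = {
      if (t$text == "a") list(kind = "iri", value = paste0(RDF, "type"))
      else if (t$text %in% c("true", "false")) list(kind = "literal", value = t$text, type = "boolean")
      else stop_sparql(sprintf("unexpected token %s", dQuote(t$text)), t$pos)
    },
    stop_sparql(sprintf("unexpected token %s", dQuote(t$text)), t$pos)
  )
}

parse_group <- function(st, prefixes) {
  sp_expect(st, "op", "{")
  elems <- list()
  repeat {
    t <- sp_peek(st)
    if (is.null(t)) stop_sparql("unterminated group: missing '}'", nchar_end(st))
    if (t$kind == "op" && t$text == "}") { sp_next(st); break }
    if (sp_is_kw(t, "FILTER")) {
      sp_next(st)
      sp_expect(st, "op", "(")
      ex <- parse_or(st, prefixes)
      sp_expect(st, "op", ")")
      elems[[length(elems) + 1L]] <- list(kind = "filter", expr = ex)
      next
    }
    if (sp_is_kw(t, "OPTIONAL")) {
      sp_next(st)
      elems[[length(elems) + 1L]] <- list(kind = "optional",
                                          group = parse_group(st, prefixes))
      next
    }
    s <- parse_term(st, prefixes)
    p <- parse_term(st, prefixes)
    mod <- NULL
    nt <- sp_peek(st)
    if (!is.null(nt) && nt$kind == "op" && nt$text %in% c("*", "+")) {
      if (p$kind != "iri") stop_sparql("property paths need a fixed predicate", nt$pos)
      mod <- nt$text
      sp_next(st)
    }
    o <- parse_term(st, prefixes)
    nt <- sp_peek(st)
    if (!is.null(nt) && nt$kind == "op" && nt$text == ".") sp_next(st)
    elems[[length(elems) + 1L]] <- list(kind = "pattern", s = s, p = p, o = o,
                                        mod = mod)
  }
  elems
}

parse_or <- function(st, prefixes) {
  left <- parse_and(st, prefixes)
  repeat {
    t <- sp_peek(st)
    if (!is.null(t) && t$kind == "op" && t$text == "||") {
      sp_next(st)
      left <- list(op = "||", left = left, right = parse_and(st, prefixes))
    } else return(left)
  }
}
parse_and <- function(st, prefixes) {
  left <- parse_unary(st, prefixes)
  repeat {
    t <- sp_peek(st)
    if (!is.null(t) && t$kind == "op" && t$text == "&&") {
      sp_next(st)
      left <- list(op = "&&", left = left, right = parse_unary(st, prefixes))
    } else return(left)
  }
}
parse_unary <- function(st, prefixes) {
  t <- sp_peek(st)
  if (!is.null(t) && t$kind == "op" && t$text == "!") {
    sp_next(st)
    return(list(op = "!", left = parse_unary(st, prefixes)))
  }
  parse_rel(st, prefixes)
}
parse_rel <- function(st, prefixes) {
  left <- parse_primary(st, prefixes)
  t <- sp_peek(st)
  if (!is.null(t) && t$kind == "op" && t$text %in% c("=", "!=", "<", "<=", ">", ">=")) {
    sp_next(st)
    return(list(op = t$text, left = left, right = parse_primary(st, prefixes)))
  }
  left
}
parse_primary <- function(st, prefixes) {
  t <- sp_peek(st)
  if (is.null(t)) stop_sparql("unexpected end of expression", nchar_end(st))
  if (t$kind == "op" && t$text == "(") {
    sp_next(st)
    ex <- parse_or(st, prefixes)
    sp_expect(st, "op", ")")
    return(ex)
  }
  if (t$kind == "ident" && toupper(t$text) %in% c("BOUND", "STR", "STRSTARTS")) {
    fn <- toupper(t$text)
    sp_next(st)
    sp_expect(st, "op", "(")
    args <- list(parse_or(st, prefixes))
    while (!is.null(sp_peek(st)) && sp_peek(st)$kind == "op" &&
           sp_peek(st)$text == ",") {
      sp_next(st)
      args[[length(args) + 1L]] <- parse_or(st, prefixes)
    }
    sp_expect(st, "op", ")")
    return(list(op = "call", fn = fn, args = args))
  }
  list(op = "term", term = parse_term(st, prefixes))
}

# --- evaluation ---

unit_solution <- function() {
  structure(data.frame(row.names = 1L), names = character(0))
}

match_pattern <- function(df, pat) {
  if (!is.null(pat$mod)) return(match_path(df, pat))
  cand <- df
  if (pat$s$kind == "iri") cand <- cand[cand$s == pat$s$value, , drop = FALSE]
  if (pat$p$kind != "iri") stop("variable predicates are not supported", call. = FALSE)
  cand <- cand[cand$p == pat$p$value, , drop = FALSE]
  if (pat$o$kind == "iri") {
    cand <- cand[cand$o == pat$o$value & cand$type == "iri", , drop = FALSE]
  } else if (pat$o$kind == "literal") {
    if (pat$o$type %in% c("decimal", "integer")) {
      keep <- cand$type %in% c("decimal", "integer") &
        suppressWarnings(as.numeric(cand$o)) == as.numeric(pat$o$value)
      keep[is.na(keep)] <- FALSE
      cand <- cand[keep, , drop = FALSE]
    } else {
      cand <- cand[cand$o == pat$o$value & cand$type == pat$o$type, , drop = FALSE]
    }
  }
  out <- list()
  if (pat$s$kind == "var") out[[pat$s$name]] <- enc_term("iri", cand$s)
  if (pat$o$kind == "var") out[[pat$o$name]] <- enc_term(cand$type, cand$o)
  bindings_df(out, nrow(cand), pat)
}

bindings_df <- function(cols, nmatch, pat) {
  if (!length(cols)) {
    # fully ground pattern: acts as an existence test
    return(if (nmatch > 0L) unit_solution() else
      structure(data.frame(row.names = integer(0)), names = character(0)))
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  names(df) <- names(cols)
  # same variable in two positions of one pattern: keep consistent rows only
  if (pat$s$kind == "var" && pat$o$kind == "var" && pat$s$name == pat$o$name) {
    df <- df[df[[1]] == df[[2]], 1, drop = FALSE]
  }
  unique(df)
}

# transitive closure table for p* / p+ over iri-objects of predicate p
match_path <- function(df, pat) {
  base <- df[df$p == pat$p$value & df$type == "iri", c("s", "o"), drop = FALSE]
  pairs <- unique(base)
  repeat {
    ext <- merge(pairs, base, by.x = "o", by.y = "s")
    ext <- unique(data.frame(s = ext$s, o = ext$o.y, stringsAsFactors = FALSE))
    merged <- unique(rbind(pairs, ext))
    if (nrow(merged) == nrow(pairs)) break
    pairs <- merged
  }
  if (pat$mod == "*") {
    nodes <- unique(c(df$s, df$o[df$type == "iri"]))
    pairs <- unique(rbind(pairs, data.frame(s = nodes, o = nodes,
                                            stringsAsFactors = FALSE)))
  }
  if (pat$s$kind == "iri") pairs <- pairs[pairs$s == pat$s$value, , drop = FALSE]
  if (pat$o$kind == "iri") pairs <- pairs[pairs$o == pat$o$value, , drop = FALSE]
  out <- list()
  if (pat$s$kind == "var") out[[pat$s$name]] <- enc_term("iri", pairs$s)
  if (pat$o$kind == "var") out[[pat$o$name]] <- enc_term("iri", pairs$o)
  bindings_df(out, nrow(pairs), pat)
}

join_solutions <- function(a, b) {
  if (is.null(a)) return(b)
  common <- intersect(names(a), names(b))
  if (!length(common)) {
    if (!nrow(a) || !nrow(b)) {
      empty <- a[integer(0), , drop = FALSE]
      for (nm in names(b)) empty[[nm]] <- character(0)
      return(empty)
    }
    return(merge(a, b, by = NULL))
  }
  merge(a, b, by = common, stringsAsFactors = FALSE)
}

left_join_solutions <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) {
    if (!nrow(b)) {
      for (nm in names(b)) a[[nm]] <- NA_character_
      return(a)
    }
    return(merge(a, b, by = NULL))
  }
  merge(a, b, by = common, all.x = TRUE)
}

eval_group <- function(df, elems) {
  sol <- NULL
  filters <- list()
  for (el in elems) {
    if (el$kind == "pattern") {
      sol <- join_solutions(sol, match_pattern(df, el))
    } else if (el$kind == "optional") {
      inner <- eval_group(df, el$group)
      sol <- if (is.null(sol)) inner else left_join_solutions(sol, inner)
    } else if (el$kind == "filter") {
      filters[[length(filters) + 1L]] <- el$expr
    }
  }
  if (is.null(sol)) sol <- unit_solution()
  for (f in filters) {
    if (!nrow(sol)) break
    keep <- vapply(seq_len(nrow(sol)), function(i) {
      isTRUE(eval_expr(f, sol[i, , drop = FALSE]))
    }, logical(1))
    sol <- sol[keep, , drop = FALSE]
  }
  sol
}

term_value <- function(term, row) {
  if (term$kind == "var") {
    if (!term$name %in% names(row)) return(NULL)
    comp <- row[[term$name]]
    if (is.na(comp)) return(NULL)
    decode_composite(comp)
  } else if (term$kind == "iri") {
    term$value
  } else {
    decode_composite(enc_term(term$type, term$value))
  }
}

decode_composite <- function(comp) {
  ty <- dec_type(comp)
  v <- dec_value(comp)
  switch(ty,
         decimal = as.numeric(v),
         integer = as.numeric(v),
         boolean = identical(v, "true"),
         v)
}

eval_expr <- function(ex, row) {
  if (!is.null(ex$op)) {
    switch(ex$op,
      "term" = return(term_value(ex$term, row)),
      "call" = {
        if (ex$fn == "BOUND") {
          t <- ex$args[[1]]$term
          return(t$name %in% names(row) && !is.na(row[[t$name]]))
        }
        vals <- lapply(ex$args, eval_expr, row = row)
        if (ex$fn == "STR") return(as.character(vals[[1]]))
        if (ex$fn == "STRSTARTS") {
          return(startsWith(as.character(vals[[1]]), as.character(vals[[2]])))
        }
      },
      "!" = return(!isTRUE(eval_expr(ex$left, row))),
      "&&" = return(isTRUE(eval_expr(ex$left, row)) && isTRUE(eval_expr(ex$right, row))),
      "||" = return(isTRUE(eval_expr(ex$left, row)) || isTRUE(eval_expr(ex$right, row))),
      {
        l <- eval_expr(ex$left, row)
        r <- eval_expr(ex$right, row)
        if (is.null(l) || is.null(r)) return(FALSE)
        if (is.numeric(l) && is.numeric(r)) {
          return(switch(ex$op, "=" = l == r, "!=" = l != r, "<" = l < r,
                        "<=" = l <= r, ">" = l > r, ">=" = l >= r))
        }
        l <- as.character(l); r <- as.character(r)
        return(switch(ex$op, "=" = l == r, "!=" = l != r, "<" = l < r,
                      "<=" = l <= r, ">" = l > r, ">=" = l >= r))
      }
    )
  }
  stop("malformed expression", call. = FALSE)
}

decode_column <- function(comp) {
  types <- dec_type(comp[!is.na(comp)])
  vals <- ifelse(is.na(comp), NA_character_, dec_value(comp))
  if (length(types) && all(types %in% c("decimal", "integer"))) {
    as.numeric(vals)
  } else if (length(types) && all(types == "boolean")) {
    vals == "true"
  } else {
    vals
  }
}

#' Run a SPARQL query against a store
#'
#' Supports the core of SPARQL 1.1 used by the toolkit's query patterns:
#' `PREFIX`, `SELECT [DISTINCT] ?vars|* WHERE`, `ASK`, basic graph patterns,
#' `FILTER` (comparisons, `&&`, `||`, `!`, `BOUND`, `STR`, `STRSTARTS`),
#' `OPTIONAL`, and transitive property paths `p*` / `p+` on fixed predicates.
#' The prefixes `rdf`, `rdfs`, `skos`, `xsd`, `os` and `oskg` are
#' pre-declared. Syntax outside the subset raises an error naming the
#' character position.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param query_text SPARQL query string.
#' @return for SELECT, a data frame with one column per projected variable
#'   (numeric where all bindings are numeric, `NA` for unbound optionals);
#'   for ASK, a logical scalar.
#' @examples
#' st <- kg_store()
#' kg_add_triples(st, data.frame(s = "urn:a", p = "urn:p", o = "urn:b",
#'                               type = "iri"))
#' sparql(st, "SELECT ?x WHERE { ?x <urn:p> <urn:b> }")
#' @export
sparql <- function(store, query_text) {
  df <- as_triples(store)
  st <- sp_state(sparql_tokenize(query_text))
  prefixes <- DEFAULT_SPARQL_PREFIXES()
  while (sp_is_kw(sp_peek(st), "PREFIX")) {
    sp_next(st)
    pn <- sp_expect(st, "pname")
    if (!grepl(":$", pn$text)) stop_sparql("expected 'prefix:'", pn$pos)
    ir <- sp_expect(st, "iri")
    prefixes[sub(":$", "", pn$text)] <- ir$text
  }
  head <- sp_peek(st)
  if (sp_is_kw(head, "ASK")) {
    sp_next(st)
    if (sp_is_kw(sp_peek(st), "WHERE")) sp_next(st)
    sol <- eval_group(df, parse_group(st, prefixes))
    return(nrow(sol) > 0L)
  }
  if (!sp_is_kw(head, "SELECT")) {
    stop_sparql("expected SELECT or ASK",
                if (is.null(head)) 1L else head$pos)
  }
  sp_next(st)
  distinct <- FALSE
  if (sp_is_kw(sp_peek(st), "DISTINCT")) { distinct <- TRUE; sp_next(st) }
  vars <- character()
  star <- FALSE
  repeat {
    t <- sp_peek(st)
    if (!is.null(t) && t$kind == "var") { vars <- c(vars, t$text); sp_next(st); next }
    if (!is.null(t) && t$kind == "op" && t$text == "*" && !length(vars)) {
      star <- TRUE; sp_next(st); next
    }
    break
  }
  if (!star && !length(vars)) {
    stop_sparql("SELECT needs variables or *", nchar_end(st))
  }
  if (sp_is_kw(sp_peek(st), "WHERE")) sp_next(st)
  sol <- eval_group(df, parse_group(st, prefixes))
  if (star) vars <- names(sol)
  out <- data.frame(row.names = seq_len(nrow(sol)))
  for (v in vars) {
    col <- if (v %in% names(sol)) sol[[v]] else rep(NA_character_, nrow(sol))
    out[[v]] <- decode_column(col)
  }
  rownames(out) <- NULL
  if (distinct) out <- unique(out)
  rownames(out) <- NULL
  out
}
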