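# Turtle serialisation.
#
# The writer emits one triple per line with absolute IRIs and typed literals;
# the reader accepts that profile plus @prefix declarations and prefixed
# names, which covers hand-written fixtures. Blank nodes, multi-line
# literals and [] syntax are not part of the profile.

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- ""
    j <- 1L
    while (j <= nchar(s)) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < nchar(s)) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- paste0(res, ch)
        j <- j + 1L
      }
    }
    out[i] <- res
  }
  out
}

XSD_OF_TYPE <- c(decimal = "decimal", integer = "integer",
                 dateTime = "dateTime", boolean = "boolean")

#' Write a graph to a Turtle file
#'
#' @param x a [kg_store()] or triple data frame.
#' @param path output file path or connection.
#' @return `path`, invisibly.
#' @export
kg_write_turtle <- function(x, path) {
  df <- as_triples(x)
  obj <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    obj[i] <- switch(df$type[i],
      iri = paste0("<", df$o[i], ">"),
      string = paste0("\"", escape_literal(df$o[i]), "\""),
      paste0("\"", escape_literal(df$o[i]), "\"^^<", XSD,
             XSD_OF_TYPE[[df$type[i]]], ">"))
  }
  writeLines(paste0("<", df$s, "> <", df$p, "> ", obj, " ."), con = path)
  invisible(path)
}

#' Read a Turtle file into a triple data frame
#'
#' Accepts the writer's line-oriented profile plus `@prefix` declarations and
#' prefixed names. Untyped numeric literals become decimals (integers when
#' they have no fraction), `true`/`false` become booleans.
#'
#' @param path input file path or connection.
#' @return a triple data frame; add it to a store with [kg_add_triples()].
#' @export
kg_read_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prefixes <- c(rdf = RDF, rdfs = RDFS, skos = SKOS, xsd = XSD, os = OS,
                oskg = kg_namespace())
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    pm <- regmatches(line, regexec(
      "^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*)?:\\s*<([^>]*)>\\s*\\.$", line))[[1]]
    if (length(pm)) {
      prefixes[pm[2]] <- pm[3]
      next
    }
    parsed <- tryCatch(parse_turtle_line(line, prefixes),
                       error = function(e) {
      stop(sprintf("turtle parse error at line %d: %s", ln, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[length(rows) + 1L]] <- parsed
  }
  if (!length(rows)) return(empty_triples())
  dedupe_triples(do.call(rbind, rows))
}

resolve_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
  if (tok == "a") return(paste0(RDF, "type"))
  m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*):([^ ]*)$", tok))[[1]]
  if (!length(m) || !(m[2] %in% names(prefixes))) {
    stop(sprintf("cannot resolve term %s", dQuote(tok)))
  }
  paste0(prefixes[[m[2]]], m[3])
}

parse_turtle_line <- function(line, prefixes) {
  if (!grepl("\\.$", line)) stop("missing terminating '.'")
  body <- trimws(sub("\\.$", "", line))
  # subject and predicate are whitespace-delimited non-literal terms
  sp <- regmatches(body, regexec("^(<[^>]*>|[A-Za-z][A-Za-z0-9_-]*:[^ ]*)\\s+(<[^>]*>|a|[A-Za-z][A-Za-z0-9_-]*:[^ ]*)\\s+(.*)$", body))[[1]]
  if (!length(sp)) stop("expected '<s> <p> o .'")
  s <- resolve_term(sp[2], prefixes)
  p <- resolve_term(sp[3], prefixes)
  orest <- trimws(sp[4])
  if (startsWith(orest, "\"")) {
    # find unescaped closing quote
    chars <- strsplit(orest, "")[[1]]
    close <- NA_integer_
    j <- 2L
    while (j <= length(chars)) {
      if (chars[j] == "\\") { j <- j + 2L; next }
      if (chars[j] == "\"") { close <- j; break }
      j <- j + 1L
    }
    if (is.na(close)) stop("unterminated literal")
    lex <- unescape_literal(substr(orest, 2L, close - 1L))
    tail <- trimws(substr(orest, close + 1L, nchar(orest)))
    if (!nzchar(tail)) return(triple(s, p, lex, "string"))
    dm <- regmatches(tail, regexec("^\\^\\^(<[^>]*>|[A-Za-z][A-Za-z0-9_-]*:[^ ]*)$", tail))[[1]]
    if (!length(dm)) stop(sprintf("unexpected text after literal: %s", tail))
    dt <- resolve_term(dm[2], prefixes)
    ty <- names(XSD_OF_TYPE)[match(local_name(dt), XSD_OF_TYPE)]
    if (is.na(ty)) ty <- "string"
    return(triple(s, p, lex, ty))
  }
  if (startsWith(orest, "<") || grepl("^[A-Za-z][A-Za-z0-9_-]*:", orest)) {
    return(triple(s, p, resolve_term(orest, prefixes), "iri"))
  }
  if (orest %in% c("true", "false")) return(triple(s, p, orest, "boolean"))
  if (grepl("^[+-]?[0-9]+$", orest)) return(triple(s, p, orest, "integer"))
  if (grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", orest)) {
    return(triple(s, p, orest, "decimal"))
  }
  stop(sprintf("cannot parse object %s", dQuote(orest)))
}
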