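# Free-text property-string parsing.
#
# Provider property strings arrive in many dialects: "134.4 °F at 760 mmHg
# (NTP, 1992)", "1,000,000 mg/L (at 25 °C)", "In water, miscible/1 × 10 + 6
# mg/L/at 25 °C.". The parser extracts numeric quantities with recognizable
# units, keeps "at ..."/"@ ..." clauses as measurement conditions, records
# inequality/approximation qualifiers, and discards everything without a
# numeric value (qualitative entries like "Miscible.").

NUM_RE <- "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"

new_parsed_quantity <- function(value, unit, qualifier = "none",
                                conditions = list(), source_string = "") {
  stopifnot(is.finite(value))
  structure(list(value = as.numeric(value), unit = unit,
                 qualifier = qualifier, conditions = conditions,
                 source_string = source_string),
            class = "parsed_quantity")
}

#' @export
print.parsed_quantity <- function(x, ...) {
  cond <- if (length(x$conditions)) {
    paste0(" @ ", paste(vapply(x$conditions, function(cn)
      sprintf("%g %s (%s)", cn$value, cn$unit, cn$quantity_kind),
      character(1)), collapse = ", "))
  } else ""
  q <- if (x$qualifier != "none") paste0(" [", x$qualifier, "]") else ""
  cat(sprintf("<parsed_quantity> %g %s%s%s\n", x$value, x$unit, q, cond))
  invisible(x)
}

# "1 × 10 + 6", "1 x 10+6", "2.5 × 10^-3" -> e-notation.
normalise_sci_notation <- function(s) {
  s <- gsub("−", "-", s)  # unicode minus
  gsub(paste0("(", NUM_RE, ")\\s*[×xX*]\\s*10\\s*\\^?\\s*([+-]?)\\s*([0-9]+)"),
       "\\1e\\2\\3", s, perl = TRUE)
}

strip_thousands <- function(s) {
  gsub("(?<=[0-9]),(?=[0-9]{3}(?![0-9]))", "", s, perl = TRUE)
}

detect_qualifier <- function(s) {
  ls <- tolower(s)
  if (grepl("greater than or equal to|>=|≥|\\bat least\\b|not less than", ls)) return("at_least")
  if (grepl("less than or equal to|<=|≤|\\bat most\\b|not more than", ls)) return("at_most")
  if (grepl("greater than|^\\s*>", ls)) return("at_least")
  if (grepl("less than|^\\s*<", ls)) return("at_most")
  if (grepl("~|\\bapprox|\\babout\\b|\\bca\\.", ls)) return("approx")
  "none"
}

# Try to read a unit immediately after a number. Candidates are built from up
# to two whitespace tokens ("mm Hg", "deg F") and, within a token, from
# prefixes split at "/" ("mg/L/at" -> "mg/L"). Longest candidate wins.
match_unit_after <- function(after_text) {
  lead <- regmatches(after_text,
                     regexpr("^[ °µA-Za-z][ °µA-Za-z0-9/^]*",
                             after_text))
  if (!length(lead)) return(NULL)
  toks <- strsplit(trimws(lead), "[[:space:]]+")[[1]]
  if (!length(toks)) return(NULL)
  cands <- character()
  for (k in seq_len(min(2L, length(toks)))) {
    joined <- paste(toks[seq_len(k)], collapse = " ")
    parts <- strsplit(joined, "/", fixed = TRUE)[[1]]
    for (j in rev(seq_along(parts))) {
      cands <- c(cands, paste(parts[seq_len(j)], collapse = "/"))
    }
  }
  cands <- unique(cands[nzchar(cands)])
  cands <- cands[order(-nchar(cands))]
  for (cand in cands) {
    cand <- sub("[. ]+$", "", cand)
    if (!is.null(lookup_unit(cand))) return(cand)
  }
  NULL
}

condition_kind_for <- function(unit_text) {
  u <- lookup_unit(unit_text)
  if (is.null(u)) return(NA_character_)
  switch(u$dimension, temperature = "temperature", pressure = "pressure",
         u$dimension)
}

#' Parse a free-text property string into quantities
#'
#' Extracts every numeric value followed by a recognizable unit. A quantity
#' preceded by `"at"` or `"@"` is a measurement condition (e.g. the 760 mmHg
#' in `"134.4 °F at 760 mmHg"`), attached to the measured quantities rather
#' than reported as a value. Trailing parenthetical citations contribute
#' nothing (their bare numbers have no unit). Scientific-notation dialects
#' (`1 × 10 + 6`, `1e6`, `1.0E+06`) and comma thousands separators are
#' handled; bare numbers without a recognizable unit are dropped.
#'
#' @param text one raw property string.
#' @return a list of `parsed_quantity` objects; empty when no numeric value
#'   with a unit is found (such records are discarded downstream).
#' @examples
#' parse_property_string("134.4 °F at 760 mmHg (NTP, 1992)")
#' parse_property_string("Miscible with many organic solvents.")
#' @export
parse_property_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  s <- strip_thousands(normalise_sci_notation(text))
  qualifier <- detect_qualifier(s)

  m <- gregexpr(NUM_RE, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")

  values <- list()
  conditions <- list()
  for (i in seq_along(starts)) {
    tok <- substr(s, starts[i], starts[i] + lens[i] - 1L)
    before <- substr(s, max(1L, starts[i] - 8L), starts[i] - 1L)
    after <- substr(s, starts[i] + lens[i], nchar(s))
    unit <- match_unit_after(sub("^[[:space:]]*", "", after))
    if (is.null(unit)) next
    is_condition <- grepl("(?i)(\\bat|@)[[:space:](]*$", before, perl = TRUE)
    val <- as.numeric(tok)
    if (!is.finite(val)) next
    if (is_condition) {
      conditions[[length(conditions) + 1L]] <-
        list(quantity_kind = condition_kind_for(unit), value = val, unit = unit)
    } else {
      values[[length(values) + 1L]] <- list(value = val, unit = unit, token = tok)
    }
  }
  lapply(values, function(v) {
    q <- new_parsed_quantity(v$value, v$unit, qualifier, conditions, text)
    attr(q, "numeric_token") <- v$token
    q
  })
}

chemkg_canonicalization_error <- function(msg) {
  structure(class = c("chemkg_canonicalization_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Rewrite a parsed quantity in the canonical unit of its property kind
#'
#' Temperatures go to kelvin, pressures to kPa, mass concentrations and
#' densities to kg/m^3, molar masses to g/mol. Conditions are converted
#' likewise. Idempotent. A quantity whose unit has the wrong dimension for
#' the kind (e.g. a pressure offered as a boiling point) raises a
#' `chemkg_canonicalization_error`; callers discard such records and log the
#' reason.
#'
#' @param q a `parsed_quantity` from [parse_property_string()].
#' @param kind property-kind label the quantity is claimed to measure.
#' @return the canonicalised `parsed_quantity`.
#' @examples
#' q <- parse_property_string("134.4 °F at 760 mmHg")[[1]]
#' to_canonical(q, "BoilingPoint")
#' @export
to_canonical <- function(q, kind) {
  stopifnot(inherits(q, "parsed_quantity"))
  expected_dim <- kind_dimension(kind)
  u <- lookup_unit(q$unit)
  if (is.null(u)) {
    stop(chemkg_canonicalization_error(
      sprintf("unknown unit %s for kind %s", dQuote(q$unit), kind)))
  }
  if (!is.na(expected_dim) && u$dimension != expected_dim) {
    stop(chemkg_canonicalization_error(
      sprintf("unit %s has dimension %s, but kind %s expects %s",
              dQuote(q$unit), u$dimension, kind, expected_dim)))
  }
  conv <- convert_to_canonical(q$value, q$unit)
  out <- q
  out$value <- conv$value
  out$unit <- conv$unit
  out$conditions <- lapply(q$conditions, function(cn) {
    cu <- lookup_unit(cn$unit)
    if (is.null(cu)) return(cn)
    cc <- convert_to_canonical(cn$value, cn$unit)
    list(quantity_kind = cn$quantity_kind, value = cc$value, unit = cc$unit)
  })
  out
}

#' Build a property record from a canonical quantity
#'
#' Carries the original string and acquisition date onto the record and lifts
#' pressure/temperature conditions into the reference state (pressure
#' preferred when both are present, as for boiling points). New records are
#' never recommended; the curation stage appends the recommended copy.
#'
#' @param q canonicalised `parsed_quantity` (see [to_canonical()]).
#' @param kind property-kind label.
#' @param next_index 1-based index to assign.
#' @param provenance a [provenance()].
#' @param timestamp acquisition time (`POSIXct` or ISO-8601 string), optional.
#' @return a [property_record()].
#' @export
build_property_record <- function(q, kind, next_index, provenance,
                                  timestamp = NULL) {
  stopifnot(inherits(q, "parsed_quantity"))
  ref <- NULL
  conds <- Filter(function(cn) cn$quantity_kind %in% c("pressure", "temperature"),
                  q$conditions)
  if (length(conds)) {
    is_p <- vapply(conds, function(cn) cn$quantity_kind == "pressure", logical(1))
    pick <- if (any(is_p)) conds[[which(is_p)[1]]] else conds[[1]]
    ref <- reference_state(pick$quantity_kind, pick$value, pick$unit)
  }
  property_record(kind = kind, index = next_index, value = q$value,
                  unit = q$unit, provenance = provenance,
                  original_string = q$source_string,
                  date_acquired = timestamp, ref_state = ref,
                  is_recommended = FALSE, qualifier = q$qualifier)
}

#' Format a value at printed display precision
#'
#' Truncates (toward zero) at `digits` decimals, the display convention used
#' for curated kelvin values (134.4 °F renders as 330.03888, not 330.03889).
#'
#' @param x numeric vector.
#' @param digits decimals to keep (default 5).
#' @return character vector.
#' @export
format_display <- function(x, digits = 5) {
  vapply(x, function(xi) {
    # round far below the truncation digit first so the binary representation
    # of decimal inputs (808.85 -> 808.8499999...) cannot flip the truncation
    full <- formatC(xi, format = "f", digits = digits + 4)
    cut <- sub(sprintf("^(-?[0-9]+\\.[0-9]{%d}).*$", digits), "\\1", full)
    cut <- sub("0+$", "", cut)
    sub("\\.$", "", cut)
  }, character(1))
}
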