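# Recommended-value selection and discrepancy detection.
#
# Multiple sources report the same property with unit-rounding scatter and the
# occasional far-off entry (often a typo in the original string). Curation
# groups approximately equal values, picks a preferred member of the largest
# group, stores it as a new record flagged recommended with agent provenance,
# and can flag entries deviating strongly from the recommended value.

rel_distance <- function(a, b) {
  lo <- pmin(abs(a), abs(b))
  d <- abs(a - b)
  ifelse(d == 0, 0, ifelse(lo == 0, Inf, d / lo))
}

#' Group approximately equivalent property values
#'
#' Single-linkage grouping: two records join the same group whenever a chain
#' of pairs with relative distance `|v_i - v_j| / min(|v_i|, |v_j|) <= rel_tol`
#' connects them. Groups partition the records and are reported in order of
#' their first member.
#'
#' @param records list of [property_record()]s, all of the same kind and in
#'   the canonical unit.
#' @param rel_tol relative tolerance in (0, 1).
#' @return a list of `value_group`s, each with `member_indices` (positions in
#'   `records`) and `center` (median of member values).
#' @examples
#' recs <- lapply(seq_along(c(100, 104, 250)), function(i)
#'   property_record("BoilingPoint", i, c(100, 104, 250)[i], "K",
#'                   provenance("src")))
#' group_equivalent(recs, 0.05)
#' @export
group_equivalent <- function(records, rel_tol) {
  stopifnot(is.list(records), length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "property_record")))
  stopifnot(is.numeric(rel_tol), length(rel_tol) == 1L,
            rel_tol > 0, rel_tol < 1)
  kinds <- vapply(records, `[[`, character(1), "kind")
  units <- vapply(records, `[[`, character(1), "unit")
  if (length(unique(kinds)) > 1L) stop("mixed property kinds", call. = FALSE)
  if (length(unique(units)) > 1L) stop("mixed units", call. = FALSE)
  v <- vapply(records, `[[`, numeric(1), "value")
  n <- length(v)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && rel_distance(v[i], v[j]) <= rel_tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- which(roots == r)
    structure(list(member_indices = members, center = stats::median(v[members])),
              class = "value_group")
  })
}

original_numeric_token <- function(rec) {
  if (is.null(rec$original_string)) return(NULL)
  s <- strip_thousands(normalise_sci_notation(rec$original_string))
  m <- regexpr(NUM_RE, s, perl = TRUE)
  if (m == -1L) return(NULL)
  regmatches(s, m)
}

decimal_places <- function(token) {
  if (is.null(token)) return(-1L)
  token <- sub("[eE].*$", "", token)
  if (!grepl("\\.", token)) return(0L)
  nchar(sub("^[^.]*\\.", "", token))
}

# Metric preference is judged on the unit spelling in the original string:
# the first registered alias found after the numeric token decides. Records
# without an original string count as metric (they are already canonical).
original_is_metric <- function(rec) {
  if (is.null(rec$original_string)) return(TRUE)
  s <- strip_thousands(normalise_sci_notation(rec$original_string))
  m <- regexpr(NUM_RE, s, perl = TRUE)
  if (m == -1L) return(TRUE)
  after <- substr(s, m + attr(m, "match.length"), nchar(s))
  unit <- match_unit_after(sub("^[[:space:]]*", "", after))
  if (is.null(unit)) return(TRUE)
  isTRUE(lookup_unit(unit)$metric)
}

#' Select the recommended value among property records
#'
#' Implements the curation policy: (1) group approximately equivalent values
#' ([group_equivalent()]); (2) the winning group is the largest, ties broken
#' by the group center closest to the global median; (3) within the winner,
#' prefer records whose original string used metric units over imperial ones;
#' (4) among those, prefer the original numeric token with the most decimal
#' places; (5) finally the lowest index wins. The result is a new record
#' (index continuing after the inputs) with `is_recommended = TRUE` and
#' provenance label `"PubChem agent"`; it carries no original string and no
#' reference state since it summarises a group.
#'
#' @param records list of [property_record()]s of one kind, canonical unit.
#' @param rel_tol grouping tolerance, default 0.10.
#' @return the recommended [property_record()]; attribute `"chosen_index"`
#'   gives the position of the member it copies.
#' @export
select_recommended <- function(records, rel_tol = 0.10) {
  if (!length(records)) stop("no records to select from", call. = FALSE)
  groups <- group_equivalent(records, rel_tol)
  v <- vapply(records, `[[`, numeric(1), "value")
  sizes <- vapply(groups, function(g) length(g$member_indices), integer(1))
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    gmed <- stats::median(v)
    centers <- vapply(groups[best], `[[`, numeric(1), "center")
    best <- best[order(abs(centers - gmed))][1]
  }
  members <- groups[[best[1]]]$member_indices

  metric <- vapply(records[members], original_is_metric, logical(1))
  if (any(metric)) members <- members[metric]
  dp <- vapply(records[members],
               function(r) decimal_places(original_numeric_token(r)), integer(1))
  members <- members[dp == max(dp)]
  chosen <- members[which.min(vapply(records[members], `[[`, integer(1), "index"))]

  src <- records[[chosen]]
  rec <- property_record(kind = src$kind,
                         index = max(vapply(records, `[[`, integer(1), "index")) + 1L,
                         value = src$value, unit = src$unit,
                         provenance = provenance("PubChem agent"),
                         is_recommended = TRUE)
  attr(rec, "chosen_index") <- chosen
  rec
}

#' Flag records discrepant from the recommended value
#'
#' A record is discrepant when its relative deviation from the recommended
#' value strictly exceeds `rel_threshold` (default 20%). The recommended
#' record itself is never flagged.
#'
#' @param records list of [property_record()]s.
#' @param recommended the recommended [property_record()]; its value must be
#'   positive.
#' @param rel_threshold relative deviation threshold, default 0.20.
#' @return the flagged subset of `records` (possibly empty), with attribute
#'   `"flagged_positions"` giving their positions in the input.
#' @export
flag_discrepant <- function(records, recommended, rel_threshold = 0.20) {
  stopifnot(inherits(recommended, "property_record"))
  if (recommended$value <= 0) {
    stop("recommended value must be positive", call. = FALSE)
  }
  v <- vapply(records, `[[`, numeric(1), "value")
  dev <- abs(v - recommended$value) / recommended$value
  is_rec <- vapply(records, function(r) {
    isTRUE(r$is_recommended) && r$index == recommended$index
  }, logical(1))
  sel <- which(dev > rel_threshold & !is_rec)
  out <- records[sel]
  attr(out, "flagged_positions") <- sel
  out
}

#' Write an audit report of discrepant records
#'
#' One tab-separated row per flagged record: species IRI, property kind,
#' canonical value (display precision), unit, provenance locator or label.
#'
#' @param species_iri species the records belong to.
#' @param flagged output of [flag_discrepant()].
#' @param file connection or path; `""` prints to stdout.
#' @return the report lines, invisibly.
#' @export
write_audit_report <- function(species_iri, flagged, file = "") {
  header <- paste("species_iri", "property_kind", "value", "unit", "provenance",
                  sep = "\t")
  rows <- vapply(flagged, function(r) {
    prov <- if (!is.null(r$provenance$locator)) r$provenance$locator else r$provenance$label
    paste(species_iri, r$kind, format_display(r$value), r$unit, prov, sep = "\t")
  }, character(1))
  lines <- c(header, rows)
  writeLines(lines, con = file)
  invisible(lines)
}
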