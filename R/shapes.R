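# Structural validation of emitted graphs.
#
# The shipped shape set (inst/extdata/shapes.ttl gives the declarative SHACL
# rendering) is enforced natively over the triple frame:
#   SpeciesLabelShape        a species has exactly one rdfs:label
#   SpeciesIdentifierShape   a species has at least one identifier
#   IdentifierValueShape     an identifier node has value and provenance
#   PropertyValueShape       a property node has value, unit and provenance
#   RecommendedAgentShape    a recommended property's provenance is labelled
#                            "PubChem agent"
#   BondOrderShape           bond order is a positive integer
#   PeakPositionShape        a peak has a position

#' Validate a graph against the shipped shape set
#'
#' @param graph a [kg_store()] or triple data frame.
#' @return a `validation_report`: list with `conforms` (logical) and
#'   `violations`, a data frame with columns `focus`, `shape`, `message`.
#'   `conforms` is `TRUE` exactly when `violations` is empty.
#' @export
validate_shapes <- function(graph) {
  df <- as_triples(graph)
  v <- list()
  bad <- function(focus, shape, message) {
    v[[length(v) + 1L]] <<- data.frame(focus = focus, shape = shape,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }

  type_p <- paste0(RDF, "type")
  species_nodes <- sel(df, p = type_p, o = os_iri("Species"))$s
  for (sn in species_nodes) {
    labels <- sel(df, s = sn, p = paste0(RDFS, "label"))$o
    if (length(labels) != 1L) {
      bad(sn, "SpeciesLabelShape",
          sprintf("species must have exactly one rdfs:label, found %d",
                  length(labels)))
    }
    if (!nrow(sel(df, s = sn, p = os_iri("hasIdentifier")))) {
      bad(sn, "SpeciesIdentifierShape", "species must have >= 1 identifier")
    }
  }

  id_nodes <- unique(sel(df, p = os_iri("hasIdentifier"))$o)
  for (idn in id_nodes) {
    for (need in c("value", "hasProvenance")) {
      if (!nrow(sel(df, s = idn, p = os_iri(need)))) {
        bad(idn, "IdentifierValueShape",
            sprintf("identifier node lacks os:%s", need))
      }
    }
  }

  prop_nodes <- unique(sel(df, p = os_iri("hasProperty"))$o)
  for (pn in prop_nodes) {
    for (need in c("value", "unit", "hasProvenance")) {
      if (!nrow(sel(df, s = pn, p = os_iri(need)))) {
        bad(pn, "PropertyValueShape",
            sprintf("property node lacks os:%s", need))
      }
    }
    if (identical(obj1(df, pn, os_iri("isRecommended")), "true")) {
      prov <- obj1(df, pn, os_iri("hasProvenance"))
      lbl <- if (is.null(prov)) NULL else obj1(df, prov, paste0(RDFS, "label"))
      if (!identical(lbl, "PubChem agent")) {
        bad(pn, "RecommendedAgentShape",
            "recommended property must carry provenance label \"PubChem agent\"")
      }
    }
  }

  orders <- sel(df, p = os_iri("hasBondOrder"))
  for (i in seq_len(nrow(orders))) {
    ok <- orders$type[i] == "integer" &&
      grepl("^[0-9]+$", orders$o[i]) && as.integer(orders$o[i]) >= 1L
    if (!ok) {
      bad(orders$s[i], "BondOrderShape",
          sprintf("bond order %s is not a positive integer", dQuote(orders$o[i])))
    }
  }

  peak_nodes <- sel(df, p = type_p, o = os_iri("Peak"))$s
  for (pk in peak_nodes) {
    if (!nrow(sel(df, s = pk, p = os_iri("peakPosition")))) {
      bad(pk, "PeakPositionShape", "peak lacks a position")
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(focus = character(), shape = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(conforms = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$conforms) {
    cat("<validation_report> conforms\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] %s: %s\n", x$violations$shape[i],
                  x$violations$focus[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

#' Path of the shipped SHACL shapes file
#'
#' The declarative rendering of the shape set enforced by
#' [validate_shapes()].
#'
#' @return file path inside the installed package.
#' @export
chemkg_shapes_file <- function() {
  system.file("extdata", "shapes.ttl", package = "chemkg", mustWork = TRUE)
}
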