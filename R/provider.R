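# Provider access.
#
# Providers hand the agent three payload kinds per species key: a computed
# record (identifiers and computed properties), an annotation record
# (experimental property strings, GHS codes, uses, synonyms, spectra) and a
# classification record (leaf class ids resolvable to label + parents). The
# interface below is deliberately thin so tests run from local fixtures;
# live HTTP adapters can implement the same four functions.

#' Construct a provider from in-memory fixture data
#'
#' @param computed named list: key -> computed payload document.
#' @param annotation named list: key -> annotation payload document.
#' @param species_classes named list: key -> character vector of leaf class
#'   ids.
#' @param classes named list: class id -> list(label, parents).
#' @param label provider label used for provenance.
#' @return a `chemkg_provider`: list of functions `computed(key)`,
#'   `annotation(key)`, `classification(key)`, `class_node(id)`.
#' @export
list_provider <- function(computed = list(), annotation = list(),
                          species_classes = list(), classes = list(),
                          label = "fixture provider") {
  force(computed); force(annotation); force(species_classes); force(classes)
  get_or_stop <- function(tbl, key, what) {
    if (!key %in% names(tbl)) {
      stop(sprintf("provider has no %s record for key %s", what, dQuote(key)),
           call. = FALSE)
    }
    tbl[[key]]
  }
  structure(list(
    label = label,
    computed = function(key) {
      list(source = "computed",
           document = get_or_stop(computed, key, "computed"),
           provenance = provenance(label = label,
                                   locator = paste0("fixture:computed/", key)))
    },
    annotation = function(key) {
      doc <- if (key %in% names(annotation)) annotation[[key]] else list()
      list(source = "annotation", document = doc,
           provenance = provenance(label = label,
                                   locator = paste0("fixture:annotation/", key)))
    },
    classification = function(key) {
      if (key %in% names(species_classes)) {
        as.character(species_classes[[key]])
      } else {
        character()
      }
    },
    class_node = function(id) {
      node <- get_or_stop(classes, id, "classification")
      list(id = id, label = node$label,
           parents = as.character(node$parents %||% character()))
    }
  ), class = "chemkg_provider")
}

#' Construct a provider reading fixture files from a directory
#'
#' The directory layout is the one [gen_species_library()] writes:
#' `computed.json`, `annotation.json`, `species_classes.json` and
#' `classes.json`, each a JSON object keyed by species key or class id.
#'
#' @param dir fixture directory.
#' @param label provider label used for provenance.
#' @return a `chemkg_provider` (see [list_provider()]).
#' @export
fixture_provider <- function(dir, label = "fixture provider") {
  read_json_if <- function(name) {
    path <- file.path(dir, name)
    if (file.exists(path)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      list()
    }
  }
  list_provider(computed = read_json_if("computed.json"),
                annotation = read_json_if("annotation.json"),
                species_classes = read_json_if("species_classes.json"),
                classes = read_json_if("classes.json"),
                label = label)
}

#' Map a computed payload to identifiers and computed properties
#'
#' Computed records arrive already structured (value plus unit); the mapper
#' turns the identifier block into [identifier_record()]s and each computed
#' property (molecular weight, charge) into a [property_record()], all with
#' the payload's provenance.
#'
#' @param payload a computed payload from a provider (`source = "computed"`).
#' @return list with `identifiers` (list of [identifier_record()]) and
#'   `properties` (list of [property_record()], indexed from 1 per kind).
#'   A payload without an identifier block is an error: the species could
#'   not be keyed.
#' @export
map_computed_payload <- function(payload) {
  stopifnot(identical(payload$source, "computed"))
  doc <- payload$document
  ids <- doc$identifiers
  if (is.null(ids) || !length(ids)) {
    stop("computed payload has no identifier block; species cannot be keyed",
         call. = FALSE)
  }
  prov <- payload$provenance
  identifiers <- lapply(names(ids), function(kind) {
    identifier_record(kind = kind, value = as.character(ids[[kind]]),
                      provenance = prov)
  })
  props <- list()
  for (kind in names(doc$properties %||% list())) {
    p <- doc$properties[[kind]]
    props[[length(props) + 1L]] <-
      property_record(kind = kind, index = 1L, value = as.numeric(p$value),
                      unit = as.character(p$unit), provenance = prov)
  }
  list(identifiers = identifiers, properties = props)
}

#' Map an annotation payload to raw strings, hazards, uses and spectra
#'
#' Experimental property strings are preserved verbatim for the parser, each
#' with its own per-string provenance (annotation records cite their original
#' source). Absent sections yield empty collections.
#'
#' @param payload an annotation payload (`source = "annotation"`).
#' @return list with `raw_strings` (list of `(kind, text, provenance)`),
#'   `ghs` (list of [ghs_statement()]), `uses` and `synonyms` (character),
#'   and `spectra` (list of [spectrum_record()], sequence-numbered in
#'   provider order).
#' @export
map_annotation_payload <- function(payload) {
  stopifnot(identical(payload$source, "annotation"))
  doc <- payload$document
  fallback_prov <- payload$provenance

  raw_strings <- lapply(doc$properties %||% list(), function(p) {
    prov <- if (!is.null(p$provenance)) {
      provenance(label = p$provenance$label %||% NULL,
                 locator = p$provenance$locator %||% NULL)
    } else {
      fallback_prov
    }
    list(kind = as.character(p$kind), text = as.character(p$string),
         provenance = prov)
  })

  ghs <- lapply(doc$ghs %||% list(), function(g) {
    ghs_statement(as.character(g$code), as.character(g$text %||% ""))
  })

  spectra <- list()
  specs <- doc$spectra %||% list()
  for (i in seq_along(specs)) {
    sdoc <- specs[[i]]
    peaks <- lapply(sdoc$peaks %||% list(), function(pk) {
      peak(position = as.numeric(pk$position),
           intensity = as.numeric(pk$intensity %||% 1),
           multiplicity = pk$multiplicity %||% NULL)
    })
    spectra[[i]] <- spectrum_record(
      kind = as.character(sdoc$kind %||% "NMR1D"), peaks = peaks,
      sequence_number = i,
      solvent = sdoc$solvent %||% NULL,
      frequency = if (!is.null(sdoc$frequency)) as.numeric(sdoc$frequency) else NULL,
      ionization_mode = sdoc$ionization_mode %||% NULL)
  }

  list(raw_strings = raw_strings, ghs = ghs,
       uses = as.character(unlist(doc$uses %||% character())),
       synonyms = as.character(unlist(doc$synonyms %||% character())),
       spectra = spectra)
}
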