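# Embedded triple store.
#
# Triples live in a data frame with columns s (subject IRI), p (predicate
# IRI), o (object lexical form) and type, one of "iri", "string", "decimal",
# "integer", "dateTime", "boolean". A store is an environment wrapping such a
# frame with set semantics.

TRIPLE_TYPES <- c("iri", "string", "decimal", "integer", "dateTime", "boolean")

empty_triples <- function() {
  data.frame(s = character(), p = character(), o = character(),
             type = character(), stringsAsFactors = FALSE)
}

triple <- function(s, p, o, type) {
  stopifnot(type %in% TRIPLE_TYPES)
  data.frame(s = s, p = p, o = o, type = type, stringsAsFactors = FALSE)
}

lex_decimal <- function(x) sprintf("%.17g", x)
lex_integer <- function(x) sprintf("%d", as.integer(x))
lex_boolean <- function(x) if (isTRUE(x)) "true" else "false"

triple_key <- function(df) paste(df$s, df$p, df$o, df$type, sep = "\r")

dedupe_triples <- function(df) {
  df[!duplicated(triple_key(df)), , drop = FALSE]
}

#' Create an empty in-memory triple store
#'
#' @return a `kg_store` object.
#' @export
kg_store <- function() {
  e <- new.env(parent = emptyenv())
  e$triples <- empty_triples()
  class(e) <- "kg_store"
  e
}

#' @export
print.kg_store <- function(x, ...) {
  cat(sprintf("<kg_store> %d triples\n", nrow(x$triples)))
  invisible(x)
}

as_triples <- function(x) {
  if (inherits(x, "kg_store")) x$triples
  else if (is.data.frame(x)) x
  else stop("expected a kg_store or a triple data frame", call. = FALSE)
}

#' Add triples to a store
#'
#' Set semantics: re-adding an existing triple leaves the store unchanged.
#'
#' @param store a [kg_store()].
#' @param triples a triple data frame (e.g. from [emit_species_triples()]).
#' @return the store, invisibly.
#' @export
kg_add_triples <- function(store, triples) {
  stopifnot(inherits(store, "kg_store"))
  store$triples <- dedupe_triples(rbind(store$triples, as_triples(triples)))
  rownames(store$triples) <- NULL
  invisible(store)
}

#' Number of triples in a store or graph
#'
#' @param x a [kg_store()] or triple data frame.
#' @return integer count.
#' @export
kg_size <- function(x) nrow(as_triples(x))

sel <- function(df, s = NULL, p = NULL, o = NULL, type = NULL) {
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$s %in% s
  if (!is.null(p)) keep <- keep & df$p %in% p
  if (!is.null(o)) keep <- keep & df$o %in% o
  if (!is.null(type)) keep <- keep & df$type %in% type
  df[keep, , drop = FALSE]
}

obj1 <- function(df, s, p) {
  hit <- sel(df, s = s, p = p)
  if (!nrow(hit)) NULL else hit$o[1]
}

local_name <- function(iri) sub("^.*[#/]", "", iri)

# 1-based index encoded in an attached-instance IRI <Class>_<i>_Species_<uuid>
attached_index <- function(iri) {
  as.integer(sub("^.*_([0-9]+)_Species_.*$", "\\1", iri))
}

SPECTRUM_CLASS <- c(NMR1D = "1DNMRSpectra", NMR2D = "2DNMRSpectra",
                    MS = "MassSpectrometry")

#' Emit the RDF triples of a species
#'
#' Materialises every fact of a [species()] using the TBox vocabulary: the
#' molecular-formula label (`rdfs:label`), synonyms (`skos:altLabel`), atoms,
#' bonds, identifiers, property records (value, unit, provenance, original
#' string, acquisition date, reference state, recommended flag), chemical
#' classes with parent links, GHS statements, uses and spectra with their
#' peaks. Instance IRIs follow the minting conventions of
#' [mint_attached_iri()] / [mint_free_iri()], so emission is deterministic.
#'
#' @param sp a [species()].
#' @return a triple data frame.
#' @export
emit_species_triples <- function(sp) {
  stopifnot(inherits(sp, "species"))
  if (!identical(sp$label, render_formula(sp$formula))) {
    stop("species label must equal the Hill rendering of its formula",
         call. = FALSE)
  }
  u <- sp$uuid
  siri <- mint_species_iri(u)
  out <- list(
    triple(siri, paste0(RDF, "type"), os_iri("Species"), "iri"),
    triple(siri, paste0(RDFS, "label"), sp$label, "string")
  )
  add <- function(...) out[[length(out) + 1L]] <<- triple(...)

  for (al in sp$alt_labels) add(siri, paste0(SKOS, "altLabel"), al, "string")

  # provenance nodes, deduplicated by content within this species
  prov_seen <- character()
  prov_iri <- function(pv) {
    key <- paste(pv$label %||% "", pv$locator %||% "", sep = "\r")
    hit <- match(key, prov_seen)
    if (!is.na(hit)) return(mint_free_iri("Reference", paste0(u, "-ref", hit)))
    prov_seen <<- c(prov_seen, key)
    iri <- mint_free_iri("Reference", paste0(u, "-ref", length(prov_seen)))
    add(iri, paste0(RDF, "type"), os_iri("Reference"), "iri")
    if (!is.null(pv$label)) add(iri, paste0(RDFS, "label"), pv$label, "string")
    if (!is.null(pv$locator)) add(iri, os_iri("url"), pv$locator, "string")
    iri
  }

  for (a in sp$atoms) {
    airi <- mint_attached_iri("Atom", a$index, u)
    add(siri, os_iri("hasAtom"), airi, "iri")
    add(airi, paste0(RDF, "type"), os_iri("Atom"), "iri")
    add(airi, os_iri("index"), lex_integer(a$index), "integer")
    add(airi, os_iri("isElement"), a$element, "string")
    if (!is.null(a$x)) add(airi, os_iri("hasXCoordinate"), lex_decimal(a$x), "decimal")
    if (!is.null(a$y)) add(airi, os_iri("hasYCoordinate"), lex_decimal(a$y), "decimal")
    if (!is.null(a$z)) add(airi, os_iri("hasZCoordinate"), lex_decimal(a$z), "decimal")
  }

  for (i in seq_along(sp$bonds)) {
    b <- sp$bonds[[i]]
    biri <- mint_attached_iri("AtomicBond", i, u)
    add(siri, os_iri("hasAtomicBond"), biri, "iri")
    add(biri, paste0(RDF, "type"), os_iri("AtomicBond"), "iri")
    add(biri, os_iri("definedBy"), mint_attached_iri("Atom", b$atom_a, u), "iri")
    add(biri, os_iri("definedBy"), mint_attached_iri("Atom", b$atom_b, u), "iri")
    add(biri, os_iri("hasBondOrder"), lex_integer(b$order), "integer")
  }

  id_counts <- integer()
  for (idr in sp$identifiers) {
    k <- idr$kind
    id_counts[k] <- (if (is.na(id_counts[k])) 0L else id_counts[k]) + 1L
    iiri <- mint_attached_iri(k, id_counts[[k]], u)
    add(siri, os_iri("hasIdentifier"), iiri, "iri")
    add(iiri, paste0(RDF, "type"), os_iri(k), "iri")
    add(iiri, os_iri("value"), idr$value, "string")
    add(iiri, os_iri("hasProvenance"), prov_iri(idr$provenance), "iri")
  }

  for (pr in sp$properties) {
    piri <- mint_attached_iri(pr$kind, pr$index, u)
    add(siri, os_iri("hasProperty"), piri, "iri")
    add(piri, paste0(RDF, "type"), os_iri(pr$kind), "iri")
    add(piri, os_iri("value"), lex_decimal(pr$value), "decimal")
    add(piri, os_iri("unit"), pr$unit, "string")
    add(piri, os_iri("hasProvenance"), prov_iri(pr$provenance), "iri")
    add(piri, os_iri("isRecommended"), lex_boolean(pr$is_recommended), "boolean")
    if (!is.null(pr$original_string)) {
      add(piri, os_iri("originalDataString"), pr$original_string, "string")
    }
    if (!is.null(pr$date_acquired)) {
      add(piri, os_iri("dateAcquired"), pr$date_acquired, "dateTime")
    }
    if (pr$qualifier != "none") {
      add(piri, os_iri("qualifier"), pr$qualifier, "string")
    }
    if (!is.null(pr$ref_state)) {
      riri <- mint_free_iri("ReferenceState", paste0(u, "-", pr$kind, "-", pr$index))
      add(piri, os_iri("hasReferenceState"), riri, "iri")
      add(riri, paste0(RDF, "type"), os_iri("ReferenceState"), "iri")
      add(riri, os_iri("refQuantityKind"), pr$ref_state$quantity_kind, "string")
      add(riri, os_iri("value"), lex_decimal(pr$ref_state$value), "decimal")
      add(riri, os_iri("unit"), pr$ref_state$unit, "string")
    }
  }

  for (cl in sp$classes) {
    add(siri, os_iri("hasChemicalClass"), cl$iri, "iri")
    out[[length(out) + 1L]] <- emit_class_triples(cl)
  }

  for (i in seq_along(sp$ghs)) {
    g <- sp$ghs[[i]]
    giri <- mint_attached_iri("GHSHazardStatement", i, u)
    add(siri, os_iri("hasGHSHazardStatement"), giri, "iri")
    add(giri, paste0(RDF, "type"), os_iri("GHSHazardStatement"), "iri")
    add(giri, os_iri("code"), g$code, "string")
    if (nzchar(g$text)) add(giri, os_iri("statement"), g$text, "string")
  }

  for (i in seq_along(sp$uses)) {
    uiri <- mint_free_iri("Use", paste0(u, "-use", i))
    add(siri, os_iri("hasUse"), uiri, "iri")
    add(uiri, paste0(RDF, "type"), os_iri("Use"), "iri")
    add(uiri, paste0(RDFS, "label"), sp$uses[i], "string")
  }

  for (spec in sp$spectra) {
    cls <- SPECTRUM_CLASS[[spec$kind]]
    xiri <- mint_attached_iri(cls, spec$sequence_number, u)
    add(siri, os_iri("hasSpectralInformation"), xiri, "iri")
    add(xiri, paste0(RDF, "type"), os_iri(cls), "iri")
    add(xiri, os_iri("sequenceNumber"), lex_integer(spec$sequence_number), "integer")
    if (!is.null(spec$solvent)) add(xiri, os_iri("hasSolvent"), spec$solvent, "string")
    if (!is.null(spec$frequency)) {
      add(xiri, os_iri("hasFrequency"), lex_decimal(spec$frequency), "decimal")
    }
    if (!is.null(spec$ionization_mode)) {
      add(xiri, os_iri("hasIonizationMode"), spec$ionization_mode, "string")
    }
    for (j in seq_along(spec$peaks)) {
      pk <- spec$peaks[[j]]
      kiri <- mint_free_iri("Peak", paste0(u, "-s", spec$sequence_number, "-", j))
      add(xiri, os_iri("hasPeak"), kiri, "iri")
      add(kiri, paste0(RDF, "type"), os_iri("Peak"), "iri")
      add(kiri, os_iri("peakIndex"), lex_integer(j), "integer")
      add(kiri, os_iri("peakPosition"), lex_decimal(pk$position), "decimal")
      add(kiri, os_iri("peakIntensity"), lex_decimal(pk$intensity), "decimal")
      if (!is.null(pk$multiplicity)) {
        add(kiri, os_iri("hasMultiplicity"), pk$multiplicity, "string")
      }
    }
  }

  dedupe_triples(do.call(rbind, out))
}

emit_class_triples <- function(cl) {
  out <- list(
    triple(cl$iri, paste0(RDF, "type"), os_iri("ChemicalClass"), "iri"),
    triple(cl$iri, paste0(RDFS, "label"), cl$label, "string")
  )
  for (p in cl$parents) {
    out[[length(out) + 1L]] <- triple(cl$iri, os_iri("hasParentClass"), p, "iri")
  }
  if (!is.null(cl$source_id)) {
    out[[length(out) + 1L]] <- triple(cl$iri, os_iri("sourceId"), cl$source_id, "string")
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_provenance <- function(df, iri) {
  provenance(label = obj1(df, iri, paste0(RDFS, "label")),
             locator = obj1(df, iri, os_iri("url")))
}

#' Load a species back from a graph
#'
#' Inverse of [emit_species_triples()]: reconstructs the [species()] whose
#' subgraph is rooted at `species_iri`. Round-trips structurally:
#' `load_species(emit_species_triples(s), iri)` equals `s` for every valid
#' species.
#'
#' @param graph a [kg_store()] or triple data frame.
#' @param species_iri IRI of the species to load.
#' @return a [species()].
#' @export
load_species <- function(graph, species_iri) {
  df <- as_triples(graph)
  label <- obj1(df, species_iri, paste0(RDFS, "label"))
  if (is.null(label)) {
    stop(sprintf("species %s has no rdfs:label in this graph", species_iri),
         call. = FALSE)
  }
  uuid <- sub("^.*Species_", "", species_iri)

  atom_iris <- sel(df, s = species_iri, p = os_iri("hasAtom"))$o
  atoms <- lapply(atom_iris, function(ai) {
    atom(index = as.integer(obj1(df, ai, os_iri("index"))),
         element = obj1(df, ai, os_iri("isElement")),
         x = num_or_null(obj1(df, ai, os_iri("hasXCoordinate"))),
         y = num_or_null(obj1(df, ai, os_iri("hasYCoordinate"))),
         z = num_or_null(obj1(df, ai, os_iri("hasZCoordinate"))))
  })
  atom_index_of <- function(airi) as.integer(obj1(df, airi, os_iri("index")))

  bond_iris <- sel(df, s = species_iri, p = os_iri("hasAtomicBond"))$o
  bonds <- lapply(bond_iris, function(bi) {
    ends <- sel(df, s = bi, p = os_iri("definedBy"))$o
    idx <- vapply(ends, atom_index_of, integer(1))
    atomic_bond(idx[1], idx[2],
                as.integer(obj1(df, bi, os_iri("hasBondOrder"))))
  })

  id_iris <- sel(df, s = species_iri, p = os_iri("hasIdentifier"))$o
  if (length(id_iris)) {
    id_iris <- id_iris[order(local_name_kind(df, id_iris), attached_index(id_iris))]
  }
  identifiers <- lapply(id_iris, function(ii) {
    identifier_record(kind = local_name(obj1(df, ii, paste0(RDF, "type"))),
                      value = obj1(df, ii, os_iri("value")),
                      provenance = load_provenance(df, obj1(df, ii, os_iri("hasProvenance"))))
  })

  prop_iris <- sel(df, s = species_iri, p = os_iri("hasProperty"))$o
  if (length(prop_iris)) {
    prop_iris <- prop_iris[order(local_name_kind(df, prop_iris),
                                 attached_index(prop_iris))]
  }
  properties <- lapply(prop_iris, function(pi) {
    ref <- NULL
    riri <- obj1(df, pi, os_iri("hasReferenceState"))
    if (!is.null(riri)) {
      ref <- reference_state(obj1(df, riri, os_iri("refQuantityKind")),
                             as.numeric(obj1(df, riri, os_iri("value"))),
                             obj1(df, riri, os_iri("unit")))
    }
    property_record(kind = local_name(obj1(df, pi, paste0(RDF, "type"))),
                    index = attached_index(pi),
                    value = as.numeric(obj1(df, pi, os_iri("value"))),
                    unit = obj1(df, pi, os_iri("unit")),
                    provenance = load_provenance(df, obj1(df, pi, os_iri("hasProvenance"))),
                    original_string = obj1(df, pi, os_iri("originalDataString")),
                    date_acquired = obj1(df, pi, os_iri("dateAcquired")),
                    ref_state = ref,
                    is_recommended = identical(obj1(df, pi, os_iri("isRecommended")), "true"),
                    qualifier = obj1(df, pi, os_iri("qualifier")) %||% "none")
  })

  class_iris <- sel(df, s = species_iri, p = os_iri("hasChemicalClass"))$o
  classes <- lapply(sort(class_iris), function(ci) load_class(df, ci))

  ghs_iris <- sel(df, s = species_iri, p = os_iri("hasGHSHazardStatement"))$o
  if (length(ghs_iris)) ghs_iris <- ghs_iris[order(attached_index(ghs_iris))]
  ghs <- lapply(ghs_iris, function(gi) {
    ghs_statement(obj1(df, gi, os_iri("code")),
                  obj1(df, gi, os_iri("statement")) %||% "")
  })

  use_iris <- sel(df, s = species_iri, p = os_iri("hasUse"))$o
  if (length(use_iris)) {
    use_iris <- use_iris[order(as.integer(sub("^.*-use([0-9]+)$", "\\1", use_iris)))]
  }
  uses <- vapply(use_iris, function(ui) obj1(df, ui, paste0(RDFS, "label")),
                 character(1))

  spec_iris <- sel(df, s = species_iri, p = os_iri("hasSpectralInformation"))$o
  spectra <- lapply(spec_iris, function(xi) {
    cls <- local_name(obj1(df, xi, paste0(RDF, "type")))
    kind <- names(SPECTRUM_CLASS)[match(cls, SPECTRUM_CLASS)]
    peak_iris <- sel(df, s = xi, p = os_iri("hasPeak"))$o
    ord <- order(vapply(peak_iris, function(ki)
      as.integer(obj1(df, ki, os_iri("peakIndex"))), integer(1)))
    peaks <- lapply(peak_iris[ord], function(ki) {
      peak(position = as.numeric(obj1(df, ki, os_iri("peakPosition"))),
           intensity = as.numeric(obj1(df, ki, os_iri("peakIntensity"))),
           multiplicity = obj1(df, ki, os_iri("hasMultiplicity")))
    })
    spectrum_record(kind = kind, peaks = peaks,
                    sequence_number = as.integer(obj1(df, xi, os_iri("sequenceNumber"))),
                    solvent = obj1(df, xi, os_iri("hasSolvent")),
                    frequency = num_or_null(obj1(df, xi, os_iri("hasFrequency"))),
                    ionization_mode = obj1(df, xi, os_iri("hasIonizationMode")))
  })

  species(uuid = uuid, formula = parse_formula(label),
          alt_labels = sort(sel(df, s = species_iri, p = paste0(SKOS, "altLabel"))$o),
          atoms = atoms, bonds = bonds, identifiers = identifiers,
          properties = properties, classes = classes, ghs = ghs,
          uses = unname(uses), spectra = spectra)
}

load_class <- function(df, class_iri) {
  chemical_class(iri = class_iri,
                 label = obj1(df, class_iri, paste0(RDFS, "label")) %||% local_name(class_iri),
                 parents = sel(df, s = class_iri, p = os_iri("hasParentClass"))$o,
                 source_id = obj1(df, class_iri, os_iri("sourceId")))
}

local_name_kind <- function(df, iris) {
  vapply(iris, function(i) {
    ty <- obj1(df, i, paste0(RDF, "type"))
    if (is.null(ty)) "" else local_name(ty)
  }, character(1))
}

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Assert a class membership on a species
#'
#' Idempotent SPARQL-update-style assertion linking an existing species to an
#' existing chemical-class node.
#'
#' @param store a [kg_store()].
#' @param species_iri,class_iri IRIs already present in the store.
#' @return the store, invisibly.
#' @export
add_class_assertion <- function(store, species_iri, class_iri) {
  df <- as_triples(store)
  if (!nrow(sel(df, s = species_iri))) {
    stop(sprintf("unknown species IRI %s", species_iri), call. = FALSE)
  }
  if (!nrow(sel(df, s = class_iri)) && !any(df$o == class_iri & df$type == "iri")) {
    stop(sprintf("unknown class IRI %s", class_iri), call. = FALSE)
  }
  kg_add_triples(store, triple(species_iri, os_iri("hasChemicalClass"),
                               class_iri, "iri"))
}
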