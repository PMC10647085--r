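# Species ingestion: provider payloads -> Species -> validated triples.

class_iri_for_source_id <- function(source_id) {
  mint_free_iri("ChemicalClass", gsub("[^A-Za-z0-9-]", "-", source_id))
}

# Resolve a leaf class and all its ancestors through the provider without
# touching the store. Returns a named list id -> list(id, label, parents).
# Cycles in the provider hierarchy are an error naming the cycle.
resolve_hierarchy <- function(provider, leaf_id) {
  resolved <- list()
  visit <- function(id, path) {
    if (id %in% path) {
      stop(sprintf("classification cycle detected: %s",
                   paste(c(path[which(path == id):length(path)], id),
                         collapse = " -> ")), call. = FALSE)
    }
    if (id %in% names(resolved)) return(invisible())
    node <- provider$class_node(id)
    resolved[[id]] <<- node
    for (p in node$parents) visit(p, c(path, id))
    invisible()
  }
  visit(leaf_id, character())
  resolved
}

#' Import a classification hierarchy into the store
#'
#' Instantiates the leaf class and, recursively, every ancestor up to the
#' root, linking each class to its parents. Classes already present in the
#' store are not duplicated; repeating the call leaves the store unchanged.
#' The provider resolves `class id -> (label, parent ids)`; cycles are an
#' error naming the cycle, unknown ids are an error.
#'
#' @param provider a `chemkg_provider` (see [list_provider()]).
#' @param leaf_class_id provider id of the most specific class.
#' @param store a [kg_store()].
#' @return list of [chemical_class()] objects newly instantiated by this
#'   call (empty when everything was already present).
#' @export
import_classification_hierarchy <- function(provider, leaf_class_id, store) {
  nodes <- resolve_hierarchy(provider, leaf_class_id)
  df <- as_triples(store)
  added <- list()
  triples <- list()
  for (node in nodes) {
    iri <- class_iri_for_source_id(node$id)
    present <- nrow(sel(df, s = iri, p = paste0(RDF, "type"),
                        o = os_iri("ChemicalClass"))) > 0L
    if (present) next
    cl <- chemical_class(iri = iri, label = node$label,
                         parents = vapply(node$parents, class_iri_for_source_id,
                                          character(1), USE.NAMES = FALSE),
                         source_id = node$id)
    added[[length(added) + 1L]] <- cl
    triples[[length(triples) + 1L]] <- emit_class_triples(cl)
  }
  if (length(triples)) kg_add_triples(store, do.call(rbind, triples))
  added
}

key_identifier_kind <- function(key) {
  if (startsWith(key, "InChI=")) "InChI" else "SMILES"
}

find_species_by_identifier <- function(df, key) {
  id_nodes <- sel(df, p = os_iri("value"), o = key, type = "string")$s
  if (!length(id_nodes)) return(NULL)
  kinds <- local_name_kind(df, id_nodes)
  id_nodes <- id_nodes[kinds %in% c("InChI", "SMILES")]
  if (!length(id_nodes)) return(NULL)
  owners <- sel(df, p = os_iri("hasIdentifier"), o = id_nodes)$s
  if (!length(owners)) NULL else owners[1]
}

with_retries <- function(fn, max_retries) {
  attempt <- 0L
  repeat {
    out <- tryCatch(fn(), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    attempt <- attempt + 1L
    if (attempt > max_retries) {
      stop(sprintf("provider failure after %d attempt(s): %s", attempt,
                   conditionMessage(out)), call. = FALSE)
    }
  }
}

#' Ingest one species from provider payloads into the store
#'
#' The agent workflow: if a species carrying the key as InChI/SMILES
#' identifier already exists, its IRI is returned and the store is untouched.
#' Otherwise the provider payloads are mapped, every experimental property
#' string is parsed and canonicalised (strings without a numeric value, and
#' quantities whose unit does not fit the property's dimension, are discarded
#' with a logged reason), a recommended record is selected per property kind,
#' the classification hierarchy is resolved, the species triples are emitted
#' and shape-validated, and only then committed in one step. Any provider
#' failure (after bounded retries) or shape violation aborts with the store
#' in its pre-call state.
#'
#' @param key InChI (starting `"InChI="`) or SMILES string.
#' @param provider a `chemkg_provider`.
#' @param store a [kg_store()].
#' @param rel_tol grouping tolerance for recommended-value selection.
#' @param clock zero-argument function returning the acquisition timestamp
#'   (injectable for reproducible tests).
#' @param max_retries provider retry budget per call.
#' @return the species IRI. Attribute `"discarded"` is a data frame logging
#'   every discarded property string (kind, text, reason); attribute
#'   `"created"` says whether a new species was instantiated.
#' @export
ingest_species <- function(key, provider, store, rel_tol = 0.10,
                           clock = Sys.time, max_retries = 2L) {
  if (!is.character(key) || length(key) != 1L || is.na(key) || !nzchar(key)) {
    stop("species key must be a non-empty InChI or SMILES string", call. = FALSE)
  }
  stopifnot(inherits(provider, "chemkg_provider"), inherits(store, "kg_store"))

  existing <- find_species_by_identifier(as_triples(store), key)
  if (!is.null(existing)) {
    return(structure(existing, created = FALSE,
                     discarded = empty_discard_log()))
  }

  computed <- with_retries(function() provider$computed(key), max_retries)
  annotation <- with_retries(function() provider$annotation(key), max_retries)
  leaf_ids <- with_retries(function() provider$classification(key), max_retries)
  hierarchies <- lapply(leaf_ids, function(id) {
    with_retries(function() resolve_hierarchy(provider, id), max_retries)
  })

  mapped_c <- map_computed_payload(computed)
  mapped_a <- map_annotation_payload(annotation)

  id_values <- vapply(mapped_c$identifiers, `[[`, character(1), "value")
  id_kinds <- vapply(mapped_c$identifiers, `[[`, character(1), "kind")
  identifiers <- mapped_c$identifiers
  if (!key %in% id_values) {
    identifiers <- c(identifiers,
                     list(identifier_record(key_identifier_kind(key), key,
                                            computed$provenance)))
  }
  formula_text <- id_values[match("MolecularFormulaText", id_kinds)]
  if (is.na(formula_text)) {
    stop("computed payload lacks a molecular formula; species cannot be labelled",
         call. = FALSE)
  }

  timestamp <- clock()
  discards <- list()
  note_discard <- function(kind, text, reason) {
    discards[[length(discards) + 1L]] <<- data.frame(
      kind = kind, text = text, reason = reason, stringsAsFactors = FALSE)
  }

  by_kind <- list()
  for (pr in mapped_c$properties) {
    by_kind[[pr$kind]] <- c(by_kind[[pr$kind]], list(pr))
  }
  for (raw in mapped_a$raw_strings) {
    qs <- parse_property_string(raw$text)
    if (!length(qs)) {
      note_discard(raw$kind, raw$text, "no numeric value detected")
      next
    }
    for (q in qs) {
      cq <- tryCatch(to_canonical(q, raw$kind), error = function(e) e)
      if (inherits(cq, "error")) {
        note_discard(raw$kind, raw$text, conditionMessage(cq))
        next
      }
      rec <- build_property_record(cq, raw$kind,
                                   next_index = length(by_kind[[raw$kind]]) + 1L,
                                   provenance = raw$provenance,
                                   timestamp = timestamp)
      by_kind[[raw$kind]] <- c(by_kind[[raw$kind]], list(rec))
    }
  }
  properties <- list()
  for (kind in names(by_kind)) {
    recs <- by_kind[[kind]]
    recs <- c(recs, list(select_recommended(recs, rel_tol = rel_tol)))
    properties <- c(properties, recs)
  }

  leaf_classes <- lapply(leaf_ids, function(id) {
    node <- provider$class_node(id)
    chemical_class(iri = class_iri_for_source_id(id), label = node$label,
                   parents = vapply(node$parents, class_iri_for_source_id,
                                    character(1), USE.NAMES = FALSE),
                   source_id = id)
  })

  atoms <- lapply(computed$document$atoms %||% list(), function(a) {
    atom(index = as.integer(a$index), element = as.character(a$element),
         x = a$x %||% NULL, y = a$y %||% NULL, z = a$z %||% NULL)
  })
  bonds <- lapply(computed$document$bonds %||% list(), function(b) {
    atomic_bond(as.integer(b$atom_a), as.integer(b$atom_b),
                as.integer(b$order %||% 1L))
  })

  sp <- species(uuid = chemkg_uuid(), formula = parse_formula(formula_text),
                alt_labels = mapped_a$synonyms,
                atoms = atoms, bonds = bonds,
                identifiers = identifiers, properties = properties,
                classes = leaf_classes, ghs = mapped_a$ghs,
                uses = mapped_a$uses, spectra = mapped_a$spectra)

  triples <- emit_species_triples(sp)
  for (h in hierarchies) {
    for (node in h) {
      cl <- chemical_class(iri = class_iri_for_source_id(node$id),
                           label = node$label,
                           parents = vapply(node$parents, class_iri_for_source_id,
                                            character(1), USE.NAMES = FALSE),
                           source_id = node$id)
      triples <- rbind(triples, emit_class_triples(cl))
    }
  }
  triples <- dedupe_triples(triples)

  report <- validate_shapes(triples)
  if (!report$conforms) {
    stop(sprintf("shape validation failed; ingestion aborted (%d violation(s), first: %s)",
                 nrow(report$violations), report$violations$message[1]),
         call. = FALSE)
  }
  kg_add_triples(store, triples)

  log <- if (length(discards)) do.call(rbind, discards) else empty_discard_log()
  structure(mint_species_iri(sp$uuid), created = TRUE, discarded = log)
}

empty_discard_log <- function() {
  data.frame(kind = character(), text = character(), reason = character(),
             stringsAsFactors = FALSE)
}
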