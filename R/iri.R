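# Vocabulary namespaces. The instance (ABox) namespace is configurable via
# option "chemkg.namespace"; the TBox vocabulary namespace is fixed.
CHEMKG_DEFAULT_NAMESPACE <- "http://www.theworldavatar.com/kg/ontospecies/"
OS <- "http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#"
RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
SKOS <- "http://www.w3.org/2004/02/skos/core#"
XSD <- "http://www.w3.org/2001/XMLSchema#"

#' Instance namespace for minted IRIs
#'
#' All instance IRIs are minted under a single namespace, by default
#' `http://www.theworldavatar.com/kg/ontospecies/`. Override per session with
#' `options(chemkg.namespace = ...)`.
#'
#' @return the namespace string.
#' @export
kg_namespace <- function() {
  getOption("chemkg.namespace", CHEMKG_DEFAULT_NAMESPACE)
}

os_iri <- function(local) paste0(OS, local)

#' Mint the IRI of a species
#'
#' Species instances are named `Species_<uuid>` under the instance namespace,
#' so the same UUID always yields the same IRI.
#'
#' @param uuid species UUID string (letters, digits, hyphens).
#' @return the species IRI.
#' @examples
#' mint_species_iri("abc-1")
#' @export
mint_species_iri <- function(uuid) {
  check_uuid(uuid)
  paste0(kg_namespace(), "Species_", uuid)
}

#' Mint the IRI of an instance attached to a species
#'
#' Instances directly tied to one species (a boiling point, an identifier, an
#' atom) are named `<ClassName>_<index>_Species_<uuid>`; the 1-based index
#' distinguishes multiple instances of the same class on one species.
#'
#' @param class_name class-type name, e.g. `"BoilingPoint"`.
#' @param index 1-based integer position.
#' @param species_uuid the owning species' UUID.
#' @return the instance IRI.
#' @examples
#' mint_attached_iri("BoilingPoint", 1, "u1")
#' @export
mint_attached_iri <- function(class_name, index, species_uuid) {
  stopifnot(is.character(class_name), length(class_name) == 1L, nzchar(class_name))
  check_uuid(species_uuid)
  index <- as.integer(index)
  if (is.na(index) || index < 1L) {
    stop("index must be an integer >= 1", call. = FALSE)
  }
  paste0(kg_namespace(), class_name, "_", index, "_Species_", species_uuid)
}

#' Mint the IRI of a free-standing instance
#'
#' Instances not tied to a single species (uses, provenance records) are named
#' `<ClassName>_<uuid>`.
#'
#' @param class_name class-type name, e.g. `"Use"`.
#' @param uuid identifier string.
#' @return the instance IRI.
#' @examples
#' mint_free_iri("Use", "u9")
#' @export
mint_free_iri <- function(class_name, uuid) {
  if (!is.character(class_name) || length(class_name) != 1L || !nzchar(class_name)) {
    stop("class_name must be a non-empty string", call. = FALSE)
  }
  check_uuid(uuid)
  paste0(kg_namespace(), class_name, "_", uuid)
}

check_uuid <- function(uuid) {
  if (!is.character(uuid) || length(uuid) != 1L || is.na(uuid) ||
      !grepl("^[A-Za-z0-9][A-Za-z0-9-]*$", uuid)) {
    stop("malformed uuid: must be letters/digits/hyphens, non-empty",
         call. = FALSE)
  }
  invisible(uuid)
}

#' Generate random UUIDs
#'
#' Draws 128 random bits per UUID from R's RNG and formats them in the
#' canonical 8-4-4-4-12 hex layout, so `set.seed()` makes minting
#' reproducible.
#'
#' @param n how many UUIDs.
#' @return character vector of length `n`.
#' @examples
#' set.seed(1); chemkg_uuid()
#' @export
chemkg_uuid <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    hx <- sample(c(0:9, letters[1:6]), 32L, replace = TRUE)
    hx <- paste(hx, collapse = "")
    paste(substr(hx, 1, 8), substr(hx, 9, 12), substr(hx, 13, 16),
          substr(hx, 17, 20), substr(hx, 21, 32), sep = "-")
  }, character(1))
}
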