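# Canned query patterns over a populated store.

# class IRIs whose ancestor closure (reflexive, following os:hasParentClass)
# contains any class labelled `class_label`
descendant_class_iris <- function(df, class_label) {
  targets <- sel(df, p = paste0(RDFS, "label"), o = class_label, type = "string")$s
  targets <- intersect(targets,
                       sel(df, p = paste0(RDF, "type"), o = os_iri("ChemicalClass"))$s)
  if (!length(targets)) return(character())
  parent_p <- os_iri("hasParentClass")
  desc <- targets
  repeat {
    kids <- sel(df, p = parent_p, o = desc)$s
    merged <- union(desc, kids)
    if (length(merged) == length(desc)) break
    desc <- merged
  }
  desc
}

species_in_class <- function(df, class_label) {
  classes <- descendant_class_iris(df, class_label)
  if (!length(classes)) return(character())
  unique(sel(df, p = os_iri("hasChemicalClass"), o = classes)$s)
}

carbon_count_of <- function(df, species_iri) {
  label <- obj1(df, species_iri, paste0(RDFS, "label"))
  if (is.null(label)) return(NA_integer_)
  f <- tryCatch(parse_formula(label), error = function(e) NULL)
  if (is.null(f)) NA_integer_ else formula_count(f, "C")
}

#' Boiling points of the members of a chemical class
#'
#' Returns one row per (species, boiling-point record) for every species
#' tagged with the class — directly or through any descendant class in the
#' hierarchy (an alkanol counts as an alcohol). The carbon count comes from
#' the species' molecular-formula label; the reference pressure from the
#' record's reference state when present.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param class_label class label text, e.g. `"alcohol"`.
#' @return data frame with columns `species_iri`, `n_carbon`, `tb_K`,
#'   `p_ref_kPa` (`NA` when no reference state is recorded) and
#'   `is_recommended`. Unknown class labels yield an empty result with a
#'   message.
#' @export
query_boiling_by_class <- function(store, class_label) {
  df <- as_triples(store)
  empty <- data.frame(species_iri = character(), n_carbon = integer(),
                      tb_K = numeric(), p_ref_kPa = numeric(),
                      is_recommended = logical(), stringsAsFactors = FALSE)
  members <- species_in_class(df, class_label)
  if (!length(members)) {
    message(sprintf("no class labelled %s in store", dQuote(class_label)))
    return(empty)
  }
  rows <- list()
  for (sp in members) {
    ncarb <- carbon_count_of(df, sp)
    props <- sel(df, s = sp, p = os_iri("hasProperty"))$o
    bps <- props[local_name_kind(df, props) == "BoilingPoint"]
    for (bp in bps) {
      pref <- NA_real_
      riri <- obj1(df, bp, os_iri("hasReferenceState"))
      if (!is.null(riri) &&
          identical(obj1(df, riri, os_iri("refQuantityKind")), "pressure")) {
        pref <- as.numeric(obj1(df, riri, os_iri("value")))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species_iri = sp, n_carbon = ncarb,
        tb_K = as.numeric(obj1(df, bp, os_iri("value"))),
        p_ref_kPa = pref,
        is_recommended = identical(obj1(df, bp, os_iri("isRecommended")), "true"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$species_iri, out$tb_K), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SPARQL text for the boiling-point-by-class query
#'
#' Builds the SELECT query equivalent to [query_boiling_by_class()] (minus
#' the carbon count, which is derived from the label client-side): species
#' label, boiling-point value and optional reference pressure for all members
#' of the class, descending the class hierarchy with a transitive property
#' path.
#'
#' @param class_label class label text.
#' @return a SPARQL query string for [sparql()].
#' @export
sparql_boiling_by_class_query <- function(class_label) {
  sprintf('
SELECT ?species ?label ?tb ?pref WHERE {
  ?cls rdfs:label "%s" .
  ?cls a os:ChemicalClass .
  ?sub os:hasParentClass* ?cls .
  ?species os:hasChemicalClass ?sub .
  ?species rdfs:label ?label .
  ?species os:hasProperty ?bp .
  ?bp a os:BoilingPoint .
  ?bp os:value ?tb .
  OPTIONAL {
    ?bp os:hasReferenceState ?rs .
    ?rs os:refQuantityKind "pressure" .
    ?rs os:value ?pref .
  }
}', class_label)
}
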