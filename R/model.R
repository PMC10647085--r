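# Domain types mirroring the species TBox. Plain lists with class attributes;
# constructors validate the documented invariants.

#' Provenance of a datum
#'
#' @param label human-readable source label (e.g. a database name).
#' @param locator optional URL or DOI.
#' @return a `provenance` object. At least one of label/locator is required.
#' @export
provenance <- function(label = NULL, locator = NULL) {
  label <- scalar_chr_or_null(label, "label")
  locator <- scalar_chr_or_null(locator, "locator")
  if (is.null(label) && is.null(locator)) {
    stop("provenance needs at least one of label, locator", call. = FALSE)
  }
  structure(list(label = label, locator = locator), class = "provenance")
}

scalar_chr_or_null <- function(x, what) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NULL)
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    stop(sprintf("%s must be a non-empty string or NULL", what), call. = FALSE)
  }
  x
}

scalar_num_or_null <- function(x, what) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NULL)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a finite number or NULL", what), call. = FALSE)
  }
  as.numeric(x)
}

IDENTIFIER_KINDS <- c("InChI", "InChIKey", "IUPACName", "SMILES", "CAS",
                      "MolecularFormulaText")

#' Identifier record
#'
#' @param kind one of `"InChI"`, `"InChIKey"`, `"IUPACName"`, `"SMILES"`,
#'   `"CAS"`, `"MolecularFormulaText"`, or any other kind label.
#' @param value non-empty identifier text.
#' @param provenance a [provenance()] object.
#' @return an `identifier_record`.
#' @export
identifier_record <- function(kind, value, provenance) {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(kind),
            inherits(provenance, "provenance"))
  if (!is.character(value) || length(value) != 1L || !nzchar(value)) {
    stop("identifier value must be non-empty", call. = FALSE)
  }
  structure(list(kind = kind, value = value, provenance = provenance),
            class = "identifier_record")
}

#' Reference state of a thermodynamic property
#'
#' @param quantity_kind `"temperature"` or `"pressure"`.
#' @param value positive value in the canonical unit.
#' @param unit `"K"` for temperature, `"kPa"` for pressure.
#' @return a `reference_state`.
#' @export
reference_state <- function(quantity_kind, value, unit) {
  quantity_kind <- match.arg(quantity_kind, c("temperature", "pressure"))
  expected <- if (quantity_kind == "temperature") "K" else "kPa"
  if (!identical(unit, expected)) {
    stop(sprintf("reference-state %s must be in %s", quantity_kind, expected),
         call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0) {
    stop("reference-state value must be a positive finite number", call. = FALSE)
  }
  structure(list(quantity_kind = quantity_kind, value = as.numeric(value),
                 unit = unit),
            class = "reference_state")
}

#' One value of one property kind
#'
#' A property record holds a single canonicalised value of a property (boiling
#' point, density, solubility, molecular weight, charge, ...) together with
#' its original source string, acquisition date, optional reference state,
#' provenance and the recommended-value flag. Records of the same kind on one
#' species are numbered consecutively from 1.
#'
#' @param kind property-kind label, e.g. `"BoilingPoint"`.
#' @param index 1-based integer.
#' @param value finite numeric value in the canonical unit.
#' @param unit canonical unit text for the kind (see [canonical_unit()]).
#' @param provenance a [provenance()] object.
#' @param original_string,date_acquired,ref_state optional original text,
#'   acquisition timestamp (`POSIXct` or ISO-8601 string), and
#'   [reference_state()].
#' @param is_recommended flag; a recommended record must carry provenance
#'   label `"PubChem agent"`.
#' @param qualifier inequality/approximation qualifier of the source string:
#'   `"none"`, `"at_least"`, `"at_most"` or `"approx"`. Retained for
#'   transparency; the numeric value participates in curation unchanged.
#' @return a `property_record`.
#' @export
property_record <- function(kind, index, value, unit, provenance,
                            original_string = NULL, date_acquired = NULL,
                            ref_state = NULL, is_recommended = FALSE,
                            qualifier = "none") {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(kind),
            inherits(provenance, "provenance"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("index must be >= 1", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("property value must be finite", call. = FALSE)
  }
  canon <- canonical_unit(kind)
  if (!is.na(canon) && !identical(unit, canon)) {
    stop(sprintf("unit %s inconsistent with kind %s (canonical: %s)",
                 dQuote(unit), kind, canon), call. = FALSE)
  }
  if (isTRUE(is_recommended) && !identical(provenance$label, "PubChem agent")) {
    stop("a recommended record must carry provenance label \"PubChem agent\"",
         call. = FALSE)
  }
  if (!is.null(ref_state)) stopifnot(inherits(ref_state, "reference_state"))
  if (!is.null(date_acquired)) {
    if (is.character(date_acquired)) {
      date_acquired <- as.POSIXct(date_acquired, tz = "UTC",
                                  tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                 "%Y-%m-%d %H:%M:%S",
                                                 "%Y-%m-%d"))
    }
    date_acquired <- format(date_acquired, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  qualifier <- match.arg(qualifier, c("none", "at_least", "at_most", "approx"))
  structure(list(kind = kind, index = index, value = as.numeric(value),
                 unit = unit,
                 original_string = scalar_chr_or_null(original_string, "original_string"),
                 date_acquired = date_acquired,
                 ref_state = ref_state, provenance = provenance,
                 is_recommended = isTRUE(is_recommended),
                 qualifier = qualifier),
            class = "property_record")
}

#' Node in a classification hierarchy
#'
#' @param iri class IRI.
#' @param label class label, e.g. `"alkanol"`.
#' @param parents character vector of parent-class IRIs (may be empty).
#' @param source_id optional provider identifier (e.g. a ChEBI id).
#' @return a `chemical_class`. Self-parenting is rejected here; acyclicity of
#'   a whole hierarchy is enforced at import time.
#' @export
chemical_class <- function(iri, label, parents = character(), source_id = NULL) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri),
            is.character(label), length(label) == 1L, nzchar(label),
            is.character(parents))
  if (iri %in% parents) stop("a class cannot be its own parent", call. = FALSE)
  structure(list(iri = iri, label = label,
                 parents = sort(unique(parents)),
                 source_id = scalar_chr_or_null(source_id, "source_id")),
            class = "chemical_class")
}

#' GHS hazard statement
#'
#' @param code hazard code such as `"H350"` (letter(s) followed by digits).
#' @param text statement text.
#' @return a `ghs_statement`.
#' @export
ghs_statement <- function(code, text = "") {
  stopifnot(is.character(code), length(code) == 1L)
  if (!grepl("^[A-Za-z]+[0-9]+$", code)) {
    stop(sprintf("GHS code %s must be letters followed by digits", dQuote(code)),
         call. = FALSE)
  }
  stopifnot(is.character(text), length(text) == 1L)
  structure(list(code = code, text = text), class = "ghs_statement")
}

MULTIPLICITIES <- c("singlet", "doublet", "triplet", "quartet", "multiplet")

#' Spectral peak
#'
#' @param position peak position: chemical shift in ppm for NMR, m/z for MS.
#' @param intensity non-negative intensity (default 1).
#' @param multiplicity optional splitting pattern, one of singlet, doublet,
#'   triplet, quartet, multiplet.
#' @return a `peak`.
#' @export
peak <- function(position, intensity = 1, multiplicity = NULL) {
  stopifnot(is.numeric(position), length(position) == 1L, is.finite(position))
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity) || intensity < 0) {
    stop("peak intensity must be >= 0", call. = FALSE)
  }
  if (!is.null(multiplicity)) {
    multiplicity <- match.arg(multiplicity, MULTIPLICITIES)
  }
  structure(list(position = as.numeric(position),
                 intensity = as.numeric(intensity),
                 multiplicity = multiplicity),
            class = "peak")
}

#' Recorded spectrum of a species
#'
#' @param kind `"NMR1D"`, `"NMR2D"` or `"MS"`.
#' @param peaks list of [peak()] objects, in recorded order.
#' @param sequence_number 1-based order in which spectra of the species were
#'   acquired into the record ("first spectrum" semantics).
#' @param solvent,frequency NMR-only metadata (solvent text, frequency in MHz).
#' @param ionization_mode MS-only metadata.
#' @return a `spectrum_record`.
#' @export
spectrum_record <- function(kind, peaks, sequence_number = 1L,
                            solvent = NULL, frequency = NULL,
                            ionization_mode = NULL) {
  kind <- match.arg(kind, c("NMR1D", "NMR2D", "MS"))
  stopifnot(is.list(peaks), all(vapply(peaks, inherits, logical(1), "peak")))
  sequence_number <- as.integer(sequence_number)
  stopifnot(!is.na(sequence_number), sequence_number >= 1L)
  if (kind == "MS" && (!is.null(solvent) || !is.null(frequency))) {
    stop("MS spectra carry no solvent/frequency", call. = FALSE)
  }
  if (kind != "MS" && !is.null(ionization_mode)) {
    stop("NMR spectra carry no ionization mode", call. = FALSE)
  }
  structure(list(kind = kind, peaks = peaks, sequence_number = sequence_number,
                 solvent = scalar_chr_or_null(solvent, "solvent"),
                 frequency = scalar_num_or_null(frequency, "frequency"),
                 ionization_mode = scalar_chr_or_null(ionization_mode, "ionization_mode")),
            class = "spectrum_record")
}

#' Atom of a species
#'
#' @param index 1-based atom index, unique within the species.
#' @param element element symbol.
#' @param x,y,z optional Cartesian coordinates in Angstrom.
#' @return an `atom`.
#' @export
atom <- function(index, element, x = NULL, y = NULL, z = NULL) {
  index <- as.integer(index)
  stopifnot(!is.na(index), index >= 1L)
  if (!is_element(element)) {
    stop(sprintf("unknown element %s", dQuote(element)), call. = FALSE)
  }
  structure(list(index = index, element = element,
                 x = scalar_num_or_null(x, "x"), y = scalar_num_or_null(y, "y"),
                 z = scalar_num_or_null(z, "z")),
            class = "atom")
}

#' Bond between two atoms
#'
#' The pair is unordered: the bond (i, j) equals the bond (j, i); the
#' constructor stores the smaller index first.
#'
#' @param atom_a,atom_b distinct atom indices.
#' @param order positive integer bond order (default 1).
#' @return an `atomic_bond`.
#' @export
atomic_bond <- function(atom_a, atom_b, order = 1L) {
  atom_a <- as.integer(atom_a); atom_b <- as.integer(atom_b)
  order <- as.integer(order)
  stopifnot(!is.na(atom_a), !is.na(atom_b), atom_a >= 1L, atom_b >= 1L)
  if (atom_a == atom_b) stop("a bond needs two distinct atoms", call. = FALSE)
  if (is.na(order) || order < 1L) stop("bond order must be >= 1", call. = FALSE)
  structure(list(atom_a = min(atom_a, atom_b), atom_b = max(atom_a, atom_b),
                 order = order),
            class = "atomic_bond")
}

#' Assemble a chemical species
#'
#' The aggregate of everything the graph stores about one species. The label
#' is always the Hill rendering of the formula; synonyms go to `alt_labels`.
#' Property records are re-indexed consecutively from 1 within each kind, in
#' input order, so emitted IRIs are stable.
#'
#' @param uuid unique identifier (see [chemkg_uuid()]).
#' @param formula an `empirical_formula`, or formula text.
#' @param alt_labels character vector of synonyms (deduplicated verbatim).
#' @param atoms,bonds,identifiers,properties,classes,ghs,uses,spectra
#'   collections of the corresponding record objects ([atom()],
#'   [atomic_bond()], [identifier_record()], [property_record()],
#'   [chemical_class()], [ghs_statement()], character uses,
#'   [spectrum_record()]).
#' @return a `species` object.
#' @export
species <- function(uuid, formula, alt_labels = character(),
                    atoms = list(), bonds = list(), identifiers = list(),
                    properties = list(), classes = list(), ghs = list(),
                    uses = character(), spectra = list()) {
  check_uuid(uuid)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "empirical_formula"))
  check_all <- function(xs, cls) {
    stopifnot(is.list(xs), all(vapply(xs, inherits, logical(1), cls)))
    xs
  }
  atoms <- check_all(atoms, "atom")
  if (length(atoms)) {
    idx <- vapply(atoms, `[[`, integer(1), "index")
    if (anyDuplicated(idx)) stop("atom indices must be unique", call. = FALSE)
    atoms <- atoms[order(idx)]
  }
  bonds <- check_all(bonds, "atomic_bond")
  if (length(bonds)) {
    key <- vapply(bonds, function(b) paste(b$atom_a, b$atom_b), character(1))
    bonds <- bonds[!duplicated(key)]
    bonds <- bonds[order(vapply(bonds, `[[`, integer(1), "atom_a"),
                         vapply(bonds, `[[`, integer(1), "atom_b"))]
  }
  identifiers <- check_all(identifiers, "identifier_record")
  if (length(identifiers)) {
    # stable sort by kind; input order is preserved within a kind so minted
    # per-kind indices are reproducible
    identifiers <- identifiers[order(vapply(identifiers, `[[`, character(1), "kind"))]
  }
  properties <- check_all(properties, "property_record")
  properties <- reindex_properties(properties)
  if (length(properties)) {
    properties <- properties[order(vapply(properties, `[[`, character(1), "kind"),
                                   vapply(properties, `[[`, integer(1), "index"))]
  }
  classes <- check_all(classes, "chemical_class")
  if (length(classes)) {
    classes <- classes[order(vapply(classes, `[[`, character(1), "iri"))]
    classes <- classes[!duplicated(vapply(classes, `[[`, character(1), "iri"))]
  }
  ghs <- check_all(ghs, "ghs_statement")
  stopifnot(is.character(uses), is.character(alt_labels))
  spectra <- check_all(spectra, "spectrum_record")
  if (length(spectra)) {
    spectra <- spectra[order(vapply(spectra, `[[`, integer(1), "sequence_number"))]
  }
  structure(list(uuid = uuid, label = render_formula(formula),
                 alt_labels = sort(unique(alt_labels)), formula = formula,
                 atoms = atoms, bonds = bonds, identifiers = identifiers,
                 properties = properties, classes = classes, ghs = ghs,
                 uses = unique(uses), spectra = spectra),
            class = "species")
}

# Re-number property records 1..n within each kind, preserving input order.
reindex_properties <- function(properties) {
  if (!length(properties)) return(properties)
  kinds <- vapply(properties, `[[`, character(1), "kind")
  for (k in unique(kinds)) {
    at <- which(kinds == k)
    for (j in seq_along(at)) properties[[at[j]]]$index <- j
  }
  properties
}

#' @export
print.species <- function(x, ...) {
  cat("<species> ", x$label, "  uuid: ", x$uuid, "\n", sep = "")
  cat(sprintf("  %d atoms, %d bonds, %d identifiers, %d properties, %d classes\n",
              length(x$atoms), length(x$bonds), length(x$identifiers),
              length(x$properties), length(x$classes)))
  cat(sprintf("  %d GHS statements, %d uses, %d spectra, %d synonyms\n",
              length(x$ghs), length(x$uses), length(x$spectra),
              length(x$alt_labels)))
  invisible(x)
}

#' @export
print.property_record <- function(x, ...) {
  cat(sprintf("<property_record> %s[%d] = %g %s%s\n", x$kind, x$index,
              x$value, x$unit, if (x$is_recommended) " (recommended)" else ""))
  invisible(x)
}
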