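# Synthetic fixtures with known ground truth.
#
# Everything the pipeline consumes — provider payloads with property strings
# in mixed unit dialects, classification trees, species libraries with NMR
# peak lists, observed mixture spectra — can be generated deterministically
# from a seed, so the full toolkit is testable without network access.
# Fixtures are statistically, not chemically, realistic: shifts and formulas
# are plausible but not those of real compounds.

# deterministic substream per (seed, purpose-tag): adding a generator does
# not shift existing fixtures
stream_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 69621 + h) %% 2147483647)
}

with_stream <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, tag))
  code
}

#' Specification of a synthetic fixture set
#'
#' @param seed integer; fully determines every generated artifact.
#' @param n_species library size.
#' @param outlier_rate probability that a generated property string carries a
#'   far-off (2-3x) value, emulating source typos.
#' @param dialect_weights weights over the unit dialects used to render
#'   temperature strings (`K`, `C`, `F_cond` = Fahrenheit with a 760 mmHg
#'   condition clause and citation).
#' @param tb_noise_sd standard deviation (K) of the scatter added to the
#'   class trend when drawing a species' true boiling point.
#' @param planted_mixture optional character vector of species labels to
#'   plant in a mixture spectrum.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_species = 30L, outlier_rate = 0.1,
                         dialect_weights = c(K = 1, C = 1, F_cond = 1),
                         tb_noise_sd = 2, planted_mixture = character()) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            outlier_rate >= 0, outlier_rate <= 1,
            all(dialect_weights >= 0), sum(dialect_weights) > 0,
            tb_noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 outlier_rate = outlier_rate,
                 dialect_weights = dialect_weights,
                 tb_noise_sd = tb_noise_sd,
                 planted_mixture = planted_mixture),
            class = "fixture_spec")
}

# ---- bundled replay fixtures -------------------------------------------

#' Bundled curation example: methyl-acetate boiling-point strings
#'
#' The five boiling-point strings listed in PubChem for methyl acetate, in
#' record order. Parsing and canonicalising them exercises the whole
#' parse -> convert -> curate pipeline: four sources agree near 330 K while
#' one (a likely typo in the original string) sits at 808.85 K.
#'
#' @return character vector of five raw property strings.
#' @export
methyl_acetate_bp_strings <- function() {
  c("134.4 °F at 760 mmHg (NTP, 1992)",
    "56.7 °C",
    "535.70 °C @ 760.00 mmHg (est)",
    "57 °C",
    "135 °F")
}

#' Bundled parsing example: ethanol solubility strings
#'
#' The nine solubility strings listed on the PubChem compound page for
#' ethanol — a mix of quantitative entries in different dialects and
#' qualitative ones ("Miscible.") that carry no numeric value and are
#' discarded by the parser.
#'
#' @return character vector of nine raw property strings.
#' @export
ethanol_solubility_strings <- function() {
  c("Greater than or equal to 100 mg/mL at 73 °F (NTP, 1992).",
    "1,000,000 mg/L (at 25 °C).",
    "In water, miscible/1 × 10 + 6 mg/L/at 25 °C.",
    "Miscible with ethyl ether, acetone, and chloroform; soluble in benzene.",
    "Miscible with many organic solvents.",
    "1000.0 mg/mL.",
    "Solubility in water: miscible.",
    "Soluble in water.",
    "Miscible.")
}

#' Bundled mixture example: observed catholyte 1H-NMR peaks
#'
#' The six main peaks of a 1H-NMR spectrum of a catholyte sample from
#' electrochemical CO2 reduction with an internal DMSO standard: the 2.6 ppm
#' singlet is the DMSO reference, the 4.9 ppm singlet the water solvent, the
#' remaining four are analyte peaks.
#'
#' @return list of [observed_peak()]s.
#' @export
catholyte_observed_peaks <- function() {
  list(observed_peak(8.35, "singlet", "analyte"),
       observed_peak(4.9, "singlet", "solvent"),
       observed_peak(3.51, "quartet", "analyte"),
       observed_peak(2.6, "singlet", "reference"),
       observed_peak(1.83, "singlet", "analyte"),
       observed_peak(1.04, "triplet", "analyte"))
}

# ---- property-string generation ----------------------------------------

render_temperature_string <- function(value_K, dialect) {
  switch(dialect,
    K = sprintf("%.1f K", value_K),
    C = sprintf("%.1f °C", value_K - 273.15),
    F_cond = sprintf("%.1f °F at 760 mmHg (NTP, 1992)",
                     (value_K - 273.15) * 9 / 5 + 32))
}

#' Generate heterogeneous property strings for a known true value
#'
#' Renders `true_value` in mixed unit dialects (kelvin, Celsius, Fahrenheit
#' with a pressure-condition clause and citation), injecting a far-off value
#' (x2-x3) with probability `spec$outlier_rate` per string. The ground truth
#' records the rendered value and which strings are outliers. With
#' `replay = "methyl_acetate"` the five bundled methyl-acetate strings are
#' returned instead (see [methyl_acetate_bp_strings()]).
#'
#' @param true_value true property value in the canonical unit (K for
#'   temperature kinds).
#' @param kind property kind (a temperature kind; only temperature dialects
#'   are generated).
#' @param n number of strings.
#' @param spec a [fixture_spec()].
#' @param tag substream tag, so different call sites draw independently.
#' @param replay optional replay mode (`"methyl_acetate"`).
#' @return list with `strings` (character) and `ground_truth` (data frame
#'   with columns `string`, `rendered_value`, `is_outlier`).
#' @export
gen_property_strings <- function(true_value, kind = "BoilingPoint", n = 5L,
                                 spec = fixture_spec(1), tag = "strings",
                                 replay = NULL) {
  if (identical(replay, "methyl_acetate")) {
    strings <- methyl_acetate_bp_strings()
    vals <- vapply(strings, function(s) {
      q <- to_canonical(parse_property_string(s)[[1]], kind)
      q$value
    }, numeric(1), USE.NAMES = FALSE)
    rec <- stats::median(vals)
    return(list(strings = strings,
                ground_truth = data.frame(string = strings,
                                          rendered_value = vals,
                                          is_outlier = abs(vals - rec) / rec > 0.2,
                                          stringsAsFactors = FALSE)))
  }
  stopifnot(n >= 1L, identical(kind_dimension(kind), "temperature"))
  with_stream(spec$seed, paste0(tag, "/", kind, "/", true_value), {
    dialects <- sample(names(spec$dialect_weights), n, replace = TRUE,
                       prob = spec$dialect_weights)
    is_outlier <- stats::runif(n) < spec$outlier_rate
    rendered <- numeric(n)
    strings <- character(n)
    for (i in seq_len(n)) {
      v <- true_value
      if (is_outlier[i]) v <- v * stats::runif(1, 2, 3)
      strings[i] <- render_temperature_string(v, dialects[i])
      # ground truth is the value the string round-trips to (rounding included)
      rendered[i] <- to_canonical(parse_property_string(strings[i])[[1]], kind)$value
    }
    list(strings = strings,
         ground_truth = data.frame(string = strings, rendered_value = rendered,
                                   is_outlier = is_outlier,
                                   stringsAsFactors = FALSE))
  })
}

# ---- species library ----------------------------------------------------

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

formula_weight <- function(formula) {
  sum(ATOMIC_MASS[names(formula)] * unclass(formula))
}

# class trends Tb(n) = a n^(1/3) + b, anchored on the light and C10 members
# of each real series (e.g. methane 111 K / decane 447 K)
FIXTURE_CLASS_TRENDS <- list(
  alkane = c(a = 291, b = -180),
  alkene = c(a = 285, b = -175),
  alkanol = c(a = 144, b = 194)
)

FIXTURE_CLASS_TREE <- list(
  "fix:root" = list(label = "chemical entity", parents = character()),
  "fix:hydrocarbon" = list(label = "hydrocarbon", parents = "fix:root"),
  "fix:alcohol" = list(label = "alcohol", parents = "fix:root"),
  "fix:alkane" = list(label = "alkane", parents = "fix:hydrocarbon"),
  "fix:alkene" = list(label = "alkene", parents = "fix:hydrocarbon"),
  "fix:alkanol" = list(label = "alkanol", parents = "fix:alcohol")
)

fixture_formula_text <- function(class, n) {
  switch(class,
    alkane = sprintf("C%dH%d", n, 2 * n + 2),
    alkene = sprintf("C%dH%d", n, 2 * n),
    alkanol = sprintf("C%dH%dO", n, 2 * n + 2))
}

# heavy-atom skeleton: carbon chain (+ hydroxyl oxygen for alkanols);
# alkenes get one double bond at a random chain position
fixture_structure <- function(class, n, double_pos = 1L) {
  atoms <- lapply(seq_len(n), function(i) list(index = i, element = "C"))
  bonds <- list()
  if (n > 1L) {
    bonds <- lapply(seq_len(n - 1L), function(i) {
      list(atom_a = i, atom_b = i + 1L,
           order = if (class == "alkene" && i == double_pos) 2L else 1L)
    })
  }
  if (class == "alkanol") {
    atoms[[n + 1L]] <- list(index = n + 1L, element = "O")
    bonds[[length(bonds) + 1L]] <- list(atom_a = n, atom_b = n + 1L, order = 1L)
  }
  list(atoms = atoms, bonds = bonds)
}

#' Generate a synthetic species library as provider payloads
#'
#' Draws `spec$n_species` species from the alkane/alkene/alkanol series with
#' carbon counts 1-12 (alkenes start at 2), boiling points following each
#' class's cube-root trend plus Gaussian scatter (`spec$tb_noise_sd`),
#' property strings in mixed dialects with planted outliers
#' ([gen_property_strings()]), GHS codes on a subset, heavy-atom structures
#' consistent with the class (alkenes carry exactly one double bond), a
#' six-node classification tree, and a 1-4 peak 1H-NMR spectrum per species.
#' Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `computed`, `annotation`, `species_classes`, `classes`
#'   (provider payload tables, see [list_provider()]) and `ground_truth`
#'   (data frame: `key`, `label`, `class`, `n_carbon`, `true_tb`,
#'   `n_strings`, `n_outliers`).
#' @export
gen_species_library <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  computed <- list()
  annotation <- list()
  species_classes <- list()
  gt <- list()

  draws <- with_stream(spec$seed, "library", {
    classes <- sample(c("alkane", "alkene", "alkanol"), spec$n_species,
                      replace = TRUE)
    ns <- vapply(classes, function(cl) {
      sample(if (cl == "alkene") 2:12 else 1:12, 1L)
    }, integer(1))
    noise <- stats::rnorm(spec$n_species, 0, spec$tb_noise_sd)
    has_ghs <- stats::runif(spec$n_species) < 0.3
    dpos <- vapply(ns, function(n) sample(max(1L, n - 1L), 1L), integer(1))
    n_strings <- sample(2:5, spec$n_species, replace = TRUE)
    list(classes = classes, ns = ns, noise = noise, has_ghs = has_ghs,
         dpos = dpos, n_strings = n_strings)
  })

  for (i in seq_len(spec$n_species)) {
    cl <- draws$classes[i]
    n <- draws$ns[i]
    ftxt <- fixture_formula_text(cl, n)
    trend <- FIXTURE_CLASS_TRENDS[[cl]]
    tb <- trend["a"] * n^(1 / 3) + trend["b"] + draws$noise[i]
    key <- sprintf("InChI=1S/%s/fixture-%d", ftxt, i)
    name <- sprintf("%s-%d (synthetic)", cl, i)
    struct <- fixture_structure(cl, n, draws$dpos[i])

    computed[[key]] <- list(
      identifiers = list(InChI = key,
                         MolecularFormulaText = ftxt,
                         IUPACName = name),
      properties = list(
        MolecularWeight = list(value = formula_weight(parse_formula(ftxt)),
                               unit = "g/mol"),
        Charge = list(value = 0, unit = "e")),
      atoms = struct$atoms, bonds = struct$bonds)

    strs <- gen_property_strings(tb, "BoilingPoint", draws$n_strings[i], spec,
                                 tag = paste0("bp/", i))
    peaks <- with_stream(spec$seed, paste0("nmr/", i), {
      k <- sample(1:4, 1L)
      lapply(seq_len(k), function(j) {
        list(position = round(stats::runif(1, 0.5, 10), 2),
             intensity = round(stats::runif(1, 25, 100), 1),
             multiplicity = sample(MULTIPLICITIES[1:4], 1L))
      })
    })
    ghs <- if (draws$has_ghs[i]) {
      with_stream(spec$seed, paste0("ghs/", i), {
        codes <- sample(c("H225", "H302", "H319", "H350", "H360"),
                        sample(1:2, 1L))
        lapply(codes, function(cd) list(code = cd, text = "synthetic hazard"))
      })
    } else list()

    annotation[[key]] <- list(
      properties = lapply(strs$strings, function(s) {
        list(kind = "BoilingPoint", string = s,
             provenance = list(label = "synthetic source",
                               locator = paste0("fixture:src/", i)))
      }),
      ghs = ghs,
      uses = list("synthetic test compound"),
      synonyms = list(name),
      spectra = list(list(kind = "NMR1D", solvent = "DMSO-d6", frequency = 90,
                          peaks = peaks)))

    species_classes[[key]] <- paste0("fix:", cl)
    gt[[i]] <- data.frame(key = key, label = ftxt, class = cl, n_carbon = n,
                          true_tb = unname(tb),
                          n_strings = draws$n_strings[i],
                          n_outliers = sum(strs$ground_truth$is_outlier),
                          stringsAsFactors = FALSE)
  }

  list(computed = computed, annotation = annotation,
       species_classes = species_classes, classes = FIXTURE_CLASS_TREE,
       ground_truth = do.call(rbind, gt))
}

#' Write a generated library as a fixture directory
#'
#' Writes `computed.json`, `annotation.json`, `species_classes.json`,
#' `classes.json` and `ground_truth.tsv` so [fixture_provider()] can serve
#' the library.
#'
#' @param library output of [gen_species_library()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("computed", "annotation", "species_classes", "classes")) {
    jsonlite::write_json(library[[nm]], file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(library$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate an observed mixture spectrum with known ground truth
#'
#' Takes the retained (intensity-pruned) peaks of each planted species,
#' jitters the shifts within `jitter` ppm (below half the matching window, so
#' planted species remain recoverable) and adds the DMSO reference peak at
#' 2.6 ppm and the water solvent peak at 4.9 ppm with roles set. With
#' `replay = "catholyte"` the bundled six-peak spectrum is returned instead
#' ([catholyte_observed_peaks()]).
#'
#' @param library output of [gen_species_library()].
#' @param planted character vector of species keys to plant (subset of the
#'   library; an error if a planted species has no spectrum).
#' @param spec the [fixture_spec()] (for the seed).
#' @param jitter maximum absolute shift perturbation in ppm.
#' @param replay optional replay mode (`"catholyte"`).
#' @return list of [observed_peak()]s; attribute `"planted"` carries the
#'   ground truth.
#' @export
gen_mixture_spectrum <- function(library, planted, spec, jitter = 0.1,
                                 replay = NULL) {
  if (identical(replay, "catholyte")) {
    return(structure(catholyte_observed_peaks(), planted = character()))
  }
  stopifnot(all(planted %in% names(library$annotation)))
  observed <- list(observed_peak(2.6, "singlet", "reference"),
                   observed_peak(4.9, "singlet", "solvent"))
  with_stream(spec$seed, paste0("mixture/", paste(planted, collapse = ",")), {
    for (key in planted) {
      sdocs <- library$annotation[[key]]$spectra
      if (is.null(sdocs) || !length(sdocs)) {
        stop(sprintf("planted species %s has no spectrum", dQuote(key)),
             call. = FALSE)
      }
      pk <- lapply(sdocs[[1]]$peaks, function(p) {
        peak(p$position, p$intensity, p$multiplicity)
      })
      for (p in prune_minor_peaks(pk, 0.20)) {
        observed[[length(observed) + 1L]] <- observed_peak(
          p$position + stats::runif(1, -jitter, jitter),
          p$multiplicity, "analyte")
      }
    }
    structure(observed, planted = planted)
  })
}

# ---- planted catholyte fixture ------------------------------------------

catholyte_fixture_species <- function(label_formula, uuid, tb, peaks) {
  bp <- property_record("BoilingPoint", 1L, tb, "K",
                        provenance("synthetic source"))
  recs <- list(bp, select_recommended(list(bp)))
  species(uuid = uuid, formula = label_formula,
          identifiers = list(identifier_record(
            "InChI", sprintf("InChI=1S/%s/planted-%s", label_formula, uuid),
            provenance("synthetic source"))),
          properties = recs,
          spectra = list(spectrum_record("NMR1D", peaks, 1L,
                                         solvent = "DMSO-d6", frequency = 90)))
}

#' Planted species library for the catholyte mixture example
#'
#' Builds a store holding four species whose pruned 1H-NMR peaks all fall
#' inside the +/- 0.2 ppm windows of the bundled catholyte spectrum
#' ([catholyte_observed_peaks()]) — formic acid (8.30 singlet), acetic acid
#' (1.90 singlet), ethanol and ethoxyethane (quartet/triplet pairs near
#' 3.5/1.1 ppm) — plus three decoys: one with a peak outside every window,
#' one with the right shift but wrong multiplicity, and one with two peaks
#' crowding a single observed window. All seven pass the candidate filter
#' (C/H/O only, C < 5, recommended boiling point above 15 °C), so the
#' two-stage matcher alone separates planted species from decoys.
#'
#' @return list with `store` (a [kg_store()]), `expected` (IRIs of the four
#'   planted species) and `decoys` (IRIs of the three decoys).
#' @export
catholyte_fixture_store <- function() {
  mk <- function(formula, uuid, tb, ...) {
    catholyte_fixture_species(formula, uuid, tb, list(...))
  }
  planted <- list(
    mk("CH2O2", "formic-acid", 374.0, peak(8.30, 100, "singlet")),
    mk("C2H4O2", "acetic-acid", 391.0, peak(1.90, 100, "singlet")),
    mk("C2H6O", "ethanol", 351.4,
       peak(3.55, 100, "quartet"), peak(1.10, 90, "triplet")),
    mk("C4H10O", "ethoxyethane", 307.6,
       peak(3.45, 100, "quartet"), peak(1.15, 90, "triplet"))
  )
  decoys <- list(
    mk("CH4O", "decoy-outside", 338.0, peak(3.20, 100, "singlet")),
    mk("C3H6O", "decoy-multiplicity", 329.0, peak(8.30, 100, "doublet")),
    mk("C3H8O", "decoy-crowded", 370.0,
       peak(1.70, 100, "singlet"), peak(1.95, 100, "singlet"))
  )
  store <- kg_store()
  for (sp in c(planted, decoys)) {
    kg_add_triples(store, emit_species_triples(sp))
  }
  list(store = store,
       expected = vapply(planted, function(s) mint_species_iri(s$uuid),
                         character(1)),
       decoys = vapply(decoys, function(s) mint_species_iri(s$uuid),
                       character(1)))
}
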