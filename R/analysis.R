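# Analysis agents: NMR mixture identification, co-solvent selection,
# homologous-series trend fitting, classification auditing.

#' Observed NMR peak
#'
#' @param shift chemical shift in ppm.
#' @param multiplicity optional splitting pattern.
#' @param role `"analyte"` (participates in matching), `"reference"` (e.g.
#'   the DMSO standard) or `"solvent"` (e.g. water); reference and solvent
#'   peaks are excluded from the matching windows.
#' @return an `observed_peak`.
#' @export
observed_peak <- function(shift, multiplicity = NULL, role = "analyte") {
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  if (!is.null(multiplicity)) multiplicity <- match.arg(multiplicity, MULTIPLICITIES)
  role <- match.arg(role, c("analyte", "reference", "solvent"))
  structure(list(shift = as.numeric(shift), multiplicity = multiplicity,
                 role = role),
            class = "observed_peak")
}

recommended_property_value <- function(df, species_iri, kind) {
  props <- sel(df, s = species_iri, p = os_iri("hasProperty"))$o
  props <- props[local_name_kind(df, props) == kind]
  for (p in props) {
    if (identical(obj1(df, p, os_iri("isRecommended")), "true")) {
      return(as.numeric(obj1(df, p, os_iri("value"))))
    }
  }
  NA_real_
}

all_species_iris <- function(df) {
  sel(df, p = paste0(RDF, "type"), o = os_iri("Species"))$s
}

species_formula <- function(df, species_iri) {
  label <- obj1(df, species_iri, paste0(RDFS, "label"))
  if (is.null(label)) return(NULL)
  tryCatch(parse_formula(label), error = function(e) NULL)
}

#' Filter candidate species for NMR mixture analysis
#'
#' Selects the species that could plausibly occur in a liquid-phase sample of
#' a C/H/O reaction mixture: formula contains only C, H, O with carbon count
#' `< c_max` and oxygen count `< o_max` (hydrogen unconstrained), and the
#' recommended boiling point exceeds `tb_min_K` (default 288.15 K = 15 °C,
#' safely below a 25 °C experiment so partially liquid species stay in).
#' Species without a recommended boiling point are excluded rather than
#' guessed.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param c_max,o_max exclusive upper bounds on carbon/oxygen counts.
#' @param tb_min_K minimum recommended boiling point (strict).
#' @return character vector of species IRIs.
#' @export
filter_nmr_candidates <- function(store, c_max = 5, o_max = 10,
                                  tb_min_K = 288.15) {
  df <- as_triples(store)
  out <- character()
  for (sp in all_species_iris(df)) {
    f <- species_formula(df, sp)
    if (is.null(f)) next
    if (!formula_matches(f, "bounded_CxHyOz", x_max = c_max, z_max = o_max)) next
    tb <- recommended_property_value(df, sp, "BoilingPoint")
    if (is.na(tb) || tb <= tb_min_K) next
    out <- c(out, sp)
  }
  out
}

#' Discard minor peaks of a spectrum
#'
#' Keeps the peaks whose intensity is at least `rel_threshold` (default 20%)
#' of the spectrum's highest peak.
#'
#' @param peaks non-empty list of [peak()]s.
#' @param rel_threshold relative intensity threshold.
#' @return the retained peaks.
#' @export
prune_minor_peaks <- function(peaks, rel_threshold = 0.20) {
  if (!length(peaks)) stop("cannot prune an empty peak list", call. = FALSE)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak")))
  imax <- max(vapply(peaks, `[[`, numeric(1), "intensity"))
  Filter(function(p) p$intensity >= rel_threshold * imax, peaks)
}

#' Pull each candidate's first 1H-NMR spectrum from the store
#'
#' For every candidate the first (lowest sequence number) 1D-NMR spectrum is
#' selected and its minor peaks pruned ([prune_minor_peaks()]). Candidates
#' without NMR data are dropped.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param species_iris candidate species.
#' @param rel_threshold intensity threshold for pruning.
#' @return named list: species IRI -> list of retained [peak()]s.
#' @export
nmr_species_library <- function(store, species_iris, rel_threshold = 0.20) {
  df <- as_triples(store)
  lib <- list()
  for (sp in species_iris) {
    spec_iris <- sel(df, s = sp, p = os_iri("hasSpectralInformation"))$o
    nmr <- spec_iris[local_name_kind(df, spec_iris) == "1DNMRSpectra"]
    if (!length(nmr)) next
    seqs <- vapply(nmr, function(xi)
      as.integer(obj1(df, xi, os_iri("sequenceNumber"))), integer(1))
    first <- nmr[which.min(seqs)]
    peak_iris <- sel(df, s = first, p = os_iri("hasPeak"))$o
    if (!length(peak_iris)) next
    peaks <- lapply(peak_iris, function(ki) {
      peak(position = as.numeric(obj1(df, ki, os_iri("peakPosition"))),
           intensity = as.numeric(obj1(df, ki, os_iri("peakIntensity")) %||% "1"),
           multiplicity = obj1(df, ki, os_iri("hasMultiplicity")))
    })
    lib[[sp]] <- prune_minor_peaks(peaks, rel_threshold)
  }
  lib
}

#' Stage-1 NMR matching: window coverage
#'
#' A species is a candidate when every retained library peak lies within
#' `window` ppm of at least one observed analyte peak (reference and solvent
#' peaks are excluded from matching). Each library peak is assigned to the
#' nearest covering observed peak.
#'
#' @param library named list species IRI -> pruned [peak()]s (see
#'   [nmr_species_library()]).
#' @param observed list of [observed_peak()]s.
#' @param window half-width of the matching window in ppm (default 0.2).
#' @return list of `match_result`s, one per surviving candidate: fields
#'   `species_iri`, `matched_pairs` (list of `list(observed, library)`), and
#'   `unmatched_library_peaks` (always empty for candidates).
#' @export
match_species_to_spectrum <- function(library, observed, window = 0.2) {
  stopifnot(is.list(observed),
            all(vapply(observed, inherits, logical(1), "observed_peak")))
  analyte <- Filter(function(p) p$role == "analyte", observed)
  results <- list()
  if (!length(library)) return(results)
  shifts <- vapply(analyte, `[[`, numeric(1), "shift")
  for (sp in names(library)) {
    pairs <- list()
    covered <- TRUE
    for (lp in library[[sp]]) {
      if (!length(shifts)) { covered <- FALSE; break }
      d <- abs(shifts - lp$position)
      j <- which.min(d)
      if (d[j] > window) { covered <- FALSE; break }
      pairs[[length(pairs) + 1L]] <- list(observed = analyte[[j]], library = lp)
    }
    if (covered) {
      results[[length(results) + 1L]] <-
        structure(list(species_iri = sp, matched_pairs = pairs,
                       unmatched_library_peaks = list()),
                  class = "match_result")
    }
  }
  results
}

#' Stage-2 NMR refinement: multiplicity and peak counting
#'
#' Retains a stage-1 candidate when (a) every matched pair agrees on
#' multiplicity — pairs whose library peak has no recorded multiplicity pass
#' — and (b) no observed analyte window contains more than one of the
#' candidate's library peaks (a singlet/triplet/quartet pattern cannot be
#' explained by two coinciding peaks).
#'
#' @param candidates list of `match_result`s from
#'   [match_species_to_spectrum()].
#' @param observed the observed peak list used for matching.
#' @param window matching half-width in ppm.
#' @return character vector of surviving species IRIs.
#' @export
refine_by_multiplicity <- function(candidates, observed, window = 0.2) {
  analyte <- Filter(function(p) p$role == "analyte", observed)
  keep <- character()
  for (cand in candidates) {
    ok <- TRUE
    for (pr in cand$matched_pairs) {
      lm <- pr$library$multiplicity
      om <- pr$observed$multiplicity
      if (!is.null(lm) && !is.null(om) && !identical(lm, om)) { ok <- FALSE; break }
    }
    if (ok) {
      lib_pos <- vapply(cand$matched_pairs, function(pr) pr$library$position,
                        numeric(1))
      for (op in analyte) {
        if (sum(abs(lib_pos - op$shift) <= window) > 1L) { ok <- FALSE; break }
      }
    }
    if (ok) keep <- c(keep, cand$species_iri)
  }
  keep
}

#' Identify mixture components from an observed 1H-NMR spectrum
#'
#' The full two-stage workflow: filter plausible species
#' ([filter_nmr_candidates()]), pull and prune their first 1H-NMR spectra
#' ([nmr_species_library()]), keep species whose peaks are all covered by
#' observed windows ([match_species_to_spectrum()]), then refine by
#' multiplicity and peak counting ([refine_by_multiplicity()]).
#'
#' @param store a [kg_store()].
#' @param observed list of [observed_peak()]s.
#' @param window matching half-width in ppm.
#' @param c_max,o_max,tb_min_K candidate filter bounds (see
#'   [filter_nmr_candidates()]).
#' @return character vector of identified species IRIs.
#' @export
identify_mixture <- function(store, observed, window = 0.2, c_max = 5,
                             o_max = 10, tb_min_K = 288.15) {
  cands <- filter_nmr_candidates(store, c_max, o_max, tb_min_K)
  lib <- nmr_species_library(store, cands)
  stage1 <- match_species_to_spectrum(lib, observed, window)
  refine_by_multiplicity(stage1, observed, window)
}

species_ghs_codes <- function(df, species_iri) {
  gi <- sel(df, s = species_iri, p = os_iri("hasGHSHazardStatement"))$o
  vapply(gi, function(g) obj1(df, g, os_iri("code")) %||% "", character(1))
}

#' Select co-solvent candidates for a reference solvent
#'
#' Members of a solvent class (hierarchy descent) whose recommended boiling
#' point differs from the reference's by at least `delta_tb_min_K` (ease of
#' separation by distillation), excluding species carrying GHS hazard codes
#' with an excluded prefix (default H350 carcinogenicity and H360
#' reproductive toxicity) and, optionally, species boiling above `tb_max_K`
#' (cost of solvent recovery).
#'
#' @param store a [kg_store()] or triple data frame.
#' @param ref_species IRI of the reference solvent; it must have a
#'   recommended boiling point.
#' @param class_label solvent class to search, e.g. `"alcohol"`.
#' @param delta_tb_min_K minimum |Tb - Tb_ref| (default 15 K, inclusive).
#' @param excluded_hazard_prefixes GHS code prefixes that disqualify.
#' @param tb_max_K optional strict upper bound on the candidate Tb.
#' @return character vector of candidate species IRIs.
#' @export
select_cosolvents <- function(store, ref_species, class_label,
                              delta_tb_min_K = 15,
                              excluded_hazard_prefixes = c("H350", "H360"),
                              tb_max_K = NULL) {
  df <- as_triples(store)
  tb_ref <- recommended_property_value(df, ref_species, "BoilingPoint")
  if (is.na(tb_ref)) {
    stop("reference species has no recommended boiling point", call. = FALSE)
  }
  out <- character()
  for (sp in setdiff(species_in_class(df, class_label), ref_species)) {
    tb <- recommended_property_value(df, sp, "BoilingPoint")
    if (is.na(tb)) next
    if (abs(tb - tb_ref) < delta_tb_min_K) next
    if (!is.null(tb_max_K) && tb >= tb_max_K) next
    codes <- species_ghs_codes(df, sp)
    if (length(codes) && any(vapply(excluded_hazard_prefixes, function(px)
      any(startsWith(codes, px)), logical(1)))) next
    out <- c(out, sp)
  }
  out
}

#' Fit a cube-root trend to boiling points of a homologous series
#'
#' Least-squares fit of `Tb(n) = a * n^(1/3) + b` over (carbon count,
#' boiling point) pairs — linear in the `(n^(1/3), 1)` basis, solved in
#' closed form.
#'
#' @param points data frame with columns `n` (carbon count) and `tb`
#'   (boiling point in K), or a list of `c(n, tb)` pairs.
#' @return a `trend_fit`: list with `a` (K), `b` (K), `residual_ss`,
#'   `n_points`.
#' @export
fit_cube_root <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- data.frame(n = vapply(points, `[[`, numeric(1), 1L),
                         tb = vapply(points, `[[`, numeric(1), 2L))
  }
  stopifnot(is.data.frame(points), all(c("n", "tb") %in% names(points)))
  if (length(unique(points$n)) < 2L) {
    stop("need at least 2 distinct carbon counts to fit a trend", call. = FALSE)
  }
  x <- points$n^(1 / 3)
  fit <- stats::lm(tb ~ x, data = data.frame(x = x, tb = points$tb))
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 residual_ss = sum(stats::residuals(fit)^2),
                 n_points = nrow(points)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> Tb(n) = %.4f * n^(1/3) + %.4f  (%d points, RSS %.4g)\n",
              x$a, x$b, x$n_points, x$residual_ss))
  invisible(x)
}

#' Extrapolate a boiling point from a fitted trend
#'
#' @param fit a `trend_fit` from [fit_cube_root()].
#' @param n carbon count(s), >= 1.
#' @return predicted boiling point(s) in K: `a * n^(1/3) + b`.
#' @export
extrapolate_bp <- function(fit, n) {
  stopifnot(inherits(fit, "trend_fit"), all(n >= 1))
  fit$a * n^(1 / 3) + fit$b
}

#' The shipped classification-rule registry
#'
#' Maps class labels to the structural rule their members must satisfy:
#' a sum-formula pattern and, where meaningful, an exact double-bond count.
#' Ships with alkane, alkene and alkanol; extend by passing a YAML file with
#' entries of the same shape.
#'
#' @param path optional YAML file of additional rules (entries keyed by rule
#'   name with fields `class_label`, `pattern`, optional
#'   `double_bond_count`).
#' @return named list of rules.
#' @export
rule_registry <- function(path = NULL) {
  rules <- list(
    alkane = list(class_label = "alkane", pattern = "alkane_CnH2n2",
                  double_bond_count = 0L),
    alkene = list(class_label = "alkene", pattern = "alkene_CnH2n",
                  double_bond_count = 1L),
    alkanol = list(class_label = "alkanol", pattern = "alkanol_CnH2n2O",
                   double_bond_count = 0L)
  )
  if (!is.null(path)) {
    extra <- yaml::read_yaml(path)
    for (nm in names(extra)) rules[[nm]] <- extra[[nm]]
  }
  rules
}

species_satisfies_rule <- function(df, species_iri, rule) {
  f <- species_formula(df, species_iri)
  if (is.null(f)) return(FALSE)
  if (!formula_matches(f, rule$pattern)) return(FALSE)
  if (!is.null(rule$double_bond_count)) {
    bonds <- sel(df, s = species_iri, p = os_iri("hasAtomicBond"))$o
    orders <- vapply(bonds, function(b)
      as.integer(obj1(df, b, os_iri("hasBondOrder")) %||% "1"), integer(1))
    if (sum(orders == 2L) != rule$double_bond_count) return(FALSE)
  }
  TRUE
}

#' Find species missing a classification tag
#'
#' Species satisfying a structural rule (sum-formula pattern plus, when the
#' rule gives one, an exact double-bond count) that are not tagged with the
#' rule's class — neither directly nor through a descendant class.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param rule a rule from [rule_registry()].
#' @return character vector of species IRIs missing the tag.
#' @export
find_missing_class_tags <- function(store, rule) {
  df <- as_triples(store)
  tagged <- species_in_class(df, rule$class_label)
  out <- character()
  for (sp in setdiff(all_species_iris(df), tagged)) {
    if (species_satisfies_rule(df, sp, rule)) out <- c(out, sp)
  }
  out
}

#' Check consistency of existing classification tags
#'
#' Species tagged with a class that fail the class's structural rule —
#' e.g. a species tagged "alkene" whose sum formula is not CnH2n.
#'
#' @param store a [kg_store()] or triple data frame.
#' @param rule a rule from [rule_registry()].
#' @return data frame with columns `species_iri` and `reason`.
#' @export
check_class_consistency <- function(store, rule) {
  df <- as_triples(store)
  rows <- list()
  for (sp in species_in_class(df, rule$class_label)) {
    if (!species_satisfies_rule(df, sp, rule)) {
      label <- obj1(df, sp, paste0(RDFS, "label")) %||% "?"
      rows[[length(rows) + 1L]] <- data.frame(
        species_iri = sp,
        reason = sprintf("tagged %s but formula %s fails pattern %s",
                         rule$class_label, label, rule$pattern),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    data.frame(species_iri = character(), reason = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}
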