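# Independent brute-force oracles and fixture builders shared by the tests.

OS_NS <- "http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"

# transitive-closure grouping oracle: all-pairs relative distances, then
# connected components by repeated expansion (independent of the union-find
# implementation in group_equivalent)
oracle_group_components <- function(values, rel_tol) {
  n <- length(values)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    lo <- min(abs(values[i]), abs(values[j]))
    d <- abs(values[i] - values[j])
    adj[i, j] <- if (d == 0) TRUE else if (lo == 0) FALSE else d / lo <= rel_tol
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        tgt <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), comp))
}

# reachability oracle over a parent map id -> parent ids
oracle_ancestors <- function(parents_of, leaf) {
  seen <- character()
  frontier <- leaf
  while (length(frontier)) {
    nxt <- character()
    for (id in frontier) {
      if (id %in% seen) next
      seen <- c(seen, id)
      nxt <- c(nxt, parents_of[[id]])
    }
    frontier <- nxt
  }
  sort(seen)
}

# dense grid-search least-squares oracle for the cube-root fit
oracle_grid_fit <- function(n, tb, a_range, b_range, step) {
  best <- c(a = NA, b = NA)
  best_ss <- Inf
  for (a in seq(a_range[1], a_range[2], by = step)) {
    for (b in seq(b_range[1], b_range[2], by = step)) {
      ss <- sum((tb - (a * n^(1 / 3) + b))^2)
      if (ss < best_ss) { best_ss <- ss; best <- c(a = a, b = b) }
    }
  }
  best
}

make_bp_record <- function(index, value, original = NULL, prov = provenance("src")) {
  property_record("BoilingPoint", index, value, "K", prov,
                  original_string = original)
}

bp_records <- function(values, originals = NULL) {
  lapply(seq_along(values), function(i) {
    make_bp_record(i, values[i],
                   if (is.null(originals)) NULL else originals[i])
  })
}

# Table-4-shaped records: parse + canonicalise the bundled methyl-acetate
# strings into indexed property records
methyl_acetate_records <- function() {
  strings <- methyl_acetate_bp_strings()
  recs <- list()
  for (i in seq_along(strings)) {
    q <- parse_property_string(strings[i])[[1]]
    recs[[i]] <- build_property_record(to_canonical(q, "BoilingPoint"),
                                       "BoilingPoint", i,
                                       provenance("src", paste0("urn:src:", i)))
  }
  recs
}

# randomised species covering every optional component; deterministic per i
random_species <- function(i) {
  set.seed(1000 + i)
  n_c <- sample(1:6, 1)
  formula_txt <- sprintf("C%dH%d%s", n_c, 2 * n_c + 2,
                         if (runif(1) < 0.5) "O" else "")
  n_atoms <- sample(0:4, 1)
  atoms <- lapply(seq_len(n_atoms), function(k) {
    if (runif(1) < 0.5) {
      atom(k, sample(c("C", "H", "O"), 1),
           x = round(runif(1), 3), y = round(runif(1), 3), z = round(runif(1), 3))
    } else {
      atom(k, sample(c("C", "H", "O"), 1))
    }
  })
  bonds <- if (n_atoms >= 2) {
    lapply(seq_len(n_atoms - 1L), function(k) {
      atomic_bond(k, k + 1L, sample(1:2, 1))
    })
  } else list()
  props <- list()
  kinds <- sample(c("BoilingPoint", "Density", "MolecularWeight"),
                  sample(1:3, 1))
  for (kd in kinds) {
    unit <- canonical_unit(kd)
    val <- round(runif(1, 10, 500), 3)
    props[[length(props) + 1L]] <- property_record(
      kd, 1L, val, unit, provenance("src", "urn:x"),
      original_string = if (runif(1) < 0.5) sprintf("%g %s", val, unit) else NULL,
      date_acquired = if (runif(1) < 0.5) "2023-04-01T10:00:00Z" else NULL,
      ref_state = if (kd == "BoilingPoint" && runif(1) < 0.5) {
        reference_state("pressure", 101.325, "kPa")
      } else NULL,
      qualifier = sample(c("none", "at_least", "approx"), 1))
    if (runif(1) < 0.5) {
      props[[length(props) + 1L]] <- property_record(
        kd, 2L, val, unit, provenance("PubChem agent"), is_recommended = TRUE)
    }
  }
  classes <- if (runif(1) < 0.7) {
    list(chemical_class(paste0("urn:cls:", sample(letters, 1)), "some class",
                        parents = if (runif(1) < 0.5) "urn:cls:root" else character(),
                        source_id = if (runif(1) < 0.5) "SRC:1" else NULL))
  } else list()
  spectra <- if (runif(1) < 0.6) {
    pk <- lapply(seq_len(sample(1:3, 1)), function(k) {
      peak(round(runif(1, 0.5, 10), 2), round(runif(1, 10, 100), 1),
           if (runif(1) < 0.7) sample(c("singlet", "triplet", "quartet"), 1) else NULL)
    })
    list(spectrum_record("NMR1D", pk, 1L,
                         solvent = if (runif(1) < 0.5) "DMSO-d6" else NULL,
                         frequency = if (runif(1) < 0.5) 400 else NULL))
  } else list()
  species(uuid = sprintf("rt-%04d", i), formula = formula_txt,
          alt_labels = if (runif(1) < 0.5) c("syn b", "syn a") else character(),
          atoms = atoms, bonds = bonds,
          identifiers = list(identifier_record(
            "InChI", paste0("InChI=1S/", formula_txt, "/rt", i),
            provenance("PubChem", "urn:pc"))),
          properties = props, classes = classes,
          ghs = if (runif(1) < 0.4) list(ghs_statement("H225", "flammable")) else list(),
          uses = if (runif(1) < 0.4) c("solvent", "fuel") else character(),
          spectra = spectra)
}

# store of species with given formulas/Tbs/classes for audit and query tests
build_audit_store <- function(entries) {
  store <- kg_store()
  iris <- character()
  for (e in entries) {
    props <- list()
    if (!is.null(e$tb)) {
      src <- property_record("BoilingPoint", 1L, e$tb, "K", provenance("src"))
      props <- list(src, select_recommended(list(src)))
    }
    sp <- species(uuid = e$uuid, formula = e$formula,
                  identifiers = list(identifier_record(
                    "InChI", paste0("InChI=1S/", e$formula, "/", e$uuid),
                    provenance("src"))),
                  properties = props,
                  bonds = e$bonds %||% list(),
                  atoms = e$atoms %||% list(),
                  classes = e$classes %||% list(),
                  ghs = e$ghs %||% list())
    kg_add_triples(store, emit_species_triples(sp))
    iris[e$uuid] <- mint_species_iri(e$uuid)
  }
  list(store = store, iris = iris)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
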