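# Provider payload mapping, hierarchy import and atomic species ingestion.

fixed_clock <- function() as.POSIXct("2023-04-01 12:00:00", tz = "UTC")

ethanol_like_payloads <- function() {
  computed <- list(
    identifiers = list(InChI = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
                       InChIKey = "LFQSCWFLJHTTHZ-UHFFFAOYSA-N",
                       IUPACName = "ethanol",
                       SMILES = "CCO",
                       MolecularFormulaText = "C2H6O"),
    properties = list(MolecularWeight = list(value = 46.07, unit = "g/mol"),
                      Charge = list(value = 0, unit = "e")))
  annotation <- list(
    properties = lapply(ethanol_solubility_strings(), function(s) {
      list(kind = "Solubility", string = s,
           provenance = list(label = "PubChem annotation", locator = "urn:ann"))
    }),
    ghs = list(list(code = "H225", text = "Highly flammable liquid")),
    uses = list("solvent"),
    synonyms = list("ethanol", "EtOH"),
    spectra = list(list(kind = "NMR1D", solvent = "DMSO-d6", frequency = 90,
                        peaks = list(list(position = 1.06, intensity = 90,
                                          multiplicity = "triplet"),
                                     list(position = 3.44, intensity = 100,
                                          multiplicity = "quartet")))))
  list(computed = computed, annotation = annotation)
}

test_that("computed payloads map to identifiers and computed properties", {
  p <- ethanol_like_payloads()
  prov <- list_provider(computed = list(k = p$computed), label = "prov")
  mapped <- map_computed_payload(prov$computed("k"))
  expect_length(mapped$identifiers, 5L)
  expect_setequal(vapply(mapped$identifiers, `[[`, character(1), "kind"),
                  c("InChI", "InChIKey", "IUPACName", "SMILES",
                    "MolecularFormulaText"))
  expect_length(mapped$properties, 2L)
  mw <- mapped$properties[[1]]
  expect_identical(mw$kind, "MolecularWeight")
  expect_equal(mw$value, 46.07)

  # absent charge: no record, no error
  no_charge <- p$computed
  no_charge$properties$Charge <- NULL
  prov2 <- list_provider(computed = list(k = no_charge))
  mapped2 <- map_computed_payload(prov2$computed("k"))
  expect_length(mapped2$properties, 1L)

  # no identifiers: the species cannot be keyed
  broken <- p$computed
  broken$identifiers <- NULL
  prov3 <- list_provider(computed = list(k = broken))
  expect_error(map_computed_payload(prov3$computed("k")), "identifier block")
})

test_that("annotation payloads keep strings verbatim with per-string provenance", {
  p <- ethanol_like_payloads()
  prov <- list_provider(annotation = list(k = p$annotation))
  mapped <- map_annotation_payload(prov$annotation("k"))
  expect_length(mapped$raw_strings, 9L)
  expect_identical(vapply(mapped$raw_strings, `[[`, character(1), "text"),
                   ethanol_solubility_strings())
  expect_identical(mapped$raw_strings[[1]]$provenance$label, "PubChem annotation")
  expect_length(mapped$spectra, 1L)
  expect_identical(mapped$spectra[[1]]$sequence_number, 1L)
  expect_identical(mapped$uses, "solvent")

  empty <- map_annotation_payload(list_provider()$annotation("missing"))
  expect_length(empty$raw_strings, 0L)
  expect_length(empty$ghs, 0L)
  expect_length(empty$spectra, 0L)
})

chain_provider <- function() {
  list_provider(classes = list(
    A = list(label = "leaf", parents = list("B")),
    B = list(label = "middle", parents = list("C")),
    C = list(label = "root", parents = list())))
}

test_that("hierarchy import instantiates each ancestor exactly once", {
  prov <- chain_provider()
  store <- kg_store()
  added <- import_classification_hierarchy(prov, "A", store)
  expect_length(added, 3L)
  df <- store$triples
  parent_links <- df[df$p == paste0(OS_NS, "hasParentClass"), ]
  expect_identical(nrow(parent_links), 2L)

  # idempotence
  n0 <- kg_size(store)
  again <- import_classification_hierarchy(prov, "A", store)
  expect_length(again, 0L)
  expect_identical(kg_size(store), n0)

  # pre-seeded ancestors are not duplicated
  store2 <- kg_store()
  import_classification_hierarchy(prov, "B", store2)
  n_mid <- kg_size(store2)
  added2 <- import_classification_hierarchy(prov, "A", store2)
  expect_length(added2, 1L)
  expect_identical(added2[[1]]$source_id, "A")
  expect_true(kg_size(store2) > n_mid)
})

test_that("hierarchy import detects cycles and unknown ids", {
  cyclic <- list_provider(classes = list(
    A = list(label = "a", parents = list("B")),
    B = list(label = "b", parents = list("A"))))
  expect_error(import_classification_hierarchy(cyclic, "A", kg_store()),
               "cycle")
  expect_error(import_classification_hierarchy(chain_provider(), "Z", kg_store()),
               "no classification record")
})

test_that("hierarchy import equals the reachability oracle on random DAGs", {
  set.seed(606)
  for (trial in 1:8) {
    n <- sample(5:50, 1)
    ids <- sprintf("N%02d", seq_len(n))
    parents_of <- stats::setNames(lapply(seq_len(n), function(i) {
      if (i == n) character() else {
        k <- sample(0:min(3, n - i), 1)
        if (k == 0) character() else sample(ids[(i + 1):n], k)
      }
    }), ids)
    prov <- list_provider(classes = stats::setNames(lapply(ids, function(id) {
      list(label = paste("class", id), parents = as.list(parents_of[[id]]))
    }), ids))
    leaf <- ids[1]
    store <- kg_store()
    added <- import_classification_hierarchy(prov, leaf, store)
    got <- sort(vapply(added, `[[`, character(1), "source_id"))
    expect_identical(got, oracle_ancestors(parents_of, leaf))
  }
})

full_fixture_provider <- function() {
  p <- ethanol_like_payloads()
  key <- p$computed$identifiers$InChI
  bp_annotation <- list(
    properties = lapply(methyl_acetate_bp_strings(), function(s) {
      list(kind = "BoilingPoint", string = s,
           provenance = list(label = "HMDB", locator = "urn:hmdb"))
    }))
  list_provider(
    computed = stats::setNames(list(p$computed), key),
    annotation = stats::setNames(list(bp_annotation), key),
    species_classes = stats::setNames(list("A"), key),
    classes = list(A = list(label = "alkanol", parents = list("B")),
                   B = list(label = "alcohol", parents = list())))
}

test_that("ingestion builds records, recommended values and classes", {
  prov <- full_fixture_provider()
  key <- "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"
  store <- kg_store()
  set.seed(1)
  iri <- ingest_species(key, prov, store, clock = fixed_clock)
  expect_true(attr(iri, "created"))

  sp <- load_species(store, as.character(iri))
  bps <- Filter(function(p) p$kind == "BoilingPoint", sp$properties)
  expect_length(bps, 6L)
  expect_identical(sum(vapply(bps, `[[`, logical(1), "is_recommended")), 1L)
  rec <- Filter(function(p) p$is_recommended, bps)[[1]]
  expect_equal(rec$value, 329.85)
  expect_identical(rec$index, 6L)
  # original strings and acquisition dates were stamped
  expect_identical(bps[[1]]$original_string, methyl_acetate_bp_strings()[1])
  expect_identical(bps[[1]]$date_acquired, "2023-04-01T12:00:00Z")
  # classification hierarchy imported to the root
  df <- store$triples
  labels <- df$o[df$p == paste0(RDFS_NS, "label")]
  expect_true(all(c("alkanol", "alcohol") %in% labels))
  # exactly one recommended record per kind with values
  for (kind in c("MolecularWeight", "Charge")) {
    ps <- Filter(function(p) p$kind == kind, sp$properties)
    expect_identical(sum(vapply(ps, `[[`, logical(1), "is_recommended")), 1L)
  }
})

test_that("re-ingesting a known key returns the same IRI without changes", {
  prov <- full_fixture_provider()
  key <- "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"
  store <- kg_store()
  set.seed(2)
  iri1 <- ingest_species(key, prov, store, clock = fixed_clock)
  n1 <- kg_size(store)
  iri2 <- ingest_species(key, prov, store, clock = fixed_clock)
  expect_identical(as.character(iri1), as.character(iri2))
  expect_false(attr(iri2, "created"))
  expect_identical(kg_size(store), n1)
  expect_error(ingest_species("", prov, store), "non-empty")
})

test_that("ingestion is atomic under provider failure", {
  p <- ethanol_like_payloads()
  key <- p$computed$identifiers$InChI
  flaky <- list_provider(computed = stats::setNames(list(p$computed), key))
  # annotation succeeds but classification resolution always fails
  flaky$classification <- function(key) "MISSING-CLASS"
  class(flaky) <- "chemkg_provider"
  store <- kg_store()
  before <- store$triples
  expect_error(ingest_species(key, flaky, store, max_retries = 1L),
               "provider failure")
  expect_identical(store$triples, before)
})

test_that("discarded strings are logged with reasons", {
  prov <- full_fixture_provider()
  p <- ethanol_like_payloads()
  key2 <- "InChI=1S/C2H6O/mixed"
  mixed_annotation <- list(properties = list(
    list(kind = "Solubility", string = "Miscible.",
         provenance = list(label = "src")),
    list(kind = "BoilingPoint", string = "5 mmHg",
         provenance = list(label = "src")),
    list(kind = "Solubility", string = "1000.0 mg/mL",
         provenance = list(label = "src"))))
  comp2 <- p$computed
  comp2$identifiers$InChI <- key2
  prov2 <- list_provider(computed = stats::setNames(list(comp2), key2),
                         annotation = stats::setNames(list(mixed_annotation), key2))
  store <- kg_store()
  set.seed(3)
  iri <- ingest_species(key2, prov2, store, clock = fixed_clock)
  log <- attr(iri, "discarded")
  expect_identical(nrow(log), 2L)
  expect_setequal(log$reason[log$text == "Miscible."], "no numeric value detected")
  expect_match(log$reason[log$text == "5 mmHg"], "dimension")
  sp <- load_species(store, as.character(iri))
  sols <- Filter(function(pr) pr$kind == "Solubility", sp$properties)
  expect_length(sols, 2L)  # one parsed + one recommended
})
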