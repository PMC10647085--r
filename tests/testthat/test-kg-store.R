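# Triple emission, loading, Turtle IO, shape validation and SPARQL.

test_that("emission materialises label and synonyms with the TBox predicates", {
  sp <- species("u-lbl", "C2H6O", alt_labels = "ethanol",
                identifiers = list(identifier_record("InChI", "InChI=1S/x",
                                                     provenance("src"))))
  g <- emit_species_triples(sp)
  siri <- mint_species_iri("u-lbl")
  expect_true(any(g$s == siri & g$p == paste0(RDFS_NS, "label") & g$o == "C2H6O"))
  expect_true(any(g$s == siri & g$p == paste0(SKOS_NS, "altLabel") & g$o == "ethanol"))
  # minimal species: empty optional collections still emit a valid graph
  minimal <- species("u-min", "CH4",
                     identifiers = list(identifier_record("SMILES", "C",
                                                          provenance("src"))))
  gm <- emit_species_triples(minimal)
  expect_true(validate_shapes(gm)$conforms)
})

test_that("emit/load round-trips randomised species structurally", {
  for (i in 1:25) {
    sp <- random_species(i)
    g <- emit_species_triples(sp)
    sp2 <- load_species(g, mint_species_iri(sp$uuid))
    expect_identical(sp2, sp)
  }
})

test_that("loading from a multi-species graph isolates one subgraph", {
  a <- random_species(101)
  b <- random_species(102)
  store <- kg_store()
  kg_add_triples(store, emit_species_triples(a))
  kg_add_triples(store, emit_species_triples(b))
  a2 <- load_species(store, mint_species_iri(a$uuid))
  expect_identical(a2, a)
  expect_error(load_species(store, mint_species_iri("not-there")), "label")
})

test_that("a hand-written Turtle fixture loads to the expected species", {
  path <- tempfile(fileext = ".ttl")
  ns <- kg_namespace()
  writeLines(c(
    "@prefix oskg: <http://www.theworldavatar.com/kg/ontospecies/> .",
    "oskg:Species_tiny a os:Species .",
    "oskg:Species_tiny rdfs:label \"H2O\" .",
    "oskg:Species_tiny os:hasIdentifier oskg:InChI_1_Species_tiny .",
    "oskg:InChI_1_Species_tiny a os:InChI .",
    "oskg:InChI_1_Species_tiny os:value \"InChI=1S/H2O/h1H2\" .",
    "oskg:InChI_1_Species_tiny os:hasProvenance oskg:Reference_tiny-ref1 .",
    "oskg:Reference_tiny-ref1 a os:Reference .",
    "oskg:Reference_tiny-ref1 rdfs:label \"PubChem\" ."
  ), path)
  g <- kg_read_turtle(path)
  sp <- load_species(g, paste0(ns, "Species_tiny"))
  expected <- species("tiny", "H2O",
                      identifiers = list(identifier_record(
                        "InChI", "InChI=1S/H2O/h1H2", provenance("PubChem"))))
  expect_identical(sp, expected)
})

test_that("Turtle writing and reading preserve the triple set", {
  sp <- random_species(55)
  g <- emit_species_triples(sp)
  path <- tempfile(fileext = ".ttl")
  kg_write_turtle(g, path)
  g2 <- kg_read_turtle(path)
  key <- function(df) sort(paste(df$s, df$p, df$o, df$type, sep = "\r"))
  expect_identical(key(g2), key(g))
  # literals with embedded quotes and newlines survive
  tricky <- data.frame(s = "urn:s", p = "urn:p",
                       o = "line1\nsays \"hi\"\tend\\", type = "string")
  kg_write_turtle(tricky, path)
  expect_identical(kg_read_turtle(path)$o, tricky$o)
  expect_error(kg_read_turtle(textConnection("<urn:a> <urn:b>")), "line 1")
})

test_that("shape validation flags each mutated mandatory field", {
  sp <- random_species(7)
  g <- emit_species_triples(sp)
  expect_true(validate_shapes(g)$conforms)

  drop_pred <- function(g, pred_local) {
    g[g$p != paste0(OS_NS, pred_local) &
        !(g$p == paste0(RDFS_NS, "label") & pred_local == "label"), ,
      drop = FALSE]
  }
  # removing the label
  r <- validate_shapes(drop_pred(g, "label"))
  expect_false(r$conforms)
  expect_true("SpeciesLabelShape" %in% r$violations$shape)
  # removing identifiers
  r <- validate_shapes(g[g$p != paste0(OS_NS, "hasIdentifier"), ])
  expect_true("SpeciesIdentifierShape" %in% r$violations$shape)
  # removing a property unit
  r <- validate_shapes(g[g$p != paste0(OS_NS, "unit"), ])
  expect_false(r$conforms)
  expect_true(all(r$violations$shape == "PropertyValueShape"))
  expect_match(r$violations$message[1], "os:unit")

  # bond order zero
  bad <- g
  bad$o[bad$p == paste0(OS_NS, "hasBondOrder")] <- "0"
  if (any(bad$p == paste0(OS_NS, "hasBondOrder"))) {
    r <- validate_shapes(bad)
    expect_true("BondOrderShape" %in% r$violations$shape)
  }
})

test_that("recommended records require agent provenance in the graph", {
  sp <- species("u-rec", "CH4",
                identifiers = list(identifier_record("SMILES", "C",
                                                     provenance("src"))),
                properties = list(
                  make_bp_record(1, 111.6),
                  property_record("BoilingPoint", 2, 111.6, "K",
                                  provenance("PubChem agent"),
                                  is_recommended = TRUE)))
  g <- emit_species_triples(sp)
  expect_true(validate_shapes(g)$conforms)
  tampered <- g
  lblrow <- tampered$p == paste0(RDFS_NS, "label") & tampered$o == "PubChem agent"
  tampered$o[lblrow] <- "somewhere else"
  r <- validate_shapes(tampered)
  expect_true("RecommendedAgentShape" %in% r$violations$shape)
})

test_that("class assertions are idempotent and feed the class query", {
  res <- build_audit_store(list(
    list(uuid = "pent-2-ene", formula = "C5H10", tb = 309.2,
         bonds = list(atomic_bond(2, 3, 2)))))
  store <- res$store
  cls <- chemical_class(paste0(kg_namespace(), "ChemicalClass_alkene"),
                        "alkene")
  kg_add_triples(store, chemkg:::emit_class_triples(cls))
  n0 <- kg_size(store)
  expect_identical(nrow(query_boiling_by_class(store, "alkene")), 0L)

  add_class_assertion(store, res$iris[["pent-2-ene"]], cls$iri)
  expect_identical(kg_size(store), n0 + 1L)
  add_class_assertion(store, res$iris[["pent-2-ene"]], cls$iri)
  expect_identical(kg_size(store), n0 + 1L)
  q <- query_boiling_by_class(store, "alkene")
  expect_identical(unique(q$species_iri), unname(res$iris[["pent-2-ene"]]))
  expect_error(add_class_assertion(store, "urn:nope", cls$iri), "unknown species")
})

test_that("class queries descend the hierarchy and match a linear-scan oracle", {
  ns <- kg_namespace()
  alcohol <- chemical_class(paste0(ns, "ChemicalClass_alcohol"), "alcohol")
  alkanol <- chemical_class(paste0(ns, "ChemicalClass_alkanol"), "alkanol",
                            parents = alcohol$iri)
  set.seed(77)
  entries <- lapply(1:20, function(i) {
    n <- sample(1:8, 1)
    list(uuid = sprintf("qsp-%02d", i),
         formula = sprintf("C%dH%dO", n, 2 * n + 2),
         tb = 300 + 10 * n,
         classes = list(sample(list(alcohol, alkanol, NULL), 1)[[1]]))
  })
  entries <- lapply(entries, function(e) {
    if (is.null(e$classes[[1]])) e$classes <- list()
    e
  })
  res <- build_audit_store(entries)
  got <- query_boiling_by_class(res$store, "alcohol")
  direct_label <- vapply(entries, function(e) {
    if (length(e$classes)) e$classes[[1]]$label else ""
  }, character(1))
  want_iris <- sort(unname(res$iris[direct_label %in% c("alcohol", "alkanol")]))
  expect_identical(sort(unique(got$species_iri)), want_iris)
  # species tagged alkanol are included when querying the parent
  expect_true(any(direct_label == "alkanol"))
  expect_message(query_boiling_by_class(res$store, "no such class"), "no class")
})

test_that("the SPARQL engine answers the documented query shapes", {
  st <- kg_store()
  kg_add_triples(st, data.frame(s = "urn:a", p = "urn:p", o = "urn:b",
                                type = "iri"))
  one <- sparql(st, "SELECT ?x WHERE { ?x <urn:p> <urn:b> }")
  expect_identical(one$x, "urn:a")
  expect_false(sparql(st, "ASK { <urn:a> <urn:p> <urn:missing> }"))
  expect_true(sparql(st, "ASK { <urn:a> <urn:p> ?o }"))
  expect_error(sparql(st, "SELECT ?x WHERE { ?x <urn:p %% }"),
               "character [0-9]+")
  expect_error(sparql(st, "CONSTRUCT { }"), "SELECT or ASK")
})

test_that("the class-trend SPARQL query equals the direct implementation", {
  lib <- gen_species_library(fixture_spec(seed = 3, n_species = 12))
  prov <- list_provider(lib$computed, lib$annotation, lib$species_classes,
                        lib$classes)
  store <- kg_store()
  set.seed(31)
  for (key in names(lib$computed)) ingest_species(key, prov, store)
  direct <- query_boiling_by_class(store, "alcohol")
  via_sparql <- sparql(store, sparql_boiling_by_class_query("alcohol"))
  expect_identical(nrow(direct), nrow(via_sparql))
  expect_identical(sort(unique(direct$species_iri)),
                   sort(unique(via_sparql$species)))
  expect_equal(sort(direct$tb_K), sort(via_sparql$tb))
  # filters and optional bindings behave
  hot <- sparql(store, "SELECT ?sp ?v WHERE { ?sp os:hasProperty ?p . ?p a os:BoilingPoint . ?p os:value ?v . FILTER(?v > 400) }")
  expect_true(all(hot$v > 400))
})
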