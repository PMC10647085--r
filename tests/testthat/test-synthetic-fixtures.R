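# Synthetic fixture generation: determinism, ground truth, ingestability.

test_that("generation is fully determined by the seed", {
  a <- gen_species_library(fixture_spec(seed = 5, n_species = 8))
  b <- gen_species_library(fixture_spec(seed = 5, n_species = 8))
  expect_identical(a, b)
  c <- gen_species_library(fixture_spec(seed = 6, n_species = 8))
  expect_false(identical(a$ground_truth, c$ground_truth))
  expect_identical(nrow(a$ground_truth), 8L)
})

test_that("outlier planting matches the requested rate at the extremes", {
  none <- fixture_spec(seed = 2, outlier_rate = 0)
  out <- gen_property_strings(350, "BoilingPoint", 8, none)
  expect_false(any(out$ground_truth$is_outlier))
  # every rendered value parses back within rounding of the true value
  expect_true(all(abs(out$ground_truth$rendered_value - 350) / 350 < 0.005))

  all_out <- fixture_spec(seed = 2, outlier_rate = 1)
  one <- gen_property_strings(350, "BoilingPoint", 1, all_out)
  expect_true(one$ground_truth$is_outlier)
  expect_gt(one$ground_truth$rendered_value, 2 * 350 * 0.95)
})

test_that("the methyl-acetate replay reproduces the five bundled strings", {
  out <- gen_property_strings(0, "BoilingPoint", replay = "methyl_acetate")
  expect_identical(out$strings, methyl_acetate_bp_strings())
  expect_identical(out$ground_truth$is_outlier, c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("generated payloads ingest without shape violations", {
  lib <- gen_species_library(fixture_spec(seed = 9, n_species = 10))
  prov <- list_provider(lib$computed, lib$annotation, lib$species_classes,
                        lib$classes)
  store <- kg_store()
  set.seed(10)
  for (key in names(lib$computed)) {
    expect_no_error(ingest_species(key, prov, store))
  }
  expect_true(validate_shapes(store)$conforms)
  # class assignments are consistent with generated formulas and structures
  for (rn in c("alkane", "alkene", "alkanol")) {
    expect_identical(nrow(check_class_consistency(store, rule_registry()[[rn]])),
                     0L)
  }
})

test_that("curation flags exactly the planted outliers beyond the threshold", {
  spec <- fixture_spec(seed = 21, outlier_rate = 0.35)
  hits <- 0L
  for (trial in 1:25) {
    true_tb <- 250 + trial * 7
    out <- gen_property_strings(true_tb, "BoilingPoint", 5, spec,
                                tag = paste0("cur/", trial))
    recs <- list()
    for (i in seq_along(out$strings)) {
      q <- parse_property_string(out$strings[i])[[1]]
      recs[[i]] <- build_property_record(to_canonical(q, "BoilingPoint"),
                                         "BoilingPoint", i, provenance("src"))
    }
    # need a clean majority for the recommended value to be well-defined
    if (sum(!out$ground_truth$is_outlier) <= length(recs) / 2) next
    rec <- select_recommended(recs)
    flagged <- attr(flag_discrepant(recs, rec), "flagged_positions")
    beyond <- which(abs(out$ground_truth$rendered_value - rec$value) /
                      rec$value > 0.20)
    expect_identical(sort(flagged), sort(beyond))
    # planted x2-x3 outliers always exceed the 20% threshold
    expect_true(all(which(out$ground_truth$is_outlier) %in% flagged))
    hits <- hits + length(flagged)
  }
  expect_gt(hits, 0L)
})

test_that("mixture spectra carry roles, jittered peaks and ground truth", {
  spec <- fixture_spec(seed = 33, n_species = 6)
  lib <- gen_species_library(spec)
  planted <- names(lib$computed)[c(2, 5)]
  obs <- gen_mixture_spectrum(lib, planted, spec)
  roles <- vapply(obs, `[[`, character(1), "role")
  expect_identical(sum(roles == "reference"), 1L)
  expect_identical(sum(roles == "solvent"), 1L)
  expect_identical(attr(obs, "planted"), planted)

  empty <- gen_mixture_spectrum(lib, character(), spec)
  expect_length(empty, 2L)

  broken <- lib
  broken$annotation[[planted[1]]]$spectra <- list()
  expect_error(gen_mixture_spectrum(broken, planted, spec), "no spectrum")

  replay <- gen_mixture_spectrum(lib, character(), spec, replay = "catholyte")
  shifts <- vapply(replay, `[[`, numeric(1), "shift")
  expect_identical(shifts, c(8.35, 4.9, 3.51, 2.6, 1.83, 1.04))
})

test_that("fixture directories round-trip through the provider", {
  lib <- gen_species_library(fixture_spec(seed = 13, n_species = 4))
  dir <- tempfile("fixtures-")
  write_fixture_dir(lib, dir)
  expect_true(all(file.exists(file.path(dir, c("computed.json", "annotation.json",
                                               "species_classes.json",
                                               "classes.json",
                                               "ground_truth.tsv")))))
  prov <- fixture_provider(dir)
  store <- kg_store()
  set.seed(14)
  key <- names(lib$computed)[1]
  iri <- ingest_species(key, prov, store)
  sp <- load_species(store, as.character(iri))
  expect_identical(sp$label, lib$ground_truth$label[1])
})

test_that("planted species are always recovered at stage 1", {
  spec <- fixture_spec(seed = 44, n_species = 10)
  lib <- gen_species_library(spec)
  prov <- list_provider(lib$computed, lib$annotation, lib$species_classes,
                        lib$classes)
  store <- kg_store()
  set.seed(45)
  iris <- vapply(names(lib$computed), function(k)
    as.character(ingest_species(k, prov, store)), character(1))
  all_lib <- nmr_species_library(store, iris)
  for (trial in 1:20) {
    pick <- sample(names(lib$computed), sample(1:3, 1))
    obs <- gen_mixture_spectrum(lib, pick, fixture_spec(seed = 100 + trial))
    stage1 <- vapply(match_species_to_spectrum(all_lib, obs),
                     `[[`, character(1), "species_iri")
    expect_true(all(iris[pick] %in% stage1))
  }
})
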