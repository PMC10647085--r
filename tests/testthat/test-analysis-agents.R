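# NMR mixture identification, co-solvent selection, trend fitting, audits.

test_that("candidate filtering enforces formula bounds and boiling point", {
  res <- build_audit_store(list(
    list(uuid = "formic", formula = "CH2O2", tb = 374),
    list(uuid = "pentanol", formula = "C5H12O", tb = 411),
    list(uuid = "dme", formula = "C2H6O", tb = 248.2),
    list(uuid = "no-bp", formula = "C2H4O2"),
    list(uuid = "amine", formula = "CH5N", tb = 340)))
  got <- filter_nmr_candidates(res$store)
  expect_identical(got, unname(res$iris[["formic"]]))
})

test_that("minor peaks are pruned at 20% of the highest intensity", {
  pk <- function(pos, int) peak(pos, int)
  kept <- prune_minor_peaks(list(pk(1, 100), pk(2, 15), pk(3, 30)))
  expect_equal(vapply(kept, `[[`, numeric(1), "intensity"), c(100, 30))
  single <- prune_minor_peaks(list(pk(5, 7)))
  expect_length(single, 1L)
  equal <- prune_minor_peaks(list(pk(1, 40), pk(2, 40), pk(3, 40)))
  expect_length(equal, 3L)
  expect_error(prune_minor_peaks(list()), "empty")
})

test_that("stage-1 matching applies the +/- window to analyte peaks only", {
  obs <- list(observed_peak(8.35, "singlet"), observed_peak(3.51, "quartet"))
  lib <- list(close = list(peak(8.30, 100, "singlet")),
              far = list(peak(3.20, 100, "singlet")),
              partial = list(peak(8.30, 100), peak(3.20, 100)))
  got <- match_species_to_spectrum(lib, obs, window = 0.2)
  expect_identical(vapply(got, `[[`, character(1), "species_iri"), "close")
  expect_equal(got[[1]]$matched_pairs[[1]]$observed$shift, 8.35)
  expect_length(match_species_to_spectrum(list(), obs), 0L)

  # reference/solvent peaks never cover a library peak
  obs2 <- list(observed_peak(2.6, "singlet", role = "reference"))
  lib2 <- list(dmso_like = list(peak(2.55, 100, "singlet")))
  expect_length(match_species_to_spectrum(lib2, obs2), 0L)
})

test_that("stage-2 refinement checks multiplicity and window crowding", {
  obs <- list(observed_peak(8.35, "singlet"), observed_peak(1.83, "singlet"))
  lib <- list(
    wrong_mult = list(peak(8.30, 100, "doublet")),
    unknown_mult = list(peak(8.30, 100)),
    crowded = list(peak(1.70, 100, "singlet"), peak(1.95, 100, "singlet")))
  stage1 <- match_species_to_spectrum(lib, obs)
  expect_setequal(vapply(stage1, `[[`, character(1), "species_iri"),
                  c("wrong_mult", "unknown_mult", "crowded"))
  stage2 <- refine_by_multiplicity(stage1, obs)
  expect_identical(stage2, "unknown_mult")
})

test_that("the catholyte spectrum identifies exactly the four planted species", {
  fx <- catholyte_fixture_store()
  hits <- identify_mixture(fx$store, catholyte_observed_peaks())
  expect_setequal(hits, fx$expected)
  expect_length(intersect(hits, fx$decoys), 0L)
  # and the decoys fail for the documented reasons: one at stage 1, two at stage 2
  cands <- filter_nmr_candidates(fx$store)
  expect_setequal(cands, c(fx$expected, fx$decoys))
  lib <- nmr_species_library(fx$store, cands)
  stage1 <- vapply(match_species_to_spectrum(lib, catholyte_observed_peaks()),
                   `[[`, character(1), "species_iri")
  expect_length(setdiff(fx$decoys, stage1), 1L)
})

test_that("widening the NMR window never removes a stage-1 candidate", {
  set.seed(808)
  for (trial in 1:30) {
    obs <- lapply(seq_len(sample(2:5, 1)), function(i) {
      observed_peak(runif(1, 0.5, 10))
    })
    lib <- stats::setNames(lapply(1:6, function(i) {
      lapply(seq_len(sample(1:3, 1)), function(j) peak(runif(1, 0.5, 10), 100))
    }), paste0("sp", 1:6))
    narrow <- vapply(match_species_to_spectrum(lib, obs, window = 0.2),
                     `[[`, character(1), "species_iri")
    wide <- vapply(match_species_to_spectrum(lib, obs, window = 0.5),
                   `[[`, character(1), "species_iri")
    expect_true(all(narrow %in% wide))
  }
})

test_that("co-solvent selection applies boiling-point gap, hazards and cap", {
  ns <- kg_namespace()
  alcohol <- chemical_class(paste0(ns, "ChemicalClass_alcohol"), "alcohol")
  entries <- list(
    list(uuid = "ref-sol", formula = "C3H8O", tb = 400,
         classes = list(alcohol)),
    list(uuid = "too-close", formula = "CH4O", tb = 386,
         classes = list(alcohol)),
    list(uuid = "good", formula = "C2H6O", tb = 415,
         classes = list(alcohol)),
    list(uuid = "hazardous", formula = "C4H10O", tb = 430,
         classes = list(alcohol),
         ghs = list(ghs_statement("H350", "may cause cancer"))),
    list(uuid = "too-hot", formula = "C6H14O", tb = 445,
         classes = list(alcohol)),
    list(uuid = "not-alcohol", formula = "C5H12", tb = 430),
    list(uuid = "no-bp-ref", formula = "C2H6"))
  res <- build_audit_store(entries)
  got <- select_cosolvents(res$store, res$iris[["ref-sol"]], "alcohol")
  expect_setequal(got, unname(res$iris[c("good", "too-hot")]))
  capped <- select_cosolvents(res$store, res$iris[["ref-sol"]], "alcohol",
                              tb_max_K = 423.15)
  expect_identical(capped, unname(res$iris[["good"]]))
  expect_error(select_cosolvents(res$store, res$iris[["no-bp-ref"]], "alcohol"),
               "recommended boiling point")

  # the gap criterion is symmetric between candidate and reference
  for (a in c("ref-sol", "good", "too-close")) {
    for (b in setdiff(c("ref-sol", "good", "too-close"), a)) {
      tb <- function(u) query_boiling_by_class(res$store, "alcohol")
      pass_ab <- res$iris[[b]] %in% select_cosolvents(res$store, res$iris[[a]],
                                                      "alcohol",
                                                      excluded_hazard_prefixes = character())
      pass_ba <- res$iris[[a]] %in% select_cosolvents(res$store, res$iris[[b]],
                                                      "alcohol",
                                                      excluded_hazard_prefixes = character())
      expect_identical(pass_ab, pass_ba)
    }
  }
})

test_that("cube-root fitting recovers exact and noisy coefficients", {
  n <- 1:10
  exact <- fit_cube_root(data.frame(n = n, tb = 100 * n^(1 / 3) + 50))
  expect_equal(exact$a, 100, tolerance = 1e-6)
  expect_equal(exact$b, 50, tolerance = 1e-6)
  expect_lt(exact$residual_ss, 1e-12)

  two <- fit_cube_root(data.frame(n = c(2, 9), tb = c(260, 330)))
  expect_equal(two$residual_ss, 0, tolerance = 1e-18)
  expect_equal(extrapolate_bp(two, 2), 260)
  expect_equal(extrapolate_bp(two, 9), 330)

  set.seed(909)
  noisy_tb <- 100 * n^(1 / 3) + 50 + rnorm(10, 0, 2)
  fit <- fit_cube_root(data.frame(n = n, tb = noisy_tb))
  grid <- oracle_grid_fit(n, noisy_tb, c(90, 110), c(40, 60), 0.05)
  expect_equal(fit$a, unname(grid["a"]), tolerance = 0.05)
  expect_equal(fit$b, unname(grid["b"]), tolerance = 0.05)

  # analytic normal-equations solution
  x <- n^(1 / 3)
  beta <- solve(rbind(c(length(x), sum(x)), c(sum(x), sum(x^2))),
                c(sum(noisy_tb), sum(x * noisy_tb)))
  expect_equal(fit$b, beta[1], tolerance = 1e-9)
  expect_equal(fit$a, beta[2], tolerance = 1e-9)

  expect_error(fit_cube_root(data.frame(n = c(3, 3), tb = c(1, 2))), "distinct")
})

test_that("extrapolation follows the fitted cube-root curve", {
  fit <- structure(list(a = 100, b = 50), class = "trend_fit")
  expect_equal(extrapolate_bp(fit, 8), 250)
  expect_equal(extrapolate_bp(fit, 1), 150)
  preds <- extrapolate_bp(fit, 1:20)
  expect_true(all(diff(preds) > 0))
})

test_that("missing-tag detection and consistency checks follow the rules", {
  ns <- kg_namespace()
  alkene_cls <- chemical_class(paste0(ns, "ChemicalClass_alkene"), "alkene")
  entries <- list(
    list(uuid = "pent-2-ene", formula = "C5H10", tb = 309,
         atoms = lapply(1:5, function(i) atom(i, "C")),
         bonds = list(atomic_bond(1, 2), atomic_bond(2, 3, 2),
                      atomic_bond(3, 4), atomic_bond(4, 5))),
    list(uuid = "tagged-ethene", formula = "C2H4", tb = 169,
         atoms = list(atom(1, "C"), atom(2, "C")),
         bonds = list(atomic_bond(1, 2, 2)),
         classes = list(alkene_cls)),
    list(uuid = "alkadiene", formula = "C20H38", tb = 600,
         atoms = lapply(1:20, function(i) atom(i, "C")),
         bonds = c(list(atomic_bond(1, 2, 2), atomic_bond(3, 4, 2)),
                   lapply(4:19, function(i) atomic_bond(i, i + 1))),
         classes = list(alkene_cls)),
    list(uuid = "plain-alkane", formula = "C3H8", tb = 231,
         atoms = lapply(1:3, function(i) atom(i, "C")),
         bonds = list(atomic_bond(1, 2), atomic_bond(2, 3))))
  res <- build_audit_store(entries)
  rule <- rule_registry()$alkene

  missing <- find_missing_class_tags(res$store, rule)
  expect_identical(missing, unname(res$iris[["pent-2-ene"]]))

  bad <- check_class_consistency(res$store, rule)
  expect_identical(bad$species_iri, unname(res$iris[["alkadiene"]]))
  expect_match(bad$reason, "C20H38")

  # tagging the missing species clears the report
  add_class_assertion(res$store, res$iris[["pent-2-ene"]], alkene_cls$iri)
  expect_length(find_missing_class_tags(res$store, rule), 0L)

  empty <- check_class_consistency(kg_store(), rule)
  expect_identical(nrow(empty), 0L)
})

test_that("audits agree with a linear-scan oracle on a random library", {
  lib <- gen_species_library(fixture_spec(seed = 17, n_species = 25))
  prov <- list_provider(lib$computed, lib$annotation, lib$species_classes,
                        lib$classes)
  store <- kg_store()
  set.seed(18)
  keys <- names(lib$computed)
  iris <- vapply(keys, function(k) as.character(ingest_species(k, prov, store)),
                 character(1))
  rule <- rule_registry()$alkene
  # remove the alkene tags from a third of the alkenes, then audit
  df <- store$triples
  alkene_iri <- chemkg:::class_iri_for_source_id("fix:alkene")
  tagged <- iris[lib$ground_truth$class == "alkene"]
  drop <- tagged[seq_along(tagged) %% 3 == 0]
  store$triples <- df[!(df$s %in% drop & df$o == alkene_iri), ]

  got <- sort(find_missing_class_tags(store, rule))
  expect_identical(got, sort(unname(drop)))
  expect_identical(nrow(check_class_consistency(store, rule)), 0L)
})
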