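test_that("identical configs and seeds reproduce the dataset byte for byte", {
  dir <- withr::local_tempdir()
  p1 <- write_synthetic_dataset(small_config(seed = 4), file.path(dir, "a"))
  p2 <- write_synthetic_dataset(small_config(seed = 4), file.path(dir, "b"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }
  # a different seed changes the library
  p3 <- write_synthetic_dataset(small_config(seed = 5), file.path(dir, "c"))
  expect_false(identical(readLines(p1[["library"]]), readLines(p3[["library"]])))
})

test_that("the realised active fraction matches the configured background", {
  lib <- generate_library(generator_config(seed = 2))
  truth <- lib$truth$compound_truth
  expect_equal(mean(truth$active), 0.25, tolerance = 0.03)
  expect_identical(nrow(lib$compounds), 2000L)
})

test_that("every emitted structure parses cleanly", {
  cfg <- small_config(seed = 9)
  lib <- generate_library(cfg)
  drugs <- generate_drug_panels(cfg, lib$truth)
  refs <- generate_reference_sets(cfg)
  smiles <- c(lib$compounds$smiles, drugs$panels$smiles,
              refs$actives$smiles, refs$decoys$smiles)
  expect_true(all(validate_smiles(smiles)))
})

test_that("an enrichment factor of one marks no plant as enriched", {
  cfg <- small_config(seed = 3, enriched_active_fraction = 0.25)
  lib <- generate_library(cfg)
  expect_identical(sum(lib$truth$plant_truth$enriched), 0L)
  # and all plants then sample uniformly: sizes stay in the ordinary range
  expect_true(all(lengths(lib$plants$compound_ids) <=
                  cfg$compounds_per_plant[2]))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_plants = 5, enriched_plants = 10),
               "enriched_plants")
  expect_error(generator_config(enriched_plants = 2, isolate_plants = 3),
               "isolate_plants")
  expect_error(generator_config(background_active_fraction = 1.2), "fractions")
  expect_error(generate_library(generator_config(n_compounds = 60000L)),
               "capacity")
})

test_that("panel sizes and stage labels follow the configuration", {
  cfg <- small_config(seed = 1)
  lib <- generate_library(cfg)
  drugs <- generate_drug_panels(cfg, lib$truth)
  got <- table(drugs$panels$stage)
  expect_identical(got[["preclinical"]], 12L)
  expect_identical(got[["clinical"]], 20L)
  expect_identical(got[["approved"]], 30L)
  expect_false(anyDuplicated(drugs$panels$drug_id) > 0)
  expect_identical(length(drugs$planned$isolate_drug_ids), 2L)
  expect_true(all(drugs$planned$isolate_drug_ids %in%
                  drugs$panels$drug_id[drugs$panels$stage == "approved"]))
})

test_that("actives sit closer to the drug panels than inactives (separability)", {
  cfg <- small_config(seed = 8)
  lib <- generate_library(cfg)
  drugs <- generate_drug_panels(cfg, lib$truth)
  truth <- lib$truth$compound_truth
  fps <- maccs_fingerprint(lib$compounds$smiles, lib$compounds$compound_id)
  dfps <- maccs_fingerprint(drugs$panels$smiles, drugs$panels$drug_id)
  tc <- tanimoto_matrix(fps, dfps)
  best <- apply(tc, 1, max)
  margin <- mean(best[truth$active]) - mean(best[!truth$active])
  expect_gt(margin, 0.1)
})

test_that("approved-panel coverage of true actives lands near the target", {
  cfg <- generator_config(seed = 1)
  lib <- generate_library(cfg)
  drugs <- generate_drug_panels(cfg, lib$truth)
  truth <- lib$truth$compound_truth
  act <- truth$compound_id[truth$active]
  fps <- maccs_fingerprint(
    lib$compounds$smiles[match(act, lib$compounds$compound_id)], act)
  ap <- drugs$panels[drugs$panels$stage == "approved", ]
  afps <- maccs_fingerprint(ap$smiles, ap$drug_id)
  coverage <- mean(apply(tanimoto_matrix(fps, afps), 1, max) >= 0.70)
  expect_equal(coverage, cfg$drug_similarity_target, tolerance = 0.10 / 0.75)
})
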