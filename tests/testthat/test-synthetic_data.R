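test_that("generator specs are validated and seeds are mandatory", {
  expect_error(generator_spec(), "seed is mandatory")
  expect_error(generator_spec(n_total = 0, seed = 1))
  expect_error(generator_spec(origin_fractions = c(synthetic = 0.9,
                                                   natural = 0.2,
                                                   undefined = 0.2),
                              seed = 1))
})

test_that("origin counts follow largest-remainder apportionment", {
  # the default fractions at full scale give exactly 287/130/125
  expect_equal(pmtscreen:::apportion(542, c(0.530, 0.240, 0.230)),
               c(287L, 130L, 125L))
  expect_equal(sum(pmtscreen:::apportion(100, c(1, 1, 1) / 3)), 100)
})

test_that("rosters are reproducible and pass ingestion with zero rejects", {
  spec <- generator_spec(n_total = 60, seed = 23)
  r1 <- generate_roster(spec)
  r2 <- generate_roster(spec)
  expect_identical(r1$roster$smiles, r2$roster$smiles)
  expect_identical(r1$truth, r2$truth)
  expect_equal(nrow(attr(r1$roster, "rejects")), 0)
  expect_equal(nrow(r1$roster), 60)
  # truth pairs one-to-one with the roster
  expect_identical(r1$truth$compound_id, r1$roster$compound_id)
  # origin labels follow the requested fractions
  expect_equal(unname(table(r1$truth$origin)[c("synthetic", "natural",
                                               "undefined")]),
               pmtscreen:::apportion(60, spec$origin_fractions)[c(1, 2, 3)],
               ignore_attr = TRUE)
})

test_that("an all-PFAS mix is fully noncyclic and halogen-flagged", {
  spec <- generator_spec(
    n_total = 25,
    origin_fractions = c(synthetic = 1, natural = 0, undefined = 0),
    family_weights = list(synthetic = c(pfas = 1),
                          natural = c(pfas = 1),
                          undefined = c(pfas = 1)),
    seed = 31)
  ros <- generate_roster(spec)$roster
  expect_true(all(is_noncyclic(ros)))
  fp <- maccs_fingerprint(ros)
  expect_true(all(fp[, "134"] == 1L))
})

test_that("zero-noise properties let the rule screen recover the truth", {
  spec <- generator_spec(n_total = 80, property_coverage = 1,
                         label_noise = 0, seed = 37)
  g <- generate_roster(spec)
  props <- as_properties(generate_properties(g$roster, g$truth, spec))
  recovered <- vapply(g$roster$compound_id, function(id) {
    assess_compound(property_record(props, id))$hazard_class
  }, character(1))
  expect_identical(unname(recovered), g$truth$true_class)
})

test_that("label noise corrupts the recovery at the stated rate", {
  spec <- generator_spec(n_total = 150, property_coverage = 1,
                         label_noise = 0.10, seed = 41)
  g <- generate_roster(spec)
  props <- as_properties(generate_properties(g$roster, g$truth, spec))
  recovered <- vapply(g$roster$compound_id, function(id) {
    assess_compound(property_record(props, id))$hazard_class
  }, character(1))
  mismatch <- mean(recovered != g$truth$true_class)
  # binomial band around 10% at n = 150 (3 sigma ~ 7.3%)
  expect_gt(mismatch, 0.02)
  expect_lt(mismatch, 0.20)
})

test_that("zero coverage routes every compound to the ML screen", {
  spec <- generator_spec(n_total = 20, property_coverage = 0, seed = 43)
  g <- generate_roster(spec)
  props <- generate_properties(g$roster, g$truth, spec)
  expect_equal(nrow(props), 0)
})

test_that("training sets carry the planted rule and refuse degeneracy", {
  spec <- generator_spec(seed = 29)
  tr <- generate_training_set(spec, n = 80)
  expect_equal(length(tr$labels), 80)
  expect_true(all(sort(unique(tr$labels)) == c(0, 1)))
  # labels equal the rule evaluated on the returned features
  expect_identical(tr$labels,
                   as.integer(tr$features$logP_estimate < spec$logp_cutoff &
                                tr$features$n_halogen >= 1))
  # identical seeds give identical labels
  tr2 <- generate_training_set(spec, n = 80)
  expect_identical(tr$labels, tr2$labels)
  expect_error(generate_training_set(spec, n = 40,
                                     rule_features = c("no_such", "nope")),
               "absent from descriptor set")
})

test_that("concentration tables separate EF and NER by orders of magnitude", {
  spec <- generator_spec(n_total = 40, seed = 47)
  ros <- generate_roster(spec)$roster
  conc <- generate_concentrations(ros, spec)
  expect_true(all(conc$depth_cm >= 0 & conc$depth_cm <= 150))
  expect_true(all(conc$conc_ng_g_dw >= 0))
  ratio <- mean(conc$conc_ng_g_dw[conc$fraction == "NER"]) /
    mean(conc$conc_ng_g_dw[conc$fraction == "EF"])
  expect_gt(ratio, 100)
  expect_lt(ratio, 10000)
  # reproducible; and a site-free spec yields a valid empty table
  conc2 <- generate_concentrations(ros, spec)
  expect_identical(conc, conc2)
  spec0 <- generator_spec(n_total = 40, n_sites = 0, seed = 47)
  expect_equal(nrow(generate_concentrations(ros, spec0)), 0)
})

test_that("simulated studies write ingestible files", {
  spec <- generator_spec(n_total = 30, seed = 53)
  dir <- withr::local_tempdir()
  sim <- simulate_study(spec, dir = dir, n_train = 40)
  ros <- read_roster(file.path(dir, "roster.csv"))
  expect_equal(nrow(ros), 30)
  expect_equal(nrow(attr(ros, "rejects")), 0)
  props <- read_properties(file.path(dir, "properties.csv"))
  expect_s3_class(props, "pmt_properties")
  kn <- read_known_list(file.path(dir, "known_list.csv"))
  expect_true(all(kn$key_type == "structure"))
  conc <- read_concentrations(file.path(dir, "concentrations.csv"))
  expect_equal(nrow(attr(conc, "rejects")), 0)
})
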