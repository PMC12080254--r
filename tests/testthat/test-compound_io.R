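test_that("roster reading accepts valid rows and collects rejects", {
  df <- data.frame(
    compound_id = c("A", "B", "C"),
    name = c("ethanol", "benzene", "carbon tet"),
    smiles = c("CCO", "c1ccccc1", "ClC(Cl)(Cl)Cl"),
    origin = c("synthetic", "natural", NA),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  ros <- read_roster(f)
  expect_s3_class(ros, "pmt_roster")
  expect_equal(nrow(ros), 3)
  expect_equal(ros$origin, c("synthetic", "natural", "undefined"))
  expect_equal(nrow(attr(ros, "rejects")), 0)

  # malformed structure is rejected, not fatal; counts add up
  df2 <- rbind(df, data.frame(compound_id = "D", name = "broken",
                              smiles = "C1CC", origin = "synthetic"))
  write.csv(df2, f, row.names = FALSE)
  expect_warning(ros2 <- read_roster(f), "rejected")
  expect_equal(nrow(ros2), 3)
  rej <- attr(ros2, "rejects")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$compound_id, "D")
  expect_equal(nrow(ros2) + nrow(rej), nrow(df2))
})

test_that("duplicate ids and unknown origin labels are errors", {
  expect_error(as_roster(data.frame(compound_id = c("A", "A"),
                                    smiles = c("CCO", "CCC"))),
               "duplicate compound_id")
  expect_error(as_roster(data.frame(compound_id = "A", smiles = "CCO",
                                    origin = "mineral")),
               "unrecognized origin")
})

test_that("dedup merges structures by canonical form, keeping the first id", {
  ros <- as_roster(data.frame(
    compound_id = c("A", "B", "C", "D"),
    smiles = c("CCO", "OCC", "CCC", "C(Cl)(Cl)(Cl)Cl"),
    origin = c("undefined", "synthetic", "natural", "undefined"),
    stringsAsFactors = FALSE))
  dd <- canonicalize_and_dedup(ros)
  expect_equal(nrow(dd), 3)
  expect_equal(dd$compound_id, c("A", "C", "D"))
  # merged record takes the synthetic-over-undefined origin precedence
  expect_equal(dd$origin[dd$compound_id == "A"], "synthetic")
  log <- attr(dd, "merge_log")
  expect_equal(log$dropped_id, "B")

  # two spellings of tetrachloromethane collapse to one canonical form
  ros2 <- as_roster(data.frame(compound_id = c("X", "Y"),
                               smiles = c("ClC(Cl)(Cl)Cl",
                                          "C(Cl)(Cl)(Cl)Cl")))
  expect_equal(nrow(canonicalize_and_dedup(ros2)), 1)
  # distinct molecules stay distinct
  ros3 <- as_roster(data.frame(compound_id = c("X", "Y"),
                               smiles = c("CCO", "CCC")))
  expect_equal(nrow(canonicalize_and_dedup(ros3)), 2)
})

test_that("dedup is idempotent", {
  ros <- as_roster(data.frame(
    compound_id = paste0("M", 1:5),
    smiles = c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1", "CCC")))
  once <- canonicalize_and_dedup(ros)
  twice <- canonicalize_and_dedup(once)
  for (col in names(once)) expect_identical(once[[col]], twice[[col]])
  expect_equal(nrow(attr(twice, "merge_log")), 0)
})

test_that("roster round-trips through write/read with identical structures", {
  ros <- as_roster(data.frame(
    compound_id = c("A", "B"),
    smiles = c("OCC", "C1=CC=CC=C1"),
    origin = c("natural", "synthetic"),
    cas = c("64-17-5", NA), stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_roster(ros, f)
  back <- read_roster(f)
  expect_equal(back$canonical_smiles, ros$canonical_smiles)
  expect_equal(back$origin, ros$origin)
  expect_equal(back$cas, ros$cas)
})

test_that("roster reading from SDF recovers ids and structures", {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(A = "CCO",
                                                  B = "c1ccccc1")))
  f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  ros <- read_roster(f)
  expect_equal(nrow(ros), 2)
  expect_equal(ros$canonical_smiles, canonical_smiles(c("CCO", "c1ccccc1")))
  expect_true(all(ros$origin == "undefined"))
})

test_that("property table parsing enforces the pH window and rejects bad rows", {
  df <- data.frame(
    compound_id = c("A", "A", "A", "B", "B", "C"),
    property = c("half_life_freshwater_d", "log_koc", "tox_flag",
                 "log_koc", "half_life_freshwater_d", "log_koc"),
    value = c("50", "2.5", "aquatic_tox", "1.4", "-3", "2.2"),
    ph = c(NA, 7, NA, 10, NA, 6.5), stringsAsFactors = FALSE)
  expect_warning(props <- as_properties(df), "pH")
  recA <- property_record(props, "A")
  expect_equal(recA$half_lives, 50)
  expect_equal(recA$log_koc_by_ph$log_koc, 2.5)
  expect_equal(recA$tox_flags, "aquatic_tox")
  expect_equal(recA$evidence_quality, "experimental")
  # pH 10 row dropped but the compound still counts as having evidence
  recB <- property_record(props, "B")
  expect_equal(nrow(recB$log_koc_by_ph), 0)
  expect_equal(recB$evidence_quality, "experimental")
  # negative half-life was rejected
  rej <- attr(props, "rejects")
  expect_true(any(rej$compound_id == "B" & grepl("half-life", rej$reason)))
  # absent compound gets the explicit no-evidence record
  recZ <- property_record(props, "Z")
  expect_equal(recZ$evidence_quality, "none")
  expect_length(recZ$half_lives, 0)
})

test_that("concentration ingestion applies the depth window and value checks", {
  df <- data.frame(
    compound_id = c("A", "A", "B", "B"),
    site_id = "S1", latitude = 33,
    depth_cm = c(10, 200, 50, 30),
    fraction = c("EF", "EF", "XX", "NER"),
    conc_ng_g_dw = c(12, 5, 7, -1), stringsAsFactors = FALSE)
  expect_warning(conc <- as_concentrations(df), "rejected")
  expect_equal(nrow(conc), 1)
  expect_equal(nrow(attr(conc, "rejects")), 3)
})

test_that("known list canonicalizes structure keys and flags conflicts", {
  kn <- as_known_list(data.frame(
    match_key = c("OCC", "7446-09-5"),
    listed_class = c("vPvM", "not_PMT_vPvM")))
  expect_equal(kn$key_type, c("structure", "cas"))
  expect_equal(kn$match_key[1], canonical_smiles("CCO"))
  expect_error(as_known_list(data.frame(
    match_key = c("CCO", "OCC"),
    listed_class = c("vPvM", "PMT"))), "conflicting")
  # identical duplicates are tolerated (collapsed)
  kn2 <- as_known_list(data.frame(match_key = c("CCO", "OCC"),
                                  listed_class = c("vPvM", "vPvM")))
  expect_equal(nrow(kn2), 1)
})
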