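test_that("persistence tiers follow the 40/60 day cutoffs", {
  expect_equal(assess_persistence(50), "P")
  expect_equal(assess_persistence(1000), "vP")
  expect_equal(assess_persistence(numeric(0)), "unknown")
  # boundary values are not above threshold
  expect_equal(assess_persistence(40), "not_P")
  expect_equal(assess_persistence(60), "P")
  # median aggregation by default, max as worst case
  expect_equal(assess_persistence(c(10, 50, 70)), "P")
  cfg <- pmt_config(halflife_agg = "max")
  expect_equal(assess_persistence(c(10, 50, 70), cfg), "vP")
})

test_that("mobility tiers follow the strict <3.0 / <2.0 log Koc cutoffs", {
  koc <- function(...) data.frame(ph = 7, log_koc = c(...))
  expect_equal(assess_mobility(koc(2.5)), "M")
  expect_equal(assess_mobility(koc(3.0)), "not_M")
  expect_equal(assess_mobility(koc(2.0)), "M")   # < 2.0 is strict
  expect_equal(assess_mobility(koc(1.99)), "vM")
  expect_equal(assess_mobility(NULL), "unknown")
  # minimum over the pH window: the most mobile observed form decides
  expect_equal(assess_mobility(data.frame(ph = c(5, 8),
                                          log_koc = c(1.0, 2.6))), "vM")
  expect_equal(min(1.0, 2.6), 1.0)  # brute-force aggregation check
  # rows outside pH 4-9 are ignored
  expect_equal(assess_mobility(data.frame(ph = c(3, 7),
                                          log_koc = c(0.5, 3.4))), "not_M")
})

test_that("toxicity is flag-based with explicit unknown", {
  expect_equal(assess_toxicity("endocrine_disruption"), "T")
  expect_equal(assess_toxicity(character(0), "experimental"),
               "not_established")
  expect_equal(assess_toxicity(character(0), "none"), "unknown")
})

test_that("tier combination matches the documented class logic", {
  expect_equal(combine_tiers("vP", "vM", "T"), "PMT_and_vPvM")
  expect_equal(combine_tiers("P", "M", "T"), "PMT")
  expect_equal(combine_tiers("P", "M", "not_established"), "not_PMT_vPvM")
  expect_equal(combine_tiers("vP", "vM", "not_established"), "vPvM")
  expect_equal(combine_tiers("vP", "vM", "unknown"), "vPvM")
  expect_equal(combine_tiers("unknown", "vM", "T"), "unresolved")
  expect_equal(combine_tiers("not_P", "unknown", "unknown"),
               "not_PMT_vPvM")
  expect_error(combine_tiers("maybe", "vM", "T"))
})

test_that("tiers are monotone in the underlying evidence", {
  tier_rank <- c(not_P = 0, P = 1, vP = 2)
  mob_rank <- c(not_M = 0, M = 1, vM = 2)
  set.seed(11)
  for (i in 1:200) {
    hl <- runif(sample(1:4, 1), 1, 120)
    t1 <- assess_persistence(hl)
    t2 <- assess_persistence(hl + runif(1, 0, 80))
    expect_gte(tier_rank[t2], tier_rank[t1])
    koc <- data.frame(ph = runif(2, 4, 9), log_koc = runif(2, 0, 6))
    m1 <- assess_mobility(koc)
    koc2 <- koc
    koc2$log_koc <- koc2$log_koc - runif(1, 0, 3)
    m2 <- assess_mobility(koc2)
    expect_gte(mob_rank[m2], mob_rank[m1])
  }
  # adding a flag never removes T
  expect_equal(assess_toxicity(c("CMR", "STOT_RE")), "T")
})

test_that("known-list lookup matches by canonical structure then CAS", {
  ros <- as_roster(data.frame(
    compound_id = c("A", "B", "C"),
    smiles = c("OCC", "CCC", "ClC(Cl)Cl"),
    cas = c(NA, "109-66-0", "67-66-3"), stringsAsFactors = FALSE))
  kn <- as_known_list(data.frame(
    match_key = c("CCO", "67-66-3"),
    listed_class = c("vPvM", "PMT")))
  hits <- lookup_known(ros, kn)
  expect_equal(hits$compound_id, c("A", "C"))
  expect_equal(hits$hazard_class, c("vPvM", "PMT"))
  expect_equal(hits$match_by, c("structure", "cas"))
  # different SMILES spelling of a listed structure still matches
  ros2 <- as_roster(data.frame(compound_id = "Z", smiles = "C(O)C"))
  expect_equal(lookup_known(ros2, kn)$hazard_class, "vPvM")
  # absent compound yields no row
  ros3 <- as_roster(data.frame(compound_id = "Q", smiles = "CCCCCC"))
  expect_equal(nrow(lookup_known(ros3, kn)), 0)
})

test_that("assess_compound composes tiers from a property record", {
  a <- assess_compound(prec(hl = c(80, 90),
                            koc = data.frame(ph = 7, log_koc = 1.2),
                            flags = "CMR"))
  expect_equal(a$hazard_class, "PMT_and_vPvM")
  b <- assess_compound(prec(quality = "none"))
  expect_equal(b$hazard_class, "unresolved")
})
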