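test_that("prevalence counts agree with brute-force substructure counts", {
  smis <- c(ccl4 = "ClC(Cl)(Cl)Cl", cbr4 = "BrC(Br)(Br)Br",
            hexane = "CCCCCC")
  fp <- maccs_fingerprint(smis)
  tab <- prevalence_table(fp, k = 166)
  # the halogen key (134) occurs in 2 of the 3 compounds
  expect_equal(tab$count[tab$key == 134], 2L)
  expect_equal(tab$proportion[tab$key == 134], 100 * 2 / 3)
  # the k = 1 head is the lowest-numbered key among those at max count
  top <- prevalence_table(fp, k = 1)
  max_count <- max(colSums(fp[, , drop = FALSE]))
  expect_equal(top$count, as.integer(max_count))
  candidates <- as.integer(colnames(fp)[colSums(fp) == max_count])
  expect_equal(top$key, min(candidates))

  # one halogenated compound alone: key 134 at 100%
  tab1 <- prevalence_table(fp, subset_ids = "ccl4", k = 40)
  expect_equal(tab1$proportion[tab1$key == 134], 100)

  # full table proportions equal per-key brute force on the fixture
  smis2 <- fixture_smiles()[1:15]
  fp2 <- maccs_fingerprint(smis2)
  orc <- oracle_maccs(smis2)
  tab2 <- prevalence_table(fp2, k = 200)
  brute <- colSums(orc)
  for (r in seq_len(nrow(tab2))) {
    expect_equal(tab2$count[r], unname(brute[as.character(tab2$key[r])]))
  }
})

test_that("prevalence tables are deterministic, bounded and monotone", {
  smis <- fixture_smiles()[1:12]
  fp <- maccs_fingerprint(smis)
  tab <- prevalence_table(fp, k = 10)
  expect_true(all(tab$count <= length(smis)))
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 100))
  # sorted by count desc then key asc
  expect_true(all(diff(tab$count) <= 0))
  ties <- split(tab$key, tab$count)
  expect_true(all(vapply(ties, function(k) all(diff(k) > 0), logical(1))))
  # removing a compound never increases any key count
  tab_small <- prevalence_table(fp, subset_ids = names(smis)[-1], k = 200)
  joined <- merge(as.data.frame(tab), as.data.frame(tab_small),
                  by = "key", suffixes = c("_all", "_small"))
  expect_true(all(joined$count_small <= joined$count_all))
  expect_error(prevalence_table(fp, subset_ids = character(0)), "empty")
  expect_error(prevalence_table(fp, subset_ids = "nonexistent"),
               "no fingerprint")
})

test_that("table contrast reports shared and unique keys", {
  smis <- fixture_smiles()[1:12]
  fp <- maccs_fingerprint(smis)
  a <- prevalence_table(fp, k = 5, label = "a")
  expect_length(contrast_tables(a, a)$unique_to_a, 0)
  expect_equal(contrast_tables(a, a)$shared, a$key)
  # disjoint tables of k = 3
  m <- matrix(0L, 2, 166, dimnames = list(c("x", "y"),
                                          as.character(1:166)))
  m["x", c(10, 20, 30)] <- 1L
  m["y", c(40, 50, 60)] <- 1L
  ta <- prevalence_table(m, "x", k = 3, label = "x")
  tb <- prevalence_table(m, "y", k = 3, label = "y")
  ct <- contrast_tables(ta, tb)
  expect_length(ct$unique_to_a, 3)
  expect_length(ct$unique_to_b, 3)
  expect_length(ct$shared, 0)
  expect_error(contrast_tables(ta, prevalence_table(m, "y", k = 2)),
               "different k")
})

test_that("planted strata separate by their characteristic halogen keys", {
  # PFAS-like stratum vs brominated-natural stratum
  pfas <- c(p1 = "OC(=O)C(F)(F)F",
            p2 = "OC(=O)C(F)(F)C(F)(F)F",
            p3 = "OS(=O)(=O)C(F)(F)C(F)(F)F",
            p4 = "OCCC(F)(F)C(F)(F)F")
  brom <- c(b1 = "Oc1ccc(Br)cc1", b2 = "Oc1cc(Br)cc(Br)c1",
            b3 = "COc1ccc(Br)cc1", b4 = "OC(=O)CBr")
  fp <- maccs_fingerprint(c(pfas, brom))
  ta <- prevalence_table(fp, names(pfas), k = 20, label = "synthetic")
  tb <- prevalence_table(fp, names(brom), k = 20, label = "natural")
  ct <- contrast_tables(ta, tb)
  expect_true(42 %in% ct$unique_to_a)  # fluorine key only in PFAS stratum
  expect_true(46 %in% ct$unique_to_b)  # bromine key only in natural stratum
})

test_that("noncyclic fraction counts ring-free molecular graphs", {
  ros <- as_roster(data.frame(
    compound_id = c("benzene", "hexane", "cyclohexane"),
    smiles = c("c1ccccc1", "CCCCCC", "C1CCCCC1")))
  expect_equal(noncyclic_fraction(ros), 100 / 3)
  chains <- as_roster(data.frame(compound_id = c("a", "b"),
                                 smiles = c("CCC", "CCO")))
  expect_equal(noncyclic_fraction(chains), 100)
  rings <- as_roster(data.frame(compound_id = c("a", "b"),
                                smiles = c("C1CC1", "c1ccccc1")))
  expect_equal(noncyclic_fraction(rings), 0)
  expect_error(noncyclic_fraction(ros, character(0)), "empty")
})

test_that("prevalence export writes CSV and Markdown layouts", {
  fp <- maccs_fingerprint(c(a = "ClC(Cl)(Cl)Cl", b = "Clc1ccccc1"))
  tab <- prevalence_table(fp, k = 5, label = "demo")
  path <- file.path(withr::local_tempdir(), "tab")
  export_prevalence(tab, path)
  expect_true(file.exists(paste0(path, ".csv")))
  md <- readLines(paste0(path, ".md"))
  expect_true(any(grepl("Feature number", md)))
  back <- read.csv(paste0(path, ".csv"))
  expect_equal(back$key, tab$key)
})
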