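# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; nothing is read from disk.

# A diverse fixture of common environmental chemicals (SMILES).
fixture_smiles <- function() c(
  pfoa = "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  pfbs = "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  tfa = "OC(=O)C(F)(F)F",
  tcep = "O=P(OCCCl)(OCCCl)OCCCl",
  tcpp = "CC(COP(=O)(OCC(C)Cl)OCC(C)Cl)Cl",
  tep = "O=P(OCC)(OCC)OCC",
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  phenol = "Oc1ccccc1",
  chlorophenol = "Oc1ccc(Cl)cc1",
  dichlorophenol = "Oc1ccc(Cl)cc1Cl",
  trichlorophenol = "Oc1cc(Cl)c(Cl)cc1Cl",
  chlorobenzene = "Clc1ccccc1",
  bromophenol = "Oc1ccc(Br)cc1",
  dibromophenol = "Oc1cc(Br)cc(Br)c1",
  bromoanisole = "COc1ccc(Br)cc1",
  chloroacetic = "OC(=O)CCl",
  dichloroacetic = "OC(=O)C(Cl)Cl",
  bromoacetic = "OC(=O)CBr",
  chloroethanol = "OCCCl",
  bromoethanol = "OCCBr",
  dichloropropane = "CC(Cl)CCl",
  chlorohexane = "CCCCCCCl",
  hexane = "CCCCCC",
  octane = "CCCCCCCC",
  cyclohexane = "C1CCCCC1",
  ethanol = "CCO",
  butanol = "CCCCO",
  acetone = "CC(C)=O",
  butyric = "CCCC(=O)O",
  ccl4 = "ClC(Cl)(Cl)Cl",
  chloroform = "ClC(Cl)Cl",
  dcm = "ClCCl",
  bromoform = "BrC(Br)Br",
  tbca = "OC(=O)C(Br)(Br)Br",
  limonene = "CC(=C)C1CCC(C)=CC1",
  pinene = "CC1=CCC2CC1C2(C)C",
  linalool = "CC(C)=CCCC(C)(O)C=C",
  geraniol = "CC(C)=CCCC(C)=CCO",
  menthol = "CC1CCC(C(C)C)C(O)C1",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  atrazine = "CCNc1nc(Cl)nc(NC(C)C)n1",
  naphthalene = "c1ccc2ccccc2c1",
  ddt = "Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl",
  triclosan = "Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl",
  methylparaben = "COC(=O)c1ccc(O)cc1",
  tribromoanisole = "COc1cc(Br)cc(Br)c1Br",
  mcpa = "Cc1ccc(OCC(O)=O)c(Cl)c1",
  trichloroethene = "ClC=C(Cl)Cl",
  nacl_acetate = "CC(=O)O.CCO"
)

# Independent MACCS oracle: per-key brute-force substructure counting via
# the public SMARTS dictionary and the generic SMARTS matcher, with the
# three structural keys computed by routes independent of the package's
# fingerprint path (ring perception for key 125, fragment notation for
# key 166).
oracle_maccs <- function(smiles) {
  keys <- maccs_keys()
  can <- canonical_smiles(smiles)
  ids <- names(smiles)
  sdf <- pmtscreen:::mol_sdfset(can, ids)
  out <- matrix(0L, nrow = length(smiles), ncol = 166,
                dimnames = list(ids, as.character(1:166)))
  for (r in seq_len(nrow(keys))) {
    k <- keys$key[r]
    if (keys$smarts[r] == "?") next
    counts <- suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, keys$smarts[r], uniqueMatches = TRUE))
    out[, as.character(k)] <- as.integer(counts >= keys$min_count[r])
  }
  # key 125: > 1 aromatic ring, by ring perception
  n_arom <- vapply(seq_along(smiles), function(i) {
    ri <- ChemmineR::rings(sdf[[i]], type = "all", arom = TRUE)
    small <- lengths(ri$RINGS) <= 7   # exclude fused-system envelopes
    sum(unlist(ri$AROMATIC)[small])
  }, numeric(1))
  out[, "125"] <- as.integer(n_arom >= 2)
  # key 166: > 1 fragment, by disconnection in the canonical SMILES
  out[, "166"] <- as.integer(grepl(".", can, fixed = TRUE))
  out[, "1"] <- 0L
  out
}

# Small numeric feature sets for exercising the model machinery without
# any chemistry.
toy_features <- function(n = 120, p = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  data.frame(compound_id = sprintf("T%03d", seq_len(n)), X,
             stringsAsFactors = FALSE)
}

toy_labels <- function(features) {
  as.integer(features$f1 + 0.8 * features$f2 > 0)
}

# A minimal hand-built model bundle for testing pure geometry of the
# applicability domain.
geometry_bundle <- function(train, threshold = 10) {
  structure(list(
    booster = NULL,
    columns = colnames(train),
    medians = stats::setNames(rep(0, ncol(train)), colnames(train)),
    center = stats::setNames(rep(0, ncol(train)), colnames(train)),
    scale = stats::setNames(rep(1, ncol(train)), colnames(train)),
    train_matrix = train,
    train_labels = rep(0L, nrow(train)),
    ad_threshold = threshold, ad_k = 1, ad_multiplier = 3,
    nn_mean = NA_real_, nn_sd = NA_real_,
    label_definition = "test", prob_cutoff = 0.5,
    seed = 1L, nrounds = 0L, params = list()
  ), class = "pmt_model_bundle")
}

# property record constructor shorthand
prec <- function(hl = numeric(0), koc = NULL, flags = character(0),
                 quality = "experimental") {
  if (is.null(koc)) koc <- data.frame(ph = numeric(0), log_koc = numeric(0))
  list(half_lives = hl, log_koc_by_ph = koc, tox_flags = flags,
       evidence_quality = quality)
}
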