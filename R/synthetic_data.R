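# Synthetic study generator.
#
# Builds compound rosters, experimental property tables, known-list
# extracts, ML training sets and concentration tables with a known ground
# truth, so every stage of the screening pipeline can be exercised and
# verified without any external data. Structures are assembled from motif
# grammars (perfluorinated chains, organophosphate esters, halogenated
# aromatics, halogenated small aliphatics, terpenoid-like naturals, plain
# alkanes/alcohols/acids), which guarantees chemically valid, parseable
# SMILES and controllable fingerprint signatures.
#
# The planted ground truth is a monotone rule on two named descriptors:
# a compound is a true PMT/vPvM positive iff its logP estimate is below a
# cutoff (default 2: hydrophilic, hence mobile) AND it carries at least
# one halogen (persistence surrogate). Property tables and training
# labels are drawn consistently with that truth, so the rule screen, the
# ML screen and the full pipeline can all recover it.

#' Generator specification
#'
#' Bundles all knobs of the synthetic study. Defaults emulate the roster
#' scale and composition of a permafrost active-layer monitoring
#' compilation: 542 compounds split 287/130/125 across
#' synthetic/natural/undefined origin, about a third of which satisfy the
#' planted PMT/vPvM rule, experimental property coverage for roughly a
#' quarter of compounds, a small previously-assessed known list, and
#' log-normal EF/NER concentrations with the NER location three orders of
#' magnitude above the EF.
#'
#' @param n_total roster size (default 542).
#' @param origin_fractions fractions per origin (synthetic, natural,
#'   undefined); must sum to 1. Counts are assigned by largest-remainder
#'   rounding, so the default gives exactly 287/130/125.
#' @param family_weights per-origin named weights over the motif families
#'   `pfas`, `organophosphate`, `halo_aromatic_cl`, `halo_aromatic_br`,
#'   `halo_aliphatic`, `terpenoid`, `alkanoid`.
#' @param property_coverage fraction of compounds with experimental
#'   property data (default 0.25).
#' @param known_fraction fraction of compounds on the known list
#'   (default 0.05).
#' @param label_noise probability that a generated property record
#'   contradicts the planted truth (default 0).
#' @param logp_cutoff planted-rule logP cutoff (default 2).
#' @param subclass_probs split of true positives into PMT / vPvM /
#'   PMT_and_vPvM (default 7:4:4, normalized).
#' @param n_sites number of sampling sites (default 12).
#' @param latitude_range site latitude range in decimal degrees
#'   (default c(30, 39), a plateau-like span).
#' @param conc concentration model: log-normal meanlog/sdlog for the EF,
#'   log offset of the NER location (default log(1000)), NER reporting
#'   probability, per-site detection probability, and a mild
#'   south-increasing latitude trend on the location parameter (per
#'   degree).
#' @param seed mandatory integer seed. Each generator operation derives
#'   its own stream from it, so calls are order-independent.
#' @return a validated `pmt_generator_spec` list.
#' @export
generator_spec <- function(n_total = 542,
                           origin_fractions = c(synthetic = 0.530,
                                                natural = 0.240,
                                                undefined = 0.230),
                           family_weights = NULL,
                           property_coverage = 0.25,
                           known_fraction = 0.05,
                           label_noise = 0,
                           logp_cutoff = 2,
                           subclass_probs = c(PMT = 7, vPvM = 4,
                                              PMT_and_vPvM = 4) / 15,
                           n_sites = 12,
                           latitude_range = c(30, 39),
                           conc = list(ef_meanlog = log(30), ef_sdlog = 1.2,
                                       ner_offset_log = log(1000),
                                       ner_sdlog = 1.2, ner_prob = 0.6,
                                       detect_prob = 0.15,
                                       lat_trend = 0.05),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_total >= 1,
            abs(sum(origin_fractions) - 1) < 1e-8,
            all(origin_fractions >= 0),
            identical(names(origin_fractions), ORIGIN_LEVELS),
            property_coverage >= 0, property_coverage <= 1,
            known_fraction >= 0, known_fraction <= 1,
            label_noise >= 0, label_noise <= 1,
            abs(sum(subclass_probs) - 1) < 1e-8,
            n_sites >= 0)
  if (is.null(family_weights)) {
    family_weights <- list(
      synthetic = c(pfas = 0.25, organophosphate = 0.25,
                    halo_aromatic_cl = 0.30, halo_aliphatic = 0.20),
      natural = c(halo_aliphatic = 0.55, halo_aromatic_br = 0.22,
                  terpenoid = 0.12, alkanoid = 0.11),
      undefined = c(halo_aliphatic = 0.62, halo_aromatic_cl = 0.12,
                    halo_aromatic_br = 0.12, alkanoid = 0.14)
    )
  }
  structure(list(n_total = n_total, origin_fractions = origin_fractions,
                 family_weights = family_weights,
                 property_coverage = property_coverage,
                 known_fraction = known_fraction,
                 label_noise = label_noise, logp_cutoff = logp_cutoff,
                 subclass_probs = subclass_probs, n_sites = n_sites,
                 latitude_range = latitude_range, conc = conc,
                 seed = as.integer(seed)),
            class = "pmt_generator_spec")
}

# largest-remainder apportionment of n into parts proportional to fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# ---- motif grammars ---------------------------------------------------------
# each returns one SMILES string using the current RNG state

gen_pfas <- function() {
  head <- sample(c("OC(=O)", "OS(=O)(=O)", "OCC", "OCCC"), 1,
                 prob = c(0.40, 0.20, 0.25, 0.15))
  n <- sample(1:8, 1)
  tail <- sample(c("F", "C(F)F"), 1, prob = c(0.8, 0.2))
  chain <- strrep("C(F)(F)", n)
  # perfluoroether variant: an ether oxygen inside the fluorinated chain
  if (n >= 2 && stats::runif(1) < 0.3) {
    at <- sample(n - 1, 1)
    chain <- paste0(strrep("C(F)(F)", at), "O", strrep("C(F)(F)", n - at))
  }
  paste0(head, chain, tail)
}

gen_organophosphate <- function() {
  pool <- c("OC", "OCC", "OCCC", "OCCCl", "OCC(C)Cl", "OCCBr",
            "OCC(Cl)CCl", "OCCO", "OCC(Br)C")
  r <- sample(pool, 3, replace = TRUE)
  paste0("O=P(", r[1], ")(", r[2], ")", r[3])
}

# substituted benzene: prefix on atom 1, up to four substituents on the
# middle ring atoms
gen_halo_aromatic <- function(halogen = "Cl") {
  prefix <- sample(c("O", "CO", "OC(=O)", "C", ""), 1,
                   prob = c(0.35, 0.15, 0.15, 0.1, 0.25))
  n_halo <- sample(1:4, 1, prob = c(0.35, 0.3, 0.2, 0.15))
  extra <- sample(c("", "O", "C"), 1, prob = c(0.6, 0.25, 0.15))
  subs <- c(rep(halogen, n_halo), if (nzchar(extra)) extra)
  subs <- utils::head(subs, 4)
  slots <- rep("c", 4)
  pos <- sample(4, length(subs))
  slots[pos] <- paste0("c(", subs, ")")
  paste0(prefix, "c1", paste(slots, collapse = ""), "c1")
}

# small halogenated aliphatics built compositionally: a short carbon
# backbone, 1-3 halogens placed on it, and an optional polar group
# (hydroxyl, carboxylic acid, methyl ether, ketone oxygen). The space is
# large (thousands of distinct structures) and straddles the planted
# logP cutoff.
gen_halo_aliphatic <- function() {
  n_c <- sample(1:6, 1, prob = c(0.15, 0.25, 0.2, 0.18, 0.12, 0.1))
  subs <- vector("list", n_c)
  cap <- c(3, rep(2, max(n_c - 2, 0)), if (n_c > 1) 3)  # free valences
  n_x <- sample(1:3, 1, prob = c(0.45, 0.35, 0.2))
  for (j in seq_len(n_x)) {
    open <- which(vapply(subs, length, 1L) < cap)
    if (length(open) == 0) break
    at <- if (length(open) == 1) open else sample(open, 1)
    subs[[at]] <- c(subs[[at]], sample(c("Cl", "Br", "F"), 1,
                                       prob = c(0.5, 0.35, 0.15)))
  }
  grp <- sample(c("", "O", "C(=O)O", "OC", "=O"), 1,
                prob = c(0.2, 0.3, 0.25, 0.15, 0.1))
  if (nzchar(grp)) {
    if (grp == "=O" && n_c >= 3) {
      # ketone on an inner carbon with both valences free
      open <- which(vapply(subs, length, 1L) == 0)
      open <- setdiff(open, c(1, n_c))
      if (length(open) > 0) {
        at <- if (length(open) == 1) open else sample(open, 1)
        subs[[at]] <- c(subs[[at]], "=O")
      }
    } else if (grp != "=O") {
      open <- which(vapply(subs, length, 1L) < cap)
      if (length(open) > 0) {
        at <- if (length(open) == 1) open else sample(open, 1)
        subs[[at]] <- c(subs[[at]], grp)
      }
    }
  }
  paste0(vapply(subs, function(s) {
    paste0("C", paste0(vapply(s, function(b) paste0("(", b, ")"), ""),
                       collapse = ""))
  }, ""), collapse = "")
}

TERPENOID_POOL <- c(
  "CC(=C)C1CCC(C)=CC1",            # limonene-like
  "CC1=CCC2CC1C2(C)C",             # pinene-like
  "CC(C)=CCCC(C)(O)C=C",           # linalool-like
  "CC(C)=CCCC(C)=CCO",             # geraniol-like
  "CC1CCC(C(C)C)C(O)C1",           # menthol-like
  "CC1(C)C2CCC1(C)C(=O)C2",        # camphor-like
  "CC(=C)C1CC(=O)C(C)=CC1",        # carvone-like
  "CC1=CCC(CC1)C(C)(C)O",          # terpineol-like
  "CC(C)C1CCC(C)CC1O",             # menthanol-like
  "CC(C)=CCCC(C)=CC=O",            # citral-like
  "CC(C)=CCCC(=C)C=C",             # myrcene-like
  "CC(C)=CCC=C(C)C=C",             # ocimene-like
  "CC(CCC=C(C)C)CCO",              # citronellol-like
  "CC(CCC=C(C)C)CC=O",             # citronellal-like
  "CC(C)=CCCC(C)=CCCC(C)=CCO",     # farnesol-like
  "CC(C)=CCCC(C)=CCC=O",           # sesquiterpenal-like
  "CC1CCC2(C)CCC(C)C2C1",          # decalin terpenoid-like
  "CC(C)C1CCC2(C)C1CCC2O",         # bicyclic terpenol-like
  "CC(C)=CC1CC(C)(O)CC1",          # cyclic terpenol-like
  "CC(C)C1=CC(=O)CCC1C"            # cyclohexenone terpenoid-like
)

gen_terpenoid <- function() sample(TERPENOID_POOL, 1)

gen_alkanoid <- function() {
  len <- sample(3:12, 1)
  group <- sample(c("", "O", "C(=O)O"), 1, prob = c(0.45, 0.3, 0.25))
  branch <- sample(c(TRUE, FALSE), 1, prob = c(0.3, 0.7))
  base <- if (branch && len >= 4) {
    paste0("CC(C)", strrep("C", len - 3))
  } else {
    strrep("C", len)
  }
  paste0(base, group)
}

generate_structure <- function(family) {
  switch(family,
    pfas = gen_pfas(),
    organophosphate = gen_organophosphate(),
    halo_aromatic_cl = gen_halo_aromatic("Cl"),
    halo_aromatic_br = gen_halo_aromatic("Br"),
    halo_aliphatic = gen_halo_aliphatic(),
    terpenoid = gen_terpenoid(),
    alkanoid = gen_alkanoid(),
    stop("unknown motif family: ", family))
}

# ---- roster -----------------------------------------------------------------

#' Generate a synthetic compound roster with ground truth
#'
#' Draws structures from the motif grammars, assigns origin labels by the
#' spec's fractions (largest-remainder rounding: the default spec yields
#' exactly 287/130/125), and computes the planted truth: a compound is a
#' true PMT/vPvM positive iff `logP_estimate < logp_cutoff` and it
#' contains at least one halogen. True positives are assigned a subclass
#' (PMT / vPvM / PMT_and_vPvM) by the spec's subclass probabilities.
#' Structures are kept unique (canonical-SMILES collisions are
#' regenerated, with a bounded number of retries). Deterministic under
#' the spec seed.
#'
#' @param spec a [generator_spec()].
#' @return list with `roster` (a `pmt_roster`) and `truth` (data frame:
#'   compound_id, origin, family, logP_estimate, n_halogen, is_positive,
#'   true_class).
#' @export
generate_roster <- function(spec) {
  stopifnot(inherits(spec, "pmt_generator_spec"))
  if (spec$n_total < 1) stop("n_total must be at least 1")
  set.seed(spec$seed)
  counts <- apportion(spec$n_total, spec$origin_fractions)
  origin <- rep(ORIGIN_LEVELS, counts)

  seen <- character(0)
  smiles <- character(spec$n_total)
  family <- character(spec$n_total)
  for (i in seq_len(spec$n_total)) {
    w <- spec$family_weights[[origin[i]]]
    for (attempt in seq_len(60)) {
      fam <- sample(names(w), 1, prob = w)
      s <- generate_structure(fam)
      can <- canonical_smiles(s)
      if (!is.na(can) && !(can %in% seen)) break
    }
    seen <- c(seen, can)
    smiles[i] <- s
    family[i] <- fam
  }
  prefix <- c(synthetic = "SYN", natural = "NAT", undefined = "UND")
  ids <- paste0(prefix[origin], "-", sprintf("%04d", seq_len(spec$n_total)))
  roster <- as_roster(data.frame(
    compound_id = ids,
    name = paste0(family, " ", sprintf("%04d", seq_len(spec$n_total))),
    smiles = smiles, origin = origin, cas = NA_character_,
    stringsAsFactors = FALSE))

  refs <- mol_refs(roster$canonical_smiles)
  logp <- ob_props(refs)$logP
  nx <- smarts_count(refs, "[F,Cl,Br,I]")
  is_positive <- logp < spec$logp_cutoff & nx >= 1
  true_class <- rep("not_PMT_vPvM", spec$n_total)
  n_pos <- sum(is_positive)
  if (n_pos > 0) {
    true_class[is_positive] <- sample(names(spec$subclass_probs), n_pos,
                                      replace = TRUE,
                                      prob = spec$subclass_probs)
  }
  truth <- data.frame(compound_id = roster$compound_id, origin = origin,
                      family = family, logP_estimate = logp,
                      n_halogen = nx, is_positive = is_positive,
                      true_class = true_class, stringsAsFactors = FALSE)
  list(roster = roster, truth = truth)
}

# ---- properties -------------------------------------------------------------

#' Generate an experimental property table consistent with the truth
#'
#' For a sampled fraction of compounds (the spec's `property_coverage`),
#' draws freshwater half-lives, pH-resolved log Koc values and toxicity
#' flags such that the rule screen recovers the compound's true class:
#' true PMT compounds get half-lives in the P band (40-60 d), mobile but
#' not very mobile log Koc and a toxicity flag; true vPvM /
#' PMT-and-vPvM compounds get vP half-lives and vM log Koc (without/with
#' a flag); negatives get short half-lives and high log Koc. With label
#' noise epsilon, a record contradicts its truth with that probability.
#' Uncovered compounds get no rows (they are routed to the ML screen).
#'
#' @param roster,truth from [generate_roster()].
#' @param spec the [generator_spec()].
#' @return long-format property data frame (compound_id, property, value,
#'   ph) accepted by [as_properties()].
#' @export
generate_properties <- function(roster, truth, spec) {
  set.seed(spec$seed + 1L)
  n <- nrow(roster)
  n_cov <- round(spec$property_coverage * n)
  covered <- sort(sample(n, n_cov))
  rows <- list()
  add <- function(id, property, value, ph = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      compound_id = id, property = property, value = value, ph = ph,
      stringsAsFactors = FALSE)
  }
  for (i in covered) {
    id <- truth$compound_id[i]
    cls <- truth$true_class[i]
    flip <- spec$label_noise > 0 && stats::runif(1) < spec$label_noise
    eff <- if (!flip) cls else
      if (cls == "not_PMT_vPvM") "vPvM" else "not_PMT_vPvM"
    draws <- switch(eff,
      PMT = list(hl = stats::runif(1, 45, 58),
                 koc = stats::runif(1, 2.2, 2.8), tox = TRUE),
      vPvM = list(hl = stats::runif(1, 70, 400),
                  koc = stats::runif(1, 0.5, 1.8), tox = FALSE),
      PMT_and_vPvM = list(hl = stats::runif(1, 70, 400),
                          koc = stats::runif(1, 0.5, 1.8), tox = TRUE),
      not_PMT_vPvM = list(hl = stats::runif(1, 5, 35),
                          koc = stats::runif(1, 3.2, 5.5),
                          tox = stats::runif(1) < 0.3))
    for (v in draws$hl * stats::runif(sample(1:3, 1), 0.92, 1.08)) {
      add(id, "half_life_freshwater_d", round(v, 2))
    }
    for (v in draws$koc + stats::runif(sample(1:2, 1), -0.05, 0.05)) {
      add(id, "log_koc", round(v, 3), ph = round(stats::runif(1, 4, 9), 1))
    }
    if (draws$tox) add(id, "tox_flag", sample(TOX_FLAGS, 1))
  }
  if (length(rows) == 0) {
    return(data.frame(compound_id = character(0), property = character(0),
                      value = character(0), ph = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    r$value <- as.character(r$value)
    r
  }))
  rownames(out) <- NULL
  out
}

#' Generate a known-list extract from the truth
#'
#' Samples the spec's `known_fraction` of compounds and lists them under
#' their true class (subclass for positives, `not_PMT_vPvM` for
#' negatives), keyed by canonical structure.
#'
#' @param roster,truth from [generate_roster()].
#' @param spec the [generator_spec()].
#' @return data frame (match_key, listed_class) accepted by
#'   [as_known_list()].
#' @export
generate_known_list <- function(roster, truth, spec) {
  set.seed(spec$seed + 4L)
  n <- nrow(roster)
  n_known <- round(spec$known_fraction * n)
  pick <- sort(sample(n, n_known))
  data.frame(match_key = roster$canonical_smiles[pick],
             listed_class = truth$true_class[pick],
             stringsAsFactors = FALSE)
}

# ---- training set -----------------------------------------------------------

#' Generate a labelled training set with the planted rule
#'
#' Draws `n` structures from the motif grammars (balanced across all
#' families), computes the full descriptor matrix, and labels each
#' compound with the planted monotone rule: positive iff
#' `logP_estimate < logp_cutoff` and `n_halogen >= 1`. This stands in for
#' an external PMT/vPvM training set and makes the classifier's expected
#' behaviour checkable: the logP proxy must dominate importance with a
#' negative dependence.
#'
#' @param spec a [generator_spec()].
#' @param n training-set size (default 400).
#' @param rule_features the two descriptor names the rule reads (logP-like
#'   then halogen-count-like). Both must exist in the descriptor set.
#' @return list with `features` (descriptor data frame), `labels`
#'   (integer 0/1), `roster`.
#' @export
generate_training_set <- function(spec, n = 400,
                                  rule_features = c("logP_estimate",
                                                    "n_halogen")) {
  set.seed(spec$seed + 2L)
  fams <- c(pfas = 0.15, organophosphate = 0.15, halo_aromatic_cl = 0.12,
            halo_aromatic_br = 0.12, halo_aliphatic = 0.30,
            terpenoid = 0.08, alkanoid = 0.08)
  seen <- character(0)
  smiles <- character(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(60)) {
      s <- generate_structure(sample(names(fams), 1, prob = fams))
      can <- canonical_smiles(s)
      if (!is.na(can) && !(can %in% seen)) break
    }
    seen <- c(seen, can)
    smiles[i] <- s
  }
  roster <- as_roster(data.frame(
    compound_id = paste0("TRN-", sprintf("%04d", seq_len(n))),
    name = paste0("train ", seq_len(n)), smiles = smiles,
    origin = "undefined", stringsAsFactors = FALSE))
  features <- descriptor_matrix(roster)
  missing_feats <- setdiff(rule_features, names(features))
  if (length(missing_feats) > 0) {
    stop("planted-rule feature(s) absent from descriptor set: ",
         paste(missing_feats, collapse = ", "))
  }
  labels <- as.integer(features[[rule_features[1]]] < spec$logp_cutoff &
                         features[[rule_features[2]]] >= 1)
  if (length(unique(labels)) < 2) {
    stop("degenerate planted rule: all training labels are one class")
  }
  list(features = features, labels = labels, roster = roster)
}

# ---- concentrations ---------------------------------------------------------

#' Generate a synthetic concentration table
#'
#' Per compound-site observations in ng/g dry weight over `n_sites`
#' plateau-range sites. Extractable-fraction (EF) values are log-normal;
#' non-extractable-residue (NER) values share the shape but sit three
#' orders of magnitude higher by default. The location parameter rises
#' mildly toward the south (lower latitude), emulating a weak
#' north-to-south concentration gradient. Depths are uniform on 0-150 cm.
#'
#' @param roster from [generate_roster()].
#' @param spec a [generator_spec()].
#' @return concentration data frame accepted by [as_concentrations()].
#' @export
generate_concentrations <- function(roster, spec) {
  set.seed(spec$seed + 3L)
  if (spec$n_sites == 0) {
    return(data.frame(compound_id = character(0), site_id = character(0),
                      latitude = numeric(0), depth_cm = numeric(0),
                      fraction = character(0), conc_ng_g_dw = numeric(0),
                      stringsAsFactors = FALSE))
  }
  p <- spec$conc
  lat <- sort(stats::runif(spec$n_sites, spec$latitude_range[1],
                           spec$latitude_range[2]), decreasing = TRUE)
  sites <- data.frame(site_id = sprintf("S%02d", seq_len(spec$n_sites)),
                      latitude = round(lat, 3))
  rows <- list()
  for (i in seq_len(nrow(roster))) {
    det <- which(stats::runif(spec$n_sites) < p$detect_prob)
    for (s in det) {
      loc <- p$ef_meanlog +
        p$lat_trend * (spec$latitude_range[2] - sites$latitude[s])
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = roster$compound_id[i],
        site_id = sites$site_id[s],
        latitude = sites$latitude[s],
        depth_cm = round(stats::runif(1, 0, 150), 1),
        fraction = "EF",
        conc_ng_g_dw = round(stats::rlnorm(1, loc, p$ef_sdlog), 3),
        stringsAsFactors = FALSE)
      if (stats::runif(1) < p$ner_prob) {
        rows[[length(rows) + 1]] <- data.frame(
          compound_id = roster$compound_id[i],
          site_id = sites$site_id[s],
          latitude = sites$latitude[s],
          depth_cm = round(stats::runif(1, 0, 150), 1),
          fraction = "NER",
          conc_ng_g_dw = round(stats::rlnorm(1, loc + p$ner_offset_log,
                                             p$ner_sdlog), 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(compound_id = character(0), site_id = character(0),
               latitude = numeric(0), depth_cm = numeric(0),
               fraction = character(0), conc_ng_g_dw = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' roster + truth, property table, known list, training set and
#' concentration table. Optionally writes all of them (plus the truth) as
#' the delimited files the readers accept.
#'
#' @param spec a [generator_spec()].
#' @param dir optional output directory.
#' @param n_train training-set size (default 400).
#' @return list with `roster`, `truth`, `properties`, `known`,
#'   `training`, `concentrations`.
#' @export
simulate_study <- function(spec, dir = NULL, n_train = 400) {
  ros <- generate_roster(spec)
  properties <- generate_properties(ros$roster, ros$truth, spec)
  known <- generate_known_list(ros$roster, ros$truth, spec)
  training <- generate_training_set(spec, n = n_train)
  concentrations <- generate_concentrations(ros$roster, spec)
  out <- list(roster = ros$roster, truth = ros$truth,
              properties = properties, known = known, training = training,
              concentrations = concentrations)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_roster(ros$roster, file.path(dir, "roster.csv"))
    utils::write.csv(ros$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(properties, file.path(dir, "properties.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(known, file.path(dir, "known_list.csv"),
                     row.names = FALSE)
    utils::write.csv(training$features, file.path(dir,
                                                  "training_features.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(compound_id = training$features$compound_id,
                                label = training$labels),
                     file.path(dir, "training_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(concentrations, file.path(dir, "concentrations.csv"),
                     row.names = FALSE)
  }
  out
}
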