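# Open molecular descriptor set.
#
# The descriptor vector combines constitutional counts, OpenBabel bulk
# properties (logP estimate, molar refractivity, TPSA, H-bond counts),
# classical topological indices and 2D autocorrelations (Broto-Moreau ATS,
# Moran MATS, Geary GATS; lags 1-8; atomic weights mass /
# Sanderson-style electronegativity / polarizability, relative to carbon)
# computed on the hydrogen-suppressed molecular graph. Uncomputable values
# (e.g. autocorrelations of a lag longer than the molecule's diameter) are
# explicit NaN, never a silent zero.

# atomic constants: mass (u), electronegativity (Pauling), polarizability
# (1e-24 cm^3); covers the elements the pipeline encounters in
# environmental organic chemistry. Unlisted elements fall back to carbon
# (neutral weight) with a warning at compute time.
ATOM_PROPS <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P",
              "S", "Cl", "K", "Ca", "Fe", "Zn", "As", "Se", "Br", "Sn",
              "I", "Hg", "Pb"),
  mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
           26.982, 28.086, 30.974, 32.06, 35.45, 39.098, 40.078, 55.845,
           65.38, 74.922, 78.971, 79.904, 118.71, 126.904, 200.59, 207.2),
  en = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 0.93, 1.31, 1.61, 1.90, 2.19,
         2.58, 3.16, 0.82, 1.00, 1.83, 1.65, 2.18, 2.55, 2.96, 1.96, 2.66,
         2.00, 2.33),
  polarizability = c(0.667, 3.03, 1.76, 1.10, 0.802, 0.557, 24.11, 10.6,
                     6.8, 5.38, 3.63, 2.90, 2.18, 43.4, 22.8, 8.4, 5.75,
                     4.31, 3.77, 3.05, 7.7, 5.35, 5.7, 6.8),
  stringsAsFactors = FALSE
)

HALOGENS <- c("F", "Cl", "Br", "I")

atom_weights <- function(elements, prop) {
  i <- match(elements, ATOM_PROPS$element)
  ref <- ATOM_PROPS[ATOM_PROPS$element == "C", prop]
  w <- ATOM_PROPS[[prop]][i] / ref
  if (anyNA(w)) {
    warning("element(s) without tabulated atomic properties: ",
            paste(unique(elements[is.na(i)]), collapse = ", "),
            "; carbon values used")
    w[is.na(w)] <- 1
  }
  w
}

# 2D autocorrelations for one molecule: distance matrix D (topological),
# weight vector w. Returns named vector ATS/MATS/GATS for lags 1..max_lag.
# The variance-normalized forms (MATS, GATS) are ratio statistics; with
# fewer than `min_pairs` atom pairs at a lag the ratio is numerically
# unstable (a single pair can dominate), so such values are reported as
# NaN (missing) rather than as an unreliable number. The raw ATS sum is
# kept whenever at least one pair exists.
autocorrelations <- function(D, w, max_lag = 8, suffix, min_pairs = 3) {
  n <- length(w)
  out <- stats::setNames(
    rep(NaN, 3 * max_lag),
    c(paste0("ATS", seq_len(max_lag), suffix),
      paste0("MATS", seq_len(max_lag), suffix),
      paste0("GATS", seq_len(max_lag), suffix)))
  if (n < 2) return(out)
  wbar <- mean(w)
  dev <- w - wbar
  var_n <- sum(dev^2) / n          # Moran denominator
  var_n1 <- sum(dev^2) / (n - 1)   # Geary denominator
  for (k in seq_len(max_lag)) {
    pair <- which(D == k, arr.ind = TRUE)   # ordered pairs, both directions
    delta <- nrow(pair)
    if (delta == 0) next
    out[paste0("ATS", k, suffix)] <-
      sum(w[pair[, 1]] * w[pair[, 2]]) / 2
    if (delta < 2 * min_pairs) next  # delta counts ordered pairs
    if (var_n > 0) {
      out[paste0("MATS", k, suffix)] <-
        (sum(dev[pair[, 1]] * dev[pair[, 2]]) / delta) / var_n
    }
    if (var_n1 > 0) {
      out[paste0("GATS", k, suffix)] <-
        (sum((w[pair[, 1]] - w[pair[, 2]])^2) / (2 * delta)) / var_n1
    }
  }
  out
}

descriptor_names_cache <- NULL

#' Molecular descriptor matrix for a compound set
#'
#' Computes the full open descriptor set for each compound. The set
#' includes, among others, `logP_estimate` (atom-contribution
#' octanol-water partition coefficient) and `carbon_fraction` (carbon
#' atoms over all atoms including hydrogens), the two descriptors the
#' screening model's interpretation leans on most. Identical canonical
#' structures always give identical vectors. Descriptors that cannot be
#' computed for a molecule (e.g. an autocorrelation at a lag exceeding the
#' topological diameter, or a centered autocorrelation of a
#' single-element molecule) are explicit `NaN`.
#'
#' @param x a `pmt_roster` or a (optionally named) character vector of
#'   SMILES.
#' @param max_lag maximum topological lag for the autocorrelation
#'   descriptors (default 8).
#' @return data frame: `compound_id` plus one numeric column per
#'   descriptor, in a fixed order shared across calls.
#' @export
descriptor_matrix <- function(x, max_lag = 8) {
  if (inherits(x, "pmt_roster")) {
    smiles <- x$canonical_smiles
    ids <- x$compound_id
  } else {
    smiles <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else paste0("mol", seq_along(x))
  }
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("unparseable structure(s) at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  }
  refs <- mol_refs(can)
  props <- ob_props(refs)
  n_arom_atoms <- smarts_count(refs, "a")
  n_arom_rings <- count_aromatic_rings(refs)
  n_rot <- tryCatch(
    smarts_count(refs, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"),
    error = function(e) rep(NaN, length(ids)))
  graphs <- mol_graph_set(can, ids, formulas = props$formula)

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    gi <- graphs[[i]]
    elements <- gi$elements
    bonds <- gi$bonds
    g <- gi$graph
    n_heavy <- length(elements)
    fcounts <- parse_formula(props$formula[i])
    nH <- gi$n_hydrogen
    n_total <- n_heavy + nH
    cnt <- function(el) sum(elements == el)
    n_halogen <- sum(elements %in% HALOGENS)
    n_hetero <- sum(!elements %in% c("C", "H"))
    deg <- igraph::degree(g)
    n_frag <- gi$n_fragments
    n_rings <- nrow(bonds) - n_heavy + n_frag
    D <- igraph::distances(g)
    finite_D <- D[is.finite(D) & D > 0]
    # topological indices on the heavy-atom graph
    wiener <- if (length(finite_D) > 0) sum(finite_D) / 2 else 0
    diam <- if (length(finite_D) > 0) max(finite_D) else 0
    zagreb1 <- sum(deg^2)
    zagreb2 <- if (nrow(bonds) > 0) {
      sum(deg[bonds[, "a1"]] * deg[bonds[, "a2"]])
    } else 0
    randic <- if (nrow(bonds) > 0) {
      sum(1 / sqrt(deg[bonds[, "a1"]] * deg[bonds[, "a2"]]))
    } else 0
    # information content over element composition (all atoms incl. H)
    all_counts <- fcounts[fcounts > 0]
    p_el <- all_counts / sum(all_counts)
    ic0 <- -sum(p_el * log2(p_el))
    sic0 <- if (sum(all_counts) > 1) ic0 / log2(sum(all_counts)) else NaN

    const <- c(
      n_heavy_atoms = n_heavy,
      n_atoms_total = n_total,
      n_hydrogen = nH,
      molecular_weight = props$MW[i],
      n_carbon = cnt("C"),
      n_nitrogen = cnt("N"),
      n_oxygen = cnt("O"),
      n_sulfur = cnt("S"),
      n_phosphorus = cnt("P"),
      n_fluorine = cnt("F"),
      n_chlorine = cnt("Cl"),
      n_bromine = cnt("Br"),
      n_iodine = cnt("I"),
      n_halogen = n_halogen,
      n_heteroatoms = n_hetero,
      carbon_fraction = cnt("C") / n_total,
      heteroatom_fraction = n_hetero / n_total,
      halogen_fraction_heavy = n_halogen / n_heavy,
      n_bonds = nrow(bonds),
      n_double_bonds = sum(bonds[, "order"] == 2),
      n_triple_bonds = sum(bonds[, "order"] == 3),
      n_rings = n_rings,
      n_aromatic_atoms = n_arom_atoms[i],
      n_aromatic_rings = n_arom_rings[i],
      aromatic_fraction = n_arom_atoms[i] / n_heavy,
      n_fragments = n_frag,
      n_rotatable_bonds = n_rot[i],
      mean_degree = mean(deg),
      n_branch_atoms = sum(deg >= 3),
      n_terminal_atoms = sum(deg == 1),
      zagreb_m1 = zagreb1,
      zagreb_m2 = zagreb2,
      randic_index = randic,
      wiener_index = wiener,
      topo_diameter = diam,
      IC0 = ic0,
      SIC0 = sic0,
      logP_estimate = props$logP[i],
      molar_refractivity = props$MR[i],
      tpsa = props$TPSA[i],
      hbd_count = props$HBD[i],
      hba_count = props$HBA1[i]
    )
    Dk <- D
    Dk[!is.finite(Dk)] <- -1  # disconnected pairs contribute to no lag
    ac <- c(
      autocorrelations(Dk, atom_weights(elements, "mass"), max_lag, "m"),
      autocorrelations(Dk, atom_weights(elements, "en"), max_lag, "e"),
      autocorrelations(Dk, atom_weights(elements, "polarizability"),
                       max_lag, "p"))
    rows[[i]] <- c(const, ac)
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(compound_id = ids, mat, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Descriptor vector for a single compound
#'
#' @param smiles a single SMILES string.
#' @param max_lag see [descriptor_matrix()].
#' @return named numeric vector of descriptor values.
#' @export
descriptor_vector <- function(smiles, max_lag = 8) {
  stopifnot(length(smiles) == 1)
  df <- descriptor_matrix(smiles, max_lag = max_lag)
  unlist(df[1, -1])
}

#' Descriptor name map
#'
#' Maps descriptor names used in the PMT/vPvM QSAR literature (computed
#' there with a proprietary descriptor engine) to the open proxies this
#' package computes. Numeric equality with the proprietary implementations
#' is not claimed; the proxies capture the same structural property.
#'
#' @return data frame with columns `literature_name`, `open_name`, `note`.
#' @export
descriptor_name_map <- function() {
  data.frame(
    literature_name = c("LOGPcons", "C%", "GATS8m", "MATS1m", "SIC0",
                        "GATS1s"),
    open_name = c("logP_estimate", "carbon_fraction", "GATS8m", "MATS1m",
                  "SIC0", "GATS1e"),
    note = c(
      "consensus logP replaced by an atom-contribution logP estimate",
      "carbon atoms over all atoms including hydrogens",
      "Geary autocorrelation, lag 8, mass-weighted (same definition)",
      "Moran autocorrelation, lag 1, mass-weighted (same definition)",
      "structural information content, order 0 (same definition)",
      "no intrinsic-state weighting in the open set; electronegativity is the nearest analogue"),
    stringsAsFactors = FALSE
  )
}

#' Export feature matrices
#'
#' Writes the fingerprint matrix (wide CSV and sparse triplet TSV), the
#' descriptor matrix (wide CSV) and a column manifest (JSON, including the
#' descriptor name map) to a directory.
#'
#' @param fingerprints matrix from [maccs_fingerprint()].
#' @param descriptors data frame from [descriptor_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fingerprints, descriptors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(compound_id = rownames(fingerprints),
                              fingerprints, check.names = FALSE),
                   file.path(dir, "fingerprints.csv"), row.names = FALSE)
  nz <- which(fingerprints != 0, arr.ind = TRUE)
  trip <- data.frame(compound_id = rownames(fingerprints)[nz[, 1]],
                     key = colnames(fingerprints)[nz[, 2]], value = 1L)
  trip <- trip[order(trip$compound_id, as.integer(trip$key)), ]
  utils::write.table(trip, file.path(dir, "fingerprints_triplet.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE)
  manifest <- list(
    fingerprint_keys = as.integer(colnames(fingerprints)),
    descriptor_columns = setdiff(names(descriptors), "compound_id"),
    descriptor_name_map = descriptor_name_map()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
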