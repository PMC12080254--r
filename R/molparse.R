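# Internal molecule handling built on ChemmineR/ChemmineOB (OpenBabel).
# All structure I/O in the package funnels through these helpers so that
# canonicalization and parse-failure behaviour are uniform.

#' Canonicalize SMILES strings
#'
#' Rewrites each SMILES into OpenBabel canonical form. Invalid structures
#' (unparseable SMILES) yield `NA` rather than an error, so callers can
#' collect rejects.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("CCO", "OCC", "C1CC"))
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", trimws(s))),
      error = function(e) ""
    )
    out <- trimws(sub("\t.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse a vector of (valid) SMILES into an SDFset; names become molecule ids.
# Callers must have screened out invalid SMILES beforehand.
mol_sdfset <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids), !anyNA(smiles))
  x <- smiles
  names(x) <- ids
  suppressWarnings(ChemmineR::smiles2sdf(x))
}

# OpenBabel molecule references parsed straight from SMILES (one per
# element). This path is robust for degenerate structures (e.g. a single
# heavy atom) that the SDF round-trip cannot represent cleanly.
mol_refs <- function(smiles) {
  stopifnot(!anyNA(smiles))
  refs <- suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                           identity))
  if (length(refs) != length(smiles)) {
    stop("SMILES parsing dropped molecules (", length(refs), " of ",
         length(smiles), " parsed)")
  }
  refs
}

# bulk OpenBabel properties (logP, MR, TPSA, H-bond counts, MW, formula)
ob_props <- function(refs) {
  do.call(rbind, lapply(refs, ChemmineOB::prop_OB))
}

# Element symbols of the heavy atoms in one SDF molecule.
mol_elements <- function(sdf_one) {
  ab <- ChemmineR::atomblock(sdf_one)
  sub("_.*$", "", rownames(ab))
}

# Bond table (atom1, atom2, order) of one SDF molecule; zero-row matrix for
# molecules without bonds or with an unusable bond block.
mol_bonds <- function(sdf_one) {
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("a1", "a2", "order")))
  bb <- tryCatch(ChemmineR::bondblock(sdf_one), error = function(e) NULL)
  if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    return(empty)
  }
  m <- cbind(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  rownames(m) <- NULL
  m
}

# Hydrogen-suppressed molecular graph as an igraph object.
mol_graph <- function(sdf_one) {
  n <- nrow(ChemmineR::atomblock(sdf_one))
  b <- mol_bonds(sdf_one)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(b) > 0) {
    g <- igraph::add_edges(g, as.vector(t(b[, c("a1", "a2"), drop = FALSE])))
  }
  g
}

# Hydrogen-suppressed graphs for a SMILES vector: per molecule the heavy
# elements, the bond table, the igraph object, the fragment count and the
# hydrogen count. Molecules the SDF layer cannot represent (e.g. a single
# heavy atom) fall back to an edgeless graph with elements read off the
# molecular formula.
mol_graph_set <- function(smiles, ids, formulas = NULL) {
  sdf <- mol_sdfset(smiles, ids)
  if (is.null(formulas)) formulas <- ob_props(mol_refs(smiles))$formula
  lapply(seq_along(smiles), function(i) {
    fc <- parse_formula(formulas[i])
    nH <- if ("H" %in% names(fc)) fc[["H"]] else 0L
    heavy <- fc[names(fc) != "H"]
    n_heavy <- sum(heavy)
    ab <- tryCatch(ChemmineR::atomblock(sdf[[i]]), error = function(e) NULL)
    usable <- !is.null(ab) && is.matrix(ab) && nrow(ab) == n_heavy &&
      ncol(ab) >= 3
    if (usable) {
      elements <- sub("_.*$", "", rownames(ab))
      bonds <- mol_bonds(sdf[[i]])
    } else {
      elements <- rep(names(heavy), heavy)
      bonds <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("a1", "a2", "order")))
    }
    g <- igraph::make_empty_graph(n = n_heavy, directed = FALSE)
    if (nrow(bonds) > 0) {
      g <- igraph::add_edges(g, as.vector(t(bonds[, c("a1", "a2"),
                                                  drop = FALSE])))
    }
    list(elements = elements, bonds = bonds, graph = g,
         n_fragments = igraph::count_components(g), n_hydrogen = nH)
  })
}

# Parse a Hill-style molecular formula ("C6H5ClO") into named element counts.
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    k <- gsub("[^0-9]", "", p)
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) +
      (if (nzchar(k)) as.integer(k) else 1L)
  }
  counts
}

# Count of substructure matches per molecule for a SMARTS pattern, with
# unique (distinct atom-set) matching. Wrapper so every SMARTS query in the
# package goes through one place.
smarts_count <- function(refs, smarts) {
  as.integer(suppressWarnings(
    ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE)
  ))
}
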