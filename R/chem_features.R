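# MACCS structural-key fingerprints and cyclicity classification.
#
# Fingerprint bits follow the original 166-key MACCS numbering (key 134 =
# halogens, 103 = chlorine, 46 = bromine, 165 = any ring, 162 = aromatic,
# ...). Bit computation is delegated to OpenBabel's MACCS pattern engine;
# three keys the pattern file cannot express are handled here: key 125
# (more than one aromatic ring) and key 166 (more than one connected
# fragment) are computed from the molecular graph, and key 1 (isotope) is
# always 0 in the public dialect shipped with this package.

pkg_env <- new.env(parent = emptyenv())

#' The public 166-key MACCS dictionary
#'
#' Returns the key table shipped with the package: key number, SMARTS
#' pattern in the public dialect, the minimum match count for the bit to be
#' set, and a short name/description for keys commonly reported in
#' prevalence tables. Keys 1, 125 and 166 carry the placeholder pattern
#' `"?"`: they are not expressible as a single SMARTS and are computed
#' structurally.
#'
#' @return data frame with columns `key`, `smarts`, `min_count`,
#'   `key_name`, `description`.
#' @export
maccs_keys <- function() {
  if (is.null(pkg_env$maccs_keys)) {
    path <- system.file("extdata", "maccs_keys.tsv", package = "pmtscreen")
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    tb$key_name[tb$key_name == ""] <- paste0("key_", tb$key[tb$key_name == ""])
    pkg_env$maccs_keys <- tb
  }
  pkg_env$maccs_keys
}

# number of aromatic rings, approximated as the count of distinct 5-, 6-
# and 7-membered all-aromatic rings (covers fused systems: naphthalene = 2)
count_aromatic_rings <- function(refs) {
  smarts_count(refs, "a1aaaa1") + smarts_count(refs, "a1aaaaa1") +
    smarts_count(refs, "a1aaaaaa1")
}

#' MACCS fingerprints for a compound set
#'
#' Computes the 166-bit MACCS structural-key fingerprint for each compound:
#' bit k is set iff the molecule contains MACCS pattern k, by substructure
#' matching. Accepts a `pmt_roster` (uses its canonical structures) or a
#' character vector of SMILES.
#'
#' @param x a `pmt_roster` or a named/unnamed character vector of SMILES.
#' @return integer matrix `n x 166`; rownames are compound ids, colnames
#'   the original MACCS key numbers `"1"`..`"166"`.
#' @export
#' @examples
#' fp <- maccs_fingerprint(c(ccl4 = "ClC(Cl)(Cl)Cl", benzene = "c1ccccc1"))
#' fp["ccl4", c("134", "103", "46", "165")]
maccs_fingerprint <- function(x) {
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
  fp <- suppressWarnings(ChemmineOB::fingerprint_OB(refs, "MACCS"))
  fp <- fp[, seq_len(166), drop = FALSE]
  storage.mode(fp) <- "integer"
  # structurally computed keys
  fp[, 1] <- 0L
  fp[, 125] <- as.integer(count_aromatic_rings(refs) >= 2)
  fp[, 166] <- as.integer(grepl(".", can, fixed = TRUE))
  dimnames(fp) <- list(ids, as.character(seq_len(166)))
  fp
}

#' Is a compound noncyclic?
#'
#' A compound is noncyclic iff its molecular graph contains zero rings
#' (cyclomatic number zero). Agrees with MACCS key 165 (any ring) being
#' unset.
#'
#' @param x a `pmt_roster` or a character vector of SMILES.
#' @return logical vector, one entry per compound.
#' @export
#' @examples
#' is_noncyclic(c("CCCCCC", "C1CCCCC1"))  # TRUE, FALSE
is_noncyclic <- function(x) {
  smiles <- if (inherits(x, "pmt_roster")) x$canonical_smiles else
    as.character(x)
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("unparseable structure(s) at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  }
  ids <- paste0("m", seq_along(can))
  graphs <- mol_graph_set(can, ids)
  vapply(graphs, function(gi) {
    n_cycles <- nrow(gi$bonds) - length(gi$elements) + gi$n_fragments
    n_cycles == 0
  }, logical(1))
}
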