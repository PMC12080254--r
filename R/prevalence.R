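# MACCS-key occurrence proportions within compound subsets: top-k
# prevalence tables and origin-stratified contrasts.

#' Fingerprint prevalence table
#'
#' Counts, for each MACCS key, how many compounds in a subset contain the
#' key, and returns the k most frequent keys with their occurrence
#' proportion (percent of the subset containing the key). Ties are broken
#' deterministically: count descending, then key number ascending. Exact
#' proportions are retained; rounding is applied only on export.
#'
#' @param fingerprints matrix from [maccs_fingerprint()].
#' @param subset_ids compound ids defining the subset (default: all rows).
#' @param k table length (default 10). Keys with zero occurrences are
#'   never included.
#' @param label subset label carried in the output.
#' @return a `pmt_prevalence_table` data frame with columns `key`,
#'   `key_name`, `description`, `count`, `proportion` (percent), and
#'   attributes `subset_size`, `k`, `label`.
#' @export
prevalence_table <- function(fingerprints, subset_ids = NULL, k = 10,
                             label = "all") {
  if (is.null(subset_ids)) subset_ids <- rownames(fingerprints)
  if (length(subset_ids) == 0) stop("empty subset")
  missing_ids <- setdiff(subset_ids, rownames(fingerprints))
  if (length(missing_ids) > 0) {
    stop("no fingerprint for compound(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sub <- fingerprints[subset_ids, , drop = FALSE]
  counts <- colSums(sub)
  keys <- as.integer(colnames(fingerprints))
  ord <- order(-counts, keys)
  ord <- ord[counts[ord] > 0]
  ord <- utils::head(ord, k)
  keytab <- maccs_keys()
  ki <- match(keys[ord], keytab$key)
  out <- data.frame(
    key = keys[ord],
    key_name = keytab$key_name[ki],
    description = keytab$description[ki],
    count = as.integer(counts[ord]),
    proportion = 100 * counts[ord] / length(subset_ids),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, subset_size = length(subset_ids), k = k, label = label,
            class = c("pmt_prevalence_table", "data.frame"))
}

#' @export
print.pmt_prevalence_table <- function(x, ...) {
  cat(sprintf("MACCS prevalence table: %s (n = %d, top %d)\n",
              attr(x, "label"), attr(x, "subset_size"), attr(x, "k")))
  df <- as.data.frame(x)
  df$proportion <- sprintf("%d%%", round(df$proportion))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Contrast two prevalence tables
#'
#' Set comparison on key numbers between two tables of the same length k:
#' which keys are shared, and which appear in only one table (the
#' "inconsistent" fingerprints between two strata). Ordering within each
#' result follows the originating table.
#'
#' @param a,b `pmt_prevalence_table`s with equal `k`.
#' @return list with `shared`, `unique_to_a`, `unique_to_b` (integer key
#'   vectors) and the two labels.
#' @export
contrast_tables <- function(a, b) {
  if (!identical(attr(a, "k"), attr(b, "k"))) {
    stop("prevalence tables have different k (", attr(a, "k"), " vs ",
         attr(b, "k"), ")")
  }
  list(shared = intersect(a$key, b$key),
       unique_to_a = setdiff(a$key, b$key),
       unique_to_b = setdiff(b$key, a$key),
       label_a = attr(a, "label"), label_b = attr(b, "label"))
}

#' Noncyclic fraction of a subset
#'
#' Percent of compounds in the subset whose molecular graph has zero
#' rings.
#'
#' @param roster a `pmt_roster` (structures are taken from it).
#' @param subset_ids compound ids (default: whole roster).
#' @return percent (exact value; display convention is one decimal).
#' @export
noncyclic_fraction <- function(roster, subset_ids = NULL) {
  if (is.null(subset_ids)) subset_ids <- roster$compound_id
  if (length(subset_ids) == 0) stop("empty subset")
  i <- match(subset_ids, roster$compound_id)
  if (anyNA(i)) {
    stop("subset contains compound(s) missing from the roster")
  }
  100 * mean(is_noncyclic(roster$canonical_smiles[i]))
}

#' Export a prevalence table
#'
#' Writes CSV (exact proportions) and/or Markdown (display rounding:
#' integer percent) renderings with the standard column layout (feature
#' number, feature name, description, proportion).
#'
#' @param table a `pmt_prevalence_table`.
#' @param path output path without extension.
#' @param formats any of `"csv"`, `"md"`.
#' @return paths written, invisibly.
#' @export
export_prevalence <- function(table, path, formats = c("csv", "md")) {
  written <- character(0)
  if ("csv" %in% formats) {
    f <- paste0(path, ".csv")
    utils::write.csv(as.data.frame(table), f, row.names = FALSE)
    written <- c(written, f)
  }
  if ("md" %in% formats) {
    f <- paste0(path, ".md")
    df <- as.data.frame(table)
    lines <- c(
      sprintf("| Feature number | Feature name | Description | Proportion |"),
      "|---|---|---|---|",
      sprintf("| %d | %s | %s | %d%% |", df$key, df$key_name,
              df$description, round(df$proportion)))
    writeLines(c(sprintf("**%s** (n = %d)", attr(table, "label"),
                         attr(table, "subset_size")), "", lines), f)
    written <- c(written, f)
  }
  invisible(written)
}
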