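# Tiered persistence / mobility / toxicity assessment from experimental
# evidence, per the EU CLP-derived screening cutoffs, plus known-list
# lookup. This is a screening scheme, not a full weight-of-evidence
# evaluation; every audit trail carries that caveat.

#' Assess the persistence tier
#'
#' Aggregates the reported freshwater half-lives (median by default, max for
#' a worst-case reading) and compares against the cutoffs: above 60 d is
#' very persistent (vP), above 40 d persistent (P), at or below 40 d not
#' persistent. No data gives `"unknown"`.
#'
#' @param half_lives numeric vector of freshwater half-lives in days
#'   (possibly empty).
#' @param config a [pmt_config()].
#' @return one of `"not_P"`, `"P"`, `"vP"`, `"unknown"`.
#' @export
#' @examples
#' assess_persistence(c(50))    # "P"
#' assess_persistence(c(1000))  # "vP"
#' assess_persistence(numeric(0))  # "unknown"
assess_persistence <- function(half_lives, config = pmt_config()) {
  half_lives <- half_lives[!is.na(half_lives)]
  if (length(half_lives) == 0) return("unknown")
  agg <- switch(config$halflife_agg,
                median = stats::median(half_lives),
                max = max(half_lives))
  if (agg > config$persistence_vP_days) "vP"
  else if (agg > config$persistence_P_days) "P"
  else "not_P"
}

#' Assess the mobility tier
#'
#' Aggregates experimental log Koc values over the pH 4-9 window (minimum
#' by default: the most mobile observed speciation, conservative for water
#' protection) and applies the strict cutoffs: below 2.0 very mobile (vM),
#' below 3.0 mobile (M), otherwise not mobile. The boundary values 2.0 and
#' 3.0 are not below threshold. No usable data gives `"unknown"`.
#'
#' @param log_koc_by_ph data frame with columns `ph` and `log_koc`
#'   (possibly zero rows).
#' @param config a [pmt_config()].
#' @return one of `"not_M"`, `"M"`, `"vM"`, `"unknown"`.
#' @export
#' @examples
#' assess_mobility(data.frame(ph = 7, log_koc = 2.5))  # "M"
#' assess_mobility(data.frame(ph = 7, log_koc = 3.0))  # "not_M"
assess_mobility <- function(log_koc_by_ph, config = pmt_config()) {
  df <- log_koc_by_ph
  if (is.null(df) || nrow(df) == 0) return("unknown")
  in_window <- df$ph >= config$ph_range[1] & df$ph <= config$ph_range[2]
  vals <- df$log_koc[in_window & !is.na(df$log_koc)]
  if (length(vals) == 0) return("unknown")
  agg <- switch(config$logkoc_agg,
                min = min(vals),
                median = stats::median(vals))
  if (agg < config$logkoc_vM) "vM"
  else if (agg < config$logkoc_M) "M"
  else "not_M"
}

#' Assess the toxicity tier
#'
#' Toxicity is flag-based: a compound is toxic (T) if any of the CLP-derived
#' hazard flags is present (carcinogenic/mutagenic/reprotoxic, toxic to
#' aquatic organisms, specific target organ toxicity after repeated
#' exposure, or endocrine disruption). With experimental evidence but no
#' flag the tier is `"not_established"`; with no evidence at all it is
#' `"unknown"`. Absence of a flag never proves non-toxicity.
#'
#' @param tox_flags character vector of flags (subset of CMR, aquatic_tox,
#'   STOT_RE, endocrine_disruption).
#' @param evidence_quality `"experimental"` or `"none"`.
#' @return one of `"T"`, `"not_established"`, `"unknown"`.
#' @export
assess_toxicity <- function(tox_flags, evidence_quality = "experimental") {
  if (length(tox_flags) > 0) return("T")
  if (identical(evidence_quality, "experimental")) "not_established"
  else "unknown"
}

#' Combine criterion tiers into a hazard class
#'
#' Implements the class logic over the three criterion tiers:
#' \itemize{
#'   \item a definitive failure (`not_P` or `not_M`) gives `not_PMT_vPvM`
#'     regardless of the other tiers;
#'   \item otherwise an unknown persistence or mobility tier gives
#'     `unresolved` (the compound is routed to the ML screen);
#'   \item with persistence and mobility both satisfied: toxicity `T` gives
#'     `PMT_and_vPvM` when both tiers are at the very level (vP and vM),
#'     else `PMT`; toxicity `not_established` gives `vPvM` at the very
#'     level, else `not_PMT_vPvM` (PMT requires T); toxicity `unknown`
#'     gives `vPvM` at the very level (vPvM needs no toxicity), else
#'     `unresolved`.
#' }
#'
#' @param persistence `"not_P"`, `"P"`, `"vP"` or `"unknown"`.
#' @param mobility `"not_M"`, `"M"`, `"vM"` or `"unknown"`.
#' @param toxicity `"T"`, `"not_established"` or `"unknown"`.
#' @return one of `"PMT"`, `"vPvM"`, `"PMT_and_vPvM"`, `"not_PMT_vPvM"`,
#'   `"unresolved"`.
#' @export
#' @examples
#' combine_tiers("vP", "vM", "T")               # "PMT_and_vPvM"
#' combine_tiers("P", "M", "not_established")   # "not_PMT_vPvM"
#' combine_tiers("unknown", "vM", "T")          # "unresolved"
combine_tiers <- function(persistence, mobility, toxicity) {
  stopifnot(persistence %in% c("not_P", "P", "vP", "unknown"),
            mobility %in% c("not_M", "M", "vM", "unknown"),
            toxicity %in% c("T", "not_established", "unknown"))
  if (persistence == "not_P" || mobility == "not_M") return("not_PMT_vPvM")
  if (persistence == "unknown" || mobility == "unknown") return("unresolved")
  very <- persistence == "vP" && mobility == "vM"
  switch(toxicity,
    "T" = if (very) "PMT_and_vPvM" else "PMT",
    "not_established" = if (very) "vPvM" else "not_PMT_vPvM",
    "unknown" = if (very) "vPvM" else "unresolved")
}

#' Rule-based assessment of one property record
#'
#' Convenience wrapper: computes the three tiers from a property record and
#' combines them.
#'
#' @param record a property record (see [property_record()]).
#' @param config a [pmt_config()].
#' @return list with `persistence`, `mobility`, `toxicity`, `hazard_class`.
#' @export
assess_compound <- function(record, config = pmt_config()) {
  p <- assess_persistence(record$half_lives, config)
  m <- assess_mobility(record$log_koc_by_ph, config)
  t <- assess_toxicity(record$tox_flags, record$evidence_quality)
  list(persistence = p, mobility = m, toxicity = t,
       hazard_class = combine_tiers(p, m, t))
}

#' Look up compounds on the known PMT/vPvM list
#'
#' Matches each roster compound against the reference list, first by
#' canonical structure, then by CAS number. Structure matching is performed
#' on canonical SMILES so different spellings of the same molecule match.
#'
#' @param roster a `pmt_roster`.
#' @param known a known list as returned by [read_known_list()].
#' @return data frame with columns `compound_id`, `hazard_class`,
#'   `match_by`; one row per matched compound (unmatched compounds are
#'   absent).
#' @export
lookup_known <- function(roster, known) {
  if (is.null(known) || nrow(known) == 0) {
    return(data.frame(compound_id = character(0), hazard_class = character(0),
                      match_by = character(0), stringsAsFactors = FALSE))
  }
  struct <- known[known$key_type == "structure", , drop = FALSE]
  cas <- known[known$key_type == "cas", , drop = FALSE]
  i_struct <- match(roster$canonical_smiles, struct$match_key)
  i_cas <- match(roster$cas, cas$match_key)
  hit_struct <- !is.na(i_struct)
  hit_cas <- !hit_struct & !is.na(i_cas)
  cls <- rep(NA_character_, nrow(roster))
  by <- rep(NA_character_, nrow(roster))
  cls[hit_struct] <- struct$listed_class[i_struct[hit_struct]]
  by[hit_struct] <- "structure"
  cls[hit_cas] <- cas$listed_class[i_cas[hit_cas]]
  by[hit_cas] <- "cas"
  keep <- hit_struct | hit_cas
  out <- data.frame(compound_id = roster$compound_id[keep],
                    hazard_class = cls[keep], match_by = by[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
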