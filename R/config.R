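#' Screening configuration
#'
#' Central configuration block for the screening pipeline. The default rule
#' thresholds are the EU CLP-derived cutoffs: freshwater half-life above 40 d
#' for persistent (P) and above 60 d for very persistent (vP); log Koc
#' strictly below 3.0 for mobile (M) and strictly below 2.0 for very mobile
#' (vM). Exposing them here means a regulatory update is a config change,
#' not a code change.
#'
#' @param persistence_P_days half-life cutoff (days) above which a compound
#'   is persistent. Default 40.
#' @param persistence_vP_days half-life cutoff (days) above which a compound
#'   is very persistent. Default 60.
#' @param logkoc_M log Koc value below which (strict) a compound is mobile.
#'   Default 3.0.
#' @param logkoc_vM log Koc value below which (strict) a compound is very
#'   mobile. Default 2.0.
#' @param halflife_agg how to aggregate multiple reported half-lives:
#'   `"median"` (robust central tendency, default) or `"max"` (worst case).
#' @param logkoc_agg how to aggregate log Koc over the pH 4-9 window:
#'   `"min"` (most mobile observed form, default) or `"median"`.
#' @param ph_range admissible pH window for log Koc evidence.
#' @param ad_k number of nearest training neighbours used for the
#'   applicability-domain distance (default 1).
#' @param ad_multiplier applicability-domain threshold is
#'   `mean + ad_multiplier * sd` of within-training nearest-neighbour
#'   distances (default 3).
#' @param prob_cutoff classifier probability above which an in-domain
#'   compound is called a PMT/vPvM candidate (default 0.5).
#' @param table_k number of rows in fingerprint prevalence tables
#'   (default 10; origin contrasts use 20).
#' @param top_n_concentrated length of the most-concentrated-positives
#'   listing (default 10).
#' @param seed default seed for stochastic steps.
#' @return a named list with class `"pmt_config"`.
#' @export
pmt_config <- function(persistence_P_days = 40,
                       persistence_vP_days = 60,
                       logkoc_M = 3.0,
                       logkoc_vM = 2.0,
                       halflife_agg = c("median", "max"),
                       logkoc_agg = c("min", "median"),
                       ph_range = c(4, 9),
                       ad_k = 1,
                       ad_multiplier = 3,
                       prob_cutoff = 0.5,
                       table_k = 10,
                       top_n_concentrated = 10,
                       seed = 42) {
  halflife_agg <- match.arg(halflife_agg)
  logkoc_agg <- match.arg(logkoc_agg)
  stopifnot(persistence_P_days > 0,
            persistence_vP_days >= persistence_P_days,
            logkoc_vM <= logkoc_M,
            length(ph_range) == 2, ph_range[1] < ph_range[2],
            ad_k >= 1, ad_multiplier >= 0,
            prob_cutoff > 0, prob_cutoff < 1,
            table_k >= 1, top_n_concentrated >= 1)
  structure(list(
    persistence_P_days = persistence_P_days,
    persistence_vP_days = persistence_vP_days,
    logkoc_M = logkoc_M,
    logkoc_vM = logkoc_vM,
    halflife_agg = halflife_agg,
    logkoc_agg = logkoc_agg,
    ph_range = ph_range,
    ad_k = ad_k,
    ad_multiplier = ad_multiplier,
    prob_cutoff = prob_cutoff,
    table_k = table_k,
    top_n_concentrated = top_n_concentrated,
    seed = seed
  ), class = "pmt_config")
}

#' @export
print.pmt_config <- function(x, ...) {
  cat("PMT/vPvM screening configuration\n")
  cat(sprintf("  persistence: P > %g d, vP > %g d (agg: %s)\n",
              x$persistence_P_days, x$persistence_vP_days, x$halflife_agg))
  cat(sprintf("  mobility:    M < %g, vM < %g log Koc at pH %g-%g (agg: %s)\n",
              x$logkoc_M, x$logkoc_vM, x$ph_range[1], x$ph_range[2],
              x$logkoc_agg))
  cat(sprintf("  AD: k = %d nearest neighbour(s), threshold mean + %g sd\n",
              x$ad_k, x$ad_multiplier))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Canonical level sets used across the package.
ORIGIN_LEVELS <- c("synthetic", "natural", "undefined")
HAZARD_CLASSES <- c("PMT", "vPvM", "PMT_and_vPvM", "not_PMT_vPvM",
                    "candidate_PMT_vPvM", "unresolved")
TOX_FLAGS <- c("CMR", "aquatic_tox", "STOT_RE", "endocrine_disruption")
DECIDED_BY <- c("known_list", "rules", "ml_model", "none")
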