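# Orchestration of the three-step screening and report generation.
#
# Step order is strict: (1) known-list lookup, (2) rule-based assessment
# of experimental evidence, (3) ML prediction gated by the applicability
# domain. Each compound is decided by exactly the first step that
# resolves it; shuffling roster order changes no outcome. The rule screen
# is a screening-level assessment (not a full weight-of-evidence
# protocol); the audit trail carries that caveat.

POSITIVE_CLASSES <- c("PMT", "vPvM", "PMT_and_vPvM", "candidate_PMT_vPvM")

#' Run the three-step screening
#'
#' @param roster a `pmt_roster`.
#' @param properties a `pmt_properties` object (or `NULL`: no
#'   experimental evidence, everything not on the known list goes to the
#'   ML screen).
#' @param known a known list (or `NULL`).
#' @param bundle a `pmt_model_bundle` (or `NULL`: unresolved compounds
#'   stay unresolved, with a warning).
#' @param descriptors optional precomputed [descriptor_matrix()] for the
#'   roster (computed on demand otherwise).
#' @param config a [pmt_config()].
#' @return assessment data frame, one row per roster compound in roster
#'   order: `compound_id`, `persistence`, `mobility`, `toxicity`,
#'   `hazard_class`, `decided_by`, `detail`.
#' @export
run_screening <- function(roster, properties = NULL, known = NULL,
                          bundle = NULL, descriptors = NULL,
                          config = pmt_config()) {
  n <- nrow(roster)
  out <- data.frame(
    compound_id = roster$compound_id,
    persistence = rep("unknown", n), mobility = rep("unknown", n),
    toxicity = rep("unknown", n),
    hazard_class = rep("unresolved", n),
    decided_by = rep("none", n),
    detail = rep("", n),
    stringsAsFactors = FALSE)

  # step 1: known list
  if (!is.null(known)) {
    hits <- lookup_known(roster, known)
    i <- match(hits$compound_id, out$compound_id)
    out$hazard_class[i] <- hits$hazard_class
    out$decided_by[i] <- "known_list"
    out$detail[i] <- paste0("step 1: known-list match by ", hits$match_by)
  }

  # step 2: rules on experimental evidence
  undecided <- which(out$decided_by == "none")
  caveat <- "screening-level assessment, not full weight of evidence"
  for (i in undecided) {
    rec <- property_record(properties, roster$compound_id[i])
    a <- assess_compound(rec, config)
    out$persistence[i] <- a$persistence
    out$mobility[i] <- a$mobility
    out$toxicity[i] <- a$toxicity
    if (a$hazard_class != "unresolved") {
      out$hazard_class[i] <- a$hazard_class
      out$decided_by[i] <- "rules"
      out$detail[i] <- sprintf("step 2: rules (P=%s, M=%s, T=%s; %s)",
                               a$persistence, a$mobility, a$toxicity,
                               caveat)
    }
  }

  # step 3: ML with AD gate
  remaining <- which(out$decided_by == "none")
  if (length(remaining) > 0) {
    if (is.null(bundle)) {
      warning(length(remaining),
              " compound(s) remain unresolved: no model bundle supplied")
      out$detail[remaining] <- "unresolved: no experimental data, no model"
    } else {
      sub <- roster[remaining, , drop = FALSE]
      feats <- if (is.null(descriptors)) {
        descriptor_matrix(sub)
      } else {
        descriptors[match(sub$compound_id, descriptors$compound_id), ,
                    drop = FALSE]
      }
      pred <- predict_pmt(bundle, feats)
      stopifnot(identical(pred$compound_id, sub$compound_id))
      out$hazard_class[remaining] <- pred$hazard_class
      out$decided_by[remaining] <- pred$decided_by
      out$detail[remaining] <- paste0("step 3: ", pred$detail)
    }
  }
  out
}

#' Summarize a screening run
#'
#' Aggregates the assessment table into the screening report: class and
#' decision-step counts, the positive percentage, origin and cyclicity
#' breakdowns of the positives, per-fraction (EF/NER) concentration
#' summaries over positive compounds, per-site totals ordered north to
#' south with a Spearman rank correlation between latitude and site
#' total (descriptive, sign only — no significance claim), and the
#' most-concentrated positive compounds.
#'
#' @param assessments from [run_screening()].
#' @param roster the `pmt_roster` screened.
#' @param concentrations optional concentration data frame
#'   ([as_concentrations()] / [read_concentrations()]).
#' @param config a [pmt_config()].
#' @return a `pmt_screening_report` list; see Details in the vignette.
#' @export
summarize_screening <- function(assessments, roster, concentrations = NULL,
                                config = pmt_config()) {
  stopifnot(setequal(assessments$compound_id, roster$compound_id))
  n <- nrow(assessments)
  class_counts <- as.list(table(factor(assessments$hazard_class,
                                       levels = HAZARD_CLASSES)))
  step_counts <- as.list(table(factor(assessments$decided_by,
                                      levels = DECIDED_BY)))
  pos_ids <- assessments$compound_id[assessments$hazard_class %in%
                                       POSITIVE_CLASSES]
  n_pos <- length(pos_ids)
  positive_percent <- 100 * n_pos / n

  origin <- roster$origin[match(pos_ids, roster$compound_id)]
  origin_counts <- as.list(table(factor(origin, levels = ORIGIN_LEVELS)))
  nat_or_undef_percent <- if (n_pos > 0) {
    100 * sum(origin %in% c("natural", "undefined")) / n_pos
  } else NA_real_
  noncyclic_pct <- if (n_pos > 0) {
    noncyclic_fraction(roster, pos_ids)
  } else NA_real_

  conc_summary <- NULL
  site_summary <- NULL
  top_conc <- NULL
  lat_cor <- NULL
  if (!is.null(concentrations) && nrow(concentrations) > 0) {
    known_ids <- concentrations$compound_id %in% roster$compound_id
    if (any(!known_ids)) {
      warning(sum(!known_ids),
              " concentration row(s) reference unknown compounds; dropped")
    }
    conc <- concentrations[known_ids, , drop = FALSE]
    pconc <- conc[conc$compound_id %in% pos_ids, , drop = FALSE]
    if (nrow(pconc) > 0) {
      conc_summary <- lapply(split(pconc$conc_ng_g_dw, pconc$fraction),
                             function(v) {
                               list(n = length(v), mean = mean(v),
                                    min = min(v), max = max(v))
                             })
      site <- split(pconc, pconc$site_id)
      site_summary <- do.call(rbind, lapply(site, function(d) {
        data.frame(site_id = d$site_id[1], latitude = d$latitude[1],
                   total_conc_ng_g_dw = sum(d$conc_ng_g_dw),
                   n_observations = nrow(d), stringsAsFactors = FALSE)
      }))
      site_summary <- site_summary[order(-site_summary$latitude), ,
                                   drop = FALSE]
      rownames(site_summary) <- NULL
      if (nrow(site_summary) >= 3) {
        rho <- suppressWarnings(
          stats::cor(site_summary$latitude,
                     site_summary$total_conc_ng_g_dw,
                     method = "spearman"))
        lat_cor <- list(
          spearman_rho = rho,
          direction = if (!is.finite(rho) || rho == 0) "none"
                      else if (rho < 0) "south-increasing"
                      else "north-increasing")
      }
      by_cpd <- split(pconc$conc_ng_g_dw, pconc$compound_id)
      peak <- vapply(by_cpd, max, numeric(1))
      ord <- order(-peak)[seq_len(min(config$top_n_concentrated,
                                      length(peak)))]
      top_conc <- data.frame(
        compound_id = names(peak)[ord],
        name = roster$name[match(names(peak)[ord], roster$compound_id)],
        max_conc_ng_g_dw = unname(peak[ord]), stringsAsFactors = FALSE)
    }
  }

  structure(list(
    n_total = n,
    class_counts = class_counts,
    step_counts = step_counts,
    n_positive = n_pos,
    positive_percent = positive_percent,
    origin_counts_positive = origin_counts,
    natural_or_undefined_percent = nat_or_undef_percent,
    noncyclic_percent_positive = noncyclic_pct,
    concentration_summary = conc_summary,
    site_summary = site_summary,
    latitude_correlation = lat_cor,
    top_concentrated = top_conc,
    config = unclass(config),
    seed = config$seed,
    assessments = assessments
  ), class = "pmt_screening_report")
}

#' @export
print.pmt_screening_report <- function(x, ...) {
  cat("PMT/vPvM screening report\n")
  cat(sprintf("  compounds screened: %d\n", x$n_total))
  cc <- x$class_counts
  cat(sprintf("  PMT %d | vPvM %d | PMT&vPvM %d | candidates %d | negative %d | unresolved %d\n",
              cc$PMT, cc$vPvM, cc$PMT_and_vPvM, cc$candidate_PMT_vPvM,
              cc$not_PMT_vPvM, cc$unresolved))
  cat(sprintf("  positive: %d (%.1f%%)\n", x$n_positive,
              x$positive_percent))
  if (!is.na(x$noncyclic_percent_positive)) {
    cat(sprintf("  noncyclic among positives: %.1f%%\n",
                x$noncyclic_percent_positive))
  }
  if (!is.null(x$concentration_summary)) {
    for (fr in names(x$concentration_summary)) {
      s <- x$concentration_summary[[fr]]
      cat(sprintf("  %s: mean %.0f ng/g dw (range %.0f-%.0f, n=%d)\n",
                  fr, s$mean, s$min, s$max, s$n))
    }
  }
  invisible(x)
}

#' Write a screening report to disk
#'
#' Emits `report.json` (machine-readable, byte-identical across re-runs
#' on identical inputs and seed), `report.md` (human summary) and
#' `assessments.csv` (the per-compound table).
#'
#' @param report a `pmt_screening_report`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  csv_path <- file.path(dir, "assessments.csv")

  payload <- unclass(report)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")

  utils::write.csv(report$assessments, csv_path, row.names = FALSE)

  cc <- report$class_counts
  lines <- c(
    "# PMT/vPvM screening report", "",
    sprintf("- Compounds screened: **%d**", report$n_total),
    sprintf("- PMT: %d, vPvM: %d, PMT&vPvM: %d, ML candidates: %d",
            cc$PMT, cc$vPvM, cc$PMT_and_vPvM, cc$candidate_PMT_vPvM),
    sprintf("- Not PMT/vPvM: %d, unresolved: %d", cc$not_PMT_vPvM,
            cc$unresolved),
    sprintf("- Positive overall: %d (%.1f%%)", report$n_positive,
            report$positive_percent),
    sprintf("- Decided by: known list %d, rules %d, ML model %d, none %d",
            report$step_counts$known_list, report$step_counts$rules,
            report$step_counts$ml_model, report$step_counts$none))
  if (!is.na(report$noncyclic_percent_positive)) {
    lines <- c(lines, sprintf("- Noncyclic among positives: %.1f%%",
                              report$noncyclic_percent_positive))
  }
  if (!is.null(report$concentration_summary)) {
    lines <- c(lines, "", "## Concentrations of positives (ng/g dw)")
    for (fr in names(report$concentration_summary)) {
      s <- report$concentration_summary[[fr]]
      lines <- c(lines, sprintf("- %s: mean %.1f, range %.1f-%.1f (n=%d)",
                                fr, s$mean, s$min, s$max, s$n))
    }
  }
  if (!is.null(report$latitude_correlation)) {
    lines <- c(lines, sprintf(
      "- Latitude vs site total: Spearman rho %.2f (%s; descriptive)",
      report$latitude_correlation$spearman_rho,
      report$latitude_correlation$direction))
  }
  lines <- c(lines, "",
             paste0("_Rule screen caveat: screening-level assessment ",
                    "following cutoff criteria, not a full ",
                    "weight-of-evidence evaluation._"))
  writeLines(lines, md_path)
  invisible(c(json_path, md_path, csv_path))
}
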