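# Ingestion and validation of compound rosters, experimental property
# tables, concentration tables and the known PMT/vPvM reference list.
#
# File formats (all plain text):
#   roster:         CSV/TSV (compound_id, name, smiles, origin, cas) or SDF
#   properties:     CSV/TSV long (compound_id, property, value, ph) with
#                   property in {half_life_freshwater_d, log_koc, tox_flag}
#   concentrations: CSV/TSV (compound_id, site_id, latitude, depth_cm,
#                   fraction, conc_ng_g_dw)
#   known list:     CSV (match_key, listed_class)

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = TRUE)
}

normalize_origin <- function(origin, n) {
  if (is.null(origin)) origin <- rep(NA_character_, n)
  origin <- tolower(trimws(as.character(origin)))
  origin[is.na(origin) | origin == "" | origin == "unknown"] <- "undefined"
  bad <- setdiff(unique(origin), ORIGIN_LEVELS)
  if (length(bad) > 0) {
    stop("unrecognized origin label(s): ", paste(bad, collapse = ", "),
         " (expected synthetic/natural/undefined)")
  }
  origin
}

build_roster <- function(df) {
  required <- c("compound_id", "smiles")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$compound_id <- trimws(as.character(df$compound_id))
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id in roster: ",
         paste(unique(df$compound_id[duplicated(df$compound_id)]),
               collapse = ", "))
  }
  if (is.null(df$name)) df$name <- df$compound_id
  if (is.null(df$cas)) df$cas <- NA_character_
  df$cas <- trimws(as.character(df$cas))
  df$cas[df$cas == ""] <- NA_character_
  df$origin <- normalize_origin(df$origin, nrow(df))

  can <- canonical_smiles(df$smiles)
  ok <- !is.na(can)
  rejects <- data.frame(
    row = which(!ok),
    compound_id = df$compound_id[!ok],
    smiles = as.character(df$smiles)[!ok],
    reason = rep("unparseable structure", sum(!ok)),
    stringsAsFactors = FALSE
  )
  roster <- data.frame(
    compound_id = df$compound_id[ok],
    name = as.character(df$name)[ok],
    smiles = as.character(df$smiles)[ok],
    canonical_smiles = can[ok],
    origin = df$origin[ok],
    cas = df$cas[ok],
    stringsAsFactors = FALSE
  )
  rownames(roster) <- NULL
  if (nrow(rejects) > 0) {
    warning(nrow(rejects), " structure(s) rejected as unparseable; ",
            "see attr(x, \"rejects\")")
  }
  structure(roster, rejects = rejects, class = c("pmt_roster", "data.frame"))
}

#' Read a compound roster
#'
#' Reads a roster of compounds from a delimited table (CSV/TSV with columns
#' `compound_id`, `name`, `smiles`, `origin`, `cas`; only id and SMILES are
#' mandatory) or from an SDF file carrying equivalent tags. Structures are
#' canonicalized on ingestion; rows whose SMILES cannot be parsed are not an
#' error — they are dropped and collected in the `"rejects"` attribute with
#' a reason, so that reject count + accepted count always equals the input
#' row count. A missing or empty origin label becomes the explicit
#' `"undefined"` bucket. Duplicated `compound_id`s are an error.
#'
#' @param path path to a `.csv`/`.tsv` roster or a `.sdf` file.
#' @return a `pmt_roster` data frame with columns `compound_id`, `name`,
#'   `smiles`, `canonical_smiles`, `origin`, `cas`, and a `"rejects"`
#'   attribute (data frame of rejected rows).
#' @seealso [canonicalize_and_dedup()], [write_roster()]
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdf <- ChemmineR::read.SDFset(path)
    db <- ChemmineR::datablock(sdf)
    get_tag <- function(block, tag) {
      if (tag %in% names(block)) block[[tag]] else NA_character_
    }
    df <- data.frame(
      compound_id = vapply(seq_along(db), function(i) {
        v <- get_tag(db[[i]], "compound_id")
        if (is.na(v)) ChemmineR::sdfid(sdf[i]) else v
      }, character(1)),
      name = vapply(db, get_tag, character(1), tag = "name"),
      smiles = vapply(seq_along(sdf), function(i) {
        tryCatch(trimws(sub("\t.*$", "",
          ChemmineOB::convertFormat("SDF", "SMI",
            paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")))),
          error = function(e) NA_character_)
      }, character(1)),
      origin = vapply(db, get_tag, character(1), tag = "origin"),
      cas = vapply(db, get_tag, character(1), tag = "cas"),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read_delim_auto(path)
  }
  build_roster(df)
}

#' Construct a roster from an in-memory data frame
#'
#' Same validation and canonicalization as [read_roster()] but starting from
#' a data frame (used by the simulator and by tests).
#'
#' @param df data frame with at least `compound_id` and `smiles`.
#' @return a `pmt_roster` data frame; see [read_roster()].
#' @export
as_roster <- function(df) build_roster(as.data.frame(df))

#' Write a roster to CSV
#'
#' @param roster a `pmt_roster`.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(as.data.frame(roster)[, c("compound_id", "name", "smiles",
                                             "origin", "cas")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Canonicalize and deduplicate a roster
#'
#' Merges records that share the same canonical structure, keeping the first
#' `compound_id` in roster order. The origin of a merged record follows the
#' precedence synthetic > natural > undefined (conservative toward the
#' anthropogenic interpretation); the first non-missing CAS is kept and the
#' merge provenance is recorded in the `"merge_log"` attribute. Applying the
#' operation twice gives the same result as applying it once.
#'
#' @param roster a `pmt_roster`.
#' @return a deduplicated `pmt_roster` with a `"merge_log"` attribute
#'   (data frame: kept_id, dropped_id, canonical_smiles).
#' @export
canonicalize_and_dedup <- function(roster) {
  stopifnot(is.data.frame(roster), "canonical_smiles" %in% names(roster))
  groups <- split(seq_len(nrow(roster)), roster$canonical_smiles)
  keep_rows <- sort(vapply(groups, min, integer(1)))
  out <- as.data.frame(roster)[keep_rows, , drop = FALSE]
  log_rows <- list()
  for (g in groups) {
    if (length(g) < 2) next
    g <- sort(g)
    kept <- g[1]
    origins <- roster$origin[g]
    out_row <- which(keep_rows == kept)
    out$origin[out_row] <- ORIGIN_LEVELS[min(match(origins, ORIGIN_LEVELS))]
    cas <- roster$cas[g]
    cas <- cas[!is.na(cas)]
    if (length(cas) > 0) out$cas[out_row] <- cas[1]
    log_rows[[length(log_rows) + 1]] <- data.frame(
      kept_id = roster$compound_id[kept],
      dropped_id = roster$compound_id[g[-1]],
      canonical_smiles = roster$canonical_smiles[kept],
      stringsAsFactors = FALSE
    )
  }
  merge_log <- if (length(log_rows) > 0) {
    do.call(rbind, log_rows)
  } else {
    data.frame(kept_id = character(0), dropped_id = character(0),
               canonical_smiles = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, rejects = attr(roster, "rejects"), merge_log = merge_log,
            class = c("pmt_roster", "data.frame"))
}

# ---- experimental property tables ------------------------------------------

#' Convert a long property table to a property set
#'
#' The long format has columns `compound_id`, `property`, `value`, `ph` with
#' `property` one of `half_life_freshwater_d`, `log_koc`, `tox_flag`. For
#' `tox_flag` rows, `value` holds the flag name (one of CMR, aquatic_tox,
#' STOT_RE, endocrine_disruption). log Koc rows outside the pH 4-9 window
#' are dropped with a warning; rows with a negative half-life are rejected.
#' Flags are presence-only: the absence of a flag never proves
#' non-toxicity.
#'
#' @param df long-format property data frame.
#' @param config a [pmt_config()] (controls the admissible pH window).
#' @return a `pmt_properties` object: a named list of per-compound records,
#'   each with `half_lives`, `log_koc_by_ph` (data frame ph/log_koc),
#'   `tox_flags` and `evidence_quality`. Rejected rows are kept in the
#'   `"rejects"` attribute.
#' @export
as_properties <- function(df, config = pmt_config()) {
  df <- as.data.frame(df)
  required <- c("compound_id", "property", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("property table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$ph)) df$ph <- NA_real_
  df$compound_id <- trimws(as.character(df$compound_id))
  df$property <- trimws(as.character(df$property))

  rejects <- list()
  reject <- function(i, reason) {
    rejects[[length(rejects) + 1]] <<- data.frame(
      row = i, compound_id = df$compound_id[i], property = df$property[i],
      value = as.character(df$value[i]), reason = reason,
      stringsAsFactors = FALSE)
  }

  records <- list()
  rec_of <- function(id) {
    if (is.null(records[[id]])) {
      records[[id]] <<- list(
        half_lives = numeric(0),
        log_koc_by_ph = data.frame(ph = numeric(0), log_koc = numeric(0)),
        tox_flags = character(0),
        evidence_quality = "experimental")
    }
    id
  }

  n_ph_dropped <- 0L
  for (i in seq_len(nrow(df))) {
    id <- df$compound_id[i]
    prop <- df$property[i]
    if (prop == "half_life_freshwater_d") {
      v <- suppressWarnings(as.numeric(df$value[i]))
      if (is.na(v) || v <= 0) { reject(i, "non-positive or non-numeric half-life"); next }
      rec_of(id)
      records[[id]]$half_lives <- c(records[[id]]$half_lives, v)
    } else if (prop == "log_koc") {
      v <- suppressWarnings(as.numeric(df$value[i]))
      ph <- suppressWarnings(as.numeric(df$ph[i]))
      if (is.na(v)) { reject(i, "non-numeric log_koc"); next }
      if (is.na(ph) || ph < config$ph_range[1] || ph > config$ph_range[2]) {
        n_ph_dropped <- n_ph_dropped + 1L
        rec_of(id)  # evidence exists even if this row is unusable
        next
      }
      rec_of(id)
      records[[id]]$log_koc_by_ph <- rbind(
        records[[id]]$log_koc_by_ph,
        data.frame(ph = ph, log_koc = v))
    } else if (prop == "tox_flag") {
      flag <- trimws(as.character(df$value[i]))
      if (!flag %in% TOX_FLAGS) { reject(i, "unknown toxicity flag"); next }
      rec_of(id)
      records[[id]]$tox_flags <- union(records[[id]]$tox_flags, flag)
    } else {
      reject(i, "unknown property")
    }
  }
  if (n_ph_dropped > 0) {
    warning(n_ph_dropped, " log_koc row(s) outside pH ",
            config$ph_range[1], "-", config$ph_range[2], " dropped")
  }
  rejects <- if (length(rejects) > 0) do.call(rbind, rejects) else
    data.frame(row = integer(0), compound_id = character(0),
               property = character(0), value = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(records, rejects = rejects, class = "pmt_properties")
}

#' Read an experimental property table
#'
#' @param path CSV/TSV file in the long format described in
#'   [as_properties()].
#' @param config a [pmt_config()].
#' @return a `pmt_properties` object.
#' @export
read_properties <- function(path, config = pmt_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_properties(read_delim_auto(path), config = config)
}

#' Fetch the property record for one compound
#'
#' Compounds absent from the table get an empty record with
#' `evidence_quality = "none"` — missing data is explicit, never an error.
#'
#' @param properties a `pmt_properties` object (or `NULL`).
#' @param compound_id compound key.
#' @return a property record list.
#' @export
property_record <- function(properties, compound_id) {
  rec <- if (!is.null(properties)) properties[[compound_id]] else NULL
  if (is.null(rec)) {
    rec <- list(half_lives = numeric(0),
                log_koc_by_ph = data.frame(ph = numeric(0),
                                           log_koc = numeric(0)),
                tox_flags = character(0),
                evidence_quality = "none")
  }
  rec
}

# ---- concentrations ---------------------------------------------------------

#' Read a concentration table
#'
#' Observations are concentrations in ng/g dry weight of a compound at a
#' sampling site, split into the extractable fraction (EF) and
#' non-extractable residues (NER). Rows outside the 0-150 cm depth window,
#' with a negative/non-finite value, or with an unknown fraction label are
#' rejected (collected in the `"rejects"` attribute), mirroring the
#' selection applied at compilation of the monitoring data.
#'
#' @param path CSV/TSV with columns compound_id, site_id, latitude,
#'   depth_cm, fraction, conc_ng_g_dw.
#' @param max_depth_cm depth cutoff in cm (default 150).
#' @return data frame of accepted rows with a `"rejects"` attribute.
#' @export
read_concentrations <- function(path, max_depth_cm = 150) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_concentrations(read_delim_auto(path), max_depth_cm = max_depth_cm)
}

#' @rdname read_concentrations
#' @param df in-memory concentration data frame.
#' @export
as_concentrations <- function(df, max_depth_cm = 150) {
  df <- as.data.frame(df)
  required <- c("compound_id", "site_id", "latitude", "depth_cm", "fraction",
                "conc_ng_g_dw")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("concentration table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$conc_ng_g_dw <- suppressWarnings(as.numeric(df$conc_ng_g_dw))
  df$depth_cm <- suppressWarnings(as.numeric(df$depth_cm))
  ok <- !is.na(df$conc_ng_g_dw) & is.finite(df$conc_ng_g_dw) &
    df$conc_ng_g_dw >= 0 &
    !is.na(df$depth_cm) & df$depth_cm >= 0 & df$depth_cm <= max_depth_cm &
    df$fraction %in% c("EF", "NER")
  rejects <- df[!ok, , drop = FALSE]
  if (nrow(rejects) > 0) {
    warning(nrow(rejects), " concentration row(s) rejected; ",
            "see attr(x, \"rejects\")")
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejects = rejects)
}

# ---- known PMT/vPvM reference list -----------------------------------------

#' Read a known PMT/vPvM reference list
#'
#' The list maps a match key (a structure as SMILES, or a CAS registry
#' number) to a previously assessed class. Structure keys are canonicalized
#' so lookups are robust to SMILES respelling. Conflicting duplicate entries
#' (same key, different class) are a load-time error.
#'
#' @param path CSV with columns `match_key`, `listed_class` (one of PMT,
#'   vPvM, PMT_and_vPvM, not_PMT_vPvM).
#' @return data frame with columns `match_key`, `listed_class`,
#'   `key_type` (`"structure"` or `"cas"`).
#' @export
read_known_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_known_list(read_delim_auto(path))
}

#' @rdname read_known_list
#' @param df in-memory known-list data frame.
#' @export
as_known_list <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(c("match_key", "listed_class"), names(df))
  if (length(missing_cols) > 0) {
    stop("known list missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$listed_class),
                 c("PMT", "vPvM", "PMT_and_vPvM", "not_PMT_vPvM"))
  if (length(bad) > 0) {
    stop("unknown listed_class value(s): ", paste(bad, collapse = ", "))
  }
  key <- trimws(as.character(df$match_key))
  looks_cas <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", key)
  can <- rep(NA_character_, length(key))
  can[!looks_cas] <- canonical_smiles(key[!looks_cas])
  key_type <- ifelse(looks_cas, "cas",
                     ifelse(is.na(can), "cas", "structure"))
  match_key <- ifelse(key_type == "structure", can, key)
  out <- data.frame(match_key = match_key,
                    listed_class = as.character(df$listed_class),
                    key_type = key_type, stringsAsFactors = FALSE)
  dup <- duplicated(out$match_key)
  if (any(dup)) {
    conf <- vapply(unique(out$match_key[dup]), function(k) {
      length(unique(out$listed_class[out$match_key == k])) > 1
    }, logical(1))
    if (any(conf)) {
      stop("conflicting duplicate entries in known list for key(s): ",
           paste(unique(out$match_key[dup])[conf], collapse = ", "))
    }
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
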