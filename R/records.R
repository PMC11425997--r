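#' @keywords internal
"_PACKAGE"

# Canonical category orders; used for validation and for deterministic
# group ordering in reports.
fh_strategy_levels <- c("cascade", "universal", "opportunistic", "combination")
fh_outcome_levels  <- c("QALY", "LYG", "adverse_events_averted", "deaths_averted")

# Mandatory columns of the study table (internal names).
fh_study_cols <- c("study_id", "strategy_type", "outcome_measure",
                   "delta_cost", "delta_effect", "wtp")
fh_interval_cols <- c("cost_low", "cost_high", "effect_low", "effect_high")

# External (file) column names <-> internal names.
fh_csv_map <- c(study_id = "study_id",
                strategy_type = "strategy_type",
                outcome_measure = "outcome_measure",
                delta_cost_usd2023 = "delta_cost",
                delta_effect = "delta_effect",
                cost_low = "cost_low",
                cost_high = "cost_high",
                effect_low = "effect_low",
                effect_high = "effect_high",
                wtp_usd2023 = "wtp",
                perspective = "perspective")

#' Construct an interval
#'
#' A plain numeric vector `c(low, high)` with `low <= high`.  Used for
#' cost, effect, ICER and net-benefit uncertainty bounds throughout the
#' package; units are those of the bounded quantity.
#'
#' @param low,high Interval endpoints.
#' @return Named numeric vector of length 2.
#' @export
interval <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (low > high)
    stop("interval: 'low' (", low, ") must not exceed 'high' (", high, ")")
  c(low = low, high = high)
}

#' Validate a table of study records
#'
#' Checks the invariants of extracted economic-evaluation records: known
#' strategy and outcome categories, numeric incremental cost and effect,
#' strictly positive willingness-to-pay threshold, and ordered uncertainty
#' intervals where present.  Called by [load_studies()] and by the
#' synthesis functions; exported so hand-built tables can be checked too.
#'
#' @param studies A data frame of study records (internal column names:
#'   `study_id`, `strategy_type`, `outcome_measure`, `delta_cost`,
#'   `delta_effect`, `wtp`, optionally `cost_low`/`cost_high`/
#'   `effect_low`/`effect_high`, `perspective`).
#' @return The validated data frame, invisibly.
#' @export
validate_studies <- function(studies) {
  stopifnot(is.data.frame(studies))
  missing <- setdiff(fh_study_cols, names(studies))
  if (length(missing))
    stop("study table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(studies) == 0L)
    return(invisible(studies))
  for (col in c("delta_cost", "delta_effect", "wtp"))
    if (!is.numeric(studies[[col]]))
      stop("column '", col, "' must be numeric")
  bad <- which(!studies$strategy_type %in% fh_strategy_levels)
  if (length(bad))
    stop("unknown strategy_type '", studies$strategy_type[bad[1]],
         "' in row ", bad[1], " (expected one of: ",
         paste(fh_strategy_levels, collapse = ", "), ")")
  bad <- which(!studies$outcome_measure %in% fh_outcome_levels)
  if (length(bad))
    stop("unknown outcome_measure '", studies$outcome_measure[bad[1]],
         "' in row ", bad[1], " (expected one of: ",
         paste(fh_outcome_levels, collapse = ", "), ")")
  bad <- which(!is.finite(studies$wtp) | studies$wtp <= 0)
  if (length(bad))
    stop("wtp must be a positive number (row ", bad[1], ")")
  for (pair in list(c("cost_low", "cost_high"), c("effect_low", "effect_high"))) {
    if (all(pair %in% names(studies))) {
      lo <- studies[[pair[1]]]; hi <- studies[[pair[2]]]
      bad <- which(!is.na(lo) & !is.na(hi) & lo > hi)
      if (length(bad))
        stop(pair[1], " exceeds ", pair[2], " in row ", bad[1])
    }
  }
  invisible(studies)
}

#' Read study records from CSV or JSON
#'
#' Reads extracted economic-evaluation records in the package's study
#' schema.  CSV columns: `study_id, strategy_type, outcome_measure,
#' delta_cost_usd2023, delta_effect, cost_low, cost_high, effect_low,
#' effect_high, wtp_usd2023, perspective`; a JSON file carries an array of
#' objects with the same field names.  One row represents one
#' (study, outcome-measure) membership, so a publication contributing to
#' several synthesis groups appears on several rows.  Costs and thresholds
#' are expected in the reference currency-year (2023 USD); see
#' [convert_to_reference()].
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return A data frame of validated records, row order preserved, with
#'   internal column names (`delta_cost`, `wtp`, ...).
#' @seealso [write_studies()], [make_groups()]
#' @export
load_studies <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  } else {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0L) {
      # empty array: vacuous input, keep the schema
      raw <- as.data.frame(stats::setNames(
        replicate(length(fh_csv_map), character(0), simplify = FALSE),
        names(fh_csv_map)), stringsAsFactors = FALSE)
    }
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  }
  ext_needed <- names(fh_csv_map)[fh_csv_map %in% fh_study_cols]
  missing <- setdiff(ext_needed, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  keep <- intersect(names(fh_csv_map), names(raw))
  out <- raw[, keep, drop = FALSE]
  names(out) <- unname(fh_csv_map[keep])
  num_cols <- intersect(c("delta_cost", "delta_effect", fh_interval_cols, "wtp"),
                        names(out))
  for (col in num_cols) {
    v <- out[[col]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA_character_
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' in column '", col,
             "', row ", bad[1])
      out[[col]] <- parsed
    } else {
      out[[col]] <- as.numeric(v)
    }
  }
  validate_studies(out)
  out
}

#' Write study records to CSV or JSON
#'
#' Inverse of [load_studies()].  Numeric fields are serialized with 17
#' significant digits so a write/load round trip reproduces every value
#' bit-exactly.
#'
#' @param studies Validated study data frame (internal column names).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  validate_studies(studies)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  ext <- studies
  for (col in setdiff(unname(fh_csv_map), names(ext))) ext[[col]] <- NA
  ext <- ext[, unname(fh_csv_map), drop = FALSE]
  names(ext) <- names(fh_csv_map)
  # decimal serialization at 17 significant digits so doubles survive a
  # round trip bit-exactly (jsonlite's numeric writer does not)
  num <- vapply(ext, is.numeric, logical(1))
  for (col in names(ext)[num])
    ext[[col]] <- ifelse(is.na(ext[[col]]), NA_character_,
                         sprintf("%.17g", ext[[col]]))
  if (format == "csv") {
    utils::write.csv(ext, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    jsonlite::write_json(ext, path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Partition study records into synthesis groups
#'
#' Evidence is pooled only across studies that evaluated the same screening
#' strategy and reported the same outcome measure.  Records are therefore
#' partitioned by `(strategy_type, outcome_measure)`; groups are returned
#' in a fixed deterministic order (cascade before universal before
#' opportunistic/combination, then QALY, LYG, adverse events averted,
#' deaths averted) so that reports are reproducible.
#'
#' @param studies Validated study data frame.
#' @return A list of synthesis groups, each a list with elements
#'   `strategy_type`, `outcome_measure` and `records` (the sub-data-frame,
#'   original row order preserved), of class `"fh_group"`.
#' @export
make_groups <- function(studies) {
  validate_studies(studies)
  if (nrow(studies) == 0L) return(list())
  s <- factor(studies$strategy_type, levels = fh_strategy_levels)
  o <- factor(studies$outcome_measure, levels = fh_outcome_levels)
  keys <- split(seq_len(nrow(studies)), list(s, o), drop = TRUE)
  ord <- order(vapply(keys, function(i) {
    as.integer(s[i[1]]) * 10L + as.integer(o[i[1]])
  }, integer(1)))
  lapply(keys[ord], function(idx) {
    g <- list(strategy_type = studies$strategy_type[idx[1]],
              outcome_measure = studies$outcome_measure[idx[1]],
              records = studies[idx, , drop = FALSE])
    class(g) <- "fh_group"
    g
  })
}

#' @export
print.fh_group <- function(x, ...) {
  cat(sprintf("Synthesis group: %s (%s), %d record(s)\n",
              x$strategy_type, x$outcome_measure, nrow(x$records)))
  print(x$records, ...)
  invisible(x)
}

#' Construct a subgroup health distribution
#'
#' Describes how baseline health and health opportunity costs fall across
#' socioeconomic groups, ordered from most to least deprived (IMD1 =
#' most-deprived fifth).  `qale` is the baseline quality-adjusted life
#' expectancy per person (years, the h_i entering the Atkinson index);
#' `opp_share` is the proportion of forgone health borne by each group
#' (the d_j of the group net-health-benefit formula); `pop_share` is the
#' fraction of screened patients in each group.
#'
#' @param labels Character vector of group names.
#' @param qale Positive numeric vector, baseline QALE per person.
#' @param opp_share Opportunity-cost shares, summing to 1.
#' @param pop_share Population shares, summing to 1; defaults to equal.
#' @return A data frame of class `"fh_distribution"` with columns `group`,
#'   `qale`, `opp_share`, `pop_share`.
#' @seealso [default_distribution()], [generate_distribution()]
#' @export
subgroup_distribution <- function(labels, qale, opp_share,
                                  pop_share = rep(1 / length(qale), length(qale))) {
  n <- length(qale)
  if (length(labels) != n || length(opp_share) != n || length(pop_share) != n)
    stop("labels, qale, opp_share and pop_share must have equal length")
  if (any(!is.finite(qale)) || any(qale <= 0))
    stop("all qale values must be positive and finite")
  if (abs(sum(opp_share) - 1) > 1e-9)
    stop("opp_share must sum to 1 (got ", format(sum(opp_share), digits = 12), ")")
  if (abs(sum(pop_share) - 1) > 1e-9)
    stop("pop_share must sum to 1 (got ", format(sum(pop_share), digits = 12), ")")
  out <- data.frame(group = as.character(labels), qale = as.numeric(qale),
                    opp_share = as.numeric(opp_share),
                    pop_share = as.numeric(pop_share),
                    stringsAsFactors = FALSE)
  class(out) <- c("fh_distribution", "data.frame")
  out
}

#' Read a subgroup distribution from CSV
#'
#' Expects columns `group, qale, opp_share, pop_share`.
#'
#' @param path Path to the CSV file.
#' @return An `"fh_distribution"` data frame; see [subgroup_distribution()].
#' @export
load_distribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "qale", "opp_share", "pop_share")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  subgroup_distribution(raw$group, raw$qale, raw$opp_share, raw$pop_share)
}
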