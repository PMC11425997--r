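# End-to-end report generation: study CSV in, per-group synthesis JSON,
# per-scenario DCEA JSON and a human-readable summary out.  Deterministic:
# identical inputs give byte-identical output files.

fh_group_json <- function(g) {
  list(strategy = g$strategy, outcome = g$outcome, n_studies = g$n_studies,
       total_cost = g$total_cost, total_effect = g$total_effect,
       icer = g$icer, icer_low = g$icer_interval[["low"]],
       icer_high = g$icer_interval[["high"]], dominance = g$dominance,
       weights = as.numeric(g$weights), nhb = as.numeric(g$nhb),
       weighted_cost = g$weighted_cost, weighted_effect = g$weighted_effect,
       tnhb = g$tnhb, tnhb_low = g$tnhb_interval[["low"]],
       tnhb_high = g$tnhb_interval[["high"]])
}

fh_dcea_json <- function(r) {
  list(label = r$scenario$label, n_total = r$scenario$n_total,
       epsilon = r$scenario$epsilon,
       group_nhb = as.numeric(r$group_nhb), total_nhb = r$total_nhb,
       qale_pre = as.numeric(r$qale_pre), qale_post = as.numeric(r$qale_post),
       atkinson_pre = r$atkinson_pre, atkinson_post = r$atkinson_post,
       edeh_pre = r$edeh_pre, edeh_post = r$edeh_post,
       delta_edeh = r$delta_edeh, equity_impact = r$equity_impact,
       direction = r$direction)
}

#' Run the full synthesis and DCEA pipeline on input files
#'
#' Loads a study table, synthesizes every (strategy, outcome) group,
#' optionally runs an aggregate DCEA per scenario, and writes one JSON
#' file per synthesis group (`synthesis_<strategy>_<outcome>.json`), one
#' per scenario (`dcea_<label>.json`) and a `summary.txt` mirroring the
#' column structure of the published tables.  JSON is serialized at full
#' precision; the summary rounds currencies to whole dollars for display.
#'
#' @param studies_path Path to a study CSV/JSON (see [load_studies()]).
#' @param out_dir Output directory; created if absent.
#' @param distribution_path Optional subgroup-distribution CSV
#'   (see [load_distribution()]); the default quintile distribution is
#'   used when absent.
#' @param scenarios Optional data frame of DCEA scenario rows with columns
#'   `study_id, delta_cost_pp, delta_qaly_pp, wtp, n_total` (the shape of
#'   [table4_fixture()]), or a path to such a CSV.
#' @param mode Interval mode passed to [synthesize()].
#' @param epsilon Inequality aversion for the DCEA scenarios.
#' @param verbose Log progress to standard error.
#' @return Invisibly, a list with the `fh_synthesis` object, the list of
#'   `fh_dcea` results and the paths written.
#' @export
run_all <- function(studies_path, out_dir, distribution_path = NULL,
                    scenarios = NULL, mode = c("paper", "delta"),
                    epsilon = 10.95, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(...)
  studies <- load_studies(studies_path)
  if (nrow(studies) == 0L)
    stop("no study records in file: ", studies_path)
  dist <- if (is.null(distribution_path)) default_distribution()
          else load_distribution(distribution_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say("synthesizing ", nrow(studies), " records")
  fit <- synthesize(studies, mode = mode)
  paths <- character(0)
  for (g in fit$groups) {
    p <- file.path(out_dir, sprintf("synthesis_%s_%s.json",
                                    g$strategy, g$outcome))
    jsonlite::write_json(fh_group_json(g), p, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  dcea_results <- list()
  if (!is.null(scenarios)) {
    if (is.character(scenarios)) {
      scenarios <- utils::read.csv(scenarios, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(scenarios))) {
      sc <- dcea_scenario(delta_qaly_pp = scenarios$delta_qaly_pp[i],
                          delta_cost_pp = scenarios$delta_cost_pp[i],
                          wtp_threshold = scenarios$wtp[i],
                          n_total = scenarios$n_total[i],
                          distribution = dist, epsilon = epsilon,
                          label = scenarios$study_id[i])
      r <- run_dcea(sc)
      dcea_results[[scenarios$study_id[i]]] <- r
      p <- file.path(out_dir, sprintf("dcea_%s.json", scenarios$study_id[i]))
      jsonlite::write_json(fh_dcea_json(r), p, auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
      paths <- c(paths, p)
    }
  }
  sp <- file.path(out_dir, "summary.txt")
  con <- file(sp, open = "wt")
  on.exit(close(con))
  writeLines("Synthesized cost-effectiveness by group", con)
  tab <- as.data.frame(fit)
  for (col in c("total_cost", "icer", "icer_low", "icer_high",
                "weighted_cost", "tnhb", "tnhb_low", "tnhb_high"))
    tab[[col]] <- round(tab[[col]])
  writeLines(utils::capture.output(print(tab, row.names = FALSE)), con)
  if (length(dcea_results)) {
    writeLines(c("", "Aggregate DCEA by scenario"), con)
    dt <- do.call(rbind, lapply(dcea_results, function(r)
      data.frame(label = r$scenario$label,
                 total_nhb = round(r$total_nhb, 1),
                 delta_edeh = round(r$delta_edeh, 1),
                 equity_impact = round(r$equity_impact, 1),
                 direction = r$direction, stringsAsFactors = FALSE)))
    writeLines(utils::capture.output(print(dt, row.names = FALSE)), con)
  }
  paths <- c(paths, sp)
  say("wrote ", length(paths), " file(s) to ", out_dir)
  invisible(list(synthesis = fit, dcea = dcea_results, paths = paths))
}
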