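# Evidence synthesis within a (strategy, outcome) group: deterministic
# pooling of incremental costs and effects into a synthesized ICER,
# per-study net monetary benefit at each study's own willingness-to-pay
# threshold, comparative-efficiency (COMER) weights, weighted totals and
# the total net health benefit (TNHB).  This is not a likelihood-based
# meta-analysis: the pooled ICER is the ratio of sums.

#' Average multi-cohort results into one record
#'
#' Some evaluations report results separately for several cohorts (e.g.
#' screening 20- and 35-year-olds); such cohorts are combined into a
#' single study-level result by arithmetic averaging of the incremental
#' costs and of the incremental effects.
#'
#' @param cohorts A data frame or matrix with columns/cols `delta_cost`
#'   and `delta_effect`, one row per cohort, or a list of `c(cost, effect)`
#'   pairs.
#' @return Named numeric vector `c(delta_cost =, delta_effect =)`.
#' @export
combine_cohorts <- function(cohorts) {
  if (is.list(cohorts) && !is.data.frame(cohorts))
    cohorts <- do.call(rbind, lapply(cohorts, function(x) {
      data.frame(delta_cost = x[[1]], delta_effect = x[[2]])
    }))
  if (is.matrix(cohorts)) cohorts <- as.data.frame(cohorts)
  if (!all(c("delta_cost", "delta_effect") %in% names(cohorts)))
    stop("cohorts need 'delta_cost' and 'delta_effect'")
  if (nrow(cohorts) == 0L) stop("cannot combine an empty cohort list")
  c(delta_cost = mean(cohorts$delta_cost),
    delta_effect = mean(cohorts$delta_effect))
}

#' Pool incremental costs and effects of a synthesis group
#'
#' Totals are plain sums over the member studies (cost-saving studies keep
#' their negative costs in the sum); the synthesized ICER is the ratio of
#' the totals.  When the total cost is negative and the total effect
#' positive the strategy dominates its comparator and no finite ratio is
#' reported (`icer = NA`, `dominance = "dominant"`); the mirror case is
#' `"dominated"`.
#'
#' @param group An `"fh_group"` from [make_groups()], or a study data
#'   frame (treated as one group).
#' @return List with `total_cost`, `total_effect`, `icer`, `dominance`.
#' @export
pool_group <- function(group) {
  records <- if (inherits(group, "fh_group")) group$records else group
  validate_studies(records)
  if (nrow(records) == 0L) stop("cannot pool an empty group")
  total_cost <- sum(records$delta_cost)
  total_effect <- sum(records$delta_effect)
  dominance <- if (total_cost < 0 && total_effect > 0) "dominant"
               else if (total_cost > 0 && total_effect < 0) "dominated"
               else "none"
  icer <- NA_real_
  if (dominance == "none") {
    if (total_effect == 0)
      stop("pooled incremental effect is zero; ICER undefined")
    icer <- total_cost / total_effect
  }
  list(total_cost = total_cost, total_effect = total_effect,
       icer = icer, dominance = dominance)
}

#' Per-study net monetary benefit
#'
#' `wtp * delta_effect - delta_cost`, in 2023 US dollars, at the study's
#' own (converted) willingness-to-pay threshold.  Positive values mean the
#' monetized health gain exceeds the incremental cost.
#'
#' @param record One study record (data frame row or list with
#'   `delta_cost`, `delta_effect`, `wtp`), or a whole study data frame
#'   (vectorized).
#' @return Net monetary benefit(s), USD.
#' @export
net_monetary_benefit <- function(record) {
  if (is.null(record$wtp) || any(is.na(record$wtp)))
    stop("record has no willingness-to-pay threshold")
  record$wtp * record$delta_effect - record$delta_cost
}

#' Comparative-efficiency (COMER) weights
#'
#' Weights studies within a synthesis group proportionally to the inverse
#' square of their net monetary benefit: `w_i = NHB_i^-2 / sum(NHB^-2)`.
#' Studies with net benefit near zero — the efficient frontier — dominate
#' the weighted synthesis, while studies with very large |NHB| are nearly
#' ignored.  The rule is sign-insensitive (squaring), invariant to a
#' common positive rescaling of all NHB values, and undefined when any
#' NHB is exactly zero.
#'
#' @param nhb_values Numeric vector of per-study net monetary benefits,
#'   all nonzero.
#' @return Weights in `[0, 1]` summing to 1.
#' @export
comer_weights <- function(nhb_values) {
  stopifnot(is.numeric(nhb_values), length(nhb_values) >= 1L)
  if (any(!is.finite(nhb_values)))
    stop("net benefit values must be finite")
  if (any(nhb_values == 0))
    stop("COMER weights are undefined when a study's net benefit is ",
         "exactly zero; supply explicit weights instead")
  # rescale by the smallest |NHB| before squaring to dodge under/overflow
  inv2 <- (min(abs(nhb_values)) / nhb_values)^2
  inv2 / sum(inv2)
}

#' Weighted totals and total net health benefit
#'
#' Applies a weight vector (normally from [comer_weights()]) to a group's
#' incremental costs, incremental effects and per-study net benefits.
#'
#' @param records Study data frame of the group.
#' @param weights Weights summing to 1, one per record.
#' @param nhb Optional precomputed per-study net benefits; recomputed from
#'   the records when missing.
#' @return List with `weighted_cost`, `weighted_effect`, `tnhb`.
#' @export
weighted_totals <- function(records, weights, nhb = NULL) {
  if (nrow(records) != length(weights))
    stop("length mismatch: ", nrow(records), " records vs ",
         length(weights), " weights")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1")
  if (is.null(nhb)) nhb <- net_monetary_benefit(records)
  list(weighted_cost = sum(weights * records$delta_cost),
       weighted_effect = sum(weights * records$delta_effect),
       tnhb = sum(weights * nhb))
}

#' Fixed proportional interval around a point estimate
#'
#' The reproduction-mode uncertainty rule: every reported synthesis
#' interval equals the point estimate +/- 25%.  Endpoints are ordered, so
#' negative points swap them.
#'
#' @param point Point estimate.
#' @return An [interval()] `(0.75 * point, 1.25 * point)`, ordered.
#' @export
paper_interval <- function(point) {
  stopifnot(is.numeric(point), length(point) == 1L)
  if (is.na(point)) return(c(low = NA_real_, high = NA_real_))
  interval(min(0.75 * point, 1.25 * point),
           max(0.75 * point, 1.25 * point))
}

#' Delta-method confidence interval for a cost/effect ratio
#'
#' First-order Taylor (delta-method) variance of `R = c / e`:
#' `var(R) ~ R^2 * (se_c^2/c^2 + se_e^2/e^2 - 2 rho se_c se_e / (c e))`,
#' with a symmetric normal interval at the requested level.  Adequate when
#' the coefficient of variation of the denominator is small; for heavily
#' skewed ratios a simulation interval is preferable.
#'
#' @param total_cost,total_effect Pooled totals (`total_effect != 0`).
#' @param se_cost,se_effect Standard errors of the totals.
#' @param correlation Cost-effect correlation `rho` (default 0).
#' @param level Coverage level in (0, 1), default 0.95.
#' @return An [interval()] around the ratio.
#' @export
delta_icer_ci <- function(total_cost, total_effect, se_cost, se_effect,
                          correlation = 0, level = 0.95) {
  stopifnot(is.finite(total_cost), is.finite(total_effect),
            is.finite(se_cost), is.finite(se_effect),
            se_cost >= 0, se_effect >= 0,
            correlation >= -1, correlation <= 1,
            level > 0, level < 1)
  if (total_effect == 0) stop("total_effect must be nonzero")
  r <- total_cost / total_effect
  vr <- r^2 * (se_cost^2 / total_cost^2 + se_effect^2 / total_effect^2 -
                 2 * correlation * se_cost * se_effect /
                 (total_cost * total_effect))
  if (!is.finite(vr) || vr < 0)
    stop("delta-method variance is not finite and nonnegative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(vr)
  interval(r - half, r + half)
}

# SE from a +/-50% default interval read as a 95% normal interval.
se_from_interval <- function(low, high) (high - low) / 2 / stats::qnorm(0.975)

#' Synthesize an evidence base of FH screening evaluations
#'
#' The main fitting function.  Partitions the study records into
#' (strategy, outcome) groups, pools each group's incremental costs and
#' effects into a synthesized ICER, computes per-study net monetary
#' benefit at study-specific thresholds, derives COMER weights
#' (`w ~ NHB^-2`) and the weighted totals including the total net health
#' benefit, and attaches uncertainty intervals.
#'
#' Two interval modes are available.  `"paper"` (default) applies the
#' fixed proportional rule of [paper_interval()] (+/- 25%) to the ICER and
#' the TNHB.  `"delta"` instead derives standard errors from the per-study
#' cost/effect intervals (filled in with the +/- 50% default of
#' [default_interval()] where absent, read as 95% normal intervals) and
#' uses the delta-method ratio variance of [delta_icer_ci()] for the ICER;
#' the TNHB interval stays proportional in both modes since no sampling
#' model for the weights is defined.
#'
#' @param studies Study data frame (see [load_studies()]) or a list of
#'   `"fh_group"` objects from [make_groups()].
#' @param mode `"paper"` or `"delta"` interval propagation.
#' @param weights Optional list (or single vector) of user-supplied
#'   weights overriding the COMER rule, in group order.
#' @param level Coverage level for delta-mode intervals.
#' @return An object of class `"fh_synthesis"`: a list with elements
#'   `groups` (per-group result lists: `strategy`, `outcome`, `n_studies`,
#'   `total_cost`, `total_effect`, `icer`, `icer_interval`, `dominance`,
#'   `nhb`, `weights`, `weighted_cost`, `weighted_effect`, `tnhb`,
#'   `tnhb_interval`, `records`) and `mode`.  Has `print`, `summary`,
#'   `as.data.frame` and `coef` methods.
#' @examples
#' fit <- synthesize(table3_studies())
#' fit
#' coef(fit)
#' @export
synthesize <- function(studies, mode = c("paper", "delta"), weights = NULL,
                       level = 0.95) {
  mode <- match.arg(mode)
  groups <- if (is.data.frame(studies)) make_groups(studies)
            else studies
  if (length(groups) == 0L) stop("no study records to synthesize")
  if (!is.null(weights) && !is.list(weights)) weights <- list(weights)
  res <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    w <- if (!is.null(weights)) weights[[k]] else NULL
    res[[k]] <- synthesize_group(g, mode = mode, weights = w, level = level)
  }
  names(res) <- vapply(res, function(r) paste0(r$strategy, "(", r$outcome, ")"),
                       character(1))
  structure(list(groups = res, mode = mode), class = "fh_synthesis")
}

# One group's synthesis; records must already be cohort-averaged.
synthesize_group <- function(group, mode = "paper", weights = NULL,
                             level = 0.95) {
  records <- group$records
  pooled <- pool_group(records)
  nhb <- net_monetary_benefit(records)
  w <- if (is.null(weights)) comer_weights(nhb) else {
    if (abs(sum(weights) - 1) > 1e-9) stop("supplied weights must sum to 1")
    weights
  }
  wt <- weighted_totals(records, w, nhb)
  if (mode == "paper" || pooled$dominance != "none") {
    icer_int <- paper_interval(pooled$icer)
  } else {
    nr <- nrow(records)
    lo_c <- if (is.null(records$cost_low)) rep(NA_real_, nr) else records$cost_low
    hi_c <- if (is.null(records$cost_high)) rep(NA_real_, nr) else records$cost_high
    miss <- is.na(lo_c) | is.na(hi_c)
    if (any(miss)) {
      dflt <- t(vapply(records$delta_cost[miss], default_interval, numeric(2)))
      lo_c[miss] <- dflt[, 1]; hi_c[miss] <- dflt[, 2]
    }
    lo_e <- if (is.null(records$effect_low)) rep(NA_real_, nr) else records$effect_low
    hi_e <- if (is.null(records$effect_high)) rep(NA_real_, nr) else records$effect_high
    miss <- is.na(lo_e) | is.na(hi_e)
    if (any(miss)) {
      dflt <- t(vapply(records$delta_effect[miss], default_interval, numeric(2)))
      lo_e[miss] <- dflt[, 1]; hi_e[miss] <- dflt[, 2]
    }
    se_c <- sqrt(sum(se_from_interval(lo_c, hi_c)^2))
    se_e <- sqrt(sum(se_from_interval(lo_e, hi_e)^2))
    icer_int <- delta_icer_ci(pooled$total_cost, pooled$total_effect,
                              se_c, se_e, level = level)
  }
  list(strategy = group$strategy_type, outcome = group$outcome_measure,
       n_studies = nrow(records),
       total_cost = pooled$total_cost, total_effect = pooled$total_effect,
       icer = pooled$icer, icer_interval = icer_int,
       dominance = pooled$dominance,
       nhb = nhb, weights = w,
       weighted_cost = wt$weighted_cost,
       weighted_effect = wt$weighted_effect,
       tnhb = wt$tnhb, tnhb_interval = paper_interval(wt$tnhb),
       records = records)
}

#' @export
print.fh_synthesis <- function(x, ...) {
  cat("Synthesized cost-effectiveness of FH screening (", x$mode,
      "-mode intervals)\n\n", sep = "")
  df <- as.data.frame(x)
  show <- df[, c("strategy", "outcome", "n_studies", "icer", "icer_low",
                 "icer_high", "tnhb")]
  for (col in c("icer", "icer_low", "icer_high", "tnhb"))
    show[[col]] <- round(show[[col]])
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.fh_synthesis <- function(object, ...) {
  structure(list(table = as.data.frame(object), mode = object$mode,
                 groups = object$groups),
            class = "summary.fh_synthesis")
}

#' @export
print.summary.fh_synthesis <- function(x, ...) {
  cat("Evidence synthesis,", length(x$groups), "group(s),", x$mode,
      "mode\n\n")
  for (g in x$groups) {
    cat(sprintf("%s (%s): %d studies\n", g$strategy, g$outcome, g$n_studies))
    cat(sprintf("  total cost %s USD; total effect %s; ICER %s (%s to %s)%s\n",
                format(round(g$total_cost), big.mark = ","),
                format(g$total_effect),
                ifelse(is.na(g$icer), "--", format(round(g$icer), big.mark = ",")),
                format(round(g$icer_interval[["low"]]), big.mark = ","),
                format(round(g$icer_interval[["high"]]), big.mark = ","),
                ifelse(g$dominance == "none", "", paste0(" [", g$dominance, "]"))))
    cat(sprintf("  COMER weights: %s\n",
                paste(sprintf("%.4f", g$weights), collapse = ", ")))
    cat(sprintf("  weighted cost %s; weighted effect %s; TNHB %s USD\n",
                format(round(g$weighted_cost), big.mark = ","),
                format(round(g$weighted_effect, 2)),
                format(round(g$tnhb), big.mark = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.fh_synthesis <- function(x, ...) {
  rows <- lapply(x$groups, function(g) {
    data.frame(strategy = g$strategy, outcome = g$outcome,
               n_studies = g$n_studies, total_cost = g$total_cost,
               total_effect = g$total_effect, icer = g$icer,
               icer_low = g$icer_interval[["low"]],
               icer_high = g$icer_interval[["high"]],
               dominance = g$dominance,
               weighted_cost = g$weighted_cost,
               weighted_effect = g$weighted_effect,
               tnhb = g$tnhb,
               tnhb_low = g$tnhb_interval[["low"]],
               tnhb_high = g$tnhb_interval[["high"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.fh_synthesis <- function(object, ...) {
  stats::setNames(vapply(object$groups, function(g) g$icer, numeric(1)),
                  names(object$groups))
}
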