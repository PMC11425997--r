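# Aggregate distributional cost-effectiveness analysis (DCEA).
#
# A screening scenario is summarized by its per-person incremental QALYs
# and cost, an opportunity-cost threshold K, the number of people screened
# N, and a subgroup distribution describing baseline health (QALE) and the
# socioeconomic gradient in who bears the health opportunity cost.  The
# analysis (i) allocates the net health benefit across groups,
# NHB_j = dQALY * n_j - N * dcost * d_j / K,
# (ii) adds each group's per-person share to its baseline QALE,
# (iii) summarizes inequality before and after with the Atkinson index
# A(eps) and the equally distributed equivalent health
# EDEH = N * (1 - A) * mean(h), and (iv) reports the population equity
# impact dEDEH - dNHB, positive when screening narrows the health gap.

#' Construct a DCEA scenario
#'
#' @param delta_qaly_pp Incremental QALYs per screened person.
#' @param delta_cost_pp Incremental cost per screened person (2023 USD or
#'   the study's currency, consistent with `wtp_threshold`).
#' @param wtp_threshold Opportunity-cost threshold K per QALY (> 0): the
#'   rate at which spending displaces health elsewhere in the system.
#' @param n_total Total number of people screened (> 0).
#' @param distribution An `"fh_distribution"`
#'   (see [subgroup_distribution()]); defaults to the five-quintile IMD
#'   distribution of [default_distribution()].
#' @param epsilon Atkinson inequality-aversion parameter (>= 0); the
#'   default 10.95 is an empirical UK estimate.
#' @param label Optional scenario label.
#' @return A list of class `"fh_scenario"`.
#' @export
dcea_scenario <- function(delta_qaly_pp, delta_cost_pp, wtp_threshold,
                          n_total, distribution = default_distribution(),
                          epsilon = 10.95, label = NULL) {
  stopifnot(inherits(distribution, "fh_distribution"))
  if (!is.finite(n_total) || n_total <= 0) stop("n_total must be positive")
  if (!is.finite(wtp_threshold) || wtp_threshold <= 0)
    stop("wtp_threshold must be positive")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  structure(list(delta_qaly_pp = delta_qaly_pp,
                 delta_cost_pp = delta_cost_pp,
                 wtp_threshold = wtp_threshold, n_total = n_total,
                 distribution = distribution, epsilon = epsilon,
                 label = label),
            class = "fh_scenario")
}

#' @export
print.fh_scenario <- function(x, ...) {
  cat("DCEA scenario", if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  dQALY/person %.4g, dcost/person %.4g, K %.4g, N %.4g, eps %.4g\n",
              x$delta_qaly_pp, x$delta_cost_pp, x$wtp_threshold, x$n_total,
              x$epsilon))
  invisible(x)
}

#' Allocate the screened population across subgroups
#'
#' `n_j = n_total * pop_share_j`, kept real-valued (no rounding to whole
#' persons), so shares are honoured exactly.
#'
#' @param n_total Total screened population (> 0).
#' @param distribution An `"fh_distribution"`.
#' @return Numeric vector of per-group counts.
#' @export
allocate_population <- function(n_total, distribution) {
  stopifnot(inherits(distribution, "fh_distribution"))
  if (!is.finite(n_total) || n_total <= 0) stop("n_total must be positive")
  n_total * distribution$pop_share
}

#' Group-level net health benefit
#'
#' `NHB_j = dQALY * n_j - N * dcost * d_j / K`: each group's share of the
#' health gain minus its share `d_j` of the health forgone when `N * dcost`
#' of spending displaces other care at the threshold `K`.  Groups bearing
#' a large opportunity-cost share can come out negative.
#'
#' @param scenario An `"fh_scenario"`.
#' @return Numeric vector of NHB_j in QALYs, one per group.
#' @export
group_nhb <- function(scenario) {
  stopifnot(inherits(scenario, "fh_scenario"))
  d <- scenario$distribution
  n_j <- allocate_population(scenario$n_total, d)
  scenario$delta_qaly_pp * n_j -
    scenario$n_total * scenario$delta_cost_pp * d$opp_share /
      scenario$wtp_threshold
}

#' Population net health benefit
#'
#' Closed form `dQALY * N - N * dcost / K`; because the opportunity-cost
#' shares sum to 1 this equals the sum of the group-level benefits exactly.
#'
#' @param scenario An `"fh_scenario"`.
#' @return Total NHB in QALYs.
#' @export
total_nhb <- function(scenario) {
  stopifnot(inherits(scenario, "fh_scenario"))
  scenario$n_total * (scenario$delta_qaly_pp -
                        scenario$delta_cost_pp / scenario$wtp_threshold)
}

#' Atkinson inequality index
#'
#' `A(eps) = 1 - ((1/n) sum_i (h_i / hbar)^(1 - eps))^(1 / (1 - eps))`,
#' with the mean taken (unweighted) over the groups.  `A` lies in `[0, 1)`,
#' equals 0 iff all `h_i` are equal or `eps = 0`, and increases with the
#' aversion parameter `eps` for a fixed unequal distribution.  At
#' `eps = 1` the defining limit is the geometric mean:
#' `A = 1 - GM(h) / mean(h)`.
#'
#' @param h Positive per-person health levels (QALE, years), one per group.
#' @param epsilon Inequality aversion, `>= 0`.
#' @param pop_share Optional population shares for a weighted variant of
#'   the group mean (for non-quintile groupings); the default `NULL`
#'   weights groups equally, as the index is defined over equal-sized
#'   quintiles.
#' @return The index value.
#' @export
atkinson_index <- function(h, epsilon, pop_share = NULL) {
  stopifnot(is.numeric(h), length(h) >= 1L)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("Atkinson index requires strictly positive health levels")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  w <- if (is.null(pop_share)) rep(1 / length(h), length(h)) else {
    if (length(pop_share) != length(h)) stop("pop_share length mismatch")
    pop_share / sum(pop_share)
  }
  m <- sum(w * h)
  if (epsilon == 1)
    return(1 - exp(sum(w * log(h))) / m)
  1 - sum(w * (h / m)^(1 - epsilon))^(1 / (1 - epsilon))
}

#' Equally distributed equivalent health
#'
#' `EDEH = N * (1 - A(eps)) * mean(h)`: the total health that, shared
#' perfectly equally, would yield the same social welfare as the actual
#' distribution.  Never exceeds `N * mean(h)`, with equality iff the
#' distribution is equal (or `eps = 0`).
#'
#' @inheritParams atkinson_index
#' @param n_total Total number of patients screened (> 0).
#' @return Total EDEH in QALYs.
#' @export
edeh <- function(h, epsilon, n_total, pop_share = NULL) {
  if (!is.finite(n_total) || n_total <= 0) stop("n_total must be positive")
  a <- atkinson_index(h, epsilon, pop_share)
  w <- if (is.null(pop_share)) rep(1 / length(h), length(h))
       else pop_share / sum(pop_share)
  n_total * (1 - a) * sum(w * h)
}

#' Post-intervention QALE by group
#'
#' Folds each group's net health benefit back into its baseline health:
#' `qale_post_j = qale_pre_j + NHB_j / n_j` (the per-person increment).
#'
#' @param qale_pre Baseline per-person QALE by group.
#' @param group_nhb Group net health benefits (QALYs), as from
#'   [group_nhb()].
#' @param n_j Group population counts, all positive.
#' @return Updated per-person QALE vector.
#' @export
post_intervention_qale <- function(qale_pre, group_nhb, n_j) {
  if (length(qale_pre) != length(group_nhb) ||
      length(qale_pre) != length(n_j))
    stop("qale_pre, group_nhb and n_j must have equal length")
  if (any(!is.finite(n_j)) || any(n_j <= 0))
    stop("every group population must be positive")
  qale_pre + group_nhb / n_j
}

#' Run an aggregate distributional cost-effectiveness analysis
#'
#' Executes the full pipeline for one scenario: population allocation,
#' group and total net health benefit, pre/post health distributions,
#' Atkinson indices, EDEH before and after, and the population equity
#' impact `dEDEH - dNHB` with its direction (positive = the screening
#' programme reduces health inequality).
#'
#' @param scenario An `"fh_scenario"` from [dcea_scenario()].
#' @return An object of class `"fh_dcea"` exposing all intermediates:
#'   `n_j`, `group_nhb`, `total_nhb`, `qale_pre`, `qale_post`,
#'   `atkinson_pre`, `atkinson_post`, `edeh_pre`, `edeh_post`,
#'   `delta_edeh`, `equity_impact`, `direction`, plus the scenario.
#'   Has `print`, `summary` and `plot` methods.
#' @examples
#' sc <- dcea_scenario(delta_qaly_pp = 16.9, delta_cost_pp = 335088,
#'                     wtp_threshold = 20000, n_total = 10000)
#' run_dcea(sc)
#' @export
run_dcea <- function(scenario) {
  stopifnot(inherits(scenario, "fh_scenario"))
  d <- scenario$distribution
  n_j <- allocate_population(scenario$n_total, d)
  nhb_j <- group_nhb(scenario)
  tot <- total_nhb(scenario)
  qale_pre <- d$qale
  qale_post <- post_intervention_qale(qale_pre, nhb_j, n_j)
  if (any(qale_post <= 0))
    stop("post-intervention QALE is non-positive for group(s) ",
         paste(d$group[qale_post <= 0], collapse = ", "),
         "; the Atkinson index requires positive health levels")
  eps <- scenario$epsilon
  a_pre <- atkinson_index(qale_pre, eps)
  a_post <- atkinson_index(qale_post, eps)
  e_pre <- scenario$n_total * (1 - a_pre) * mean(qale_pre)
  e_post <- scenario$n_total * (1 - a_post) * mean(qale_post)
  delta_edeh <- e_post - e_pre
  equity <- delta_edeh - tot
  direction <- if (equity > 0) "reduces_inequality"
               else if (equity < 0) "increases_inequality" else "neutral"
  structure(list(scenario = scenario, n_j = n_j, group_nhb = nhb_j,
                 total_nhb = tot, qale_pre = qale_pre,
                 qale_post = qale_post, atkinson_pre = a_pre,
                 atkinson_post = a_post, edeh_pre = e_pre,
                 edeh_post = e_post, delta_edeh = delta_edeh,
                 equity_impact = equity, direction = direction),
            class = "fh_dcea")
}

#' @export
print.fh_dcea <- function(x, ...) {
  lab <- x$scenario$label
  cat("Aggregate DCEA", if (!is.null(lab)) paste0("'", lab, "'"), "\n")
  cat(sprintf("  total NHB   %12.1f QALYs\n", x$total_nhb))
  cat(sprintf("  delta EDEH  %12.1f QALYs\n", x$delta_edeh))
  cat(sprintf("  equity impact (dEDEH - dNHB) %.1f QALYs -> %s\n",
              x$equity_impact, gsub("_", " ", x$direction)))
  invisible(x)
}

#' @export
summary.fh_dcea <- function(object, ...) {
  d <- object$scenario$distribution
  tab <- data.frame(group = d$group, n = object$n_j,
                    nhb = object$group_nhb, qale_pre = object$qale_pre,
                    qale_post = object$qale_post,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, result = object), class = "summary.fh_dcea")
}

#' @export
print.summary.fh_dcea <- function(x, ...) {
  print(x$result)
  cat(sprintf("  Atkinson A(eps=%.4g): pre %.6f, post %.6f\n",
              x$result$scenario$epsilon, x$result$atkinson_pre,
              x$result$atkinson_post))
  cat("\nPer-group breakdown:\n")
  tab <- x$table
  tab$n <- round(tab$n, 1); tab$nhb <- round(tab$nhb, 1)
  tab$qale_pre <- round(tab$qale_pre, 3)
  tab$qale_post <- round(tab$qale_post, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot pre/post health distributions
#'
#' Side-by-side bars of per-person QALE by socioeconomic group before and
#' after the screening programme.
#'
#' @param x An `"fh_dcea"` result.
#' @param ... Passed to [graphics::barplot()].
#' @return The result, invisibly.
#' @export
plot.fh_dcea <- function(x, ...) {
  d <- x$scenario$distribution
  m <- rbind(pre = x$qale_pre, post = x$qale_post)
  colnames(m) <- d$group
  graphics::barplot(m, beside = TRUE, legend.text = c("pre", "post"),
                    ylab = "QALE per person (years)",
                    xlab = "socioeconomic group", ...)
  invisible(x)
}
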