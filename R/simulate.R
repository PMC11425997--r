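# Synthetic evidence bases with known ground truth, so every pipeline
# stage is testable without external data.

#' Generate a synthetic set of study records
#'
#' Draws per-study incremental effects lognormally, sets costs to
#' `true_icer * effect * (1 + noise)` with Gaussian multiplicative noise of
#' coefficient of variation `cost_noise_cv`, optionally flips a study to
#' cost-saving with probability `dominance_prob`, and draws each study's
#' willingness-to-pay threshold uniformly over `wtp_range`.  With zero
#' noise and no dominance the pooled ICER of any generated set equals
#' `true_icer` exactly (ratio-of-sums construction).  The +/- 50% default
#' intervals of [default_interval()] are attached to every record.
#'
#' @param n_studies Number of records (>= 1).
#' @param true_icer Ground-truth cost per effect unit.
#' @param effect_scale Median of the lognormal effect distribution.
#' @param effect_sdlog Lognormal log-scale SD of effects.  The default 0.2
#'   keeps the effective sample size of the ratio-of-sums estimator close
#'   to `n_studies` (the pooled ICER is an effect-weighted mean of the
#'   cost noise, so heavy effect spread slows its convergence); published
#'   evidence bases with order-of-magnitude effect spreads are emulated by
#'   raising it.
#' @param cost_noise_cv Coefficient of variation of cost noise (>= 0).
#' @param wtp_range Length-2 range for per-study thresholds.
#' @param dominance_prob Probability a study is flipped to cost-saving.
#' @param seed Optional integer seed; same seed, same records.
#' @param strategy_type,outcome_measure Category labels for the records.
#' @return A validated study data frame (see [load_studies()] schema).
#' @export
generate_studies <- function(n_studies, true_icer, effect_scale = 1,
                             effect_sdlog = 0.2, cost_noise_cv = 0.2,
                             wtp_range = c(20000, 150000),
                             dominance_prob = 0, seed = NULL,
                             strategy_type = "cascade",
                             outcome_measure = "QALY") {
  stopifnot(n_studies >= 1, cost_noise_cv >= 0,
            dominance_prob >= 0, dominance_prob <= 1,
            length(wtp_range) == 2L, wtp_range[1] > 0,
            wtp_range[2] >= wtp_range[1])
  if (!is.null(seed)) set.seed(as.integer(seed))
  eff <- stats::rlnorm(n_studies, meanlog = log(effect_scale),
                       sdlog = effect_sdlog)
  noise <- if (cost_noise_cv > 0)
    stats::rnorm(n_studies, 0, cost_noise_cv) else rep(0, n_studies)
  cost <- true_icer * eff * (1 + noise)
  flip <- stats::runif(n_studies) < dominance_prob
  cost[flip] <- -abs(cost[flip])
  wtp <- stats::runif(n_studies, wtp_range[1], wtp_range[2])
  ci <- t(vapply(cost, default_interval, numeric(2)))
  ei <- t(vapply(eff, default_interval, numeric(2)))
  out <- data.frame(
    study_id = sprintf("sim%03d", seq_len(n_studies)),
    strategy_type = strategy_type, outcome_measure = outcome_measure,
    delta_cost = cost, delta_effect = eff,
    cost_low = ci[, 1], cost_high = ci[, 2],
    effect_low = ei[, 1], effect_high = ei[, 2],
    wtp = wtp, perspective = "synthetic",
    stringsAsFactors = FALSE)
  validate_studies(out)
  out
}

#' Generate an interpolated subgroup distribution
#'
#' Builds an `n_groups`-group distribution by linear interpolation between
#' the endpoints of a baseline-health gradient (most- to least-deprived)
#' and of an opportunity-cost-share gradient; shares are renormalized to
#' sum to 1 while preserving their ratio structure.  Population shares are
#' equal (deprivation quintiles are population quintiles by construction).
#'
#' @param gradient `c(qale_most_deprived, qale_least_deprived)` in years;
#'   must be nondecreasing.
#' @param opp_gradient `c(share_most_deprived, share_least_deprived)`,
#'   both positive.
#' @param n_groups Number of groups (default 5, IMD1-IMD5).
#' @return An `"fh_distribution"`; see [subgroup_distribution()].
#' @export
generate_distribution <- function(gradient, opp_gradient, n_groups = 5) {
  stopifnot(length(gradient) == 2L, length(opp_gradient) == 2L,
            n_groups >= 2)
  if (gradient[1] > gradient[2])
    stop("qale gradient must be nondecreasing (most- to least-deprived)")
  if (any(opp_gradient <= 0)) stop("opportunity-cost shares must be positive")
  qale <- seq(gradient[1], gradient[2], length.out = n_groups)
  shares <- seq(opp_gradient[1], opp_gradient[2], length.out = n_groups)
  shares <- shares / sum(shares)
  subgroup_distribution(paste0("IMD", seq_len(n_groups)), qale, shares)
}

#' Default IMD-quintile distribution
#'
#' Baseline QALE interpolated linearly between 63.21 years (IMD1, most
#' deprived) and 75.00 years (IMD5, least deprived); opportunity-cost
#' shares interpolated between 26% and 14% (summing to 1); equal
#' population fifths.  The interpolation stands in for the unpublished
#' middle-quintile values; both vectors are overridable via
#' [subgroup_distribution()].
#'
#' @return An `"fh_distribution"` with five rows.
#' @export
default_distribution <- function() {
  generate_distribution(c(63.21, 75.00), c(0.26, 0.14), 5)
}
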