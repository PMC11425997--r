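# Frozen regression constants, computed once with 50-digit
# arbitrary-precision arithmetic by direct evaluation of the defining
# formulas (independent of the package implementation).
# Inputs: h = (63.21, 66.1575, 69.105, 72.0525, 75.00).
ATKINSON_DEFAULT_EPS1095 <- 0.019366776160740114
ATKINSON_DEFAULT_EPS1 <- 0.0018232229889186770
EDE_PP_DEFAULT_EPS1095 <- 67.766658933412054

# Independent, spreadsheet-style recomputation of the full DCEA pipeline:
# every step written out directly from the defining formulas, no package
# functions.
oracle_dcea <- function(dq, dc, K, N, qale, opp_share,
                        pop_share = rep(1 / length(qale), length(qale)),
                        eps = 10.95) {
  atk <- function(h, e) {
    m <- sum(h) / length(h)
    if (e == 1) {
      gm <- prod(h)^(1 / length(h))
      1 - gm / m
    } else {
      1 - (sum((h / m)^(1 - e)) / length(h))^(1 / (1 - e))
    }
  }
  n_j <- N * pop_share
  nhb_j <- dq * n_j - N * dc * opp_share / K
  h_pre <- qale
  h_post <- qale + nhb_j / n_j
  a_pre <- atk(h_pre, eps)
  a_post <- atk(h_post, eps)
  e_pre <- N * (1 - a_pre) * sum(h_pre) / length(h_pre)
  e_post <- N * (1 - a_post) * sum(h_post) / length(h_post)
  tot <- dq * N - N * dc / K
  list(n_j = n_j, nhb_j = nhb_j, a_pre = a_pre, a_post = a_post,
       edeh_pre = e_pre, edeh_post = e_post,
       total_nhb = tot, delta_edeh = e_post - e_pre,
       equity = (e_post - e_pre) - tot)
}

# Tiny fixture used by several files.
toy_studies <- function() {
  data.frame(study_id = c("a", "b", "c"),
             strategy_type = c("cascade", "cascade", "universal"),
             outcome_measure = c("QALY", "QALY", "LYG"),
             delta_cost = c(100, 200, -50),
             delta_effect = c(2, 5, 1),
             cost_low = NA_real_, cost_high = NA_real_,
             effect_low = NA_real_, effect_high = NA_real_,
             wtp = c(50000, 60000, 30000),
             perspective = "test", stringsAsFactors = FALSE)
}
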