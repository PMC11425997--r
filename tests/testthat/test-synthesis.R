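test_that("cohort averaging is the arithmetic mean of costs and effects", {
  q <- spencer_cohorts("QALY")
  expect_equal(combine_cohorts(q),
               c(delta_cost = 20836899.42, delta_effect = 97.5))
  l <- spencer_cohorts("LYG")
  expect_equal(combine_cohorts(l),
               c(delta_cost = 20836899.42, delta_effect = 61.5))
  expect_equal(combine_cohorts(list(c(123.4, 5.6))),
               c(delta_cost = 123.4, delta_effect = 5.6))
  expect_error(combine_cohorts(q[0, ]), "empty")
})

test_that("pooling sums costs and effects and flags dominance", {
  g <- make_groups(table3_studies())[[1]]   # cascade QALY
  p <- pool_group(g)
  expect_equal(p$total_cost, 39711734.41)
  expect_equal(p$total_effect, 800.15)
  expect_equal(p$icer, 39711734.41 / 800.15)
  expect_identical(p$dominance, "none")

  one <- toy_studies()[1, ]; one$delta_cost <- 100; one$delta_effect <- 2
  expect_equal(pool_group(one)$icer, 50)
  one$delta_cost <- -100
  pd <- pool_group(one)
  expect_identical(pd$dominance, "dominant")
  expect_true(is.na(pd$icer))
  one$delta_cost <- 100; one$delta_effect <- 0
  expect_error(pool_group(one), "zero")
})

test_that("pooled ICER is invariant to record order and cohort splitting", {
  s <- toy_studies()[1:2, ]
  expect_equal(pool_group(s)$icer, pool_group(s[2:1, ])$icer)
  # replace record 1 by two cohorts whose mean equals it
  split1 <- rbind(s, s[1, ], s[1, ])
  split1$delta_cost[c(1, 3, 4)] <- c(NA, 80, 120)
  split1$delta_effect[c(1, 3, 4)] <- c(NA, 1.5, 2.5)
  avg <- combine_cohorts(split1[3:4, c("delta_cost", "delta_effect")])
  merged <- s
  merged$delta_cost[1] <- avg[["delta_cost"]]
  merged$delta_effect[1] <- avg[["delta_effect"]]
  expect_equal(pool_group(merged)$icer, pool_group(s)$icer)
})

test_that("net monetary benefit is wtp * effect - cost", {
  kerr <- list(delta_cost = 4702.79, delta_effect = 0.48, wtp = 50730.8125)
  expect_equal(net_monetary_benefit(kerr), 19648)
  expect_equal(net_monetary_benefit(
    list(delta_cost = 0, delta_effect = 0, wtp = 12345)), 0)
  ademi <- list(delta_cost = -852.31, delta_effect = 1.07, wtp = 21043.6355140187)
  expect_equal(net_monetary_benefit(ademi), 23369, tolerance = 1e-9)
  expect_error(net_monetary_benefit(list(delta_cost = 1, delta_effect = 1)),
               "threshold")
})

test_that("COMER weights follow the inverse-squared net-benefit rule", {
  w <- comer_weights(c(19648, 23369, 57823, 547516, 36563))
  expect_equal(round(w, 4), c(0.4734, 0.3346, 0.0547, 0.0006, 0.1367))
  expect_equal(sum(w), 1)
  expect_equal(comer_weights(c(7, 7, 7)), rep(1 / 3, 3))
  # sign-insensitive squaring
  w2 <- comer_weights(c(806993, -64766053, 159735, -28968295))
  expect_equal(w2[1], 0.0377, tolerance = 1e-2)
  expect_equal(w2[3], 0.9623, tolerance = 1e-3)
  expect_lt(w2[2], 1e-5)
  expect_lt(w2[4], 1e-4)
  expect_error(comer_weights(c(1, 0, 2)), "zero")
})

test_that("COMER weights are scale-invariant, permutation-equivariant and
           decreasing in |NHB|", {
  set.seed(7)
  for (i in 1:20) {
    nhb <- stats::rlnorm(5, 10, 2) * sample(c(-1, 1), 5, replace = TRUE)
    w <- comer_weights(nhb)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(comer_weights(nhb * 17.3), w)
    p <- sample(5)
    expect_equal(comer_weights(nhb[p]), w[p])
    expect_identical(order(w), order(-abs(nhb)))
  }
  # extreme magnitude ranges must not under/overflow
  w <- comer_weights(c(1e-150, 1e150))
  expect_equal(w, c(1, 0))
})

test_that("weighted totals reproduce the published group aggregates", {
  g <- make_groups(table3_studies())[[1]]
  nhb <- g$records$nhb_printed
  w <- comer_weights(nhb)
  wt <- weighted_totals(g$records, w, nhb)
  expect_equal(wt$weighted_cost, 34991, tolerance = 2e-4)
  expect_equal(wt$weighted_effect, 2.99, tolerance = 2e-3)
  expect_equal(wt$tnhb, 25614, tolerance = 2e-4)

  one <- g$records[1, ]
  wt1 <- weighted_totals(one, 1, nhb[1])
  expect_equal(wt1$weighted_cost, one$delta_cost)
  expect_equal(wt1$tnhb, nhb[1])
  expect_error(weighted_totals(g$records, c(0.5, 0.5)), "mismatch")
})

test_that("reproduction-mode intervals are exactly point +/- 25%", {
  expect_equal(paper_interval(49630.4),
               c(low = 37222.8, high = 62038.0))
  expect_equal(paper_interval(0), c(low = 0, high = 0))
  expect_equal(paper_interval(4451.1), c(low = 3338.325, high = 5563.875))
  for (v in c(-5563039, -1, 0.5, 25614, 49630)) {
    iv <- paper_interval(v)
    expect_equal(sort(c(0.75 * v, 1.25 * v)), unname(iv))
  }
})

test_that("delta-method ratio interval matches its closed form", {
  expect_equal(delta_icer_ci(100, 2, 0, 0), c(low = 50, high = 50))
  z <- qnorm(0.975)
  expect_equal(delta_icer_ci(100, 2, 10, 0),
               c(low = 50 * (1 - z * 0.1), high = 50 * (1 + z * 0.1)))
  # correlation tightens the interval when cost and effect move together
  wide <- delta_icer_ci(100, 2, 10, 0.1, correlation = 0)
  tight <- delta_icer_ci(100, 2, 10, 0.1, correlation = 0.9)
  expect_lt(diff(tight), diff(wide))
  expect_error(delta_icer_ci(100, 0, 1, 1), "nonzero")
})

test_that("the full synthesis reconstructs every published table cell", {
  fit <- synthesize(table3_studies())
  fixture <- table3_fixture()
  expect_length(fit$groups, 7L)
  for (k in seq_along(fit$groups)) {
    g <- fit$groups[[k]]
    fx <- fixture[[k]]
    # per-study net benefit within 1 USD of the printed column
    expect_true(all(abs(g$nhb - fx$records$nhb_printed) <= 1),
                label = paste("NHB cells,", names(fit$groups)[k]))
    # TNHB within 0.1% of the printed cell
    expect_equal(g$tnhb, fx$printed$tnhb_printed, tolerance = 1e-3,
                 label = paste("TNHB,", names(fit$groups)[k]))
    # weight cells within 0.0005 (one known misprint excluded: the
    # cascade/deaths 0.9633 cell, recomputed 0.96226)
    dw <- abs(g$weights - fx$records$weight_printed)
    misprint <- g$strategy == "cascade" &
      g$outcome == "deaths_averted" & fx$records$study_id == "Ademi40"
    expect_true(all(dw[!misprint] <= 5e-4),
                label = paste("weights,", names(fit$groups)[k]))
  }
  # cascade TNHBs positive, universal TNHBs negative
  tnhb <- vapply(fit$groups, `[[`, 0, "tnhb")
  expect_true(all(tnhb[1:4] > 0))
  expect_true(all(tnhb[5:7] < 0))
})

test_that("synthesis object methods expose the group table", {
  fit <- synthesize(toy_studies())
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 2L)
  expect_true(all(c("icer", "tnhb", "dominance") %in% names(df)))
  expect_named(coef(fit), c("cascade(QALY)", "universal(LYG)"))
  expect_output(print(fit), "cascade")
  expect_output(print(summary(fit)), "COMER weights")
})

test_that("delta mode changes the ICER interval unless variances imply it", {
  s <- toy_studies()[1:2, ]
  paper <- synthesize(s, mode = "paper")$groups[[1]]$icer_interval
  delta <- synthesize(s, mode = "delta")$groups[[1]]$icer_interval
  expect_false(isTRUE(all.equal(unname(paper), unname(delta))))
  # reported study intervals take precedence over the +/-50% default
  s$cost_low <- s$delta_cost * 0.99; s$cost_high <- s$delta_cost * 1.01
  s$effect_low <- s$delta_effect * 0.99; s$effect_high <- s$delta_effect * 1.01
  tight <- synthesize(s, mode = "delta")$groups[[1]]$icer_interval
  expect_lt(diff(tight), diff(delta))
})
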