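test_that("population allocation honours shares without rounding", {
  d <- default_distribution()
  expect_equal(allocate_population(10000, d), rep(2000, 5))
  expect_equal(allocate_population(6393, d), rep(1278.6, 5))
  skew <- subgroup_distribution(paste0("g", 1:5), rep(70, 5),
                                rep(0.2, 5), c(1, 0, 0, 0, 0))
  expect_equal(allocate_population(1, skew), c(1, 0, 0, 0, 0))
  expect_error(allocate_population(-3, d), "positive")
})

test_that("group net health benefit follows the allocation formula", {
  mckay <- dcea_scenario(delta_qaly_pp = 16.9, delta_cost_pp = 335088,
                         wtp_threshold = 20000, n_total = 10000)
  nhb <- group_nhb(mckay)
  expect_equal(nhb[1], 16.9 * 2000 - 10000 * 335088 * 0.26 / 20000)
  expect_equal(nhb[1], -9761.44)
  # zero cost: pure health gain
  free <- dcea_scenario(16.9, 0, 20000, 10000)
  expect_equal(group_nhb(free), 16.9 * allocate_population(10000, free$distribution))
  # a group bearing no opportunity cost keeps its full gain
  d <- subgroup_distribution(paste0("g", 1:5), seq(63, 75, length.out = 5),
                             c(0.4, 0.3, 0.2, 0.1, 0))
  sc <- dcea_scenario(1, 1000, 20000, 1000, distribution = d)
  expect_equal(group_nhb(sc)[5], 1 * 200)
})

test_that("total NHB matches the closed form and the published column", {
  mckay <- dcea_scenario(16.9, 335088, 20000, 10000)
  expect_equal(total_nhb(mckay), 1456)
  chen <- dcea_scenario(0.49, 5989, 150000, 1000)
  expect_equal(total_nhb(chen), 450.0733, tolerance = 1e-6)
  # break-even: monetized gain equals cost
  even <- dcea_scenario(2, 2 * 30000, 30000, 500)
  expect_equal(total_nhb(even), 0)
})

test_that("group NHBs conserve the closed-form total", {
  set.seed(11)
  for (i in 1:25) {
    d <- generate_distribution(sort(runif(2, 50, 80)),
                               runif(2, 0.05, 0.5), sample(3:8, 1))
    sc <- dcea_scenario(runif(1, 0.1, 20), runif(1, -5000, 4e5),
                        runif(1, 1e4, 2e5), runif(1, 100, 2e4),
                        distribution = d)
    expect_equal(sum(group_nhb(sc)), total_nhb(sc), tolerance = 1e-12)
  }
})

test_that("Atkinson index matches its defining formula and frozen oracle", {
  # equality or zero aversion gives zero
  expect_equal(atkinson_index(rep(70, 5), 10.95), 0)
  expect_equal(atkinson_index(c(63.21, 66.16, 69.11, 72.05, 75), 0), 0)
  h <- default_distribution()$qale
  expect_equal(atkinson_index(h, 10.95), ATKINSON_DEFAULT_EPS1095,
               tolerance = 1e-12)
  expect_equal(atkinson_index(h, 1), ATKINSON_DEFAULT_EPS1, tolerance = 1e-12)
  expect_error(atkinson_index(c(70, -1), 2), "positive")
})

test_that("Atkinson index is bounded, monotone in aversion, and respects
           Pigou-Dalton transfers", {
  set.seed(23)
  for (i in 1:20) {
    h <- runif(5, 40, 90)
    eps <- runif(1, 0.2, 15)
    a <- atkinson_index(h, eps)
    expect_gte(a, 0); expect_lt(a, 1)
    expect_lte(atkinson_index(h, eps * 0.5), a + 1e-12)
    # small mean-preserving transfer from a better-off to a worse-off group
    lo <- which.min(h); hi <- which.max(h)
    t <- 0.05 * (h[hi] - h[lo])
    h2 <- h; h2[lo] <- h2[lo] + t; h2[hi] <- h2[hi] - t
    expect_lte(atkinson_index(h2, eps), a + 1e-12)
  }
  # continuity at the geometric-mean limit
  h <- default_distribution()$qale
  expect_lt(abs(atkinson_index(h, 1 + 1e-6) - atkinson_index(h, 1)), 1e-6)
  expect_lt(abs(atkinson_index(h, 1 - 1e-6) - atkinson_index(h, 1)), 1e-6)
})

test_that("EDEH is mean health discounted by inequality", {
  expect_equal(edeh(rep(70, 4), 5, 100), 7000)
  h <- default_distribution()$qale
  expect_equal(edeh(h, 10.95, 1), EDE_PP_DEFAULT_EPS1095, tolerance = 1e-12)
  # never exceeds undiscounted total health; equality iff equal
  expect_lt(edeh(h, 10.95, 1000), 1000 * mean(h))
  expect_lte(edeh(h, 10.95, 1), mean(h))
})

test_that("post-intervention QALE adds the per-person group increment", {
  q <- c(63.21, 66.16, 69.11, 72.05, 75)
  expect_equal(post_intervention_qale(q, rep(0, 5), rep(100, 5)), q)
  expect_equal(post_intervention_qale(q, rep(50, 5), rep(100, 5)), q + 0.5)
  expect_equal(post_intervention_qale(63.21, -9761.44, 2000),
               63.21 - 4.88072)
  expect_error(post_intervention_qale(q, rep(0, 5), c(0, rep(1, 4))),
               "positive")
})

test_that("the DCEA pipeline matches an independent step-by-step oracle", {
  d <- default_distribution()
  cases <- list(
    list(dq = 16.9, dc = 335088, K = 20000, N = 10000),
    list(dq = 0.48, dc = 2781, K = 30000, N = 6393),
    list(dq = 1.07, dc = -1134, K = 28000, N = 1000),
    # opportunity cost concentrated on the least-deprived group
    list(dq = 0.5, dc = 20000, K = 30000, N = 5000,
         dist = subgroup_distribution(paste0("g", 1:5), d$qale,
                                      c(0.02, 0.03, 0.05, 0.1, 0.8))))
  for (cs in cases) {
    dist <- if (is.null(cs$dist)) d else cs$dist
    sc <- dcea_scenario(cs$dq, cs$dc, cs$K, cs$N, distribution = dist)
    got <- run_dcea(sc)
    want <- oracle_dcea(cs$dq, cs$dc, cs$K, cs$N, dist$qale, dist$opp_share)
    expect_equal(got$group_nhb, want$nhb_j, tolerance = 1e-9)
    expect_equal(got$total_nhb, want$total_nhb, tolerance = 1e-9)
    expect_equal(got$atkinson_pre, want$a_pre, tolerance = 1e-9)
    expect_equal(got$atkinson_post, want$a_post, tolerance = 1e-9)
    expect_equal(got$edeh_pre, want$edeh_pre, tolerance = 1e-6)
    expect_equal(got$delta_edeh, want$delta_edeh, tolerance = 1e-6)
    expect_equal(got$equity_impact, want$equity, tolerance = 1e-6)
  }
})

test_that("symmetric scenarios have zero equity impact", {
  eq <- subgroup_distribution(paste0("g", 1:5), rep(70, 5), rep(0.2, 5))
  sc <- dcea_scenario(1, 10000, 20000, 1000, distribution = eq)
  r <- run_dcea(sc)
  expect_equal(r$atkinson_pre, 0)
  expect_equal(r$atkinson_post, 0)
  expect_equal(r$delta_edeh, r$total_nhb)
  expect_equal(r$equity_impact, 0)
  expect_identical(r$direction, "neutral")
})

test_that("cost-saving cascade screening reduces inequality under defaults", {
  ademi <- dcea_scenario(1.07, -1134, 28000, 1000, label = "Ademi40")
  r <- run_dcea(ademi)
  expect_equal(r$total_nhb, 1110.5, tolerance = 1e-3)
  expect_identical(r$direction, "reduces_inequality")
  expect_gt(r$equity_impact, 0)
  expect_equal(sum(r$group_nhb), r$total_nhb, tolerance = 1e-9)
})

test_that("equity impact is invariant to consistent group relabeling", {
  d <- default_distribution()
  p <- c(3, 1, 5, 2, 4)
  dp <- subgroup_distribution(d$group[p], d$qale[p], d$opp_share[p],
                              d$pop_share[p])
  a <- run_dcea(dcea_scenario(0.48, 2781, 30000, 6393, distribution = d))
  b <- run_dcea(dcea_scenario(0.48, 2781, 30000, 6393, distribution = dp))
  expect_equal(a$equity_impact, b$equity_impact, tolerance = 1e-10)
  expect_equal(a$group_nhb[p], b$group_nhb, tolerance = 1e-10)
})

test_that("runs abort when post-intervention health is driven non-positive", {
  sc <- dcea_scenario(0.01, 1e9, 20000, 100)
  expect_error(run_dcea(sc), "positive health")
})

test_that("result methods print and plot", {
  r <- run_dcea(dcea_scenario(16.9, 335088, 20000, 10000, label = "McKay"))
  expect_output(print(r), "equity impact")
  expect_output(print(summary(r)), "Atkinson")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(r))
})
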