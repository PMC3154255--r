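test_that("a fully collapsed PSA reproduces the deterministic run exactly", {
  p <- degenerate_params()
  det <- deterministic_run(p)
  samples <- run_psa(p, n_runs = 2, seed = 99)
  expect_identical(samples$d_cost_hc[1], samples$d_cost_hc[2])
  expect_identical(samples$d_cost_hc[1], det$incremental$d_cost_hc)
  expect_identical(samples$d_cost_soc[1], det$incremental$d_cost_soc)
  expect_identical(samples$d_dalys[1], det$incremental$d_dalys_averted)
  expect_identical(attr(samples, "rejected_draws"), 0L)
})

test_that("PSA runs are reproducible and replayable draw by draw", {
  p <- base_params()
  a <- run_psa(p, n_runs = 20, seed = 7)
  b <- run_psa(p, n_runs = 20, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # replay run 13 from the master seed only
  rp <- psa_draw(p, seed = 7, i = 13)
  counts <- cascade_counts(rp$params)
  econ_ref <- scenario_economics(run_cohort(rp$params, "reference"),
                                 rp$params, counts$n_treated)
  econ_int <- scenario_economics(run_cohort(rp$params, "intervention"),
                                 rp$params, counts$n_treated, counts)
  expect_identical(a$d_cost_hc[13], econ_int$cost_hc_total - econ_ref$cost_hc_total)
  expect_identical(a$d_dalys[13], econ_ref$dalys - econ_int$dalys)
})

test_that("a null intervention averts nothing and costs its own delivery", {
  p <- null_intervention_params()
  samples <- run_psa(p, n_runs = 30, seed = 5)
  expect_true(all(abs(samples$d_dalys) < 1e-9))
  # with the cascade fixed, every draw's extra cost is the one-off
  # screening + intervention cost
  det <- deterministic_run(p)
  one_off <- det$screening_cost + det$intervention_cost
  expect_true(all(abs(samples$d_cost_hc - one_off) < 1e-6))
  expect_true(all(abs(samples$d_cost_soc - one_off) < 1e-6))
})

test_that("PSA mean increments carry the expected signs under base specs", {
  p <- base_params()
  samples <- run_psa(p, n_runs = 300, seed = 1)
  expect_gt(mean(samples$d_dalys), 0)
  expect_lt(mean(samples$d_cost_soc), 0)
})

test_that("cost-effectiveness plane fractions classify crafted points", {
  four <- fake_psa(d_cost_hc = c(1, -1, -1, 1), d_dalys = c(1, 1, -1, -1))
  expect_equal(ce_plane(four, "healthcare"),
               c(NE = 0.25, SE = 0.25, SW = 0.25, NW = 0.25))
  all_se <- fake_psa(d_cost_hc = c(-2, -1), d_dalys = c(1, 2))
  expect_equal(ce_plane(all_se, "healthcare")[["SE"]], 1)
  # boundary: zero cost counts as "not additional cost"
  edge <- fake_psa(d_cost_hc = 0, d_dalys = 1)
  expect_equal(ce_plane(edge, "healthcare")[["SE"]], 1)
  expect_equal(sum(ce_plane(four, "healthcare")), 1, tolerance = 1e-9)
})

test_that("acceptability curve equals the net-monetary-benefit definition", {
  set.seed(42)
  s <- fake_psa(d_cost_hc = rnorm(500, 10, 40), d_dalys = rnorm(500, 2, 1))
  cc <- ceac(s, wtp = c(0, 10, 100), perspective = "healthcare")
  expect_equal(cc$probability[1], mean(s$d_cost_hc <= 0))
  expect_equal(cc$probability[3],
               mean(100 * s$d_dalys - s$d_cost_hc >= 0))
  # monotone non-decreasing in willingness to pay when all effects > 0
  pos <- fake_psa(d_cost_hc = rnorm(500, 10, 40),
                  d_dalys = abs(rnorm(500, 2, 1)) + 1e-6)
  curve <- ceac(pos, wtp = seq(0, 200, 10), perspective = "healthcare")
  expect_true(all(diff(curve$probability) >= 0))
  # and it saturates at 1 for large thresholds
  expect_equal(ceac(pos, wtp = 1e9)$probability, 1)
})

test_that("two-alternative acceptability curves are coherent", {
  set.seed(9)
  s <- fake_psa(d_cost_hc = rnorm(400, 5, 30), d_dalys = rnorm(400, 1, 2))
  flipped <- fake_psa(d_cost_hc = -s$d_cost_hc, d_dalys = -s$d_dalys)
  wtp <- seq(0, 100, 5)
  a <- ceac(s, wtp)$probability
  b <- ceac(flipped, wtp)$probability
  # continuous draws: ties have probability zero, so curves sum to 1
  expect_equal(a + b, rep(1, length(wtp)), tolerance = 1e-12)
})

test_that("the ICER is invariant to the screened fraction", {
  p <- base_params()
  base <- deterministic_run(p, use_point_estimates = FALSE)
  p2 <- p
  p2$cascade$f_participate_screen <- 0.37 * p$cascade$f_participate_screen
  scaled <- deterministic_run(p2, use_point_estimates = FALSE)
  expect_lt(abs(scaled$incremental$icer_hc$ratio /
                base$incremental$icer_hc$ratio - 1), 1e-9)
  expect_lt(abs(scaled$incremental$icer_soc$ratio /
                base$incremental$icer_soc$ratio - 1), 1e-9)
  # the increments themselves scale linearly
  expect_equal(scaled$incremental$d_cost_hc, 0.37 * base$incremental$d_cost_hc,
               tolerance = 1e-9)
  expect_equal(scaled$incremental$d_dalys_averted,
               0.37 * base$incremental$d_dalys_averted, tolerance = 1e-9)
})
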