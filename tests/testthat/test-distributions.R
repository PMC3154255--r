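test_that("constant-hazard transform matches the published per-cycle values", {
  expect_lt(abs(annual_to_cycle_prob(21 / 111, 13) - 0.016), 0.0005)
  expect_lt(abs(annual_to_cycle_prob(14 / 109, 13) - 0.011), 0.0005)
  expect_identical(annual_to_cycle_prob(0, 13), 0)
  expect_identical(annual_to_cycle_prob(1, 13), 1)
})

test_that("transform is monotone, bounded by the annual probability, and invertible", {
  p <- seq(0, 1, by = 0.05)
  pc <- annual_to_cycle_prob(p, 13)
  expect_true(all(diff(pc) > 0))
  expect_true(all(pc <= p))
  expect_true(all(abs(cycle_to_annual_prob(pc, 13) - p) < 1e-12))
  expect_error(annual_to_cycle_prob(1.2), "\\[0, 1\\]")
  expect_error(annual_to_cycle_prob(-0.1), "\\[0, 1\\]")
})

test_that("beta spec means reproduce the published point estimates", {
  p <- base_params()$psa_specs
  expect_lt(abs(dist_mean(p$f_participate_screen) - 0.725), 0.001)
  expect_lt(abs(dist_mean(p$f_screened_to_interview) - 0.095), 0.001)
  expect_lt(abs(dist_mean(p$f_not_excluded) - 0.595), 0.001)
  expect_lt(abs(dist_mean(p$qol_sub) - 0.906), 0.001)
  expect_equal(dist_mean(dist_spec("beta", 1, 1, point_estimate = 0.5)), 0.5)
})

test_that("sampling is reproducible, respects support, and converges to the mean", {
  spec <- dist_spec("beta", 106, 11, point_estimate = 106 / 117)
  x <- dist_sample(spec, 50000, seed = 42)
  expect_lt(abs(mean(x) - 0.906), 0.005)
  expect_true(all(x >= 0 & x <= 1))
  expect_identical(x, dist_sample(spec, 50000, seed = 42))

  g <- moments_to_gamma(268, 150, 419)
  y <- dist_sample(g, 20000, seed = 7)
  expect_true(all(y > 0))
  expect_lt(abs(mean(y) - 268) / 268, 0.02)
})

test_that("degenerate specs short-circuit to the point estimate", {
  g <- moments_to_gamma(132, 132, 132)
  expect_true(g$degenerate)
  expect_identical(dist_sample(g, 5, seed = 1), rep(132, 5))
  expect_identical(dist_mean(g), 132)
})

test_that("method-of-moments gamma reconstruction has the requested moments", {
  # oracle: recompute mean and sd from the returned shape and scale
  g <- moments_to_gamma(132, 73, 207)
  expect_equal(g$shape_a * g$shape_b, 132, tolerance = 1e-12)
  expect_equal(sqrt(g$shape_a) * g$shape_b, (207 - 73) / (2 * 1.96),
               tolerance = 1e-12)
  g2 <- moments_to_gamma(268, 150, 419)
  expect_equal(g2$shape_a * g2$shape_b, 268, tolerance = 1e-12)
  expect_error(moments_to_gamma(-5, -6, 1), "positive")
})

test_that("spec invariants are enforced at construction", {
  expect_error(dist_spec("beta", -1, 2, point_estimate = 0.5), "positive")
  expect_error(dist_spec("beta", 2, 2, point_estimate = 1.5), "\\[0, 1\\]")
  expect_error(dist_spec("gamma", 2, 2, point_estimate = 5,
                         ci_low = 6, ci_high = 7), "ci_low")
  expect_silent(dist_spec("gamma", 2, 2, point_estimate = 5))
})
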