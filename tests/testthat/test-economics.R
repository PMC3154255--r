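test_that("discount factors follow the closed form", {
  expect_identical(discount_factor(0.04, 0, 13), 1)
  expect_equal(discount_factor(0.04, 13, 13), 1 / 1.04, tolerance = 1e-12)
  expect_equal(discount_factor(0.015, 65, 13), 1.015^-5, tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1), "non-negative")
  expect_error(discount_factor(0.04, -1), ">= 0")
})

test_that("a person-year in a state accrues its disability weight in DALYs", {
  p <- base_params()
  p$grid$horizon_cycles <- 13L
  in_mde <- constant_trajectory(p, "MDE_1")
  expect_equal(dalys(in_mde, p, cohort_size = 1, discount = FALSE), 0.46,
               tolerance = 1e-12)
  in_sub <- constant_trajectory(p, "SUB")
  expect_equal(dalys(in_sub, p, cohort_size = 1, discount = FALSE), 0.097,
               tolerance = 1e-12)
  # zero weights annihilate
  p$weights <- list(dw_sub = 0, dw_mde = 0, dw_rec = 0)
  expect_identical(dalys(in_mde, p, discount = FALSE), 0)
  # discounting can only shrink the total
  p <- base_params()
  p$grid$horizon_cycles <- 13L
  expect_lt(dalys(constant_trajectory(p, "MDE_1"), p),
            dalys(constant_trajectory(p, "MDE_1"), p, discount = FALSE))
})

test_that("cycle costs price states at the published per-cycle amounts", {
  p <- base_params()
  p$grid$horizon_cycles <- 1L
  sub <- constant_trajectory(p, "SUB")
  expect_equal(cycle_costs(sub, p, "healthcare", discount = FALSE), 132)
  mde <- constant_trajectory(p, "MDE_1")
  expect_equal(cycle_costs(mde, p, "societal", discount = FALSE), 615)
  # recovered persons are costed like sub-threshold under usual care
  rec <- constant_trajectory(p, "REC_5")
  expect_equal(cycle_costs(rec, p, "healthcare", discount = FALSE), 132)
  # intervention-scenario sub-threshold carries the treatment-year cost
  sub_int <- constant_trajectory(p, "SUB", scenario = "intervention")
  expect_equal(cycle_costs(sub_int, p, "healthcare", discount = FALSE), 139)
  # an empty cohort costs nothing
  expect_identical(cycle_costs(sub, p, "healthcare", cohort_size = 0), 0)
})

test_that("ICER labelling follows the quadrant of the mean increments", {
  expect_equal(icer(0, 10)$ratio, 0)
  expect_equal(icer(0, 10)$label, "ratio")
  cs <- icer(-390e6, 12e3)
  expect_equal(cs$label, "cost saving")
  dom <- icer(5e6, -100)
  expect_equal(dom$label, "dominated")
  expect_equal(icer(16.8e6, 12e3)$ratio, 1400)
  und <- icer(1e6, 0)
  expect_true(is.na(und$ratio))
  expect_equal(und$label, "undefined")
})

test_that("identical scenarios yield zero increments apart from one-off costs", {
  p <- base_params()
  p$transitions$p_inc_year_int <- p$transitions$p_inc_year_ref
  p$costs$sub_int_hc <- p$costs$sub_ref_hc
  p$costs$sub_int_soc <- p$costs$sub_ref_soc
  p$discounts <- list(rate_costs = 0, rate_effects = 0)
  counts <- cascade_counts(p)
  ref <- scenario_economics(run_cohort(p, "reference"), p, counts$n_treated)
  int <- scenario_economics(run_cohort(p, "intervention"), p,
                            counts$n_treated, counts)
  inc <- incremental_results(ref, int)
  expect_identical(inc$d_dalys_averted, 0)
  expect_equal(inc$d_cost_hc, int$one_off, tolerance = 1e-12)
  expect_equal(inc$d_cost_soc, int$one_off, tolerance = 1e-12)
})

test_that("DALYs and costs are linear in cohort size", {
  p <- base_params()
  traj <- run_cohort(p, "reference")
  expect_equal(dalys(traj, p, cohort_size = 1000), 1000 * dalys(traj, p),
               tolerance = 1e-12)
  expect_equal(cycle_costs(traj, p, "societal", cohort_size = 1000),
               1000 * cycle_costs(traj, p, "societal"), tolerance = 1e-12)
})

test_that("the intervention scenario requires cascade counts for one-off costs", {
  p <- base_params()
  traj <- run_cohort(p, "intervention")
  expect_error(scenario_economics(traj, p, 1000), "counts")
})
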