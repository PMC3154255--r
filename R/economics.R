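#' Discount factor for a model cycle
#'
#' Continuous-in-cycles compounding: `(1 + rate)^(-cycle / cycles_per_year)`.
#' Costs and health effects carry different annual rates (4% and 1.5%
#' in the base case, per Dutch guidance), so the factor is computed per
#' quantity.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (0-based; vectorised).
#' @param cycles_per_year Cycles per year (default 13).
#' @return Discount factor(s); 1 at cycle 0.
#' @export
discount_factor <- function(rate, cycle, cycles_per_year = 13L) {
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  if (any(cycle < 0)) stop("`cycle` must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle / cycles_per_year)
}

state_weight_vector <- function(params) {
  states <- state_names(params)
  w <- numeric(length(states))
  w[states == "SUB"] <- params$weights$dw_sub
  w[grepl("^MDE", states)] <- params$weights$dw_mde
  w[grepl("^REC", states)] <- params$weights$dw_rec
  w
}

state_cost_vector <- function(params, scenario, phase,
                              perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  states <- state_names(params)
  cost <- params$costs
  sub <- if (scenario == "intervention" && phase == "effect") {
    if (perspective == "healthcare") cost$sub_int_hc else cost$sub_int_soc
  } else {
    if (perspective == "healthcare") cost$sub_ref_hc else cost$sub_ref_soc
  }
  mde <- if (perspective == "healthcare") cost$mde_hc else cost$mde_soc
  # recovered persons are costed like sub-threshold persons under usual care
  rec <- if (perspective == "healthcare") cost$sub_ref_hc else cost$sub_ref_soc
  v <- numeric(length(states))
  v[states == "SUB"] <- sub
  v[grepl("^MDE", states)] <- mde
  v[grepl("^REC", states)] <- rec
  v
}

cycle_time_weights <- function(traj, params) {
  # time lived during cycle t is attributed to the state occupied at the
  # start of cycle t; with the half-cycle correction the entry/exit rows
  # get half weight and the state at each recorded cycle the average of
  # adjacent cycles is approximated by trapezoid weights
  horizon <- params$grid$horizon_cycles
  if (isTRUE(params$options$half_cycle_correction)) {
    w <- rep(1, horizon + 1L)
    w[1L] <- 0.5
    w[horizon + 1L] <- 0.5
    w
  } else {
    c(rep(1, horizon), 0)
  }
}

#' Disability-adjusted life years accrued over a trajectory
#'
#' Each cycle contributes time-in-state (one thirteenth of a year)
#' multiplied by the occupied state's disability weight, discounted at
#' the annual effects rate.  No mortality component: DALYs here are
#' pure years lived with disability.
#'
#' @param traj A [run_cohort()] trajectory.
#' @param params An `mcp_params` object (supplies weights, discount
#'   rate and grid).
#' @param cohort_size Number of persons the trajectory represents.
#' @param discount If `FALSE`, report undiscounted DALYs.
#' @return DALYs (a single number).
#' @examples
#' # one person spending a full year in a major depressive episode
#' # accrues dw_mde = 0.46 undiscounted DALYs
#' @export
dalys <- function(traj, params, cohort_size = 1, discount = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  horizon <- params$grid$horizon_cycles
  w_state <- state_weight_vector(params)
  w_time <- cycle_time_weights(traj, params)
  df <- if (discount) {
    discount_factor(params$discounts$rate_effects, 0:horizon,
                    params$grid$cycles_per_year)
  } else {
    rep(1, horizon + 1L)
  }
  per_cycle <- drop(traj$occupancy %*% w_state) # dw-weighted cohort fraction
  sum(per_cycle * w_time * df) * params$grid$cycle_years * cohort_size
}

#' Cycle costs accrued over a trajectory
#'
#' Sums per-cycle state costs (health-care or societal perspective;
#' the societal figures already include health-care costs) over the
#' horizon, discounted at the annual cost rate.  During the effect
#' phase of the intervention scenario the sub-threshold state carries
#' the under-treatment cost; afterwards health-service use reverts to
#' the usual-care level.  One-off screening/intervention costs are not
#' included here (see [cascade_costs()]).
#'
#' @param traj A [run_cohort()] trajectory.
#' @param params An `mcp_params` object.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param cohort_size Number of persons the trajectory represents.
#' @param discount If `FALSE`, report undiscounted costs.
#' @return Costs in euros (a single number).
#' @export
cycle_costs <- function(traj, params,
                        perspective = c("healthcare", "societal"),
                        cohort_size = 1, discount = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  perspective <- match.arg(perspective)
  horizon <- params$grid$horizon_cycles
  eff <- params$transitions$effect_duration_cycles
  v_eff <- state_cost_vector(params, traj$scenario, "effect", perspective)
  v_post <- state_cost_vector(params, traj$scenario, "post", perspective)
  w_time <- cycle_time_weights(traj, params)
  df <- if (discount) {
    discount_factor(params$discounts$rate_costs, 0:horizon,
                    params$grid$cycles_per_year)
  } else {
    rep(1, horizon + 1L)
  }
  in_effect <- (0:horizon) < eff
  per_cycle <- ifelse(in_effect,
                      drop(traj$occupancy %*% v_eff),
                      drop(traj$occupancy %*% v_post))
  sum(per_cycle * w_time * df) * cohort_size
}

#' Economic summary of one scenario
#'
#' @param traj A [run_cohort()] trajectory.
#' @param params An `mcp_params` object.
#' @param cohort_size Number of persons entering the model.
#' @param counts Optional [cascade_counts()]; required for the
#'   intervention scenario, whose one-off screening and intervention
#'   costs are charged at t = 0.
#' @return List of class `scenario_economics`: `dalys`, `cost_hc`,
#'   `cost_soc` (cycle costs), `one_off` (0 for the reference
#'   scenario), and totals `cost_hc_total`, `cost_soc_total`.
#' @export
scenario_economics <- function(traj, params, cohort_size, counts = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  one_off <- 0
  if (traj$scenario == "intervention") {
    if (is.null(counts)) {
      stop("the intervention scenario needs cascade `counts` for its ",
           "one-off costs", call. = FALSE)
    }
    cc <- cascade_costs(counts, params)
    one_off <- cc$screening_cost + cc$intervention_cost
  }
  d <- dalys(traj, params, cohort_size)
  hc <- cycle_costs(traj, params, "healthcare", cohort_size)
  soc <- cycle_costs(traj, params, "societal", cohort_size)
  structure(list(
    dalys = d, cost_hc = hc, cost_soc = soc, one_off = one_off,
    cost_hc_total = hc + one_off, cost_soc_total = soc + one_off,
    scenario = traj$scenario
  ), class = "scenario_economics")
}

#' Incremental cost-effectiveness ratio
#'
#' The ratio of mean incremental costs to mean incremental effects.
#' Returns the ratio together with a qualitative label: `"cost saving"`
#' when the intervention both saves money and averts DALYs,
#' `"dominated"` when it costs more and loses health, `"undefined"`
#' when incremental effects are exactly zero, `"ratio"` otherwise.
#'
#' @param d_cost Mean incremental cost (euro).
#' @param d_dalys Mean incremental effect (DALYs averted; positive =
#'   health gain).
#' @return List with `ratio` (euro per DALY averted, `NA` when
#'   undefined) and `label`.
#' @export
icer <- function(d_cost, d_dalys) {
  if (d_dalys == 0) {
    return(list(ratio = NA_real_, label = "undefined"))
  }
  ratio <- d_cost / d_dalys
  label <- if (d_cost < 0 && d_dalys > 0) {
    "cost saving"
  } else if (d_cost > 0 && d_dalys < 0) {
    "dominated"
  } else {
    "ratio"
  }
  list(ratio = ratio, label = label)
}

#' Incremental results between the two scenarios
#'
#' Incremental costs are intervention minus reference (one-off
#' screening/intervention costs included); DALYs averted are reference
#' minus intervention, so positive values are health gains.
#'
#' @param ref,int [scenario_economics()] results for the reference and
#'   intervention scenarios.
#' @return List of class `incremental_result`.
#' @export
incremental_results <- function(ref, int) {
  stopifnot(inherits(ref, "scenario_economics"),
            inherits(int, "scenario_economics"))
  d_cost_hc <- int$cost_hc_total - ref$cost_hc_total
  d_cost_soc <- int$cost_soc_total - ref$cost_soc_total
  d_dalys <- ref$dalys - int$dalys
  structure(list(
    d_cost_hc = d_cost_hc,
    d_cost_soc = d_cost_soc,
    d_dalys_averted = d_dalys,
    icer_hc = icer(d_cost_hc, d_dalys),
    icer_soc = icer(d_cost_soc, d_dalys)
  ), class = "incremental_result")
}

format_icer <- function(ic) {
  if (ic$label == "cost saving") return("cost saving")
  if (ic$label == "dominated") return("dominated")
  if (ic$label == "undefined") return("undefined")
  sprintf("%s per DALY averted", format(signif(ic$ratio, 2), big.mark = ","))
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> intervention vs reference\n")
  cat(sprintf("  incremental health-care costs: %10.1f M euro\n",
              x$d_cost_hc / 1e6))
  cat(sprintf("  incremental societal costs:    %10.1f M euro\n",
              x$d_cost_soc / 1e6))
  cat(sprintf("  DALYs averted:                 %10.0f\n", x$d_dalys_averted))
  cat(sprintf("  ICER (health care):            %s\n", format_icer(x$icer_hc)))
  cat(sprintf("  ICER (societal):               %s\n", format_icer(x$icer_soc)))
  invisible(x)
}

#' Deterministic run of the full pipeline
#'
#' Runs the screening cascade, both cohort scenarios and the economic
#' accounting at a single parameterisation.  By default every
#' uncertain input is set to its PSA point estimate via
#' [psa_point_draw()] + [apply_draw()], which makes this run exactly
#' the limit of the PSA with all distributions collapsed.
#'
#' @param params An `mcp_params` object.
#' @param use_point_estimates If `FALSE`, run `params` exactly as given
#'   (no point-draw substitution).
#' @return List of class `mcp_result` with the parameterisation used,
#'   cascade counts and one-off costs, both trajectories, both
#'   [scenario_economics()] and the [incremental_results()].
#' @export
deterministic_run <- function(params, use_point_estimates = TRUE) {
  stopifnot(inherits(params, "mcp_params"))
  p <- if (use_point_estimates) {
    apply_draw(params, psa_point_draw(params$psa_specs))
  } else {
    params
  }
  counts <- cascade_counts(p)
  one_off <- cascade_costs(counts, p)
  traj_ref <- run_cohort(p, "reference")
  traj_int <- run_cohort(p, "intervention")
  econ_ref <- scenario_economics(traj_ref, p, counts$n_treated)
  econ_int <- scenario_economics(traj_int, p, counts$n_treated, counts)
  inc <- incremental_results(econ_ref, econ_int)
  structure(list(
    params_used = p,
    counts = counts,
    screening_cost = one_off$screening_cost,
    intervention_cost = one_off$intervention_cost,
    trajectories = list(reference = traj_ref, intervention = traj_int),
    economics = list(reference = econ_ref, intervention = econ_int),
    incremental = inc,
    other_hc_expenditure = inc$d_cost_hc -
      (one_off$screening_cost + one_off$intervention_cost)
  ), class = "mcp_result")
}

#' @export
print.mcp_result <- function(x, ...) {
  cat("<mcp_result> deterministic run, target population scale\n")
  cat(sprintf("  screened / treated (millions):  %.2f / %.2f\n",
              x$counts$n_screened / 1e6, x$counts$n_treated / 1e6))
  cat(sprintf("  screening costs:                %8.1f M euro\n",
              x$screening_cost / 1e6))
  cat(sprintf("  intervention costs:             %8.1f M euro\n",
              x$intervention_cost / 1e6))
  cat(sprintf("  other health-care expenditure:  %8.1f M euro\n",
              x$other_hc_expenditure / 1e6))
  print(x$incremental)
  invisible(x)
}
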