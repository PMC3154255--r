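# shared fixtures built in code

base_params <- function() default_params()

# parameter set whose PSA distributions are all collapsed to their
# point estimates (the deterministic limit of the PSA)
degenerate_params <- function() {
  p <- default_params()
  p$psa_specs <- collapse_spec(p$psa_specs)
  p
}

# null-intervention configuration: the intervention arm shares the
# reference arm's incidence and sub-threshold cost draws, so the two
# scenarios differ only by the one-off screening/intervention costs
null_intervention_params <- function(fixed_cascade = TRUE) {
  p <- default_params()
  p$psa_specs$p_inc_year_int <- "p_inc_year_ref"
  p$psa_specs$cost_sub_int_hc <- "cost_sub_ref_hc"
  p$psa_specs$cost_sub_int_soc <- "cost_sub_ref_soc"
  if (fixed_cascade) {
    for (nm in c("f_participate_screen", "f_screened_to_interview",
                 "f_not_excluded")) {
      p$psa_specs[[nm]] <- collapse_spec(p$psa_specs[[nm]])
    }
  }
  p
}

# hand-built trajectory: the whole cohort parked in one state
constant_trajectory <- function(params, state, scenario = "reference") {
  states <- state_names(params)
  horizon <- params$grid$horizon_cycles
  occ <- matrix(0, horizon + 1L, length(states),
                dimnames = list(0:horizon, states))
  occ[, state] <- 1
  structure(list(occupancy = occ, scenario = scenario, grid = params$grid),
            class = "trajectory")
}

# minimal PSA-sample table for plane/CEAC unit tests
fake_psa <- function(d_cost_hc, d_dalys, d_cost_soc = d_cost_hc) {
  df <- data.frame(draw = seq_along(d_dalys), d_cost_hc = d_cost_hc,
                   d_cost_soc = d_cost_soc, d_dalys = d_dalys)
  class(df) <- c("mcp_psa", "data.frame")
  df
}
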