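#' State space of the depression cohort model
#'
#' The semi-Markov process (recovery risk depending on episode
#' duration, relapse risk depending on time since recovery) is made
#' Markov by tunnel expansion: one sub-threshold state `SUB`, one major
#' depressive episode state per cycle already spent in the episode
#' (`MDE_1 ... MDE_S`), and one recovered state per cycle since
#' recovery (`REC_1 ... REC_S`).  The final tunnel state of each chain
#' is a holding bucket whose exit probability follows the curve's tail
#' rule.  There is no remission from sub-threshold depression and no
#' mortality, so the state space is closed.
#'
#' @param params An `mcp_params` object.
#' @return Character vector of state names.
#' @export
state_names <- function(params) {
  s_mde <- params$transitions$recovery_curve$span_cycles
  s_rec <- params$transitions$relapse_curve$span_cycles
  c("SUB", paste0("MDE_", seq_len(s_mde)), paste0("REC_", seq_len(s_rec)))
}

#' Per-cycle transition matrix
#'
#' Builds the row-stochastic transition matrix for one four-week cycle.
#' From `SUB` a person develops a major depressive episode with the
#' per-cycle incidence probability (the intervention value during the
#' effect phase of the intervention scenario, the reference value
#' otherwise) and otherwise stays sub-threshold.  From `MDE_k` a person
#' recovers with the recovery-curve probability at episode duration
#' `k`, else proceeds to `MDE_(k+1)` (holding in the last bucket).
#' From `REC_j` a person relapses into `MDE_1` with the relapse-curve
#' probability at time-since-recovery `j`, else proceeds to
#' `REC_(j+1)`.
#'
#' @param params An `mcp_params` object.
#' @param scenario `"reference"` or `"intervention"`.
#' @param phase `"effect"` (within the intervention's effect duration)
#'   or `"post"`.
#' @return A square row-stochastic matrix with state-name dimnames.
#' @export
transition_matrix <- function(params,
                              scenario = c("reference", "intervention"),
                              phase = c("effect", "post")) {
  scenario <- match.arg(scenario)
  phase <- match.arg(phase)
  tr <- params$transitions
  p_year <- if (scenario == "intervention" && phase == "effect") {
    tr$p_inc_year_int
  } else {
    tr$p_inc_year_ref
  }
  p_inc <- annual_to_cycle_prob(p_year, params$grid$cycles_per_year)

  s_mde <- tr$recovery_curve$span_cycles
  s_rec <- tr$relapse_curve$span_cycles
  states <- state_names(params)
  n <- length(states)
  m <- matrix(0, n, n, dimnames = list(states, states))

  i_sub <- 1L
  i_mde <- 1L + seq_len(s_mde)
  i_rec <- 1L + s_mde + seq_len(s_rec)

  m[i_sub, i_sub] <- 1 - p_inc
  m[i_sub, i_mde[1L]] <- p_inc

  r <- curve_prob(tr$recovery_curve, seq_len(s_mde))
  if (any(r < 0 | r > 1)) stop("recovery probabilities out of [0, 1]",
                               call. = FALSE)
  for (k in seq_len(s_mde)) {
    m[i_mde[k], i_rec[1L]] <- r[k]
    m[i_mde[k], i_mde[min(k + 1L, s_mde)]] <- 1 - r[k]
  }

  s <- curve_prob(tr$relapse_curve, seq_len(s_rec))
  if (any(s < 0 | s > 1)) stop("relapse probabilities out of [0, 1]",
                               call. = FALSE)
  for (j in seq_len(s_rec)) {
    m[i_rec[j], i_mde[1L]] <- s[j]
    m[i_rec[j], i_rec[min(j + 1L, s_rec)]] <- 1 - s[j]
  }
  m
}

#' Advance a cohort occupancy row by one cycle
#'
#' @param occupancy Named numeric vector over [state_names()] summing
#'   to 1.
#' @param cycle_index Zero-based index of the cycle being stepped
#'   through (the intervention's reduced incidence applies while
#'   `cycle_index < effect_duration_cycles`).
#' @param scenario `"reference"` or `"intervention"`.
#' @param params An `mcp_params` object.
#' @return Occupancy vector after one cycle.
#' @export
step_cohort <- function(occupancy, cycle_index,
                        scenario = c("reference", "intervention"),
                        params) {
  scenario <- match.arg(scenario)
  if (cycle_index < 0) stop("`cycle_index` must be >= 0", call. = FALSE)
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must sum to 1", call. = FALSE)
  }
  phase <- if (cycle_index < params$transitions$effect_duration_cycles) {
    "effect"
  } else {
    "post"
  }
  drop(occupancy %*% transition_matrix(params, scenario, phase))
}

#' Run the cohort through the full horizon
#'
#' Starts the whole cohort in sub-threshold depression and propagates
#' it through `horizon_cycles` four-week cycles.  Occupancy is recorded
#' at the start of each cycle (row `t` is the state distribution at
#' cycle `t`, `t = 0 .. horizon`).
#'
#' @param params An `mcp_params` object.
#' @param scenario `"reference"` (care as usual) or `"intervention"`
#'   (screening + minimal contact psychotherapy, with the reduced
#'   incidence lasting `effect_duration_cycles`).
#' @return Object of class `trajectory`: list with `occupancy`
#'   (matrix, `(horizon + 1) x n_states`, rows summing to 1),
#'   `scenario` and `grid`.
#' @export
run_cohort <- function(params, scenario = c("reference", "intervention")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "mcp_params"))
  horizon <- params$grid$horizon_cycles
  if (horizon < 1) stop("`horizon_cycles` must be >= 1", call. = FALSE)
  eff <- params$transitions$effect_duration_cycles

  m_effect <- transition_matrix(params, scenario, "effect")
  m_post <- transition_matrix(params, scenario, "post")

  states <- state_names(params)
  occ <- matrix(0, horizon + 1L, length(states),
                dimnames = list(0:horizon, states))
  occ[1L, "SUB"] <- 1
  for (t in seq_len(horizon)) {
    m <- if ((t - 1L) < eff) m_effect else m_post
    occ[t + 1L, ] <- occ[t, ] %*% m
  }
  structure(list(occupancy = occ, scenario = scenario, grid = params$grid),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  mde <- grepl("^MDE", colnames(x$occupancy))
  cat(sprintf("<trajectory> %s scenario, %d cycles, %d states\n",
              x$scenario, nrow(x$occupancy) - 1L, ncol(x$occupancy)))
  cat(sprintf("  in episode at final cycle: %.4f of cohort\n",
              sum(x$occupancy[nrow(x$occupancy), mde])))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  occ <- x$occupancy
  data.frame(
    cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE
  )
}

#' Aggregate tunnel states into the three clinical states
#'
#' @param traj A [run_cohort()] trajectory.
#' @return Matrix with columns `SUB`, `MDE`, `REC` over cycles.
#' @export
collapse_states <- function(traj) {
  occ <- traj$occupancy
  cbind(
    SUB = occ[, "SUB"],
    MDE = rowSums(occ[, grepl("^MDE", colnames(occ)), drop = FALSE]),
    REC = rowSums(occ[, grepl("^REC", colnames(occ)), drop = FALSE])
  )
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` one at a time (vectorised over persons)
#' under exactly the transition rules of [transition_matrix()], and
#' tallies state occupancy per cycle.  This is a validation oracle for
#' the cohort engine: by the law of large numbers its occupancy
#' estimates converge to [run_cohort()]'s deterministic cohort
#' fractions.
#'
#' @param params An `mcp_params` object.
#' @param scenario `"reference"` or `"intervention"`.
#' @param n_individuals Number of simulated persons.
#' @param seed Integer seed for reproducibility.
#' @param keep_paths If `TRUE`, also return the per-person state paths
#'   (integer matrix, persons x cycles; memory-heavy for large n).
#' @return Object of class `trajectory` (occupancy = empirical state
#'   fractions), with a `paths` element when `keep_paths = TRUE`.
#' @export
microsim_cohort <- function(params, scenario = c("reference", "intervention"),
                            n_individuals, seed = 1L, keep_paths = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  tr <- params$transitions
  s_mde <- tr$recovery_curve$span_cycles
  s_rec <- tr$relapse_curve$span_cycles
  states <- state_names(params)
  n_states <- length(states)
  horizon <- params$grid$horizon_cycles
  eff <- tr$effect_duration_cycles

  p_inc_eff <- annual_to_cycle_prob(
    if (scenario == "intervention") tr$p_inc_year_int else tr$p_inc_year_ref,
    params$grid$cycles_per_year)
  p_inc_post <- annual_to_cycle_prob(tr$p_inc_year_ref,
                                     params$grid$cycles_per_year)
  r <- curve_prob(tr$recovery_curve, seq_len(s_mde))
  s <- curve_prob(tr$relapse_curve, seq_len(s_rec))

  # integer state codes: 1 = SUB, 2..(1+s_mde) = MDE_k, then REC_j
  i_mde1 <- 2L
  i_rec1 <- 1L + s_mde + 1L
  state <- rep.int(1L, n_individuals)
  occ <- matrix(0, horizon + 1L, n_states,
                dimnames = list(0:horizon, states))
  occ[1L, ] <- tabulate(state, n_states) / n_individuals
  paths <- if (keep_paths) {
    p <- matrix(NA_integer_, n_individuals, horizon + 1L)
    p[, 1L] <- state
    p
  }

  for (t in seq_len(horizon)) {
    p_inc <- if ((t - 1L) < eff) p_inc_eff else p_inc_post
    u <- stats::runif(n_individuals)
    new <- state

    is_sub <- state == 1L
    new[is_sub] <- ifelse(u[is_sub] < p_inc, i_mde1, 1L)

    is_mde <- state >= i_mde1 & state < i_rec1
    if (any(is_mde)) {
      k <- state[is_mde] - 1L
      recov <- u[is_mde] < r[k]
      new[is_mde] <- ifelse(recov, i_rec1,
                            pmin(state[is_mde] + 1L, i_rec1 - 1L))
    }

    is_rec <- state >= i_rec1
    if (any(is_rec)) {
      j <- state[is_rec] - (i_rec1 - 1L)
      rel <- u[is_rec] < s[j]
      new[is_rec] <- ifelse(rel, i_mde1,
                            pmin(state[is_rec] + 1L, n_states))
    }

    state <- new
    occ[t + 1L, ] <- tabulate(state, n_states) / n_individuals
    if (keep_paths) paths[, t + 1L] <- state
  }

  out <- structure(list(occupancy = occ, scenario = scenario,
                        grid = params$grid),
                   class = "trajectory")
  if (keep_paths) out$paths <- paths
  out
}
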