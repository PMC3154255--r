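psa_draw_order <- function(specs) {
  nm <- names(specs)
  concrete <- nm[!vapply(specs, is.character, logical(1))]
  aliases <- setdiff(nm, concrete)
  list(concrete = concrete, aliases = aliases)
}

draw_is_valid <- function(draw, params) {
  frac <- draw[c("f_participate_screen", "f_screened_to_interview",
                 "f_not_excluded", "p_inc_year_ref", "p_inc_year_int",
                 "qol_sub")]
  if (any(!is.finite(draw))) return(FALSE)
  if (any(frac < 0 | frac > 1)) return(FALSE)
  cyc <- annual_to_cycle_prob(draw[c("p_inc_year_ref", "p_inc_year_int")],
                              params$grid$cycles_per_year)
  all(cyc <= 1)
}

sample_psa_draw <- function(specs, seed, params, max_tries = 100L) {
  ord <- psa_draw_order(specs)
  set.seed(seed)
  rejected <- 0L
  repeat {
    draw <- vapply(ord$concrete,
                   function(nm) dist_sample(specs[[nm]], 1L),
                   numeric(1))
    for (nm in ord$aliases) draw[nm] <- draw[[specs[[nm]]]]
    if (draw_is_valid(draw, params)) {
      attr(draw, "rejected") <- rejected
      return(draw)
    }
    rejected <- rejected + 1L
    if (rejected >= max_tries) {
      stop("PSA draw rejected ", max_tries, " times; check the ",
           "distribution specs", call. = FALSE)
    }
  }
}

#' Probabilistic sensitivity analysis
#'
#' Propagates the joint parameter uncertainty through the whole
#' pipeline: for each run, every distribution in `params$psa_specs` is
#' sampled once (independently; alias entries reuse another spec's
#' draw so that, e.g., a null-intervention configuration shares draws
#' between arms), the drawn values are installed with [apply_draw()],
#' the screening cascade and both cohort scenarios are re-run, and the
#' incremental costs (both perspectives) and DALYs averted are
#' recorded.
#'
#' Reproducibility: a single master `seed` generates one sub-seed per
#' run, so any individual run can be replayed with [psa_draw()]
#' without recomputing the rest.
#'
#' @param params An `mcp_params` object.
#' @param n_runs Number of Monte-Carlo runs (5000 in the base case).
#' @param seed Master integer seed.
#' @return Data frame of class `mcp_psa` with columns `draw`,
#'   `d_cost_hc`, `d_cost_soc`, `d_dalys`; the number of rejected
#'   draws is recorded in `attr(, "rejected_draws")`.
#' @export
run_psa <- function(params, n_runs = 5000L, seed = 1L) {
  stopifnot(inherits(params, "mcp_params"), n_runs >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, n_runs)
  out <- matrix(NA_real_, n_runs, 3L,
                dimnames = list(NULL, c("d_cost_hc", "d_cost_soc", "d_dalys")))
  rejected <- 0L
  for (i in seq_len(n_runs)) {
    draw <- sample_psa_draw(params$psa_specs, sub_seeds[i], params)
    rejected <- rejected + attr(draw, "rejected")
    p <- apply_draw(params, draw)
    counts <- cascade_counts(p)
    econ_ref <- scenario_economics(run_cohort(p, "reference"), p,
                                   counts$n_treated)
    econ_int <- scenario_economics(run_cohort(p, "intervention"), p,
                                   counts$n_treated, counts)
    out[i, "d_cost_hc"] <- econ_int$cost_hc_total - econ_ref$cost_hc_total
    out[i, "d_cost_soc"] <- econ_int$cost_soc_total - econ_ref$cost_soc_total
    out[i, "d_dalys"] <- econ_ref$dalys - econ_int$dalys
  }
  res <- data.frame(draw = seq_len(n_runs), out)
  attr(res, "rejected_draws") <- rejected
  attr(res, "seed") <- seed
  class(res) <- c("mcp_psa", "data.frame")
  res
}

#' Replay a single PSA run's parameter draw
#'
#' Regenerates the sub-seed stream of [run_psa()] and returns the
#' named draw (and the concrete parameter set) of run `i`, without
#' re-running the other draws.
#'
#' @param params An `mcp_params` object.
#' @param seed Master seed used in [run_psa()].
#' @param i Run index to replay.
#' @return List with `draw` (named numeric) and `params` (concrete
#'   `mcp_params`).
#' @export
psa_draw <- function(params, seed, i) {
  stopifnot(i >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, i)
  draw <- sample_psa_draw(params$psa_specs, sub_seeds[i], params)
  list(draw = draw, params = apply_draw(params, draw))
}

psa_columns <- function(samples, perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  list(
    d_cost = if (perspective == "healthcare") samples$d_cost_hc
             else samples$d_cost_soc,
    d_effect = samples$d_dalys
  )
}

#' Cost-effectiveness plane quadrant fractions
#'
#' Classifies each PSA run by the signs of its incremental effect
#' (east = health gain) and incremental cost (north = additional
#' cost).  Boundary convention: zero incremental cost counts as "not
#' additional cost" (south side) and zero incremental effect as "no
#' gain" (west side) — a probability-zero event for continuous draws,
#' fixed for reproducibility.
#'
#' @param samples An `mcp_psa` data frame.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return Named vector of fractions `NE`, `SE`, `SW`, `NW` summing
#'   to 1.
#' @export
ce_plane <- function(samples, perspective = c("healthcare", "societal")) {
  v <- psa_columns(samples, perspective)
  if (!length(v$d_effect)) stop("need at least one sample", call. = FALSE)
  east <- v$d_effect > 0
  north <- v$d_cost > 0
  c(NE = mean(east & north), SE = mean(east & !north),
    SW = mean(!east & !north), NW = mean(!east & north))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability (fraction of
#' PSA runs) that the intervention's net monetary benefit
#' `wtp * dE - dC` is non-negative.  Using net monetary benefit rather
#' than an ICER-threshold comparison handles runs with negative
#' incremental effects correctly.
#'
#' @param samples An `mcp_psa` data frame.
#' @param wtp Vector of willingness-to-pay thresholds (euro per DALY
#'   averted).
#' @param perspective `"healthcare"` or `"societal"`.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp = seq(0, 50000, by = 500),
                 perspective = c("healthcare", "societal")) {
  if (!length(wtp)) stop("`wtp` must be non-empty", call. = FALSE)
  v <- psa_columns(samples, perspective)
  prob <- vapply(wtp, function(l) mean(l * v$d_effect - v$d_cost >= 0),
                 numeric(1))
  data.frame(wtp = wtp, probability = prob)
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Means and 2.5/97.5 percentiles of the incremental quantities, the
#' ICER per perspective computed from the means (ratio of mean
#' incremental costs to mean incremental effects), quadrant fractions
#' of the cost-effectiveness plane, and acceptability curves.
#'
#' @param samples An `mcp_psa` data frame.
#' @param wtp Willingness-to-pay grid for the acceptability curves.
#' @return List of class `psa_summary`.
#' @export
psa_summary <- function(samples, wtp = seq(0, 50000, by = 500)) {
  stopifnot(inherits(samples, "mcp_psa") || is.data.frame(samples))
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  means <- c(d_cost_hc = mean(samples$d_cost_hc),
             d_cost_soc = mean(samples$d_cost_soc),
             d_dalys = mean(samples$d_dalys))
  structure(list(
    n_runs = nrow(samples),
    means = means,
    ci = list(d_cost_hc = qs(samples$d_cost_hc),
              d_cost_soc = qs(samples$d_cost_soc),
              d_dalys = qs(samples$d_dalys)),
    icer_hc = icer(means[["d_cost_hc"]], means[["d_dalys"]]),
    icer_soc = icer(means[["d_cost_soc"]], means[["d_dalys"]]),
    quadrants = list(healthcare = ce_plane(samples, "healthcare"),
                     societal = ce_plane(samples, "societal")),
    ceac = list(healthcare = ceac(samples, wtp, "healthcare"),
                societal = ceac(samples, wtp, "societal")),
    rejected_draws = attr(samples, "rejected_draws")
  ), class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary> %d runs\n", x$n_runs))
  cat(sprintf("  incremental health-care costs: %8.1f M euro (%.0f/%.0f)\n",
              x$means[["d_cost_hc"]] / 1e6, x$ci$d_cost_hc[1] / 1e6,
              x$ci$d_cost_hc[2] / 1e6))
  cat(sprintf("  incremental societal costs:    %8.1f M euro (%.0f/%.0f)\n",
              x$means[["d_cost_soc"]] / 1e6, x$ci$d_cost_soc[1] / 1e6,
              x$ci$d_cost_soc[2] / 1e6))
  cat(sprintf("  DALYs averted:                 %8.0f (%.0f/%.0f)\n",
              x$means[["d_dalys"]], x$ci$d_dalys[1], x$ci$d_dalys[2]))
  cat(sprintf("  ICER (health care):            %s\n", format_icer(x$icer_hc)))
  cat(sprintf("  ICER (societal):               %s\n", format_icer(x$icer_soc)))
  q <- x$quadrants$healthcare
  cat(sprintf("  CE plane, health care:  NE %.0f%%  SE %.0f%%  SW %.0f%%  NW %.0f%%\n",
              100 * q["NE"], 100 * q["SE"], 100 * q["SW"], 100 * q["NW"]))
  q <- x$quadrants$societal
  cat(sprintf("  CE plane, societal:     NE %.0f%%  SE %.0f%%  SW %.0f%%  NW %.0f%%\n",
              100 * q["NE"], 100 * q["SE"], 100 * q["SW"], 100 * q["NW"]))
  invisible(x)
}
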