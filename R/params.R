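#' Base-case model parameter set
#'
#' Builds the complete input set for the screening + minimal contact
#' psychotherapy (MCP) cost-effectiveness model: the cycle grid (13
#' four-week cycles per year over a five-year horizon), transition
#' parameters, per-cycle state costs by perspective, disability
#' weights, differential discount rates, the opportunistic screening
#' cascade, and the PSA distribution of every uncertain input.
#'
#' Published inputs (cascade fractions, one-year incidence counts,
#' per-cycle costs, disability weights, unit costs, discount rates) are
#' encoded with their source rows in each spec's `provenance`.  The
#' recovery and relapse curves, which exist in the source literature
#' only as graphs, default to clearly-labelled synthetic stand-ins from
#' [gen_curve()]; replace them with estimated curves where available.
#'
#' Incidence is parameterised on the one-year scale (beta on trial
#' event counts); the per-cycle probabilities used by the cohort engine
#' are obtained with [annual_to_cycle_prob()], both for point estimates
#' and for every PSA draw.  `printed_cycle_ref`/`printed_cycle_int`
#' record the published per-cycle values (1.6% and 1.1%) used as
#' consistency checks by [validate_params()].
#'
#' @param recovery_curve,relapse_curve Optional [curve_spec()]s
#'   overriding the synthetic defaults.
#' @return A list of class `mcp_params`.
#' @export
default_params <- function(recovery_curve = NULL, relapse_curve = NULL) {
  if (is.null(recovery_curve)) {
    recovery_curve <- gen_curve("exponential_decay", p_initial = 0.25,
                                decay = 0.10, span_cycles = 26L)
  }
  if (is.null(relapse_curve)) {
    relapse_curve <- gen_curve("exponential_decay", p_initial = 0.04,
                               decay = 0.08, span_cycles = 26L)
  }

  psa_specs <- list(
    f_participate_screen = dist_spec("beta", 3826, 1452,
      point_estimate = 3826 / (3826 + 1452),
      ci_low = 0.713, ci_high = 0.737,
      provenance = "screening uptake; printed 0.725 (0.713-0.737)"),
    f_screened_to_interview = dist_spec("beta", 364, 3463,
      point_estimate = 364 / (364 + 3463),
      ci_low = 0.086, ci_high = 0.105,
      provenance = "screened reaching diagnostic interview; printed 0.095 (0.086-0.105)"),
    f_not_excluded = dist_spec("beta", 217, 148,
      point_estimate = 217 / (217 + 148),
      ci_low = 0.544, ci_high = 0.645,
      provenance = "interviewed entering intervention; printed 0.595 (0.544-0.645)"),
    p_inc_year_ref = dist_spec("beta", 21, 90,
      point_estimate = 21 / 111,
      ci_low = stats::qbeta(0.025, 21, 90),
      ci_high = stats::qbeta(0.975, 21, 90),
      provenance = "one-year incidence, control arm counts 21/111; printed per-cycle 0.016 (0.010-0.023)"),
    p_inc_year_int = dist_spec("beta", 14, 95,
      point_estimate = 14 / 109,
      ci_low = stats::qbeta(0.025, 14, 95),
      ci_high = stats::qbeta(0.975, 14, 95),
      provenance = "one-year incidence under MCP, counts 14/109; printed per-cycle 0.011 (0.006-0.017)"),
    cost_sub_ref_hc = moments_to_gamma(132, 73, 207,
      provenance = "health-care cost/cycle, sub-threshold, usual care; printed gamma(15, 108)"),
    cost_sub_int_hc = moments_to_gamma(139, 94, 192,
      provenance = "health-care cost/cycle, sub-threshold under MCP (year 1); printed gamma(31, 55)"),
    cost_sub_ref_soc = moments_to_gamma(439, 219, 691,
      provenance = "societal cost/cycle, sub-threshold, usual care; printed gamma(33, 258)"),
    cost_sub_int_soc = moments_to_gamma(384, 138, 692,
      provenance = "societal cost/cycle, sub-threshold under MCP (year 1); printed gamma(16, 433)"),
    cost_mde_hc = moments_to_gamma(268, 150, 419,
      provenance = "health-care cost/cycle, major depression; printed gamma(13, 11)"),
    cost_mde_soc = moments_to_gamma(615, 308, 1022,
      provenance = "societal cost/cycle, major depression; printed gamma(14, 26)"),
    qol_sub = dist_spec("beta", 106, 11,
      point_estimate = 106 / 117,
      ci_low = 0.847, ci_high = 0.952,
      provenance = "quality of life, sub-threshold depression; printed 0.906 (0.847-0.952); disability weight = 1 - QoL")
  )

  structure(list(
    grid = list(cycles_per_year = 13L, horizon_cycles = 65L,
                cycle_years = 1 / 13),
    transitions = list(
      p_inc_year_ref = 21 / 111,
      p_inc_year_int = 14 / 109,
      printed_cycle_ref = 0.016,
      printed_cycle_int = 0.011,
      effect_duration_cycles = 13L,
      recovery_curve = recovery_curve,
      relapse_curve = relapse_curve
    ),
    costs = list(
      sub_ref_hc = 132, sub_ref_soc = 439,
      sub_int_hc = 139, sub_int_soc = 384,
      mde_hc = 268, mde_soc = 615,
      screen_step1 = 5, screen_step2 = 119, intervention = 423
    ),
    weights = list(dw_sub = 0.097, dw_mde = 0.46, dw_rec = 0.097),
    discounts = list(rate_costs = 0.04, rate_effects = 0.015),
    cascade = list(
      n_target = 7.2e6,
      f_participate_screen = 0.725,
      f_screen_positive = 0.266,
      f_interview_participate = 0.357,
      f_not_excluded = 0.595,
      f_screened_to_interview = NULL
    ),
    options = list(half_cycle_correction = FALSE),
    psa_specs = psa_specs
  ), class = "mcp_params")
}

#' @export
print.mcp_params <- function(x, ...) {
  cat("<mcp_params>\n")
  cat(sprintf("  grid:        %d cycles/year, horizon %d cycles\n",
              x$grid$cycles_per_year, x$grid$horizon_cycles))
  cat(sprintf("  incidence:   %.4f/yr (ref), %.4f/yr (intervention, %d-cycle effect)\n",
              x$transitions$p_inc_year_ref, x$transitions$p_inc_year_int,
              x$transitions$effect_duration_cycles))
  cat(sprintf("  weights:     dw_sub %.3f, dw_mde %.2f\n",
              x$weights$dw_sub, x$weights$dw_mde))
  cat(sprintf("  discounting: costs %.1f%%/yr, effects %.1f%%/yr\n",
              100 * x$discounts$rate_costs, 100 * x$discounts$rate_effects))
  cat(sprintf("  cascade:     target %.1fM persons\n", x$cascade$n_target / 1e6))
  cat(sprintf("  PSA:         %d distributions\n", length(x$psa_specs)))
  invisible(x)
}

#' Point-estimate draw from a set of PSA specs
#'
#' Resolves every spec to its [dist_mean()] (aliases, stored as
#' character strings naming another spec, copy that spec's value).
#' Feeding this draw to [apply_draw()] yields the deterministic
#' base-case parameterisation as a special case of the PSA machinery.
#'
#' @param specs Named list of [dist_spec()]s and/or alias strings.
#' @return Named numeric vector.
#' @export
psa_point_draw <- function(specs) {
  out <- vapply(specs, function(s) {
    if (is.character(s)) NA_real_ else dist_mean(s)
  }, numeric(1))
  for (nm in names(specs)) {
    if (is.character(specs[[nm]])) out[nm] <- out[[specs[[nm]]]]
  }
  out
}

#' Apply one PSA draw to a parameter set
#'
#' Produces a concrete `mcp_params` in which the uncertain inputs are
#' replaced by the drawn values: cascade fractions (the screened-to-
#' interview fraction enters as the collapsed fraction, so the same
#' sampled world feeds both counts and costs), one-year incidence
#' probabilities (converted per cycle downstream), per-cycle state
#' costs (clipped at zero), and the sub-threshold disability weight
#' taken as one minus the drawn quality-of-life weight (recovered
#' persons share it).
#'
#' @param params An `mcp_params` object.
#' @param draw Named numeric vector as produced by [psa_point_draw()]
#'   or the PSA sampler.
#' @return A concrete `mcp_params` with no remaining uncertainty.
#' @export
apply_draw <- function(params, draw) {
  stopifnot(inherits(params, "mcp_params"))
  need <- c("f_participate_screen", "f_screened_to_interview",
            "f_not_excluded", "p_inc_year_ref", "p_inc_year_int",
            "cost_sub_ref_hc", "cost_sub_int_hc", "cost_sub_ref_soc",
            "cost_sub_int_soc", "cost_mde_hc", "cost_mde_soc", "qol_sub")
  missing <- setdiff(need, names(draw))
  if (length(missing)) {
    stop("draw is missing values for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- params
  p$cascade$f_participate_screen <- unname(draw["f_participate_screen"])
  p$cascade$f_screened_to_interview <- unname(draw["f_screened_to_interview"])
  p$cascade$f_not_excluded <- unname(draw["f_not_excluded"])
  p$transitions$p_inc_year_ref <- unname(draw["p_inc_year_ref"])
  p$transitions$p_inc_year_int <- unname(draw["p_inc_year_int"])
  for (nm in c("sub_ref_hc", "sub_int_hc", "sub_ref_soc", "sub_int_soc",
               "mde_hc", "mde_soc")) {
    p$costs[[nm]] <- max(0, unname(draw[paste0("cost_", nm)]))
  }
  dw_sub <- 1 - unname(draw["qol_sub"])
  p$weights$dw_sub <- dw_sub
  p$weights$dw_rec <- dw_sub
  p
}

# ---- parameter file I/O -----------------------------------------------

required_param_keys <- list(
  grid = c("cycles_per_year", "horizon_cycles"),
  transitions = c("p_inc_year_ref", "p_inc_year_int",
                  "effect_duration_cycles"),
  curves = c("recovery", "relapse"),
  costs = c("sub_ref_hc", "sub_ref_soc", "sub_int_hc", "sub_int_soc",
            "mde_hc", "mde_soc", "screen_step1", "screen_step2",
            "intervention"),
  weights = c("dw_sub", "dw_mde", "dw_rec"),
  discounts = c("rate_costs", "rate_effects"),
  cascade = c("n_target", "f_participate_screen", "f_screen_positive",
              "f_interview_participate", "f_not_excluded")
)

read_curve_csv <- function(path, tail_rule = "hold_last") {
  if (!file.exists(path)) {
    stop("curve file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("cycle_index", "probability") %in% names(df))) {
    stop("curve CSV needs columns `cycle_index`, `probability`: ", path,
         call. = FALSE)
  }
  df <- df[order(df$cycle_index), , drop = FALSE]
  if (!identical(as.integer(df$cycle_index), seq_len(nrow(df)))) {
    stop("curve CSV cycle_index must run 1..n without gaps: ", path,
         call. = FALSE)
  }
  # monotonicity is a validate_params() check, not a parse failure,
  # so that cmd_validate() can name the offending step in its report
  curve_spec(df$probability, tail_rule = tail_rule, monotone = FALSE)
}

write_curve_csv <- function(curve, path) {
  df <- data.frame(cycle_index = seq_len(curve$span_cycles),
                   probability = curve$p)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

spec_to_list <- function(s) {
  if (is.character(s)) return(list(alias = s))
  list(family = s$family, shape_a = s$shape_a, shape_b = s$shape_b,
       point_estimate = s$point_estimate, ci_low = s$ci_low,
       ci_high = s$ci_high, provenance = s$provenance,
       degenerate = s$degenerate)
}

spec_from_list <- function(l, key) {
  if (!is.null(l$alias)) return(l$alias)
  for (f in c("family", "point_estimate")) {
    if (is.null(l[[f]])) {
      stop("psa spec `", key, "` is missing field `", f, "`", call. = FALSE)
    }
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  dist_spec(l$family, num(l$shape_a), num(l$shape_b),
            point_estimate = as.numeric(l$point_estimate),
            ci_low = num(l$ci_low), ci_high = num(l$ci_high),
            provenance = if (is.null(l$provenance)) "" else l$provenance,
            degenerate = isTRUE(l$degenerate))
}

#' Read and write parameter files
#'
#' Parameter sets are stored as a YAML document plus two 2-column curve
#' CSVs (`cycle_index`, `probability`) referenced by path relative to
#' the YAML file.  Numbers are written as decimal text with 17
#' significant digits, so a save/load round trip reproduces every value
#' bit-for-bit.  `load_params()` validates the file and raises an error
#' listing the offending keys when required entries are absent or
#' invariants are broken.
#'
#' @param path Path of the YAML parameter file.
#' @param validate If `FALSE`, skip the invariant checks after parsing
#'   (structural checks still apply); used by [cmd_validate()] to turn
#'   failures into report rows instead of errors.
#' @return `load_params()` returns an `mcp_params`; `save_params()`
#'   returns `path` invisibly.
#' @export
load_params <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  missing <- character(0)
  for (sec in names(required_param_keys)) {
    if (is.null(doc[[sec]])) {
      missing <- c(missing, sec)
      next
    }
    absent <- setdiff(required_param_keys[[sec]], names(doc[[sec]]))
    missing <- c(missing, if (length(absent)) paste0(sec, "$", absent))
  }
  if (length(missing)) {
    stop("parameter file is missing required keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dir <- dirname(path)
  tail_of <- function(c) if (is.null(c$tail_rule)) "hold_last" else c$tail_rule
  recovery <- read_curve_csv(file.path(dir, doc$curves$recovery$file),
                             tail_of(doc$curves$recovery))
  relapse <- read_curve_csv(file.path(dir, doc$curves$relapse$file),
                            tail_of(doc$curves$relapse))

  params <- default_params(recovery_curve = recovery,
                           relapse_curve = relapse)
  params$grid <- list(
    cycles_per_year = as.integer(doc$grid$cycles_per_year),
    horizon_cycles = as.integer(doc$grid$horizon_cycles),
    cycle_years = 1 / as.integer(doc$grid$cycles_per_year)
  )
  tr <- doc$transitions
  params$transitions$p_inc_year_ref <- as.numeric(tr$p_inc_year_ref)
  params$transitions$p_inc_year_int <- as.numeric(tr$p_inc_year_int)
  params$transitions$effect_duration_cycles <-
    as.integer(tr$effect_duration_cycles)
  if (!is.null(tr$printed_cycle_ref)) {
    params$transitions$printed_cycle_ref <- as.numeric(tr$printed_cycle_ref)
  }
  if (!is.null(tr$printed_cycle_int)) {
    params$transitions$printed_cycle_int <- as.numeric(tr$printed_cycle_int)
  }
  params$costs <- lapply(doc$costs, as.numeric)
  params$weights <- lapply(doc$weights, as.numeric)
  params$discounts <- lapply(doc$discounts, as.numeric)
  casc <- lapply(doc$cascade, as.numeric)
  if (is.null(doc$cascade$f_screened_to_interview)) {
    casc$f_screened_to_interview <- NULL
  }
  params$cascade <- casc
  if (!is.null(doc$options)) {
    params$options$half_cycle_correction <-
      isTRUE(doc$options$half_cycle_correction)
  }
  if (!is.null(doc$psa)) {
    params$psa_specs <- mapply(spec_from_list, doc$psa, names(doc$psa),
                               SIMPLIFY = FALSE)
  }
  if (validate) {
    ok <- validate_params(params)
    bad <- ok$check[!ok$pass]
    if (length(bad)) {
      stop("parameter file failed validation: ",
           paste(bad, collapse = "; "), call. = FALSE)
    }
  }
  params
}

#' @rdname load_params
#' @param params An `mcp_params` object.
#' @param curve_files Names of the two curve CSVs written next to the
#'   YAML file.
#' @export
save_params <- function(params, path,
                        curve_files = c(recovery = "recovery_curve.csv",
                                        relapse = "relapse_curve.csv")) {
  stopifnot(inherits(params, "mcp_params"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_curve_csv(params$transitions$recovery_curve,
                  file.path(dir, curve_files[["recovery"]]))
  write_curve_csv(params$transitions$relapse_curve,
                  file.path(dir, curve_files[["relapse"]]))
  tr <- params$transitions
  doc <- list(
    grid = list(cycles_per_year = params$grid$cycles_per_year,
                horizon_cycles = params$grid$horizon_cycles),
    transitions = list(
      p_inc_year_ref = tr$p_inc_year_ref,
      p_inc_year_int = tr$p_inc_year_int,
      printed_cycle_ref = tr$printed_cycle_ref,
      printed_cycle_int = tr$printed_cycle_int,
      effect_duration_cycles = tr$effect_duration_cycles
    ),
    curves = list(
      recovery = list(file = unname(curve_files[["recovery"]]),
                      tail_rule = tr$recovery_curve$tail_rule),
      relapse = list(file = unname(curve_files[["relapse"]]),
                     tail_rule = tr$relapse_curve$tail_rule)
    ),
    costs = params$costs,
    weights = params$weights,
    discounts = params$discounts,
    cascade = params$cascade,
    options = params$options,
    psa = lapply(params$psa_specs, spec_to_list)
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Validate a parameter set against the model's invariants
#'
#' Checks probability ranges, curve monotonicity, beta-spec consistency
#' between shape parameters and point estimates (to +/-0.001), the
#' documented per-cycle incidence values against the constant-hazard
#' transform of the one-year probabilities, cascade fraction
#' consistency (screen-positive x interview-participation against the
#' collapsed screened-to-interview fraction), and discount-rate signs.
#'
#' @param params An `mcp_params` object.
#' @return A data frame with columns `check`, `pass`, `detail`.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "mcp_params"))
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = isTRUE(pass), detail = detail,
      stringsAsFactors = FALSE)
  }
  tr <- params$transitions
  in01 <- function(x) is.finite(x) && x >= 0 && x <= 1

  add("grid$horizon_positive", params$grid$horizon_cycles >= 1)
  add("transitions$p_inc_year_ref_range", in01(tr$p_inc_year_ref))
  add("transitions$p_inc_year_int_range", in01(tr$p_inc_year_int))
  add("transitions$intervention_reduces_incidence",
      tr$p_inc_year_int <= tr$p_inc_year_ref,
      sprintf("%.4f vs %.4f", tr$p_inc_year_int, tr$p_inc_year_ref))

  for (nm in c("recovery_curve", "relapse_curve")) {
    cv <- tr[[nm]]
    add(paste0("transitions$", nm, "_range"),
        all(cv$p >= 0 & cv$p <= 1))
    add(paste0("transitions$", nm, "_monotone"),
        all(diff(cv$p) <= 1e-12),
        if (any(diff(cv$p) > 1e-12)) {
          paste0("increasing step at cycle ",
                 which(diff(cv$p) > 1e-12)[1] + 1L)
        } else "")
  }

  if (!is.null(tr$printed_cycle_ref)) {
    v <- annual_to_cycle_prob(tr$p_inc_year_ref, params$grid$cycles_per_year)
    add("transitions$printed_cycle_ref_consistent",
        abs(v - tr$printed_cycle_ref) <= 1e-3,
        sprintf("transform gives %.4f vs printed %.3f", v,
                tr$printed_cycle_ref))
  }
  if (!is.null(tr$printed_cycle_int)) {
    v <- annual_to_cycle_prob(tr$p_inc_year_int, params$grid$cycles_per_year)
    add("transitions$printed_cycle_int_consistent",
        abs(v - tr$printed_cycle_int) <= 1e-3,
        sprintf("transform gives %.4f vs printed %.3f", v,
                tr$printed_cycle_int))
  }

  for (nm in names(params$costs)) {
    add(paste0("costs$", nm, "_nonnegative"), params$costs[[nm]] >= 0)
  }
  for (nm in names(params$weights)) {
    add(paste0("weights$", nm, "_range"), in01(params$weights[[nm]]))
  }
  add("weights$dw_rec_equals_dw_sub",
      isTRUE(all.equal(params$weights$dw_rec, params$weights$dw_sub)),
      "recovered persons carry the sub-threshold disability weight")
  add("discounts$nonnegative",
      params$discounts$rate_costs >= 0 && params$discounts$rate_effects >= 0)

  cs <- params$cascade
  for (nm in c("f_participate_screen", "f_screen_positive",
               "f_interview_participate", "f_not_excluded")) {
    add(paste0("cascade$", nm, "_range"), in01(cs[[nm]]))
  }
  collapsed <- cs$f_screen_positive * cs$f_interview_participate
  target <- if (!is.null(cs$f_screened_to_interview)) {
    cs$f_screened_to_interview
  } else if (!is.null(params$psa_specs$f_screened_to_interview) &&
             !is.character(params$psa_specs$f_screened_to_interview)) {
    dist_mean(params$psa_specs$f_screened_to_interview)
  } else {
    NA_real_
  }
  if (is.finite(target)) {
    add("cascade$collapsed_fraction_consistent",
        abs(collapsed - target) <= 1e-3,
        sprintf("%.4f x %.4f = %.4f vs %.4f", cs$f_screen_positive,
                cs$f_interview_participate, collapsed, target))
  }

  for (nm in names(params$psa_specs)) {
    s <- params$psa_specs[[nm]]
    if (is.character(s)) {
      add(paste0("psa$", nm, "_alias_resolves"),
          s %in% names(params$psa_specs))
      next
    }
    if (s$family == "beta" && !s$degenerate) {
      m <- s$shape_a / (s$shape_a + s$shape_b)
      add(paste0("psa$", nm, "_beta_point_consistent"),
          abs(m - s$point_estimate) <= 1e-3,
          sprintf("a/(a+b) = %.4f vs point %.4f", m, s$point_estimate))
    }
  }

  do.call(rbind, checks)
}
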