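#' Run the full analysis and write report files
#'
#' Loads (or takes) a parameter set, validates it, runs the
#' deterministic pipeline and the probabilistic sensitivity analysis,
#' and writes, into `out_dir`:
#' \describe{
#'   \item{deterministic.csv}{cascade counts, one-off costs,
#'     incremental costs/effects and ICERs at point estimates}
#'   \item{psa_samples.csv}{one row per PSA run: incremental costs
#'     (both perspectives) and DALYs averted}
#'   \item{quadrants.csv}{cost-effectiveness plane fractions per
#'     perspective}
#'   \item{ceac.csv}{acceptability curve per perspective over the
#'     willingness-to-pay grid}
#'   \item{summary.json}{machine-readable summary at full precision}
#' }
#' Outputs are a pure function of `(params, n_runs, seed, wtp)`:
#' re-running with identical inputs reproduces every file byte for
#' byte.
#'
#' @param params An `mcp_params` object or the path of a parameter
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @param n_runs Number of PSA runs (default 5000).
#' @param seed Master seed (default 1).
#' @param wtp Willingness-to-pay grid, euro per DALY averted.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the deterministic result, PSA
#'   samples and summary, and the written file paths.
#' @export
cmd_run <- function(params, out_dir, n_runs = 5000L, seed = 1L,
                    wtp = seq(0, 50000, by = 500), quiet = FALSE) {
  log_line <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(params)) {
    log_line("loading parameters from %s", params)
    params <- load_params(params)
  }
  stopifnot(inherits(params, "mcp_params"))
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  if (is.unsorted(wtp, strictly = TRUE)) {
    stop("`wtp` must be strictly increasing", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_line("deterministic run (point estimates)")
  det <- deterministic_run(params)

  log_line("probabilistic sensitivity analysis: %d runs, seed %d",
           n_runs, seed)
  samples <- run_psa(params, n_runs = n_runs, seed = seed)
  log_line("rejected draws: %d", attr(samples, "rejected_draws"))
  summ <- psa_summary(samples, wtp = wtp)

  det_df <- data.frame(
    quantity = c("n_screened", "n_positive", "n_interviewed", "n_treated",
                 "screening_cost", "intervention_cost",
                 "other_hc_expenditure", "d_cost_hc", "d_cost_soc",
                 "dalys_averted", "icer_hc", "icer_soc"),
    value = c(det$counts$n_screened, det$counts$n_positive,
              det$counts$n_interviewed, det$counts$n_treated,
              det$screening_cost, det$intervention_cost,
              det$other_hc_expenditure, det$incremental$d_cost_hc,
              det$incremental$d_cost_soc, det$incremental$d_dalys_averted,
              det$incremental$icer_hc$ratio, det$incremental$icer_soc$ratio),
    label = c(rep("", 10), det$incremental$icer_hc$label,
              det$incremental$icer_soc$label),
    stringsAsFactors = FALSE
  )

  paths <- c(
    deterministic = file.path(out_dir, "deterministic.csv"),
    psa_samples = file.path(out_dir, "psa_samples.csv"),
    quadrants = file.path(out_dir, "quadrants.csv"),
    ceac = file.path(out_dir, "ceac.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  utils::write.csv(det_df, paths[["deterministic"]], row.names = FALSE)
  utils::write.csv(as.data.frame(samples), paths[["psa_samples"]],
                   row.names = FALSE)
  quad <- rbind(
    data.frame(perspective = "healthcare",
               quadrant = names(summ$quadrants$healthcare),
               fraction = unname(summ$quadrants$healthcare)),
    data.frame(perspective = "societal",
               quadrant = names(summ$quadrants$societal),
               fraction = unname(summ$quadrants$societal))
  )
  utils::write.csv(quad, paths[["quadrants"]], row.names = FALSE)
  ceac_df <- rbind(
    cbind(perspective = "healthcare", summ$ceac$healthcare),
    cbind(perspective = "societal", summ$ceac$societal)
  )
  utils::write.csv(ceac_df, paths[["ceac"]], row.names = FALSE)

  summary_list <- list(
    n_runs = summ$n_runs,
    seed = seed,
    deterministic = list(
      n_treated = det$counts$n_treated,
      screening_cost = det$screening_cost,
      intervention_cost = det$intervention_cost,
      d_cost_hc = det$incremental$d_cost_hc,
      d_cost_soc = det$incremental$d_cost_soc,
      dalys_averted = det$incremental$d_dalys_averted,
      icer_hc = det$incremental$icer_hc,
      icer_soc = det$incremental$icer_soc
    ),
    psa = list(
      means = as.list(summ$means),
      ci = summ$ci,
      icer_hc = summ$icer_hc,
      icer_soc = summ$icer_soc,
      quadrants = lapply(summ$quadrants, as.list),
      rejected_draws = summ$rejected_draws
    )
  )
  jsonlite::write_json(summary_list, paths[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("wrote %d files to %s", length(paths), out_dir)
  invisible(list(deterministic = det, samples = samples, summary = summ,
                 paths = paths))
}

#' Validate a parameter file and print a check report
#'
#' Runs [validate_params()] on a parameter file (or an in-memory
#' parameter set) and prints a pass/fail table.  Failures are report
#' content, not errors.
#'
#' @param params Path of a parameter YAML file or an `mcp_params`
#'   object.
#' @param quiet Suppress the printed table.
#' @return Invisibly, the checks data frame.
#' @export
cmd_validate <- function(params, quiet = FALSE) {
  if (is.character(params)) {
    path <- params
    if (!file.exists(path)) stop("parameter file not found: ", path,
                                 call. = FALSE)
    # load without the embedded stop-on-failure so problems land in the
    # report rather than aborting it
    params <- tryCatch(load_params(path, validate = FALSE),
                       error = function(e) e)
    if (inherits(params, "error")) {
      if (!quiet) cat("FAIL ", conditionMessage(params), "\n", sep = "")
      return(invisible(data.frame(check = "load", pass = FALSE,
                                  detail = conditionMessage(params))))
    }
  }
  checks <- validate_params(params)
  if (!quiet) {
    status <- ifelse(checks$pass, "ok  ", "FAIL")
    cat(sprintf("%s %s%s\n", status, checks$check,
                ifelse(nzchar(checks$detail),
                       paste0("  (", checks$detail, ")"), "")),
        sep = "")
    cat(sprintf("%d checks, %d failed\n", nrow(checks), sum(!checks$pass)))
  }
  invisible(checks)
}
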