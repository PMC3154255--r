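#' Opportunistic screening cascade counts
#'
#' Follows the target population (adults visiting their GP within a
#' year) through the two-step screening flow: agreeing to be screened,
#' screening positive for sub-threshold depression, participating in
#' the diagnostic interview, and entering the intervention after
#' exclusion of those already meeting criteria for a depressive or
#' anxiety disorder.  Counts are expected values (real numbers), not
#' rounded to whole persons.
#'
#' When `f_screened_to_interview` is set (as it is inside the PSA,
#' where the collapsed screened-to-interview fraction is sampled as one
#' quantity), the interviewed count is `n_screened` times that
#' collapsed fraction; the screen-positive count is still reported from
#' the split fractions for descriptive purposes.
#'
#' @param params An `mcp_params` object, or just its `cascade` list.
#' @return A list of class `cascade_counts` with `n_screened`,
#'   `n_positive`, `n_interviewed`, `n_treated`.
#' @examples
#' cc <- cascade_counts(default_params())
#' cc$n_positive / 1e6  # ~1.4 million screen-positives
#' cc$n_treated / 1e6   # ~0.3 million treated
#' @export
cascade_counts <- function(params) {
  cs <- if (inherits(params, "mcp_params")) params$cascade else params
  fr <- c(cs$f_participate_screen, cs$f_screen_positive,
          cs$f_interview_participate, cs$f_not_excluded)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("cascade fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cs$n_target < 0) stop("`n_target` must be non-negative", call. = FALSE)
  n_screened <- cs$n_target * cs$f_participate_screen
  n_positive <- n_screened * cs$f_screen_positive
  n_interviewed <- if (!is.null(cs$f_screened_to_interview)) {
    n_screened * cs$f_screened_to_interview
  } else {
    n_positive * cs$f_interview_participate
  }
  n_treated <- n_interviewed * cs$f_not_excluded
  structure(list(n_screened = n_screened, n_positive = n_positive,
                 n_interviewed = n_interviewed, n_treated = n_treated),
            class = "cascade_counts")
}

#' @export
print.cascade_counts <- function(x, ...) {
  cat("<cascade_counts> (millions of persons)\n")
  cat(sprintf("  screened:     %8.3f\n", x$n_screened / 1e6))
  cat(sprintf("  positive:     %8.3f\n", x$n_positive / 1e6))
  cat(sprintf("  interviewed:  %8.3f\n", x$n_interviewed / 1e6))
  cat(sprintf("  treated:      %8.3f\n", x$n_treated / 1e6))
  invisible(x)
}

#' One-off screening and intervention costs
#'
#' The first screening step is charged per person screened, the
#' diagnostic interview per interview participant, and the intervention
#' (intake, self-help manual, supporting telephone calls) per treated
#' person.  All are one-off costs incurred at the start of the horizon
#' and therefore undiscounted.
#'
#' @param counts A [cascade_counts()] result.
#' @param params An `mcp_params` object, or just its `costs` list
#'   (needs `screen_step1`, `screen_step2`, `intervention`).
#' @return List with `screening_cost` and `intervention_cost` in euros.
#' @export
cascade_costs <- function(counts, params) {
  stopifnot(inherits(counts, "cascade_counts"))
  cost <- if (inherits(params, "mcp_params")) params$costs else params
  list(
    screening_cost = counts$n_screened * cost$screen_step1 +
      counts$n_interviewed * cost$screen_step2,
    intervention_cost = counts$n_treated * cost$intervention
  )
}
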