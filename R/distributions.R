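#' Convert an annual probability to a per-cycle probability
#'
#' Transforms a one-year event probability into the probability for one
#' model cycle under a constant (time-homogeneous) hazard: the yearly
#' survival probability is split evenly, on the hazard scale, across the
#' cycles of the year.
#'
#' @param p_year Probability of the event over one year, in `[0, 1]`.
#' @param cycles_per_year Number of model cycles per year (default 13
#'   four-week cycles).
#' @return Per-cycle probability `1 - (1 - p_year)^(1/cycles_per_year)`.
#'   Vectorised over `p_year`.
#' @seealso [cycle_to_annual_prob()] for the inverse transform.
#' @examples
#' annual_to_cycle_prob(21 / 111, 13)  # ~0.016
#' annual_to_cycle_prob(14 / 109, 13)  # ~0.011
#' @export
annual_to_cycle_prob <- function(p_year, cycles_per_year = 13L) {
  if (any(!is.finite(p_year)) || any(p_year < 0) || any(p_year > 1)) {
    stop("`p_year` must lie in [0, 1]", call. = FALSE)
  }
  if (cycles_per_year < 1) stop("`cycles_per_year` must be >= 1", call. = FALSE)
  1 - (1 - p_year)^(1 / cycles_per_year)
}

#' @rdname annual_to_cycle_prob
#' @param p_cycle Per-cycle probability to aggregate back to a year.
#' @export
cycle_to_annual_prob <- function(p_cycle, cycles_per_year = 13L) {
  if (any(!is.finite(p_cycle)) || any(p_cycle < 0) || any(p_cycle > 1)) {
    stop("`p_cycle` must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_cycle)^cycles_per_year
}

#' Specify a parameter distribution for probabilistic sensitivity analysis
#'
#' A `dist_spec` records one uncertain model input: its distributional
#' family (beta for probabilities and fractions, gamma for costs), shape
#' parameters, the published point estimate on its printed scale, an
#' optional 95% interval, and a free-text provenance tag naming the
#' source row.  A spec may be degenerate (zero spread), in which case
#' every draw equals the point estimate; this is how the deterministic
#' base case is expressed as a special case of the PSA.
#'
#' For gamma specs `shape_b` is the *scale* parameter, so the
#' distribution mean is `shape_a * shape_b`.
#'
#' @param family `"beta"` or `"gamma"`.
#' @param shape_a,shape_b Positive shape parameters (shape/scale for
#'   gamma).  May be `NA` for a degenerate spec.
#' @param point_estimate Published point estimate on its printed scale.
#' @param ci_low,ci_high Optional interval bounds bracketing the point.
#' @param provenance Free-text citation tag for the source of the values.
#' @param degenerate If `TRUE` the spec has zero spread and all draws
#'   equal `point_estimate`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma"),
                      shape_a = NA_real_, shape_b = NA_real_,
                      point_estimate,
                      ci_low = NA_real_, ci_high = NA_real_,
                      provenance = "",
                      degenerate = FALSE) {
  family <- match.arg(family)
  if (!is.numeric(point_estimate) || length(point_estimate) != 1L ||
      !is.finite(point_estimate)) {
    stop("`point_estimate` must be a single finite number", call. = FALSE)
  }
  if (!degenerate) {
    if (!is.finite(shape_a) || !is.finite(shape_b) ||
        shape_a <= 0 || shape_b <= 0) {
      stop("shape parameters must be positive for a non-degenerate spec",
           call. = FALSE)
    }
  }
  if (family == "beta" && (point_estimate < 0 || point_estimate > 1)) {
    stop("a beta spec needs a point estimate in [0, 1]", call. = FALSE)
  }
  if (is.finite(ci_low) && is.finite(ci_high)) {
    if (ci_low > point_estimate || point_estimate > ci_high) {
      stop("need ci_low <= point_estimate <= ci_high", call. = FALSE)
    }
  }
  structure(
    list(family = family, shape_a = shape_a, shape_b = shape_b,
         point_estimate = point_estimate,
         ci_low = ci_low, ci_high = ci_high,
         provenance = provenance, degenerate = isTRUE(degenerate)),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<dist_spec> degenerate at %g", x$point_estimate))
  } else {
    cat(sprintf("<dist_spec> %s(%g, %g), point %g", x$family,
                x$shape_a, x$shape_b, x$point_estimate))
  }
  if (is.finite(x$ci_low)) cat(sprintf(" (%g-%g)", x$ci_low, x$ci_high))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Mean of a PSA distribution specification
#'
#' For beta specs the analytic mean `a / (a + b)`; for gamma specs the
#' published point estimate (gamma cost specs are constructed so their
#' analytic mean equals the point estimate, see [moments_to_gamma()]);
#' for degenerate specs the point estimate.
#'
#' @param spec A [dist_spec()].
#' @return The mean as a single number.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$degenerate) return(spec$point_estimate)
  switch(spec$family,
    beta  = spec$shape_a / (spec$shape_a + spec$shape_b),
    gamma = spec$point_estimate
  )
}

#' Draw random samples from a PSA distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when given, draws are reproducible.
#' @return Numeric vector of length `n`.  Degenerate specs return the
#'   point estimate repeated.
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (spec$degenerate) return(rep(spec$point_estimate, n))
  switch(spec$family,
    beta  = stats::rbeta(n, spec$shape_a, spec$shape_b),
    gamma = stats::rgamma(n, shape = spec$shape_a, scale = spec$shape_b),
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

#' Build a gamma cost spec from a point estimate and 95% interval
#'
#' Method-of-moments construction: the mean is the point estimate and
#' the standard deviation is the 95% interval half-width divided by
#' 1.96 (symmetric normal-approximation interval).  Shape and scale are
#' then `shape = mean^2 / sd^2`, `scale = sd^2 / mean`, so the returned
#' spec's analytic mean equals `mean` exactly.  A zero-width interval
#' yields a degenerate spec.
#'
#' @param mean Point estimate (must be positive).
#' @param ci_low,ci_high 95% interval bounds with
#'   `ci_low <= mean <= ci_high`.
#' @param provenance Citation tag carried on the returned spec.
#' @return A gamma (or degenerate) [dist_spec()].
#' @export
moments_to_gamma <- function(mean, ci_low, ci_high, provenance = "") {
  if (!is.finite(mean) || mean <= 0) {
    stop("`mean` must be a positive number", call. = FALSE)
  }
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop("need ci_low <= mean <= ci_high", call. = FALSE)
  }
  sd <- (ci_high - ci_low) / (2 * 1.96)
  if (sd == 0) {
    return(dist_spec("gamma", point_estimate = mean,
                     ci_low = ci_low, ci_high = ci_high,
                     provenance = provenance, degenerate = TRUE))
  }
  shape <- mean^2 / sd^2
  scale <- sd^2 / mean
  dist_spec("gamma", shape_a = shape, shape_b = scale,
            point_estimate = mean, ci_low = ci_low, ci_high = ci_high,
            provenance = provenance)
}

#' Collapse a spec (or list of specs) to zero spread
#'
#' Returns degenerate copies pinned at the point estimate.  Running the
#' PSA with all specs collapsed reproduces the deterministic pipeline.
#'
#' @param x A [dist_spec()] or a list of them (aliases, stored as
#'   character strings, are passed through untouched).
#' @return Object of the same shape with every spec degenerate.
#' @export
collapse_spec <- function(x) {
  if (inherits(x, "dist_spec")) {
    x$degenerate <- TRUE
    return(x)
  }
  if (is.list(x)) return(lapply(x, collapse_spec))
  x  # alias string
}
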