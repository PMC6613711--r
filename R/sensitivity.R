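#' Relative sensitivity of a scalar function
#'
#' Finite-difference estimate of \eqn{c^* = (x/y)\,\partial y/\partial x}
#' for a scalar function, with a multiplicative perturbation. For power
#' laws \eqn{y = x^m} the coefficient equals the exponent m (exactly so
#' for m = 2 with the central stencil).
#'
#' @param f function of one numeric argument
#' @param x evaluation point (nonzero)
#' @param rel_step relative perturbation (default 1 percent)
#' @param stencil \code{"forward"} or \code{"central"}
#' @return the estimated dimensionless coefficient
#' @export
sensitivity_coefficient <- function(f, x, rel_step = 0.01,
                                    stencil = c("forward", "central")) {
  stencil <- match.arg(stencil)
  y0 <- f(x)
  yu <- f(x * (1 + rel_step))
  if (stencil == "forward") {
    (yu - y0) / (rel_step * y0)
  } else {
    yd <- f(x * (1 - rel_step))
    (yu - yd) / (2 * rel_step * y0)
  }
}

#' Relative sensitivity coefficient of an output to a parameter
#'
#' The dimensionless relative sensitivity
#' \eqn{c^* = (x / y)\, \partial y / \partial x} is estimated by finite
#' differences with a multiplicative perturbation of the whole parameter
#' field (1 percent by default): forward,
#' \eqn{(y^+ - y) / (\delta\, y)}, or central,
#' \eqn{(y^+ - y^-) / (2 \delta\, y)}. For a pure power law
#' \eqn{y = x^m} the coefficient is the exponent m.
#'
#' @param scenario a \code{perfusion_scenario}
#' @param param one of \code{alpha, mu, phi_a, phi_v, k_a, k_v, gamma_a,
#'   gamma_v}
#' @param output one of \code{p_a, p_v, P} (flow only) or \code{TTP, MTT}
#'   (runs the tracer as well)
#' @param rel_step perturbation size (0.01 = 1 percent)
#' @param stencil \code{"forward"} (default, one extra solve) or
#'   \code{"central"}
#' @param baseline optional precomputed \code{\link{run_pipeline}} result
#'   to share across parameters
#' @return list with \code{field} (voxel map of \eqn{c^*}, NA where the
#'   output is ~0 or outside the mask) and \code{mean} over defined voxels
#' @export
relative_sensitivity <- function(scenario, param, output,
                                 rel_step = 0.01,
                                 stencil = c("forward", "central"),
                                 baseline = NULL) {
  stencil <- match.arg(stencil)
  with_tracer <- output %in% c("TTP", "MTT")
  if (is.null(baseline)) {
    baseline <- run_pipeline(scenario, with_tracer = with_tracer)
  }
  y0 <- baseline[[output]]
  if (is.null(y0)) stop("unknown output: ", output)
  up <- run_pipeline(scenario,
    factors = setNames(list(1 + rel_step), param),
    with_tracer = with_tracer
  )[[output]]
  if (stencil == "forward") {
    cstar <- (up - y0) / (rel_step * y0)
  } else {
    dn <- run_pipeline(scenario,
      factors = setNames(list(1 - rel_step), param),
      with_tracer = with_tracer
    )[[output]]
    cstar <- (up - dn) / (2 * rel_step * y0)
  }
  scale <- mean(abs(y0[scenario$domain$mask]), na.rm = TRUE)
  undef <- !is.finite(cstar) | abs(y0) < 1e-12 * max(scale, 1e-300)
  cstar[undef] <- NA_real_
  cstar[!scenario$domain$mask] <- NA_real_
  list(field = cstar, mean = mean(cstar, na.rm = TRUE))
}

#' Table of mean relative sensitivities
#'
#' Computes \code{\link{relative_sensitivity}} for every parameter/output
#' combination and returns the spatially averaged coefficients as a matrix
#' (rows: parameters, columns: outputs).
#'
#' @param scenario a \code{perfusion_scenario}
#' @param params character vector of parameter names
#' @param outputs character vector of output names
#' @param ... forwarded to \code{\link{relative_sensitivity}}
#' @return numeric matrix of mean \eqn{c^*} values
#' @export
sensitivity_table <- function(scenario,
                              params = c(
                                "alpha", "mu", "phi_a", "phi_v",
                                "k_a", "k_v", "gamma_a", "gamma_v"
                              ),
                              outputs = c("p_a", "p_v", "P"),
                              ...) {
  with_tracer <- any(outputs %in% c("TTP", "MTT"))
  base <- run_pipeline(scenario, with_tracer = with_tracer)
  rel_step <- 0.01
  m <- scenario$domain$mask
  out <- matrix(NA_real_, length(params), length(outputs),
    dimnames = list(params, outputs)
  )
  for (p in params) {
    up <- run_pipeline(scenario,
      factors = setNames(list(1 + rel_step), p),
      with_tracer = with_tracer
    )
    for (o in outputs) {
      y0 <- base[[o]]
      cstar <- (up[[o]] - y0) / (rel_step * y0)
      scale <- mean(abs(y0[m]), na.rm = TRUE)
      cstar[!is.finite(cstar) | abs(y0) < 1e-12 * max(scale, 1e-300)] <- NA
      out[p, o] <- mean(cstar[m], na.rm = TRUE)
    }
  }
  out
}
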