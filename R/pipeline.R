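#' Solve steady circulation and perfusion for a scenario
#'
#' Assembles and solves the coupled vessel-network / two-compartment Darcy
#' pressure system of a \code{perfusion_scenario} and derives the perfusion
#' map and a mass-balance audit.
#'
#' @param scenario a \code{perfusion_scenario} (see
#'   \code{\link{make_paired_scenario}}), or any list with the same fields
#' @param method linear solver passed to \code{\link{solve_pressure}}
#' @param tol relative residual tolerance
#' @return list with \code{solution} (\code{pressure_solution}),
#'   \code{perfusion} (\code{perfusion_map}) and \code{balance}
#' @export
simulate_flow <- function(scenario, method = "auto", tol = NULL) {
  cfg <- scenario$config
  if (is.null(tol)) tol <- cfg$solver_tol
  sys <- assemble_flow_system(
    scenario$domain, scenario$arterial, scenario$venous,
    scenario$kernels_a, scenario$kernels_v,
    cfg$gamma_a, cfg$gamma_v, cfg$p_root_a, cfg$p_root_v
  )
  sol <- solve_pressure(sys, method = method, tol = tol)
  list(
    solution = sol,
    perfusion = perfusion_map(sol),
    balance = mass_balance(sol)
  )
}

#' Simulate indicator dilution on a solved flow field
#'
#' Discretizes the edges into subsegments, assembles the upwind transport
#' operator, chooses the time step from the CFL bound and advances the
#' bolus with backward Euler; returns the series together with TTP/MTT
#' maps.
#'
#' @param flow result of \code{\link{simulate_flow}}
#' @param scenario the scenario that produced it (for masks and config)
#' @param t_sim simulated time window [s]
#' @return list with \code{series} (\code{tracer_series}), \code{maps}
#'   (\code{kinetic_maps}), \code{transport} and \code{stepping}
#' @export
simulate_tracer <- function(flow, scenario, t_sim = NULL) {
  cfg <- scenario$config
  if (is.null(t_sim)) t_sim <- cfg$t_sim
  sol <- flow$solution
  grid <- scenario$domain$grid
  disc_a <- discretize_edges(sol$arterial, grid, scenario$mask_a)
  disc_v <- discretize_edges(sol$venous, grid, scenario$mask_v)
  tr <- assemble_transport(sol, disc_a, disc_v,
    aif = list(C0 = cfg$C0, A = cfg$aif_A, B = cfg$aif_B, t0 = cfg$t0)
  )
  st <- tracer_timestep(tr, t_sim = t_sim, factor = cfg$cfl_factor)
  series <- backward_euler_run(tr, st$dt, st$n_steps,
    sample_dt = cfg$sample_dt
  )
  maps <- kinetic_maps(series, scenario$domain, flow$perfusion, hct = cfg$hct)
  list(series = series, maps = maps, transport = tr, stepping = st)
}

# Re-run the pipeline with multiplicative perturbations of named scalar
# parameters. A viscosity perturbation also rescales the edge conductances
# (kappa ~ 1/mu), which the networks cache.
.apply_overrides <- function(scenario, factors) {
  if (!length(factors)) return(scenario)
  cfg <- scenario$config
  dom <- scenario$domain
  for (nm in names(factors)) {
    f <- factors[[nm]]
    switch(nm,
      alpha = {
        dom$alpha <- dom$alpha * f
        cfg$alpha <- cfg$alpha * f
      },
      mu = {
        dom$mu <- dom$mu * f
        cfg$mu <- cfg$mu * f
        scenario$arterial$edges$conductance <-
          scenario$arterial$edges$conductance / f
        scenario$venous$edges$conductance <-
          scenario$venous$edges$conductance / f
      },
      phi_a = {
        dom$phi_a <- dom$phi_a * f
        cfg$phi_a <- cfg$phi_a * f
      },
      phi_v = {
        dom$phi_v <- dom$phi_v * f
        cfg$phi_v <- cfg$phi_v * f
      },
      k_a = {
        dom$k_a <- dom$k_a * f
        cfg$k_a <- cfg$k_a * f
      },
      k_v = {
        dom$k_v <- dom$k_v * f
        cfg$k_v <- cfg$k_v * f
      },
      gamma_a = cfg$gamma_a <- cfg$gamma_a * f,
      gamma_v = cfg$gamma_v <- cfg$gamma_v * f,
      stop("unknown parameter: ", nm)
    )
  }
  scenario$domain <- dom
  scenario$config <- cfg
  scenario
}

#' Run the full pipeline and collect output fields
#'
#' Convenience runner used by the sensitivity analysis: solves the flow
#' (and optionally the tracer) for a scenario with multiplicative parameter
#' perturbations applied, and returns the output fields of interest.
#'
#' @param scenario a \code{perfusion_scenario}
#' @param factors named list of multiplicative perturbations, e.g.
#'   \code{list(alpha = 1.01)}
#' @param with_tracer also run the tracer and report TTP/MTT
#' @return list of output fields \code{p_a}, \code{p_v}, \code{P} and,
#'   with tracer, \code{TTP}, \code{MTT}
#' @export
run_pipeline <- function(scenario, factors = list(), with_tracer = FALSE) {
  sc <- .apply_overrides(scenario, factors)
  flow <- simulate_flow(sc)
  out <- list(
    p_a = flow$solution$p_a,
    p_v = flow$solution$p_v,
    P = flow$perfusion$P
  )
  if (with_tracer) {
    tr <- simulate_tracer(flow, sc)
    out$TTP <- tr$maps$TTP
    out$MTT <- tr$maps$MTT
  }
  out
}
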