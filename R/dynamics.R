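#' Solver options for steady-state and transient integration
#'
#' The coupled morphogen-expander equations are integrated by the method of
#' lines on a uniform grid with a stiff solver (deSolve's `lsodar`, banded
#' Jacobian, compiled right-hand side). Steady state is detected continuously
#' through the integrator's root-finding on the normalised residual
#' `max |dC/dt| / (max C + atol)` for each species, so no fixed checking
#' cadence is needed; `check_interval` only sets the snapshot spacing of
#' transient runs.
#'
#' @param Nx Number of grid nodes (>= 51).
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param ss_tol Steady-state criterion on the normalised residual (1/time).
#' @param t_max Maximum integration time; `NULL` chooses
#'   `50 / min(k_eff, mu_eff)` from the slowest attainable effective
#'   degradation rates (capped at `1e8`).
#' @param check_interval Snapshot spacing for transient runs; `NULL` uses a
#'   logarithmic schedule.
#' @param maxsteps Maximum internal integrator steps per call.
#' @param overflow Concentration guard; any value above it aborts the run as
#'   a blow-up.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(Nx = 1001, rtol = 1e-8, atol = 1e-10,
                           ss_tol = 1e-8, t_max = NULL,
                           check_interval = NULL, maxsteps = 20000,
                           overflow = 1e12) {
  stopifnot(Nx >= 51, rtol > 0, atol > 0, ss_tol > 0, maxsteps > 0,
            overflow > 0)
  if (!is.null(t_max)) stopifnot(t_max > 0)
  if (!is.null(check_interval)) stopifnot(check_interval > 0)
  structure(list(Nx = as.integer(Nx), rtol = rtol, atol = atol,
                 ss_tol = ss_tol, t_max = t_max,
                 check_interval = check_interval,
                 maxsteps = as.integer(maxsteps), overflow = overflow),
            class = "solver_options")
}

# Parameter vector handed to the compiled right-hand side; order must match
# src/er_model.c.
c_parms <- function(p, grid) {
  c(p$DM, p$DE, p$k, p$mu, p$nuM, p$nuE, p$xi, p$zeta, p$m, p$h,
    grid$dx, grid$Nx, source_width(p),
    if (is.null(p$j0)) 0 else p$j0,
    if (identical(p$source_mode, "boundary_flux")) 1 else 0)
}

# Default horizon: long enough for the slowest attainable relaxation mode.
# The effective degradation rates are bounded below by their values at the
# expander's saturation concentration E* where production meets the
# saturating degradation mu*zeta; if production exceeds that ceiling the
# expander has no steady state and the horizon is capped (the overflow
# guard then classifies the run).
default_t_max <- function(p) {
  cap <- 1e8
  if (p$mu * p$zeta > p$nuE) {
    e_star <- p$nuE * p$zeta / (p$mu * p$zeta - p$nuE)
    k_eff <- p$k / (1 + e_star / p$xi)
    mu_eff <- p$mu / (1 + e_star / p$zeta)
    min(50 / min(k_eff, mu_eff), cap)
  } else {
    cap
  }
}

#' Assemble the method-of-lines time derivatives
#'
#' Reference implementation of the semi-discrete right-hand side: a
#' second-order central Laplacian with ghost-node reflection enforcing zero
#' diffusive flux at both boundaries, plus the reaction terms. In
#' `boundary_flux` mode the morphogen flux `j0` enters the half-width
#' control volume at x = 0. The compiled solver kernel mirrors this function
#' exactly; tests cross-check the two.
#'
#' @param p A [model_params()] object (must validate).
#' @param grid A [spatial_grid()].
#' @param M,E Concentration vectors matching the grid.
#' @return List with numeric vectors `dM` and `dE`.
#' @export
assemble_rhs <- function(p, grid, M, E) {
  if (length(M) != grid$Nx || length(E) != grid$Nx) {
    stop("assemble_rhs: M and E must have one value per grid node",
         call. = FALSE)
  }
  if (any(!is.finite(M)) || any(!is.finite(E))) {
    stop("assemble_rhs: non-finite concentrations", call. = FALSE)
  }
  n <- grid$Nx
  dx2 <- grid$dx^2
  lap <- function(v) {
    c(2 * (v[2] - v[1]),
      v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n],
      2 * (v[n - 1] - v[n])) / dx2
  }
  rt <- reaction_terms(p, grid, M, E)
  dM <- p$DM * lap(M) + rt$prod_M - rt$deg_M
  dE <- p$DE * lap(E) + rt$prod_E - rt$deg_E
  if (identical(p$source_mode, "boundary_flux")) {
    dM[1] <- dM[1] + p$j0 / (grid$dx / 2)
  }
  list(dM = dM, dE = dE)
}

# Normalised residual max |dC/dt| / (max C + atol), per species and overall.
state_residual <- function(p, grid, M, E, atol) {
  rhs <- assemble_rhs(p, grid, M, E)
  res_M <- max(abs(rhs$dM)) / (max(M) + atol)
  res_E <- max(abs(rhs$dE)) / (max(E) + atol)
  max(res_M, res_E)
}

# One lsodar call with root-stopping on the steady-state criterion and the
# overflow guard. Returns the deSolve matrix (or a condition on failure).
integrate_er <- function(p, grid, y0, times, opts, root_stop = TRUE) {
  parms <- c(c_parms(p, grid), opts$ss_tol, opts$atol, opts$overflow)
  args <- list(y = y0, times = times, func = "er_derivs",
               parms = parms, dllname = "erscaling",
               initfunc = "er_initmod", rtol = opts$rtol, atol = opts$atol,
               jactype = "bandint", bandup = 2L, banddown = 2L,
               maxsteps = opts$maxsteps)
  if (root_stop) {
    args$rootfunc <- "er_root"
    args$nroot <- 2L
  }
  suppressWarnings(try(do.call(deSolve::lsodar, args), silent = TRUE))
}

interleave <- function(M, E) {
  y <- numeric(2 * length(M))
  y[c(TRUE, FALSE)] <- M
  y[c(FALSE, TRUE)] <- E
  y
}

split_state <- function(y) {
  list(M = y[c(TRUE, FALSE)], E = y[c(FALSE, TRUE)])
}

#' Solve the coupled system to steady state
#'
#' Time-marches the morphogen-expander equations from `init` (zero
#' concentrations by default) until the normalised residual of both species
#' falls below `opts$ss_tol`, the horizon `t_max` is reached, or a
#' concentration exceeds the overflow guard. Never raises on
#' non-convergence: the returned [profile_set()] carries `converged = FALSE`
#' and the terminal residual instead.
#'
#' @param p A [model_params()] object; must pass [validate_params()].
#' @param opts A [solver_options()] object.
#' @param init Optional [profile_set()] initial condition on the same grid.
#' @return A [profile_set()] with convergence metadata.
#' @export
#' @examples
#' p <- model_params(k = 0.04, nuE = 0)  # no expander production
#' ps <- solve_steady_state(p, solver_options(Nx = 201))
#' ps$converged
solve_steady_state <- function(p, opts = solver_options(), init = NULL) {
  viol <- validate_params(p)
  if (length(viol) > 0) {
    stop("invalid model parameters: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  grid <- spatial_grid(p$L, opts$Nx)
  if (is.null(init)) {
    y0 <- numeric(2 * grid$Nx)
  } else {
    stopifnot(inherits(init, "profile_set"), init$grid$Nx == grid$Nx)
    y0 <- interleave(init$M, init$E)
  }
  t_max <- if (is.null(opts$t_max)) default_t_max(p) else opts$t_max

  s0 <- split_state(y0)
  res0 <- state_residual(p, grid, s0$M, s0$E, opts$atol)
  if (res0 < opts$ss_tol) {
    return(profile_set(grid, s0$M, s0$E, converged = TRUE, t_elapsed = 0,
                       residual = res0))
  }

  out <- integrate_er(p, grid, y0, c(0, t_max), opts)
  finalize_solution(out, p, grid, opts, t_max)
}

# Shared classification of an lsodar result into a profile_set.
finalize_solution <- function(out, p, grid, opts, t_max) {
  if (inherits(out, "try-error") || !is.matrix(out) || nrow(out) < 1) {
    return(profile_set(grid, rep(NA_real_, grid$Nx), rep(NA_real_, grid$Nx),
                       converged = FALSE, t_elapsed = NA_real_,
                       residual = Inf))
  }
  yT <- out[nrow(out), -1]
  tT <- out[nrow(out), 1]
  s <- split_state(yT)
  if (any(!is.finite(yT)) || max(abs(yT)) >= opts$overflow) {
    ps <- profile_set(grid, s$M, s$E, converged = FALSE, t_elapsed = tT,
                      residual = Inf)
    attr(ps, "reason") <- "blow-up"
    return(ps)
  }
  res <- state_residual(p, grid, s$M, s$E, opts$atol)
  converged <- res < opts$ss_tol
  # clip integrator-level negative undershoot
  M <- pmax(s$M, 0)
  E <- pmax(s$E, 0)
  profile_set(grid, M, E, converged = converged, t_elapsed = tT,
              residual = res)
}

#' Integrate a transient and return time-stamped snapshots
#'
#' @param p A [model_params()] object.
#' @param opts A [solver_options()] object.
#' @param init A [profile_set()] initial condition.
#' @param t_end Final time (> 0).
#' @param times Optional explicit snapshot times; default is a logarithmic
#'   schedule (or multiples of `opts$check_interval` when set) ending at
#'   `t_end`.
#' @return List with `times` and `snapshots` (a list of [profile_set()]s).
#' @export
simulate_transient <- function(p, opts, init, t_end, times = NULL) {
  stopifnot(t_end > 0, inherits(init, "profile_set"))
  grid <- spatial_grid(p$L, opts$Nx)
  stopifnot(init$grid$Nx == grid$Nx)
  if (is.null(times)) {
    times <- if (!is.null(opts$check_interval)) {
      unique(c(seq(0, t_end, by = opts$check_interval), t_end))
    } else {
      c(0, t_end * 10^seq(-4, 0, length.out = 49))
    }
  }
  times <- sort(unique(c(0, times, t_end)))
  y0 <- interleave(init$M, init$E)
  out <- integrate_er(p, grid, y0, times, opts, root_stop = FALSE)
  if (inherits(out, "try-error") || !is.matrix(out)) {
    stop("transient integration failed", call. = FALSE)
  }
  snaps <- lapply(seq_len(nrow(out)), function(i) {
    s <- split_state(out[i, -1])
    res <- state_residual(p, grid, s$M, s$E, opts$atol)
    profile_set(grid, s$M, s$E, converged = res < opts$ss_tol,
                t_elapsed = out[i, 1], residual = res)
  })
  list(times = out[, 1], snapshots = snaps)
}

#' Relaxation timing after a parameter perturbation
#'
#' Restarts the system from a converged base steady state under perturbed
#' parameters and integrates until the steady-state criterion holds again.
#' `t_max_total` is the time at which the spatially integrated morphogen
#' is extremal along the trajectory (a maximum when production is raised, a
#' minimum when lowered); `tau_delta` is the time to reach the new steady
#' state, measured from the perturbation.
#'
#' @param base A converged [profile_set()] under the unperturbed parameters.
#' @param p_perturbed The perturbed [model_params()]; same length and grid.
#' @param opts A [solver_options()] object.
#' @return An object of class `relaxation_result` with fields `tau_delta`,
#'   `t_max_total`, `t_ss`, `converged` and `final` (a [profile_set()]).
#' @export
relax_after_perturbation <- function(base, p_perturbed,
                                     opts = solver_options()) {
  stopifnot(inherits(base, "profile_set"), isTRUE(base$converged))
  grid <- spatial_grid(p_perturbed$L, opts$Nx)
  stopifnot(base$grid$Nx == grid$Nx)
  t_max <- if (is.null(opts$t_max)) default_t_max(p_perturbed) else opts$t_max

  res0 <- state_residual(p_perturbed, grid, base$M, base$E, opts$atol)
  if (res0 < opts$ss_tol) {
    out <- structure(list(tau_delta = 0, t_max_total = 0, t_ss = 0,
                          converged = TRUE, final = base),
                     class = "relaxation_result")
    return(out)
  }

  times <- c(0, t_max * 10^seq(-6, 0, length.out = 240))
  y0 <- interleave(base$M, base$E)
  out <- integrate_er(p_perturbed, grid, y0, times, opts)
  ps <- finalize_solution(out, p_perturbed, grid, opts, t_max)

  if (!is.matrix(out)) {
    return(structure(list(tau_delta = NA_real_, t_max_total = NA_real_,
                          t_ss = NA_real_, converged = FALSE, final = ps),
                     class = "relaxation_result"))
  }
  tt <- out[, 1]
  totals <- apply(out[, -1, drop = FALSE], 1, function(y) {
    trapz_grid(grid, split_state(y)$M)
  })
  dev <- totals - totals[1]
  i_ext <- if (max(dev) >= -min(dev)) which.max(dev) else which.min(dev)
  t_ss <- tt[length(tt)]
  structure(list(tau_delta = if (ps$converged) t_ss else NA_real_,
                 t_max_total = tt[i_ext],
                 t_ss = if (ps$converged) t_ss else NA_real_,
                 converged = ps$converged, final = ps),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf(
    "relaxation_result: tau_delta = %.4g, t_max_total = %.4g (converged = %s)\n",
    x$tau_delta, x$t_max_total, x$converged))
  invisible(x)
}

# Trapezoid integral of a nodal field over the grid.
trapz_grid <- function(grid, v) {
  grid$dx * (sum(v) - (v[1] + v[length(v)]) / 2)
}

#' Steady-state mass-balance residual
#'
#' With zero-flux boundaries a steady state balances total production
#' against total degradation for each species (the input flux `j0` counts
#' as production in `boundary_flux` mode). Returns the relative imbalance
#' `|production - degradation| / production` per species; a species with
#' zero total production reports `NA` (undefined).
#'
#' @param ps A converged [profile_set()].
#' @param p The [model_params()] that produced it.
#' @return Named numeric vector `c(M = ..., E = ...)`.
#' @export
mass_balance_residual <- function(ps, p) {
  grid <- ps$grid
  rt <- reaction_terms(p, grid, ps$M, ps$E)
  prod_M <- trapz_grid(grid, rt$prod_M) +
    if (identical(p$source_mode, "boundary_flux")) p$j0 else 0
  deg_M <- trapz_grid(grid, rt$deg_M)
  prod_E <- trapz_grid(grid, rt$prod_E)
  deg_E <- trapz_grid(grid, rt$deg_E)
  c(M = if (prod_M > 0) abs(prod_M - deg_M) / prod_M else NA_real_,
    E = if (prod_E > 0) abs(prod_E - deg_E) / prod_E else NA_real_)
}
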