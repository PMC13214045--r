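#' Model parameters for the modified expansion-repression circuit
#'
#' Bundles every rate, feedback constant and geometric quantity defining one
#' morphogen-expander system. The morphogen M is produced in a source region
#' of width `wM` at the left tissue edge, diffuses with diffusivity `DM`, and
#' is degraded at the expander-suppressed rate `k / (1 + E/xi)`. The expander
#' E diffuses with `DE`, is produced under morphogen repression at rate
#' `nuE * m^h / (m^h + M^h)`, and is degraded at the self-suppressed rate
#' `mu / (1 + E/zeta)`; `k` and `mu` are therefore upper limits for the two
#' degradation rates.
#'
#' @param DM,DE Morphogen and expander diffusivities (um^2 per model time).
#' @param k,mu Maximal morphogen and expander degradation rates (1/time).
#' @param nuM,nuE Morphogen and maximal expander production rates
#'   (concentration/time).
#' @param xi Expander concentration at which morphogen degradation is halved.
#' @param zeta Expander concentration at which its own degradation is halved.
#' @param m Morphogen concentration at which expander production is halved.
#' @param h Hill coefficient of morphogen repression of expander production.
#' @param beta Source fraction; in `"scaling_width"` mode the source width is
#'   `beta * L` and scales with tissue length.
#' @param L Tissue length (um).
#' @param source_mode One of `"scaling_width"` (source width `beta * L`),
#'   `"fixed_width"` (length-independent width `w0`), or `"boundary_flux"`
#'   (no distributed source; constant morphogen flux `j0` enters at x = 0).
#' @param w0 Fixed source width (um), used when `source_mode = "fixed_width"`.
#' @param j0 Input flux (concentration um / time), used when
#'   `source_mode = "boundary_flux"`.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [validate_params()], [reaction_terms()], [source_width()]
#' @export
#' @examples
#' p <- model_params(k = 0.04, nuE = 0.5, L = 50)
#' source_width(p)
model_params <- function(DM = 1, DE = 10, k = 0.04, mu = 0.02, nuM = 1,
                         nuE = 1, xi = 0.1, zeta = 0.1, m = 0.1, h = 4,
                         beta = 0.1, L = 50,
                         source_mode = c("scaling_width", "fixed_width",
                                         "boundary_flux"),
                         w0 = NULL, j0 = NULL) {
  source_mode <- match.arg(source_mode)
  p <- structure(list(
    DM = DM, DE = DE, k = k, mu = mu, nuM = nuM, nuE = nuE,
    xi = xi, zeta = zeta, m = m, h = h, beta = beta, L = L,
    source_mode = source_mode, w0 = w0, j0 = j0
  ), class = "model_params")
  p
}

#' Validate a parameter set against the model's invariants
#'
#' Never raises: returns a character vector of violation descriptions, empty
#' when the parameter set is admissible. Each message names the offending
#' field and the rule it breaks, so callers (config loading, the sweep) can
#' decide how to react.
#'
#' @param p A [model_params()] object.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_params <- function(p) {
  v <- character(0)
  num_fields <- c("DM", "DE", "k", "mu", "nuM", "nuE", "xi", "zeta", "m",
                  "h", "beta", "L")
  for (f in num_fields) {
    val <- p[[f]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      v <- c(v, sprintf("%s: must be a single finite number", f))
    }
  }
  if (length(v) > 0) return(v)

  pos_fields <- c("DM", "DE", "k", "mu", "xi", "zeta", "m", "L")
  for (f in pos_fields) {
    if (p[[f]] <= 0) v <- c(v, sprintf("%s: must be strictly positive", f))
  }
  # production rates may be zero (degenerate no-source / no-expander cases)
  for (f in c("nuM", "nuE")) {
    if (p[[f]] < 0) v <- c(v, sprintf("%s: must be nonnegative", f))
  }
  if (p$beta <= 0 || p$beta >= 1) {
    v <- c(v, "beta: must lie strictly between 0 and 1")
  }
  if (p$h < 1) v <- c(v, "h: Hill coefficient must be >= 1")
  if (!p$source_mode %in% c("scaling_width", "fixed_width", "boundary_flux")) {
    v <- c(v, "source_mode: unknown mode")
  }
  if (identical(p$source_mode, "fixed_width")) {
    if (is.null(p$w0) || !is.finite(p$w0) || p$w0 <= 0) {
      v <- c(v, "w0: must be a positive width in fixed_width mode")
    } else if (is.finite(p$L) && p$w0 >= p$L) {
      v <- c(v, "w0: must be smaller than the tissue length L")
    }
  }
  if (identical(p$source_mode, "boundary_flux")) {
    if (is.null(p$j0) || !is.finite(p$j0) || p$j0 <= 0) {
      v <- c(v, "j0: must be a positive input flux in boundary_flux mode")
    }
  }
  v
}

#' Effective morphogen source width
#'
#' Returns `beta * L` in `"scaling_width"` mode (the source grows with the
#' tissue), `w0` in `"fixed_width"` mode, and 0 in `"boundary_flux"` mode
#' where production enters as a point flux at x = 0.
#'
#' @param p A [model_params()] object.
#' @return Source width in um.
#' @export
source_width <- function(p) {
  switch(p$source_mode,
    scaling_width = p$beta * p$L,
    fixed_width = p$w0,
    boundary_flux = 0
  )
}

#' Rescale a parameter set to a new tissue length
#'
#' Only the geometry changes: in `"scaling_width"` mode the source width
#' follows as `beta * L`; in the other modes the source is unchanged.
#'
#' @param p A [model_params()] object.
#' @param L New tissue length (um).
#' @return A `model_params` object at length `L`.
#' @export
with_length <- function(p, L) {
  p$L <- L
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Expansion-repression model parameters\n")
  cat(sprintf("  diffusivities:  DM = %g, DE = %g um^2/t\n", x$DM, x$DE))
  cat(sprintf("  degradation:    k = %g, mu = %g /t (upper limits)\n",
              x$k, x$mu))
  cat(sprintf("  production:     nuM = %g, nuE = %g conc/t\n", x$nuM, x$nuE))
  cat(sprintf("  feedback:       xi = %g, zeta = %g, m = %g, h = %g\n",
              x$xi, x$zeta, x$m, x$h))
  cat(sprintf("  geometry:       L = %g um, source %s (wM = %g um)\n",
              x$L, x$source_mode, source_width(x)))
  invisible(x)
}

#' Uniform spatial grid on [0, L]
#'
#' @param L Tissue length (um).
#' @param Nx Number of nodes (>= 3), including both boundaries.
#' @return An object of class `spatial_grid` with elements `L`, `Nx`,
#'   `x` (node positions) and `dx` (spacing).
#' @export
spatial_grid <- function(L, Nx) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(Nx), length(Nx) == 1L, Nx >= 3)
  Nx <- as.integer(Nx)
  structure(list(L = L, Nx = Nx, x = seq(0, L, length.out = Nx),
                 dx = L / (Nx - 1L)),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("spatial_grid: %d nodes on [0, %g] um (dx = %g)\n",
              x$Nx, x$L, x$dx))
  invisible(x)
}

#' Steady-state (or snapshot) concentration profiles
#'
#' Container for morphogen and expander concentrations on a grid together
#' with convergence metadata from the solver.
#'
#' @param grid A [spatial_grid()].
#' @param M,E Numeric vectors of concentrations, one value per grid node.
#' @param converged Logical: did the solver meet its steady-state criterion?
#' @param t_elapsed Integration time at termination (model time units).
#' @param residual Maximum normalised time derivative at termination.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(grid, M, E, converged = NA, t_elapsed = NA_real_,
                        residual = NA_real_) {
  stopifnot(inherits(grid, "spatial_grid"),
            length(M) == grid$Nx, length(E) == grid$Nx)
  structure(list(grid = grid, M = as.numeric(M), E = as.numeric(E),
                 converged = converged, t_elapsed = t_elapsed,
                 residual = residual),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf(
    "profile_set: %d nodes on [0, %g] um; converged = %s (t = %.4g, residual = %.3g)\n",
    x$grid$Nx, x$grid$L, x$converged, x$t_elapsed, x$residual))
  cat(sprintf("  M: [%.4g, %.4g]   E: [%.4g, %.4g]\n",
              min(x$M), max(x$M), min(x$E), max(x$E)))
  invisible(x)
}

#' Per-node source weights for the morphogen production indicator
#'
#' The Heaviside source indicator theta(wM - x) is discretised by the
#' fractional overlap of each node's control volume with the source region,
#' so total production varies continuously as wM crosses grid nodes.
#' Boundary nodes own half-width control volumes.
#'
#' @param p A [model_params()] object.
#' @param grid A [spatial_grid()].
#' @return Numeric vector of weights in [0, 1], one per node.
#' @export
source_weights <- function(p, grid) {
  wM <- source_width(p)
  xl <- pmax(grid$x - grid$dx / 2, 0)
  xr <- pmin(grid$x + grid$dx / 2, grid$L)
  pmax(pmin(xr, wM) - xl, 0) / (xr - xl)
}

#' Evaluate reaction terms of the expansion-repression circuit
#'
#' Computes, at every grid node, the production and degradation fields for
#' both species:
#' morphogen degradation `k * M / (1 + E/xi)` (expander-suppressed),
#' morphogen production `nuM` on source nodes (zero everywhere in
#' `boundary_flux` mode), expander degradation `mu * E / (1 + E/zeta)`
#' (self-suppressed), and expander production `nuE * m^h / (m^h + M^h)`
#' (morphogen-repressed Hill function).
#'
#' @param p A [model_params()] object.
#' @param grid A [spatial_grid()].
#' @param M,E Concentration vectors matching the grid.
#' @return List with numeric fields `prod_M`, `deg_M`, `prod_E`, `deg_E`.
#' @export
reaction_terms <- function(p, grid, M, E) {
  if (length(M) != grid$Nx || length(E) != grid$Nx) {
    stop("reaction_terms: M and E must have one value per grid node",
         call. = FALSE)
  }
  w <- source_weights(p, grid)
  prod_M <- if (identical(p$source_mode, "boundary_flux")) {
    numeric(grid$Nx)
  } else {
    p$nuM * w
  }
  mh <- p$m^p$h
  list(
    prod_M = prod_M,
    deg_M = p$k * M / (1 + E / p$xi),
    prod_E = p$nuE * mh / (mh + pmax(M, 0)^p$h),
    deg_E = p$mu * E / (1 + E / p$zeta)
  )
}
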