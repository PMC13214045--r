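# Closed-form limiting solutions and gradient-shape classification.
#
# The no-feedback limit of the circuit (expander absent or feedback
# thresholds pushed to infinity) reduces the morphogen equation to a linear
# source-diffusion-degradation (SDD) problem whose steady state is known in
# closed form; it serves as the oracle for the numerical solver and as the
# no-feedback baseline the position-dependent metrics are compared against.

# sinh(u)/sinh(c) for |u| <= c, overflow-safe for large arguments.
sinh_ratio <- function(u, c) {
  sign(u) * exp(abs(u) - c) * (1 - exp(-2 * abs(u))) / (1 - exp(-2 * c))
}

#' Closed-form steady state of the constant-rate SDD model
#'
#' Exact solution of `D C'' - K C + nu * theta(wM - x) = 0` with zero-flux
#' boundaries `C'(0) = C'(L) = 0`: hyperbolic-cosine branches in the source
#' and sink regions, matched at `wM` with continuous value and derivative.
#' With decay length `lambda = sqrt(D/K)` the sink branch is proportional to
#' `cosh((L - x)/lambda)`, so e.g. `C(L)/C(wM) = 1/cosh((L - wM)/lambda)`.
#' Evaluated in an overflow-safe form usable for `L/lambda` in the hundreds.
#'
#' @param D Diffusivity (um^2/time).
#' @param K Constant degradation rate (1/time).
#' @param nu Production rate in the source region (concentration/time).
#' @param wM Source width (um), strictly less than `L`.
#' @param L Tissue length (um).
#' @param grid A [spatial_grid()] to evaluate on (its `L` must match).
#' @return Numeric vector of concentrations at the grid nodes.
#' @export
#' @examples
#' g <- spatial_grid(10, 101)
#' C <- sdd_steady_profile(1, 1, 1, 1, 10, g)
#' C[101] / C[11]            # 1/cosh(9)
sdd_steady_profile <- function(D, K, nu, wM, L, grid) {
  stopifnot(D > 0, K > 0, nu >= 0, wM > 0, L > 0)
  if (wM >= L) stop("sdd_steady_profile: wM must be smaller than L",
                    call. = FALSE)
  stopifnot(inherits(grid, "spatial_grid"), isTRUE(all.equal(grid$L, L)))
  lam <- sqrt(D / K)
  a <- wM / lam
  b <- (L - wM) / lam
  cc <- L / lam
  x <- grid$x
  C <- numeric(grid$Nx)
  src <- x <= wM
  # source branch: (nu/K) (1 - sinh(b) cosh(x/lam) / sinh(c)),
  # expanded by the product-to-sum identity to stay overflow-safe
  u <- x[src] / lam
  C[src] <- (nu / K) *
    (1 - (sinh_ratio(b + u, cc) + sinh_ratio(b - u, cc)) / 2)
  # sink branch: (nu/K) sinh(a) cosh((L - x)/lam) / sinh(c)
  v <- (L - x[!src]) / lam
  C[!src] <- (nu / K) * (sinh_ratio(a + v, cc) + sinh_ratio(a - v, cc)) / 2
  C
}

#' Parameters whose circuit degenerates to the constant-rate SDD model
#'
#' Convenience constructor used throughout the tests: expander production is
#' switched off and the feedback thresholds pushed far above any attainable
#' concentration, so the morphogen obeys the linear SDD equation with rate
#' `k` and [sdd_steady_profile()] is its exact steady state.
#'
#' @param D Morphogen diffusivity.
#' @param K Morphogen degradation rate.
#' @param nu Morphogen production rate.
#' @param L Tissue length (um).
#' @param beta Source fraction.
#' @return A [model_params()] object.
#' @export
no_feedback_params <- function(D = 1, K = 1, nu = 1, L = 10, beta = 0.1) {
  model_params(DM = D, DE = 1, k = K, mu = 1, nuM = nu, nuE = 0,
               xi = 1e12, zeta = 1e12, m = 1, h = 2, beta = beta, L = L)
}

#' Classify a gradient as exponential versus power-law
#'
#' Least-squares fits of log concentration against position for the two
#' limiting shape families of the circuit: the exponential
#' `A exp(-x/lambda)` characteristic of uniform-expander systems, and the
#' power law `B (x + c)^(-alpha)` characteristic of systems whose expander
#' has full dynamic range. Because the solver imposes zero flux at `x = L`,
#' a uniform-expander gradient is exactly `A cosh((L - x)/lambda)` — an
#' exponential with a far-boundary plateau — so the exponential family is
#' fit in both forms and the better one is kept (they coincide away from
#' the boundary). Offsets and decay lengths inside nonlinear forms are
#' found by nested 1D searches with a linear fit inside. The signed
#' `preference` score `(rss_exp - rss_pl)/(rss_exp + rss_pl)` lies in
#' `[-1, 1]`; positive values mean the power law fits better.
#'
#' @param profile A [profile_set()] with strictly positive morphogen values
#'   on the fit region.
#' @param fit_region Relative interval `c(lo, hi)` of positions `r = x/L` to
#'   fit over; default avoids the source region and the far-boundary
#'   plateau.
#' @return An object of class `shape_fit` with fields `lambda_exp`,
#'   `amp_exp`, `alpha_pl`, `offset_pl`, `rss_exp`, `rss_pl`, `preference`.
#' @export
fit_gradient_shape <- function(profile, fit_region = c(0.15, 0.95)) {
  stopifnot(inherits(profile, "profile_set"), length(fit_region) == 2,
            fit_region[1] < fit_region[2])
  grid <- profile$grid
  r <- grid$x / grid$L
  sel <- r >= fit_region[1] & r <= fit_region[2]
  if (sum(sel) < 5) {
    stop("fit_gradient_shape: fewer than 5 nodes in the fit region",
         call. = FALSE)
  }
  x <- grid$x[sel]
  M <- profile$M[sel]
  if (any(M <= 0)) {
    stop("fit_gradient_shape: morphogen must be strictly positive on the fit region",
         call. = FALSE)
  }
  lM <- log(M)

  fe <- lm(lM ~ x)
  rss_exp <- sum(fe$residuals^2)
  lambda_exp <- -1 / coef(fe)[[2]]
  amp_exp <- exp(coef(fe)[[1]])

  # zero-flux variant of the same family: A cosh((L - x)/lambda)
  L <- grid$L
  cosh_rss <- function(llam) {
    resid <- lM - log(cosh((L - x) / exp(llam)))
    sum((resid - mean(resid))^2)
  }
  oc <- optimize(cosh_rss, interval = log(c(5e-3 * L, 2 * L)))
  if (oc$objective < rss_exp) {
    rss_exp <- oc$objective
    lambda_exp <- exp(oc$minimum)
    resid <- lM - log(cosh((L - x) / lambda_exp))
    amp_exp <- exp(mean(resid))
  }

  # Nested search for the power-law offset: inner linear fit in log(x + c).
  # The offset is bounded by the fit window's start: a power law whose
  # divergence point -c lies far left of the source degenerates into an
  # exponential (c -> Inf with alpha/c fixed), which would make the two
  # shape families indistinguishable.
  pl_rss <- function(lc) {
    sum(lm(lM ~ log(x + exp(lc)))$residuals^2)
  }
  opt <- optimize(pl_rss, interval = log(c(1e-6 * grid$L, min(x))))
  c_off <- exp(opt$minimum)
  fp <- lm(lM ~ log(x + c_off))
  rss_pl <- sum(fp$residuals^2)
  alpha_pl <- -coef(fp)[[2]]

  denom <- rss_exp + rss_pl
  structure(list(
    lambda_exp = lambda_exp, amp_exp = amp_exp,
    alpha_pl = alpha_pl, offset_pl = c_off,
    rss_exp = rss_exp, rss_pl = rss_pl,
    preference = if (denom > 0) (rss_exp - rss_pl) / denom else 0
  ), class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  fam <- if (x$preference > 0) "power-law" else "exponential"
  cat(sprintf(
    "shape_fit: preference = %+.3f (%s)\n  exp: lambda = %.4g (rss %.3g)   pl: alpha = %.4g, offset = %.4g (rss %.3g)\n",
    x$preference, fam, x$lambda_exp, x$rss_exp, x$alpha_pl, x$offset_pl,
    x$rss_pl))
  invisible(x)
}

#' Analytic scaling profile of a length-invariant exponential gradient
#'
#' For a gradient of fixed shape `M ~ exp(-x/lambda)` that does not respond
#' to tissue length (no morphogen-expander feedback), the position in the
#' larger tissue carrying the concentration found at relative position `r`
#' in the smaller tissue is `rho_L = r / length_ratio` (clamped to [0, 1]),
#' giving `S_M(r) = 1 - r (1 - 1/length_ratio)`.
#'
#' @param lambda_rel Decay length relative to the smaller tissue,
#'   `lambda/L1` (does not affect the result for a fixed-shape gradient;
#'   kept for interface symmetry with [baseline_robustness_profile()]).
#' @param length_ratio `L2/L1 > 1`.
#' @param r_values Relative positions to evaluate at.
#' @return Numeric vector of `S_M` values.
#' @export
baseline_scaling_profile <- function(lambda_rel, length_ratio, r_values) {
  stopifnot(lambda_rel > 0, length_ratio > 1)
  rho <- pmin(pmax(r_values / length_ratio, 0), 1)
  1 - abs(rho - r_values)
}

#' Analytic robustness profile of an exponential gradient
#'
#' Scaling the amplitude of `M ~ exp(-x/lambda)` by `factor^(+-1)` shifts
#' every concentration threshold by `+-(lambda/L) log(factor)` in relative
#' coordinates, so away from the boundaries
#' `R_M(r) = 1 - (lambda/L) log(factor)`. Shifted positions are clamped to
#' `[0, 1]` before averaging, matching the numerical metric's convention.
#'
#' @param lambda_rel Decay length relative to tissue length, `lambda/L`.
#' @param factor Fold change applied to the amplitude (> 1).
#' @param r_values Relative positions to evaluate at.
#' @return Numeric vector of `R_M` values.
#' @export
baseline_robustness_profile <- function(lambda_rel, factor, r_values) {
  stopifnot(lambda_rel > 0, factor > 1)
  shift <- lambda_rel * log(factor)
  rho_p <- pmin(pmax(r_values + shift, 0), 1)
  rho_m <- pmin(pmax(r_values - shift, 0), 1)
  1 - (abs(rho_p - r_values) + abs(rho_m - r_values)) / 2
}
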