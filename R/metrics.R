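# Position-dependent patterning metrics: scaling S_M(r), robustness R_M(r),
# precision P_M(r), expander summaries, and patterning-region classification.

#' Position-dependent metric profile
#'
#' @param r_values Strictly increasing relative positions in [0, 1].
#' @param values Metric value at each position (<= 1).
#' @param clamped Logical flags marking positions where a boundary clamp of
#'   the inverted position to [0, 1] was applied.
#' @param ... Extra named fields (e.g. raw `sigma_r` for precision).
#' @return An object of class `metric_profile`.
#' @export
metric_profile <- function(r_values, values, clamped = NULL, ...) {
  stopifnot(length(values) == length(r_values), all(diff(r_values) > 0))
  if (is.null(clamped)) clamped <- rep(FALSE, length(r_values))
  structure(list(r = r_values, value = values, clamped = clamped, ...),
            class = "metric_profile")
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf(
    "metric_profile: %d positions on [%g, %g]; value range [%.4g, %.4g]; %d clamped\n",
    length(x$r), min(x$r), max(x$r), min(x$value), max(x$value),
    sum(x$clamped)))
  invisible(x)
}

#' Default relative-position grid for metric evaluation
#'
#' @param n Number of uniform points on [0, 1].
#' @return Numeric vector.
#' @export
default_r_grid <- function(n = 101) seq(0, 1, length.out = n)

# Floor used before taking logs of concentrations.
.conc_floor <- 1e-300

#' Invert a monotone concentration profile
#'
#' Finds, for each target concentration, the smallest relative position at
#' which the profile takes that value, by piecewise-linear interpolation on
#' log concentration (exact for exponential decay). Concentrations above
#' the profile maximum clamp to position 0, below the minimum to position
#' 1; clamps are flagged rather than dropped so downstream metrics stay
#' defined tissue-wide.
#'
#' @param r Strictly increasing relative positions of the profile nodes.
#' @param values Profile concentrations at `r`; must be monotonically
#'   non-increasing (checked up to a small relative tolerance).
#' @param conc Target concentration(s).
#' @return List with numeric `rho` and logical `clamped`, one per target.
#' @export
invert_profile <- function(r, values, conc) {
  stopifnot(length(values) == length(r), all(diff(r) > 0))
  tol <- 1e-6 * max(values)   # tolerate solver-level wiggle
  up <- which(diff(values) > tol)
  if (length(up) > 0) {
    stop(sprintf(
      "invert_profile: profile not monotonically non-increasing (first violation at r = %g)",
      r[up[1] + 1]), call. = FALSE)
  }
  v <- cummin(pmax(values, .conc_floor))  # remove numerical wiggle
  lv <- -log(v)                           # non-decreasing
  lc <- -log(pmax(conc, .conc_floor))
  n <- length(v)
  rho <- numeric(length(conc))
  clamped <- logical(length(conc))
  inside <- lc >= lv[1] & lc <= lv[n]
  if (any(inside)) {
    # ties = min picks the smallest position on flat segments
    rho[inside] <- approx(lv, r, xout = lc[inside], ties = min)$y
  }
  hi <- lc < lv[1]          # concentration above profile maximum
  lo <- lc > lv[n]          # below profile minimum
  rho[hi] <- r[1]
  rho[lo] <- r[n]
  clamped[hi | lo] <- TRUE
  list(rho = rho, clamped = clamped)
}

# Non-increasing branch of a profile, from its global maximum to the far
# edge. Strong-feedback systems can peak inside the morphogen source
# (degradation is maximal at x = 0 where the expander is lowest), so
# threshold inversion operates on the decreasing branch; concentrations
# above the branch clamp to the peak position.
decreasing_branch <- function(r, v) {
  i0 <- which.max(v)
  list(r = r[i0:length(r)], v = v[i0:length(v)])
}

# Morphogen profile of a profile_set in relative coordinates, log-linearly
# interpolated onto query positions.
profile_at_r <- function(ps, r_values, field = "M") {
  r <- ps$grid$x / ps$grid$L
  exp(approx(r, log(pmax(ps[[field]], .conc_floor)), xout = r_values,
             rule = 2)$y)
}

#' Position-dependent scaling metric S_M(r)
#'
#' Compares morphogen gradients of one system at two tissue lengths.
#' For each relative position r, the concentration `M(r; L1)` is located in
#' the larger system's profile (absolute, not normalised, concentrations);
#' the scaling metric is one minus the resulting positional shift,
#' `S_M(r) = 1 - |rho_L - r|`. A value of 1 means the concentration is
#' found at the same relative position at both lengths.
#'
#' @param ps1 Converged [profile_set()] at the smaller length L1.
#' @param ps2 Converged [profile_set()] at the larger length L2 > L1.
#' @param r_values Relative positions to evaluate at.
#' @return A [metric_profile()].
#' @export
scaling_profile <- function(ps1, ps2, r_values = default_r_grid()) {
  stopifnot(isTRUE(ps1$converged), isTRUE(ps2$converged),
            ps2$grid$L > ps1$grid$L)
  conc <- profile_at_r(ps1, r_values)
  br <- decreasing_branch(ps2$grid$x / ps2$grid$L, ps2$M)
  inv <- invert_profile(br$r, br$v, conc)
  metric_profile(r_values, 1 - abs(inv$rho - r_values), inv$clamped)
}

#' Position-dependent robustness metric R_M(r)
#'
#' Quantifies how far concentration thresholds move when a parameter
#' (canonically the morphogen production rate) is perturbed up and down by
#' a fold factor: `R_M(r) = 1 - (|rho_+ - r| + |rho_- - r|)/2`, where
#' `rho_+-` are the relative positions in the perturbed systems carrying the
#' base system's concentration `M(r)`.
#'
#' @param base,plus,minus Converged [profile_set()]s at the same tissue
#'   length: unperturbed, increased-parameter and decreased-parameter.
#' @param r_values Relative positions to evaluate at.
#' @return A [metric_profile()].
#' @export
robustness_profile <- function(base, plus, minus,
                               r_values = default_r_grid()) {
  stopifnot(isTRUE(base$converged), isTRUE(plus$converged),
            isTRUE(minus$converged),
            isTRUE(all.equal(base$grid$L, plus$grid$L)),
            isTRUE(all.equal(base$grid$L, minus$grid$L)))
  conc <- profile_at_r(base, r_values)
  bp <- decreasing_branch(plus$grid$x / plus$grid$L, plus$M)
  bm <- decreasing_branch(minus$grid$x / minus$grid$L, minus$M)
  ip <- invert_profile(bp$r, bp$v, conc)
  im <- invert_profile(bm$r, bm$v, conc)
  metric_profile(r_values,
                 1 - (abs(ip$rho - r_values) + abs(im$rho - r_values)) / 2,
                 ip$clamped | im$clamped)
}

#' Position-dependent precision metric P_M(r)
#'
#' Deterministic estimate of the positional noise of a gene-expression
#' boundary read out at concentration `M(r)`:
#' `sigma_r(r) = sqrt(M(r) / (d (dM/dr)^2))`, where `d` is an effective
#' cell size linking concentration fluctuations to the mean profile, and
#' the derivative is taken in relative coordinates by central differences.
#' `P_M(r) = 1 - sigma_r(r)`, floored at 0; where the gradient is locally
#' flat the boundary position is undefined and `sigma_r` diverges
#' (`P_M = 0`, flagged). The metric inherits the amplitude dependence
#' `sigma_r ~ M(0)^(-1/2)`: quadrupling the amplitude halves `sigma_r`.
#'
#' @param ps Converged [profile_set()].
#' @param d Effective cell size (um); canonical choice `0.02 * L1`.
#' @param r_values Relative positions to evaluate at.
#' @return A [metric_profile()] with extra fields `sigma_r` and `divergent`.
#' @export
precision_profile <- function(ps, d, r_values = default_r_grid()) {
  stopifnot(isTRUE(ps$converged), d > 0)
  r <- ps$grid$x / ps$grid$L
  M <- ps$M
  n <- length(M)
  dMdr <- c(M[2] - M[1],
            (M[3:n] - M[1:(n - 2)]) / 2,
            M[n] - M[n - 1]) / (r[2] - r[1])
  Mq <- approx(r, M, xout = r_values, rule = 2)$y
  dq <- approx(r, dMdr, xout = r_values, rule = 2)$y
  divergent <- abs(dq) < 1e-12 * max(abs(M))
  sigma <- ifelse(divergent, Inf, sqrt(Mq / (d * dq^2)))
  metric_profile(r_values, pmax(1 - sigma, 0), clamped = divergent,
                 sigma_r = sigma, divergent = divergent)
}

#' Summary statistics of an expander profile
#'
#' Computes the field's standard descriptors of a steady-state expander
#' profile:
#' * `f_E` — dynamic range `(E(L) - E(wM))/E(L)`: 0 for a uniform
#'   expander, 1 when the expander vanishes at the source edge;
#' * `lambda_E` — half-decay length: distance from the far tissue edge at
#'   which the expander last falls to `E(L)/2` (log-linear interpolation;
#'   `NA` when the profile never drops that far);
#' * `w_E` — expander source width, the integral of the morphogen-repressed
#'   production Hill term `m^h/(m^h + M^h)` over the tissue;
#' * `mu_bar` — integrated effective expander degradation rate
#'   `mu/(1 + E/zeta)` over the tissue.
#' Integrals use the trapezoid rule on the solver grid.
#'
#' @param ps Converged [profile_set()].
#' @param p The [model_params()] that produced it.
#' @return An object of class `expander_summary` with fields `f_E`,
#'   `lambda_E`, `w_E`, `mu_bar`.
#' @export
expander_summaries <- function(ps, p) {
  grid <- ps$grid
  E <- ps$E
  M <- ps$M
  EL <- E[grid$Nx]
  E_wM <- approx(grid$x, E, xout = source_width(p), rule = 2)$y
  f_E <- if (EL > 0) (EL - E_wM) / EL else NA_real_

  lambda_E <- NA_real_
  if (EL > 0) {
    half <- EL / 2
    below <- E < half
    if (any(below)) {
      i <- max(which(below))          # largest x still below half level
      if (i < grid$Nx) {
        l1 <- log(max(E[i], .conc_floor))
        l2 <- log(max(E[i + 1], .conc_floor))
        xh <- grid$x[i] + grid$dx * (log(half) - l1) / (l2 - l1)
        lambda_E <- grid$L - xh
      }
    }
  }

  mh <- p$m^p$h
  w_E <- trapz_grid(grid, mh / (mh + pmax(M, 0)^p$h))
  mu_bar <- trapz_grid(grid, p$mu / (1 + E / p$zeta))
  structure(list(f_E = f_E, lambda_E = lambda_E, w_E = w_E,
                 mu_bar = mu_bar),
            class = "expander_summary")
}

#' @export
print.expander_summary <- function(x, ...) {
  cat(sprintf(
    "expander_summary: f_E = %.3f, lambda_E = %s um, w_E = %.4g um, mu_bar = %.4g\n",
    x$f_E, if (is.na(x$lambda_E)) "not-reached" else sprintf("%.4g", x$lambda_E),
    x$w_E, x$mu_bar))
  invisible(x)
}

#' Classify a scaling profile as global, local, or neither
#'
#' Global scaling means the system maintains scaling above the
#' high-scaling threshold at every evaluated position of the target tissue
#' (the region beyond the morphogen source); local scaling means the
#' threshold is exceeded only around some position, reported as the
#' position where scaling peaks.
#'
#' @param S A [metric_profile()] of scaling values.
#' @param high_threshold Threshold defining "high scaling"; the default
#'   0.98 corresponds to a boundary-position change below 2%.
#' @param target_region Interval `c(lo, hi)` of relative positions to
#'   classify over; canonically `c(wM/L, 1)`.
#' @return List with `kind` (`"none"`, `"local"`, `"global"`) and
#'   `local_position` (`NA` unless local).
#' @export
classify_scaling <- function(S, high_threshold = 0.98,
                             target_region = c(0.1, 1)) {
  sel <- S$r >= target_region[1] & S$r <= target_region[2]
  if (!any(sel)) stop("classify_scaling: empty target region", call. = FALSE)
  v <- S$value[sel]
  r <- S$r[sel]
  high <- v >= high_threshold
  if (all(high)) {
    list(kind = "global", local_position = NA_real_)
  } else if (any(high)) {
    list(kind = "local", local_position = r[which.max(v)])
  } else {
    list(kind = "none", local_position = NA_real_)
  }
}

#' Intervals of simultaneously useful patterning
#'
#' Returns the maximal relative-position intervals on which scaling,
#' robustness and precision all exceed a common threshold; interval edges
#' interior to the grid are located by linear interpolation of the
#' threshold crossing of `min(S, R, P)`.
#'
#' @param S,R,P [metric_profile()]s on a common position grid.
#' @param threshold Common threshold; canonical value 0.95.
#' @return A data.frame with columns `lo` and `hi` (possibly zero rows).
#' @export
useful_patterning_region <- function(S, R, P, threshold = 0.95) {
  if (!isTRUE(all.equal(S$r, R$r)) || !isTRUE(all.equal(S$r, P$r))) {
    stop("useful_patterning_region: metric profiles on mismatched grids",
         call. = FALSE)
  }
  r <- S$r
  m <- pmin(S$value, R$value, P$value)
  above <- m > threshold
  if (!any(above)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  cross <- function(i, j) {
    # threshold crossing between grid indices i < j
    r[i] + (r[j] - r[i]) * (threshold - m[i]) / (m[j] - m[i])
  }
  out <- lapply(which(runs$values), function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    lo <- if (i0 == 1) r[1] else cross(i0 - 1, i0)
    hi <- if (i1 == length(r)) r[length(r)] else cross(i1, i1 + 1)
    c(lo = lo, hi = hi)
  })
  out <- as.data.frame(do.call(rbind, out))
  rownames(out) <- NULL
  out
}
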