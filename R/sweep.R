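# Parameter-space sweep: seeded log-uniform sampling, per-system evaluation
# with admissibility filters, and figure-level aggregation.

#' Sweep configuration
#'
#' Defines the sampling ranges and the measurement protocol of a parameter
#' sweep. The protocol defaults are the study conditions used throughout:
#' each system is solved at tissue lengths `L1 = 50` and `L2 = 100` um to
#' measure scaling; robustness perturbs the morphogen production rate by
#' `1.5`-fold up and down at `L1`; precision uses an effective cell size
#' `d = 0.02 L1 = 1` um; "high scaling" means `S_M >= 0.98` (a < 2% shift
#' of a boundary position) and "useful patterning" requires scaling,
#' robustness and precision all above `0.95`.
#'
#' Sampling ranges are log-uniform per parameter. The defaults span decay
#' lengths from well below to well above `L1`: diffusivities `[0.1, 100]`
#' um^2/t, rates `[1e-3, 10]` /t, production rates `[1e-3, 10]` conc/t,
#' feedback thresholds `[1e-3, 10]` conc; the Hill coefficient is drawn
#' from `{2, 4, 8}` and the source fraction is fixed at `beta = 0.1`.
#'
#' @param n_systems Number of parameter sets to draw.
#' @param seed Integer seed; every random draw in the sweep derives from it.
#' @param ranges Named list of `c(lo, hi)` log-uniform bounds.
#' @param h_values Discrete candidate Hill coefficients.
#' @param beta Fixed source fraction.
#' @param L1,L2 Tissue lengths (um), `L2 > L1`.
#' @param perturb_factor Fold change for the robustness protocol (> 1).
#' @param d Effective cell size for the precision metric (um).
#' @param high_scaling_threshold Threshold defining high scaling.
#' @param useful_threshold Threshold defining useful patterning.
#' @param informative_ratio Admissibility bound: `M(L)/M(0)` at `L1` must
#'   fall below this for the gradient to be informative.
#' @param solver A [solver_options()] object used for all solves.
#' @param r_values Relative-position grid for all metric profiles.
#' @param compute_relaxation Also time the relaxation after each
#'   production perturbation (adds two transient solves per passing
#'   system).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(n_systems = 2000, seed = 1,
                         ranges = list(
                           DM = c(0.1, 100), DE = c(0.1, 100),
                           k = c(1e-3, 10), mu = c(1e-3, 10),
                           nuM = c(1e-3, 10), nuE = c(1e-3, 10),
                           xi = c(1e-3, 10), zeta = c(1e-3, 10),
                           m = c(1e-3, 10)),
                         h_values = c(2, 4, 8), beta = 0.1,
                         L1 = 50, L2 = 100, perturb_factor = 1.5,
                         d = 0.02 * L1,
                         high_scaling_threshold = 0.98,
                         useful_threshold = 0.95,
                         informative_ratio = 0.5,
                         solver = solver_options(Nx = 501),
                         r_values = default_r_grid(),
                         compute_relaxation = TRUE) {
  stopifnot(n_systems >= 0, L2 > L1, perturb_factor > 1, d > 0)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !(rg[1] < rg[2]) || rg[1] <= 0) {
      stop(sprintf("sweep_config: invalid range for %s (need 0 < lo < hi)",
                   nm), call. = FALSE)
    }
  }
  structure(list(n_systems = as.integer(n_systems), seed = as.integer(seed),
                 ranges = ranges, h_values = h_values, beta = beta,
                 L1 = L1, L2 = L2, perturb_factor = perturb_factor, d = d,
                 high_scaling_threshold = high_scaling_threshold,
                 useful_threshold = useful_threshold,
                 informative_ratio = informative_ratio,
                 solver = solver, r_values = r_values,
                 compute_relaxation = compute_relaxation),
            class = "sweep_config")
}

# Deterministic per-system seed derived from (campaign seed, draw index),
# so any single record is re-computable in isolation; kept within the
# 32-bit integer range.
system_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 2654435) %%
               2147483647)
}

#' Draw parameter sets for a sweep
#'
#' Draws `n_systems` parameter sets, each parameter independently
#' log-uniform within its configured range, using a per-system generator
#' seeded from `(seed, draw index)`. Deterministic given the seed, and
#' every returned set passes [validate_params()].
#'
#' @param cfg A [sweep_config()].
#' @return List of [model_params()] objects (at length `L1`).
#' @export
sample_parameter_sets <- function(cfg) {
  lapply(seq_len(cfg$n_systems), function(i) {
    set.seed(system_seed(cfg$seed, i))
    draw <- vapply(cfg$ranges, function(rg) {
      10^runif(1, log10(rg[1]), log10(rg[2]))
    }, numeric(1))
    h <- cfg$h_values[sample.int(length(cfg$h_values), 1)]
    model_params(DM = draw[["DM"]], DE = draw[["DE"]], k = draw[["k"]],
                 mu = draw[["mu"]], nuM = draw[["nuM"]], nuE = draw[["nuE"]],
                 xi = draw[["xi"]], zeta = draw[["zeta"]], m = draw[["m"]],
                 h = h, beta = cfg$beta, L = cfg$L1)
  })
}

# Monotone non-increasing on the target tissue (x >= wM), up to a small
# relative tolerance for solver-level wiggle.
is_monotone_gradient <- function(ps, p) {
  sel <- ps$grid$x >= source_width(p)
  M <- ps$M[sel]
  all(diff(M) <= 1e-8 * max(ps$M))
}

# Feedback-active filter: expander above the morphogen feedback threshold
# xi throughout the bulk of the target tissue (r >= 0.1).
feedback_active <- function(ps, p, r_min = 0.1) {
  sel <- ps$grid$x / ps$grid$L >= r_min
  all(ps$E[sel] > p$xi)
}

#' Evaluate one system under the sweep protocol
#'
#' Runs the steady-state solves required by the protocol (base system at
#' both tissue lengths; production rate perturbed up and down at `L1`),
#' applies the admissibility filters in order, and computes all metrics for
#' systems that pass. Filters (reason codes): `f1` all solves converged;
#' `f2` no concentration blow-up; `f3` morphogen monotonically
#' non-increasing over the target tissue at both lengths; `f4` gradient
#' informative (`M(L)/M(0) < informative_ratio` at `L1`); `f5`
#' expansion-repression feedback active (`E > xi` for all `r >= 0.1` at
#' both lengths). Solves are staged so a system failing an early filter is
#' abandoned cheaply; failing records retain the data computed so far.
#' Never raises on solver failure.
#'
#' @param p A [model_params()] object.
#' @param cfg A [sweep_config()].
#' @return A `system_record`: list with `params`, `profiles`, `summary`,
#'   `S`, `R`, `P`, `shape`, `classification`, `useful`, `relax`, and
#'   `filter_verdict` (`list(pass, reason)`).
#' @export
evaluate_system <- function(p, cfg) {
  rec <- list(params = p, profiles = list(), summary = list(),
              S = NULL, R = NULL, P = NULL, shape = NULL,
              classification = NULL, useful = NULL, relax = list(),
              filter_verdict = list(pass = FALSE, reason = NA_character_))
  class(rec) <- "system_record"
  fail <- function(code) {
    rec$filter_verdict <- list(pass = FALSE, reason = code)
    rec
  }
  check_solve <- function(ps) {
    if (!isTRUE(ps$converged)) {
      if (identical(attr(ps, "reason"), "blow-up")) "f2" else "f1"
    } else {
      NA_character_
    }
  }

  p1 <- with_length(p, cfg$L1)
  b1 <- solve_steady_state(p1, cfg$solver)
  rec$profiles$base_L1 <- b1
  code <- check_solve(b1)
  if (!is.na(code)) return(fail(code))
  if (!is_monotone_gradient(b1, p1)) return(fail("f3"))
  if (!(b1$M[b1$grid$Nx] / b1$M[1] < cfg$informative_ratio)) {
    return(fail("f4"))
  }
  if (!feedback_active(b1, p1)) return(fail("f5"))

  p2 <- with_length(p, cfg$L2)
  b2 <- solve_steady_state(p2, cfg$solver)
  rec$profiles$base_L2 <- b2
  code <- check_solve(b2)
  if (!is.na(code)) return(fail(code))
  if (!is_monotone_gradient(b2, p2)) return(fail("f3"))
  if (!feedback_active(b2, p2)) return(fail("f5"))

  pp <- p1; pp$nuM <- p1$nuM * cfg$perturb_factor
  pm <- p1; pm$nuM <- p1$nuM / cfg$perturb_factor
  sp <- solve_steady_state(pp, cfg$solver, init = b1)
  rec$profiles$plus <- sp
  code <- check_solve(sp)
  if (!is.na(code)) return(fail(code))
  sm <- solve_steady_state(pm, cfg$solver, init = b1)
  rec$profiles$minus <- sm
  code <- check_solve(sm)
  if (!is.na(code)) return(fail(code))

  metric_err <- tryCatch({
    rec$S <- scaling_profile(b1, b2, cfg$r_values)
    rec$R <- robustness_profile(b1, sp, sm, cfg$r_values)
    rec$P <- precision_profile(b1, cfg$d, cfg$r_values)
    rec$summary <- list(L1 = expander_summaries(b1, p1),
                        L2 = expander_summaries(b2, p2))
    rec$shape <- fit_gradient_shape(b1, c(cfg$beta + 0.05, 0.95))
    rec$classification <- classify_scaling(rec$S,
                                           cfg$high_scaling_threshold,
                                           c(cfg$beta, 1))
    rec$useful <- useful_patterning_region(rec$S, rec$R, rec$P,
                                           cfg$useful_threshold)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(metric_err)) return(fail("f3"))
  if (isTRUE(cfg$compute_relaxation)) {
    rec$relax <- list(plus = relax_after_perturbation(b1, pp, cfg$solver),
                      minus = relax_after_perturbation(b1, pm, cfg$solver))
  }
  rec$filter_verdict <- list(pass = TRUE, reason = NA_character_)
  rec
}

#' Run a full parameter sweep
#'
#' Draws the configured number of parameter sets and evaluates each under
#' the sweep protocol. Records are keyed by draw index and the per-system
#' seeding makes any record re-computable in isolation.
#'
#' @param cfg A [sweep_config()].
#' @param progress Print a progress line every 100 systems.
#' @return List with `cfg` and `records` (list of `system_record`s).
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  params <- sample_parameter_sets(cfg)
  records <- vector("list", length(params))
  for (i in seq_along(params)) {
    records[[i]] <- evaluate_system(params[[i]], cfg)
    if (progress && i %% 100 == 0) {
      message(sprintf("  sweep: %d / %d systems", i, length(params)))
    }
  }
  list(cfg = cfg, records = records)
}

#' One scalar summary row per system record
#'
#' @param records List of `system_record`s (as from [run_sweep()]).
#' @return A data.frame with one row per record: the sampled parameters,
#'   filter verdict, expander summaries at both lengths, shape preference,
#'   scaling classification and relaxation times.
#' @export
summarize_records <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    p <- r$params
    pass <- isTRUE(r$filter_verdict$pass)
    data.frame(
      index = i, DM = p$DM, DE = p$DE, k = p$k, mu = p$mu, nuM = p$nuM,
      nuE = p$nuE, xi = p$xi, zeta = p$zeta, m = p$m, h = p$h,
      pass = pass,
      reason = if (pass) "" else r$filter_verdict$reason,
      f_E = if (pass) r$summary$L1$f_E else NA_real_,
      f_E_L2 = if (pass) r$summary$L2$f_E else NA_real_,
      lambda_E_rel_L1 = if (pass) {
        r$summary$L1$lambda_E / r$profiles$base_L1$grid$L
      } else NA_real_,
      lambda_E_rel_L2 = if (pass) {
        r$summary$L2$lambda_E / r$profiles$base_L2$grid$L
      } else NA_real_,
      w_E = if (pass) r$summary$L1$w_E else NA_real_,
      mu_bar = if (pass) r$summary$L1$mu_bar else NA_real_,
      preference = if (pass) r$shape$preference else NA_real_,
      kind = if (pass) r$classification$kind else NA_character_,
      local_position = if (pass) r$classification$local_position else NA_real_,
      tau_plus = if (pass && length(r$relax)) r$relax$plus$tau_delta else NA_real_,
      tau_minus = if (pass && length(r$relax)) r$relax$minus$tau_delta else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Figure-level aggregation of sweep records
#'
#' Bins passing systems by the dynamic range of their expander (`f_E` bins
#' of width 0.1) and by the position where they exhibit high scaling
#' (`S_M(r*) >=` threshold at `r* in {0.2, 0.5, 0.8}`), and computes:
#' mean and SD metric profiles per (position, bin) cell; the probability,
#' per `f_E` bin and position, that a locally or globally scaling system
#' confers useful patterning there (with the distribution's center of
#' mass); `(lambda_E/L)` pairs at the two lengths for global scalers; and
#' Spearman correlations between the gradient-shape preference and `f_E`,
#' and between the mean relaxation time and the integrated expander
#' degradation rate.
#'
#' @param records List of `system_record`s.
#' @param cfg The [sweep_config()] used to produce them.
#' @param r_stars High-scaling anchor positions.
#' @return A list with elements `summary` (per-system data.frame),
#'   `bin_profiles`, `useful_probability`, `lambda_pairs`,
#'   `spearman_shape_fE`, `spearman_tau_mubar`, `n_pass`.
#' @export
aggregate_records <- function(records, cfg, r_stars = c(0.2, 0.5, 0.8)) {
  summary <- summarize_records(records)
  passing <- records[summary$pass]
  spass <- summary[summary$pass, , drop = FALSE]
  if (nrow(spass) < 1) stop("aggregate_records: no passing records",
                            call. = FALSE)
  rr <- cfg$r_values
  fE <- pmin(pmax(spass$f_E, 0), 1)
  bin <- pmin(floor(fE * 10), 9)          # width-0.1 bins, [0.9, 1] merged

  S_at <- function(rec, r) approx(rec$S$r, rec$S$value, xout = r)$y

  bin_profiles <- list()
  for (rs in r_stars) {
    member <- vapply(passing, function(rec) {
      isTRUE(S_at(rec, rs) >= cfg$high_scaling_threshold)
    }, logical(1))
    for (b in sort(unique(bin))) {
      sel <- member & bin == b
      cell <- list(r_star = rs, bin = b, n = sum(sel))
      if (any(sel)) {
        for (metric in c("S", "R", "P")) {
          vals <- do.call(rbind, lapply(passing[sel],
                                        function(rec) rec[[metric]]$value))
          cell[[paste0("mean_", metric)]] <- colMeans(vals)
          cell[[paste0("sd_", metric)]] <- apply(vals, 2, stats::sd)
        }
      }
      bin_profiles[[sprintf("r%.1f_bin%d", rs, b)]] <- cell
    }
  }

  # useful-patterning probability per f_E bin among scaling systems
  scaling_sys <- spass$kind %in% c("local", "global")
  useful_probability <- list()
  for (b in sort(unique(bin[scaling_sys]))) {
    sel <- which(scaling_sys & bin == b)
    inside <- vapply(passing[sel], function(rec) {
      pmin(rec$S$value, rec$R$value, rec$P$value) > cfg$useful_threshold
    }, logical(length(rr)))
    prob <- rowMeans(inside)
    com <- if (sum(prob) > 0) sum(rr * prob) / sum(prob) else NA_real_
    useful_probability[[sprintf("bin%d", b)]] <-
      list(bin = b, n = length(sel), r = rr, probability = prob,
           center_of_mass = com)
  }

  glob <- spass$kind == "global"
  lambda_pairs <- spass[glob, c("index", "f_E", "lambda_E_rel_L1",
                                "lambda_E_rel_L2")]

  # degenerate (constant) inputs yield NA with a warning; keep the NA
  sp_shape <- if (nrow(spass) >= 3) {
    suppressWarnings(cor(spass$preference, spass$f_E, method = "spearman"))
  } else {
    NA_real_
  }
  tau <- (spass$tau_plus + spass$tau_minus) / 2
  ok <- is.finite(tau) & is.finite(spass$mu_bar)
  sp_tau <- if (sum(ok) >= 3) {
    suppressWarnings(cor(tau[ok], spass$mu_bar[ok], method = "spearman"))
  } else {
    NA_real_
  }

  list(summary = summary, bin_profiles = bin_profiles,
       useful_probability = useful_probability,
       lambda_pairs = lambda_pairs,
       spearman_shape_fE = sp_shape, spearman_tau_mubar = sp_tau,
       n_pass = nrow(spass))
}
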