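# Shared fixtures: analytic profiles and small reference systems, built in
# code at test time.

# Fixed-shape exponential gradient M = amp * exp(-x/lambda) as a converged
# profile_set (uniform expander E = 1).
exp_profile <- function(L, lambda, amp = 1, Nx = 501) {
  g <- spatial_grid(L, Nx)
  profile_set(g, amp * exp(-g$x / lambda), rep(1, Nx), converged = TRUE,
              t_elapsed = 0, residual = 0)
}

# Degenerate no-feedback parameter sets used as solver fixtures: the
# morphogen obeys the linear SDD equation, so sdd_steady_profile() is the
# exact steady state.
fixture_systems <- function() {
  list(
    no_feedback_params(D = 1, K = 1, nu = 1, L = 10, beta = 0.1),
    no_feedback_params(D = 5, K = 0.2, nu = 2, L = 50, beta = 0.1),
    no_feedback_params(D = 0.5, K = 0.05, nu = 0.3, L = 50, beta = 0.2)
  )
}

# A representative feedback system with an intermediate expander dynamic
# range; expander production (nuE) sits below the degradation ceiling
# (mu * zeta) so a steady state exists, and converges quickly at moderate
# resolution.
feedback_params <- function(L = 50) {
  model_params(DM = 2, DE = 100, k = 0.5, mu = 2, nuM = 1, nuE = 0.5,
               xi = 0.01, zeta = 1, m = 0.2, h = 4, beta = 0.1, L = L)
}

fast_opts <- function(Nx = 201) solver_options(Nx = Nx)
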