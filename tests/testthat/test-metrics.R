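test_that("invert_profile inverts, interpolates log-linearly, and clamps", {
  r <- seq(0, 1, length.out = 501)
  M <- exp(-r / 0.2)

  # self-inversion
  inv <- invert_profile(r, M, exp(-0.3 / 0.2))
  expect_equal(inv$rho, 0.3, tolerance = 1e-6)
  expect_false(inv$clamped)

  # hand-computed log-linear inverse on a coarse grid
  inv <- invert_profile(c(0, 0.5, 1), c(1, exp(-1), exp(-2)), exp(-0.5))
  expect_equal(inv$rho, 0.25, tolerance = 1e-12)

  # clamping above and below
  inv <- invert_profile(r, M, c(2 * max(M), min(M) / 2))
  expect_equal(inv$rho, c(0, 1))
  expect_true(all(inv$clamped))

  # flat segments resolve to the smallest position
  inv <- invert_profile(c(0, 0.25, 0.5, 1), c(1, 0.5, 0.5, 0.1), 0.5)
  expect_equal(inv$rho, 0.25)

  expect_error(invert_profile(r, rev(M), 0.5), "not monotonically")
})

test_that("scaling metric: pinning, closed forms, and amplitude shifts", {
  r <- default_r_grid()
  ps1 <- exp_profile(50, 10)

  # a perfectly scaled copy (same shape and amplitude in r) pins S to 1
  g2 <- spatial_grid(100, 501)
  ps2_scaled <- profile_set(g2, exp(-(g2$x / 100) * 5), rep(1, 501),
                            converged = TRUE)
  S <- scaling_profile(ps1, ps2_scaled, r)
  expect_equal(S$value, rep(1, length(r)), tolerance = 1e-9)

  # fixed exponential shape at both lengths: S = 1 - r/2 for L2 = 2 L1
  S <- scaling_profile(ps1, exp_profile(100, 10), r)
  expect_lt(max(abs(S$value - (1 - r / 2))), 1e-6)

  # amplitude-shifted scaled copy: S = 1 - (lambda/L2) log(1.5) interior
  ps2_amp <- profile_set(g2, 1.5 * exp(-(g2$x / 100) * 5), rep(1, 501),
                         converged = TRUE)
  S <- scaling_profile(ps1, ps2_amp, r)
  interior <- r > 0.15 & r < 0.85
  expect_lt(max(abs(S$value[interior] - (1 - 0.2 * log(1.5)))), 1e-6)
})

test_that("robustness metric: identity, closed form, clamp arithmetic", {
  r <- default_r_grid()
  base <- exp_profile(50, 10)

  R <- robustness_profile(base, base, base, r)
  expect_equal(R$value, rep(1, length(r)))

  R <- robustness_profile(base, exp_profile(50, 10, 1.5),
                          exp_profile(50, 10, 1 / 1.5), r)
  interior <- r > 0.15 & r < 0.85
  expect_lt(max(abs(R$value[interior] - (1 - 0.2 * log(1.5)))), 1e-6)

  # minus-amplitude so strongly reduced that its maximum falls below the
  # base concentration at r = 0.9: rho_- clamps to 0 while the plus
  # profile is unperturbed, so R(0.9) = 1 - 0.45
  tiny <- exp_profile(50, 10, amp = exp(-4.5) / 2)
  R <- robustness_profile(base, base, tiny, r)
  i <- which.min(abs(r - 0.9))
  expect_equal(R$value[i], 1 - 0.45, tolerance = 1e-6)
  expect_true(R$clamped[i])
})

test_that("precision metric follows the noise formula and its scaling", {
  r <- default_r_grid()
  ps <- exp_profile(1, 0.2, Nx = 2001)
  P <- precision_profile(ps, d = 1, r)
  sigma_expect <- 0.2 * exp(r / 0.4)
  # endpoints use one-sided differences; compare on the interior
  int <- r >= 0.05 & r <= 0.95
  expect_lt(max(abs(P$sigma_r - sigma_expect)[int] / sigma_expect[int]),
            1e-3)
  i <- which.min(abs(r - 0.2))
  expect_equal(P$sigma_r[i], 0.3297, tolerance = 1e-3)
  expect_equal(P$value[i], 1 - 0.3297, tolerance = 1e-3)

  # quadrupling the amplitude halves sigma_r everywhere
  P4 <- precision_profile(exp_profile(1, 0.2, amp = 4, Nx = 2001), 1, r)
  expect_equal(P4$sigma_r, P$sigma_r / 2, tolerance = 1e-9)

  # flat plateau: divergent flag, P = 0
  g <- spatial_grid(1, 501)
  flat <- profile_set(g, rep(2, 501), rep(1, 501), converged = TRUE)
  Pf <- precision_profile(flat, 1, r)
  expect_true(all(Pf$divergent))
  expect_true(all(Pf$value == 0))
})

test_that("metric values never exceed 1 and scaling/robustness stay in [0,1]", {
  r <- default_r_grid()
  set.seed(9)
  for (i in 1:10) {
    lam1 <- runif(1, 2, 30)
    lam2 <- runif(1, 2, 30)
    amp2 <- 10^runif(1, -1, 1)
    S <- scaling_profile(exp_profile(50, lam1),
                         exp_profile(100, lam2, amp2), r)
    expect_true(all(S$value <= 1 + 1e-12))
    expect_true(all(S$value >= 0))
    R <- robustness_profile(exp_profile(50, lam1),
                            exp_profile(50, lam2, amp2),
                            exp_profile(50, lam1, 1 / amp2), r)
    expect_true(all(R$value <= 1 + 1e-12))
    expect_true(all(R$value >= 0))
  }
})

test_that("expander summaries implement the standard descriptors", {
  p <- model_params(m = 0.2, h = 4, mu = 2, zeta = 1, beta = 0.1, L = 50)
  g <- spatial_grid(50, 501)

  # uniform expander: zero dynamic range, half-decay never reached
  ps <- profile_set(g, exp(-g$x / 10), rep(3, 501), converged = TRUE)
  es <- expander_summaries(ps, p)
  expect_equal(es$f_E, 0)
  expect_true(is.na(es$lambda_E))
  # uniform E = 3: mu_bar = L * mu/(1 + 3)
  expect_equal(es$mu_bar, 50 * 2 / 4, tolerance = 1e-12)

  # linear expander with E(wM) = 0.5 E(L): f_E = 0.5
  E_lin <- 0.5 + 0.5 * (g$x - 5) / 45
  ps <- profile_set(g, exp(-g$x / 10), E_lin, converged = TRUE)
  es <- expander_summaries(ps, p)
  expect_equal(es$f_E, 0.5, tolerance = 1e-6)
  expect_false(is.na(es$lambda_E))

  # M = m everywhere: the production integrand is 1/2, so w_E = L/2
  ps <- profile_set(g, rep(p$m, 501), E_lin, converged = TRUE)
  es <- expander_summaries(ps, p)
  expect_equal(es$w_E, 25, tolerance = 1e-12)
})

test_that("scaling classification separates global, local and none", {
  r <- default_r_grid()
  S1 <- metric_profile(r, rep(1, 101))
  expect_equal(classify_scaling(S1, 0.98, c(0.1, 1))$kind, "global")

  S2 <- metric_profile(r, 1 - abs(r - 0.3))
  cl <- classify_scaling(S2, 0.98, c(0.1, 1))
  expect_equal(cl$kind, "local")
  expect_equal(cl$local_position, 0.3, tolerance = 1e-9)

  S3 <- metric_profile(r, rep(0.5, 101))
  expect_equal(classify_scaling(S3, 0.98, c(0.1, 1))$kind, "none")

  expect_error(classify_scaling(S1, 0.98, c(2, 3)), "empty target region")
})

test_that("useful patterning intervals interpolate threshold crossings", {
  r <- default_r_grid()
  one <- metric_profile(r, rep(1, 101))

  u <- useful_patterning_region(one, one, one, 0.95)
  expect_equal(nrow(u), 1)
  expect_equal(c(u$lo, u$hi), c(0, 1))

  zero <- metric_profile(r, rep(0, 101))
  expect_equal(nrow(useful_patterning_region(one, one, zero, 0.95)), 0)

  # P crosses 0.95 exactly at r = 0.4
  P <- metric_profile(r, 0.95 + 0.1 * (0.4 - r))
  u <- useful_patterning_region(one, one, P, 0.95)
  expect_equal(nrow(u), 1)
  expect_equal(u$lo, 0)
  expect_equal(u$hi, 0.4, tolerance = 1e-9)

  bad <- metric_profile(seq(0, 1, length.out = 51), rep(1, 51))
  expect_error(useful_patterning_region(one, one, bad, 0.95),
               "mismatched grids")
})
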