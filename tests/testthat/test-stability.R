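test_that("F and G have the printed structure", {
  p <- model_params(mu = 2e-3, kappa = 100, zeta = 0.5)
  expect_equal(F_of(0, p), 0)
  expect_equal(G_of(0, p), 1)
  zs <- seq(0.5, 200, length.out = 100)
  expect_true(all(G_of(zs, p) >= 1))
  ## sign of F flips exactly where z^2 phi_hat^2 crosses mu kappa
  lhs <- zs^2 * phi_hat(zs, p)^2
  expect_equal(F_of(zs, p) > 0, lhs > p$mu * p$kappa)
})

test_that("dispersion roots satisfy the factored determinant", {
  set.seed(6)
  for (i in 1:20) {
    p <- model_params(mu = 10^runif(1, -4, -1), kappa = 10^runif(1, 1, 3),
                      zeta = runif(1, 0.1, 2), tau = runif(1, 0.1, 0.3),
                      Cphi = runif(1, 1, 8))
    k <- runif(2, -40, 40)
    if (sqrt(sum(k^2)) < 1) k <- k + 2
    Om <- c(cos(pi / 4), sin(pi / 4))
    roots <- dispersion_roots(k, p, Om)
    ac <- alignment_constants(p$ds / p$nu, p$u0, p$rA)
    kn <- sqrt(sum(k^2))
    k0 <- sum(k * Om); k1 <- k[2] * Om[1] - k[1] * Om[2]
    Fv <- F_of(kn, p); Gv <- G_of(kn, p)
    for (al in roots) {
      resid <- Mod((Gv * al - Fv + 1i * ac$d1 * k0) *
                     (al + 1i * ac$d2 * k0 + kn^2 * ac$gamma_s) +
                     ac$d1 * ac$d3 * k1^2)
      expect_lt(resid, 1e-8 * max(1, abs(Fv)))
    }
  }
})

test_that("parallel wavevectors decouple into density and orientation branches", {
  p <- model_params(mu = 2e-3, kappa = 100, zeta = 0.5)
  ac <- alignment_constants(p$ds / p$nu, p$u0, p$rA)
  Om <- c(cos(pi / 4), sin(pi / 4))
  z <- 25
  roots <- dispersion_roots(z * Om, p, Om)
  expect_equal(Re(roots[2]), -z^2 * ac$gamma_s)
  expect_equal(Im(roots[2]), -ac$d2 * z)
  ## F > 0 at this z (unstable regime): the density branch grows
  expect_gt(F_of(z, p), 0)
  expect_equal(Re(roots[1]), F_of(z, p) / G_of(z, p))
  expect_error(dispersion_roots(c(0, 0), p), "positive")
})

test_that("predictions are invariant under rotating the reference direction", {
  p <- model_params(mu = 2e-3, kappa = 100, zeta = 0.5)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  for (k_rel in list(c(20, 0), c(0, 20), c(15, 10))) {
    r0 <- dispersion_roots(k_rel, p, Omega0 = c(1, 0))
    r1 <- dispersion_roots(rot(k_rel, pi / 4), p,
                           Omega0 = rot(c(1, 0), pi / 4))
    expect_equal(sort(Re(r0)), sort(Re(r1)), tolerance = 1e-10)
    expect_equal(sort(Im(r0)), sort(Im(r1)), tolerance = 1e-10)
  }
})

test_that("instability is governed by b_p = mu kappa / c0", {
  expect_true(is_linearly_unstable(model_params(mu = 4e-3, kappa = 1000))$unstable)
  expect_false(is_linearly_unstable(model_params(mu = 6e-3, kappa = 1000))$unstable)
  expect_true(is_linearly_unstable(model_params(mu = 0, kappa = 1000))$unstable)

  ## stable above threshold: no growing mode anywhere on a dense scan
  p <- model_params(mu = 6e-3, kappa = 1000, zeta = 0.5)
  pr <- pattern_prediction(p)
  expect_lt(pr$alpha_max_par, 0)
  expect_lt(pr$alpha_max_perp, 0)
  expect_true(is.na(pr$S1_th) && is.na(pr$S2_th))

  ## pinned-obstacle limit: very stiff springs are stable for any fixed mu
  p_stiff <- model_params(mu = 1e-3, kappa = 1e8, zeta = 0.5)
  pr2 <- pattern_prediction(p_stiff)
  expect_lt(pr2$alpha_max_par, 0)
  expect_lt(pr2$alpha_max_perp, 0)
})

test_that("predicted cluster size grows with the bifurcation parameter", {
  p <- model_params(kappa = 1000, zeta = 0.5)
  scan <- stability_scan(p, c(2e-5, 2e-4, 6e-4, 2e-3, 4e-3))
  expect_true(all(is.finite(scan$S1_th)))
  expect_true(all(diff(scan$S1_th) > 0))
  expect_true(all(scan$alpha_max_par > 0))
  expect_true(all(diff(scan$bp) > 0))
})

test_that("travelling-band regime: parallel growth dominates the perpendicular", {
  p <- continuum_default_params(mu = 4e-3, kappa = 1000, zeta = 0.5)
  pr <- pattern_prediction(p)
  expect_gt(pr$alpha_max_par, 0)
  expect_false(is.na(pr$S1_th))
  ## the perpendicular direction is at best marginal: an order of magnitude
  ## below the parallel growth, so only bands (patterns along Omega0) emerge
  expect_lt(pr$alpha_max_perp, 0.1 * pr$alpha_max_par)
})

test_that("threshold located by dispersion-scan bisection matches c0", {
  p <- model_params(kappa = 1000, zeta = 0.5, tau = 0.15, Cphi = 5)
  th <- instability_threshold(p)
  expect_equal(th$bp_star, 1, tolerance = 1e-3)
  expect_equal(th$mu_star * p$kappa, compute_c0(p)$c0, tolerance = 1e-3)
  expect_error(instability_threshold(p, mu_lo = 0.5, mu_hi = 1), "bracket")
})

test_that("the linearized mode response reduces to the density branch when parallel", {
  p <- model_params(mu = 2e-3, kappa = 100, zeta = 0.5)
  Om <- c(cos(pi / 4), sin(pi / 4))
  z <- 20
  a1 <- dispersion_roots(z * Om, p, Om)[1]
  ts <- c(0.05, 0.1, 0.2)
  resp <- linear_mode_response(z * Om, p, ts, Om)
  expect_equal(Mod(resp), exp(Re(a1) * ts), tolerance = 1e-10)
})
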