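test_that("repulsion kernels match their closed forms and compact support", {
  p <- model_params(mu = 0.1, rR = 0.075, Cphi = 5, tau = 0.15)
  expect_equal(psi_eval(p$rR / 2, p), 6 * 0.1 / (pi * 0.075^2) * 0.25)
  expect_equal(psi_eval(p$rR, p), 0)
  expect_equal(psi_eval(2 * p$rR, p), 0)
  expect_equal(phi_eval(p$tau, p), 0)
  expect_equal(phi_eval(0, p), 3 * 5 / (2 * pi * 0.15))
  expect_error(psi_eval(-1e-3, p), "non-negative")
  expect_error(phi_eval(c(0.1, -0.2), p), "non-negative")
})

test_that("kernel gradients: zero at origin, zero outside, correct inside", {
  p <- model_params(mu = 0.1, rR = 0.075, Cphi = 5, tau = 0.15)
  expect_equal(psi_grad(c(0, 0), p), c(0, 0))
  expect_equal(phi_grad(c(0, 0), p), c(0, 0))
  expect_equal(psi_grad(c(0.1, 0.1), p), c(0, 0))
  ## central-difference check at interior offsets
  for (x in list(c(0.03, 0.01), c(-0.02, 0.04), c(0.05, -0.02))) {
    h <- 1e-7
    for (fn in list(c(psi_eval, psi_grad), c(phi_eval, phi_grad))) {
      num <- c((fn[[1]](sqrt(sum((x + c(h, 0))^2)), p) -
                fn[[1]](sqrt(sum((x - c(h, 0))^2)), p)) / (2 * h),
               (fn[[1]](sqrt(sum((x + c(0, h))^2)), p) -
                fn[[1]](sqrt(sum((x - c(0, h))^2)), p)) / (2 * h))
      expect_equal(fn[[2]](x, p), num, tolerance = 1e-5)
    }
  }
  ## matrix input preserves shape
  g <- psi_grad(rbind(c(0.02, 0.01), c(0, 0)), p)
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(g[2, ], c(0, 0))
})

test_that("normalization integrals recover mu and Cphi", {
  set.seed(1)
  for (i in 1:10) {
    p <- model_params(mu = runif(1, 0.01, 1), rR = runif(1, 0.02, 0.2),
                      Cphi = runif(1, 0.5, 10), tau = runif(1, 0.05, 0.3))
    int_psi <- integrate(function(r) 2 * pi * r * psi_eval(r, p),
                         0, p$rR, rel.tol = 1e-10)$value
    expect_equal(int_psi, p$mu, tolerance = 1e-6)
    ## |grad phi|(r) = (3 Cphi / (pi tau^2)) (1 - r/tau) on the support
    int_gphi <- integrate(function(r)
      2 * pi * r * sqrt(rowSums(phi_grad(cbind(r, 0), p)^2)),
      0, p$tau, rel.tol = 1e-10)$value
    expect_equal(int_gphi, p$Cphi, tolerance = 1e-6)
    ## integral of phi itself has the closed form Cphi * tau / 4
    int_phi <- integrate(function(r) 2 * pi * r * phi_eval(r, p),
                         0, p$tau, rel.tol = 1e-10)$value
    expect_equal(int_phi, p$Cphi * p$tau / 4, tolerance = 1e-6)
  }
})

test_that("phi_hat: value at zero, self-similarity, 2-D FFT oracle", {
  p <- model_params(Cphi = 5, tau = 0.15)
  expect_equal(phi_hat(0, p), 5 * 0.15 / 4, tolerance = 1e-10)
  expect_error(phi_hat(-1, p), "non-negative")

  ## self-similarity: phi_hat_tau(z) = tau * phi_hat_1(tau z)
  p1 <- model_params(Cphi = 5, tau = 0.45)  # tau < L/2 stands in for tau = 1
  for (z in c(1, 5, 12, 30)) {
    lhs <- phi_hat(z, p) * p$tau^0
    ## rescale: with tau' = a*tau, phi_hat'(z) = a * phi_hat(a z) for same Cphi
    a <- p1$tau / p$tau
    expect_equal(phi_hat(z, p1), a * phi_hat(a * z, p), tolerance = 1e-10)
  }

  ## oracle: 2-D FFT of the kernel sampled on a fine periodic grid
  Ng <- 1024; h <- 1 / Ng
  o <- (0:(Ng - 1)) * h; o <- pmin(o, 1 - o)
  K <- phi_eval(sqrt(outer(o^2, o^2, "+")), p)
  Kh <- Re(stats::fft(K)) * h^2
  for (nv in list(c(1, 0), c(2, 1), c(3, 3), c(5, 0), c(4, 4))) {
    z <- 2 * pi * sqrt(sum(nv^2))
    expect_lt(abs(Kh[nv[1] + 1, nv[2] + 1] - phi_hat(z, p)), 1e-6)
  }
})

test_that("c0 is tau-invariant, scales as Cphi^2, and locates an interior max", {
  ps <- lapply(c(0.1, 0.15, 0.2, 0.3), function(tau)
    model_params(Cphi = 5, tau = tau))
  c0s <- vapply(ps, function(p) compute_c0(p)$c0, numeric(1))
  expect_true(all(abs(c0s / c0s[1] - 1) < 1e-3))
  ## z_star scales as 1/tau (the product z* tau is kernel-invariant)
  zs <- vapply(ps, function(p) compute_c0(p)$z_star, numeric(1))
  expect_equal(zs * c(0.1, 0.15, 0.2, 0.3) / (zs[1] * 0.1), rep(1, 4),
               tolerance = 1e-4)
  ## quadratic scaling in Cphi
  c0_10 <- compute_c0(model_params(Cphi = 10, tau = 0.15))$c0
  expect_equal(c0_10 / c0s[2], 4, tolerance = 1e-8)
  expect_equal(compute_c0(model_params(Cphi = 0))$c0, 0)
})

test_that("bifurcation parameter reproduces the reference values", {
  expect_equal(compute_bp(model_params(mu = 4e-3, kappa = 1000, Cphi = 5)),
               0.7142, tolerance = 1e-3)
  expect_equal(compute_bp(model_params(mu = 6e-3, kappa = 1000, Cphi = 5)),
               1.0713, tolerance = 1e-3)
  expect_equal(compute_bp(model_params(mu = 0)), 0)
  ## b_p depends on mu and kappa only through their product
  expect_equal(compute_bp(model_params(mu = 4e-2, kappa = 100, Cphi = 5)),
               compute_bp(model_params(mu = 4e-3, kappa = 1000, Cphi = 5)))
})
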