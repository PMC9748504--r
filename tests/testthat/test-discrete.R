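test_that("initial state: determinism, common orientation, uniform positions", {
  p <- model_params(N = 300, M = 3000)
  a <- init_state(p, seed = 4)
  b <- init_state(p, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$theta == pi / 4))
  expect_true(all(a$Z >= 0 & a$Z < 1))
  expect_identical(a$X, a$Y)
  ## CLT bound on the empirical mean of uniform positions
  se <- sqrt(1 / 12 / p$M)
  expect_lt(max(abs(colMeans(a$Z) - 0.5)), 3 * se)
  ## independent obstacle draw flag
  cc <- init_state(p, seed = 4, obstacles_at_anchors = FALSE)
  expect_false(identical(cc$X, cc$Y))
})

test_that("mean direction: self-inclusion, two-agent average, tie-break", {
  p <- model_params(N = 0, M = 1, rA = 0.1)
  st <- manual_state(matrix(c(0.5, 0.5), 1), pi / 3)
  expect_equal(mean_direction(st, p)[1, ], c(cos(pi / 3), sin(pi / 3)))

  p2 <- model_params(N = 0, M = 2, rA = 0.1)
  st2 <- manual_state(rbind(c(0.5, 0.5), c(0.55, 0.5)), c(0, pi / 2))
  md <- mean_direction(st2, p2)
  expect_equal(md[1, ], c(1, 1) / sqrt(2))
  expect_equal(md[2, ], c(1, 1) / sqrt(2))

  ## exact cancellation keeps the current orientation
  st3 <- manual_state(rbind(c(0.5, 0.5), c(0.55, 0.5)), c(0, pi))
  md3 <- mean_direction(st3, p2)
  expect_equal(md3[1, ], c(1, 0))
  expect_equal(md3[2, ], c(-1, 0))
})

test_that("cell-list interaction sums equal the all-pairs reference", {
  p <- model_params(N = 50, M = 50)
  st <- init_state(p, seed = 8)
  st$theta <- runif(50, 0, 2 * pi)
  a <- discrete_forces(st, p, use_cells = TRUE)
  b <- discrete_forces(st, p, use_cells = FALSE)
  for (nm in names(a)) expect_lt(max(abs(a[[nm]] - b[[nm]])), 1e-12)

  ## clustered configuration (many shared cells)
  p2 <- model_params(N = 80, M = 80)
  set.seed(9)
  st2 <- init_state(p2, seed = 9)
  st2$Z <- (matrix(rnorm(160, 0.5, 0.05), ncol = 2)) %% 1
  st2$theta <- runif(80, 0, 2 * pi)
  a2 <- discrete_forces(st2, p2, use_cells = TRUE)
  b2 <- discrete_forces(st2, p2, use_cells = FALSE)
  for (nm in names(a2)) expect_lt(max(abs(a2[[nm]] - b2[[nm]])), 1e-12)
})

test_that("deterministic limits: free streaming and spring relaxation", {
  ## single agent, no obstacles, no noise: straight-line motion
  p <- model_params(N = 0, M = 1, ds = 0, mu = 0, Cphi = 0)
  st <- manual_state(matrix(c(0.2, 0.2), 1), pi / 4)
  st1 <- step_discrete(st, p, dt = 1e-3)
  expect_equal(st1$Z[1, ], c(0.2, 0.2) + 1e-3 * c(cos(pi / 4), sin(pi / 4)),
               tolerance = 1e-14)
  expect_equal(st1$theta, pi / 4)

  ## single obstacle, no agents: explicit-Euler spring contraction
  p2 <- model_params(N = 1, M = 0, d0 = 0, kappa = 1, eta = 1)
  st2 <- manual_state(matrix(numeric(0), 0, 2), numeric(0),
                      X = matrix(c(0.6, 0.5), 1), Y = matrix(c(0.5, 0.5), 1))
  dt <- 0.01
  for (i in 1:5) st2 <- step_discrete(st2, p2, dt)
  expect_equal(st2$X[1, 1] - 0.5, 0.1 * (1 - dt)^5, tolerance = 1e-12)

  expect_error(step_discrete(st2, p2, dt = -1), "positive")
})

test_that("pinned-obstacle limit: very stiff springs keep X at Y", {
  p <- model_params(N = 200, M = 0, kappa = 1e6, eta = 1, d0 = 0)
  run <- run_discrete(p, T = 5e-6, dt = 1e-7, seed = 3,
                      obstacles_at_anchors = FALSE)
  d <- run$final$X - run$final$Y
  d <- d - round(d)
  expect_lt(max(abs(d)), 0.01)
})

test_that("runs are reproducible and abort on over-large displacements", {
  p <- model_params(N = 100, M = 100, ds = 0.02, d0 = 1e-5)
  r1 <- run_discrete(p, T = 0.05, dt = 1e-3, seed = 5)
  r2 <- run_discrete(p, T = 0.05, dt = 1e-3, seed = 5)
  expect_identical(r1$final, r2$final)

  fast <- model_params(N = 0, M = 5, u0 = 1000, ds = 0)
  expect_error(run_discrete(fast, T = 0.01, dt = 1e-3, seed = 1),
               "displacement")
})

test_that("free angular diffusion accumulates variance 2 ds t", {
  ## alignment and repulsion off: agents diffuse independently on the circle
  p <- model_params(N = 0, M = 2000, mu = 0, Cphi = 0, nu = 0, ds = 0.05,
                    rA = 0.01)
  run <- run_discrete(p, T = 1, dt = 1e-3, seed = 21)
  dth <- run$final$theta - pi / 4
  dth <- atan2(sin(dth), cos(dth))
  expect_equal(var(dth), 2 * 0.05 * 1, tolerance = 0.1)
})

test_that("obstacles without agents equilibrate to the OU variance d0 eta / kappa", {
  p <- model_params(N = 1500, M = 0, d0 = 1e-4, kappa = 1, eta = 1)
  run <- run_discrete(p, T = 8, dt = 2e-3, seed = 22)
  d <- run$final$X - run$final$Y
  d <- d - round(d)
  expect_equal(var(as.vector(d)), 1e-4, tolerance = 0.1)
})

test_that("snapshot CSV writer emits both tables with seed-stable content", {
  p <- model_params(N = 5, M = 4)
  st <- init_state(p, seed = 2)
  fa <- tempfile(fileext = ".csv"); fo <- tempfile(fileext = ".csv")
  write_discrete_snapshot(st, fa, fo)
  ag <- read.csv(fa); ob <- read.csv(fo)
  expect_equal(nrow(ag), 4)
  expect_equal(nrow(ob), 5)
  expect_named(ag, c("t", "id", "x", "y", "theta"))
  expect_named(ob, c("t", "id", "x", "y", "anchor_x", "anchor_y"))
  expect_equal(ag$x, st$Z[, 1])
  unlink(c(fa, fo))
})
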