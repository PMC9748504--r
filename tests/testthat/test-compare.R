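test_that("sampling points from a density: support, determinism, uniformity", {
  rho <- matrix(0, 8, 8); rho[3, 5] <- 64   # all mass in one cell
  pts <- sample_points(rho, 50, seed = 1)
  expect_true(all(pts[, 1] >= 2 / 8 & pts[, 1] < 3 / 8))
  expect_true(all(pts[, 2] >= 4 / 8 & pts[, 2] < 5 / 8))

  expect_identical(sample_points(rho, 20, seed = 3),
                   sample_points(rho, 20, seed = 3))

  pts_u <- sample_points(matrix(1, 16, 16), 1e4, seed = 9)
  cnt <- table(factor(floor(pts_u[, 1] * 4) + 4 * floor(pts_u[, 2] * 4),
                      levels = 0:15))
  expect_gt(chisq.test(as.vector(cnt))$p.value, 0.01)
  expect_error(sample_points(matrix(-1, 2, 2), 5), "non-negative")
})

test_that("PIC deposition: locality, exact mass, naive-loop oracle", {
  h <- 1 / 16
  pt <- matrix(c(3.5 * h, 7.5 * h), 1)   # exactly at a cell center
  rho <- pic_density(pt, h)
  expect_equal(rho[4, 8], 1 / (1 * h^2))
  expect_equal(sum(rho) - rho[4, 8], 0)

  set.seed(11)
  pts <- matrix(runif(200), ncol = 2)
  for (hh in c(1 / 8, 1 / 32)) {
    dep <- pic_density(pts, hh)
    expect_equal(sum(dep) * hh^2, 1, tolerance = 1e-12)
    expect_lt(max(abs(dep - naive_pic(pts, hh))), 1e-12)
  }
  expect_error(pic_density(pts, 0.3), "integer")
})

test_that("optimal grid spacing adapts to cloud size and density shape", {
  cl <- clustered_field(Nx = 96, width = 0.03, n_bumps = 5, seed = 3)
  h_by_N <- vapply(c(200, 2000, 20000), function(N)
    optimal_grid_spacing(cl, N, seed = 5)$h_tilde, numeric(1))
  expect_true(all(diff(h_by_N) < 0))     # more points allow finer grids

  smooth <- banded_field(Nx = 96, n = 1, amplitude = 0.05)
  h_smooth <- optimal_grid_spacing(smooth, 2000, seed = 5)$h_tilde
  expect_gt(h_smooth, h_by_N[2])         # smooth densities favour coarse grids

  ## U-shaped error curve: the minimum is interior to the candidate range
  og <- optimal_grid_spacing(cl, 2000, seed = 5)
  i <- which.min(og$l2_curve$l2_error)
  expect_gt(i, 1)
  expect_lt(i, nrow(og$l2_curve))
  expect_error(optimal_grid_spacing(cl, 100, candidate_h = numeric(0)),
               "non-empty")
})

test_that("signatures partition the grid with half-open bins", {
  sig <- make_signature(matrix(c(0.5, 1.5, 2.5, 3.5), 2), n_b = 2)
  expect_equal(sig$points, c(1.75, 3.5))
  expect_equal(sig$weights, c(2, 2))

  const <- make_signature(matrix(2, 5, 5), n_b = 4)
  expect_equal(sig_total <- sum(const$weights), 25)
  expect_equal(const$weights[4], 25)     # the single occupied (last) bin

  set.seed(13)
  for (i in 1:5) {
    f <- matrix(rexp(400), 20, 20)
    auto <- make_signature(f)
    expect_equal(sum(auto$weights), 400)
    fixed <- make_signature(f, n_b = 7)
    expect_equal(sum(fixed$weights), 400)
    expect_equal(length(fixed$points), 7)
    expect_equal(fixed$points[7], max(f))
  }
  ## the n^(3/2) bin-rule variant yields (many) more bins than the standard rule
  f <- matrix(rexp(400), 20, 20)
  expect_gte(length(make_signature(f, rule = "fd_3_2")$points),
             length(make_signature(f)$points))
})

test_that("EMD: hand examples, including the unbalanced transportation case", {
  P <- list(points = 0, weights = 1)
  Q <- list(points = 5, weights = 1)
  expect_equal(emd(P, Q), 5)
  expect_equal(emd(Q, Q), 0)
  expect_equal(emd(list(points = c(0, 10), weights = c(1, 1)),
                   list(points = 5, weights = 2)), 5)
  ## unequal totals: ship min(2, 6) = 2 units at minimal cost 1 + 3
  expect_equal(emd(list(points = 0, weights = 2),
                   list(points = c(1, 3), weights = c(1, 5))), 2)
  expect_error(emd(list(points = 1, weights = -1), Q), ">= 0")
})

test_that("EMD equals the balanced 1-D Wasserstein closed form", {
  set.seed(17)
  for (i in 1:100) {
    P <- rand_signature(sample(2:12, 1))
    Q <- rand_signature(sample(2:12, 1))
    expect_equal(emd(P, Q), w1_signature_oracle(P, Q), tolerance = 1e-8)
  }
})

test_that("EMD is a metric on balanced signatures", {
  set.seed(19)
  for (i in 1:100) {
    P <- rand_signature(sample(2:8, 1))
    Q <- rand_signature(sample(2:8, 1))
    R <- rand_signature(sample(2:8, 1))
    dpq <- emd(P, Q); dqr <- emd(Q, R); dpr <- emd(P, R)
    expect_gte(dpq, 0)
    expect_equal(dpq, emd(Q, P), tolerance = 1e-10)
    expect_lte(dpr, dpq + dqr + 1e-8)
    expect_equal(emd(P, P), 0)
  }
})

test_that("PIC of a sampled cloud converges to the density as N grows", {
  cl <- clustered_field(Nx = 96, width = 0.03, n_bumps = 5, seed = 3)
  errs <- vapply(c(100, 1000, 10000), function(N) {
    dep <- pic_density(sample_points(cl, N, seed = 7), 1 / 32)
    sqrt(sum((swarmob:::interp_to_grid(dep, 96) - cl)^2) / 96^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("full comparison pipeline is self-consistent", {
  cl <- clustered_field(Nx = 96, width = 0.04, n_bumps = 4, seed = 23)
  own <- sample_points(cl, 2000, seed = 31)
  other <- uniform_cloud(2000, seed = 32)
  cmp_own <- compare_micro_macro(cl, own, seed = 33)
  cmp_other <- compare_micro_macro(cl, other, seed = 33)
  expect_lt(cmp_own$emd, cmp_other$emd)
  expect_equal(cmp_own$n_points, 2000)
  expect_true(cmp_own$h_tilde %in% (1 / (5:100)))
  expect_s3_class(cmp_own, "comparison_result")
})
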