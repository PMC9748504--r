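## independent oracles and small utilities shared across test files

## balanced 1-D Wasserstein-1 between weighted point sets via the CDF
## closed form (independent of the transportation-simplex implementation)
w1_signature_oracle <- function(P, Q) {
  W <- sum(P$weights)
  stopifnot(abs(W - sum(Q$weights)) < 1e-9 * W)
  xs <- sort(unique(c(P$points, Q$points)))
  FP <- vapply(xs, function(x) sum(P$weights[P$points <= x]), numeric(1)) / W
  FQ <- vapply(xs, function(x) sum(Q$weights[Q$points <= x]), numeric(1)) / W
  n <- length(xs)
  if (n == 1) return(0)
  sum(abs(FP[-n] - FQ[-n]) * diff(xs))
}

rand_signature <- function(nb, W = 100) {
  list(points = sort(runif(nb, 0, 10)),
       weights = as.numeric(rmultinom(1, W, rep(1, nb))))
}

## naive per-point cloud-in-cell deposition (reference for pic_density)
naive_pic <- function(pts, h, L = 1) {
  nh <- round(L / h)
  rho <- matrix(0, nh, nh)
  w <- function(i) (i %% nh) + 1
  for (p in seq_len(nrow(pts))) {
    ux <- pts[p, 1] / h - 0.5; uy <- pts[p, 2] / h - 0.5
    i0 <- floor(ux); j0 <- floor(uy); fx <- ux - i0; fy <- uy - j0
    rho[w(i0), w(j0)] <- rho[w(i0), w(j0)] + (1 - fx) * (1 - fy)
    rho[w(i0 + 1), w(j0)] <- rho[w(i0 + 1), w(j0)] + fx * (1 - fy)
    rho[w(i0), w(j0 + 1)] <- rho[w(i0), w(j0 + 1)] + (1 - fx) * fy
    rho[w(i0 + 1), w(j0 + 1)] <- rho[w(i0 + 1), w(j0 + 1)] + fx * fy
  }
  rho / (nrow(pts) * h^2)
}

## seed a single lattice mode and measure its log-slope over the second
## half of the run (the window is reported so the analytic linearized
## response can be evaluated on the same window)
measure_mode_rate <- function(params, nv, grid, t_end, dt = 2e-4,
                              scheme = "upwind2", eps = 1e-4) {
  Nx <- grid$Nx
  kvec <- 2 * pi * nv
  X <- matrix(grid$xc, Nx, Nx); Y <- t(X)
  st <- init_continuum(params, grid, seed = 1, amplitude = 0)
  st$rho <- 1 + eps * cos(kvec[1] * X + kvec[2] * Y)
  st$rho <- st$rho / mean(st$rho)
  midx <- function(n) (n %% Nx) + 1
  amp <- function(st) 2 * Mod(fft(st$rho)[midx(nv[1]), midx(nv[2])]) / Nx^2
  nst <- round(t_end / dt)
  half <- round(nst / 2)
  a0 <- t0 <- NA
  for (s in seq_len(nst)) {
    st <- step_continuum(st, params, grid, dt, scheme)
    if (s == half) { a0 <- amp(st); t0 <- st$t }
  }
  list(rate = log(amp(st) / a0) / (st$t - t0), t0 = t0, t1 = st$t)
}

## manual swarm_state constructor for hand-built configurations
manual_state <- function(Z, theta, X = matrix(0, 0, 2), Y = X) {
  structure(list(Z = Z, theta = theta, X = X, Y = Y, t = 0),
            class = "swarm_state")
}
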