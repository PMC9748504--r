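#' Periodic cell-centered grid
#'
#' Square grid with \code{Nx} cells per direction, nodes at cell centers
#' \eqn{x_i = (i - 1/2) h}, \eqn{h = L/N_x}, and periodic wrap.  The object
#' carries the spectral wavenumber arrays used by the solver (the Nyquist
#' mode is zeroed in the first-derivative arrays, as usual for odd
#' derivatives on an even grid).
#'
#' @param Nx number of cells per direction (at least 16).
#' @param L domain edge length.
#' @return An object of class \code{swarm_grid}.
#' @export
continuum_grid <- function(Nx, L = 1) {
  if (Nx < 16) stop("Nx must be at least 16")
  h <- L / Nx
  xc <- (seq_len(Nx) - 0.5) * h
  f <- 0:(Nx - 1)
  f[f > Nx / 2] <- f[f > Nx / 2] - Nx
  k <- 2 * pi * f / L
  k1 <- k
  if (Nx %% 2 == 0) k1[Nx / 2 + 1] <- 0      # zero Nyquist for odd derivatives
  KX <- matrix(k, Nx, Nx); KY <- t(KX)
  KX1 <- matrix(k1, Nx, Nx); KY1 <- t(KX1)
  structure(list(Nx = Nx, L = L, h = h, xc = xc,
                 KX = KX, KY = KY, KX1 = KX1, KY1 = KY1,
                 K2 = KX^2 + KY^2),
            class = "swarm_grid")
}

ifft2_re <- function(A) Re(fft(A, inverse = TRUE)) / length(A)

## phi sampled at minimum-image node offsets, normalized so that the
## discrete integral equals the analytic one, C_phi * tau / 4.
phi_kernel <- function(params, grid) {
  key <- sprintf("phik_%d_%.8g_%.8g_%.8g", grid$Nx, grid$L, params$tau,
                 params$Cphi)
  cached <- .swarmob_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (params$tau < 2 * grid$h)
    warning("agent-obstacle kernel under-resolved: tau < 2 h_x")
  o <- (seq_len(grid$Nx) - 1) * grid$h
  o <- pmin(o, grid$L - o)
  r <- sqrt(outer(o^2, o^2, "+"))
  K <- phi_eval(r, params)
  tot <- sum(K) * grid$h^2
  target <- params$Cphi * params$tau / 4
  if (tot > 0) K <- K * (target / tot)
  out <- list(K = K, Khat = Re(fft(K)) * grid$h^2)
  .swarmob_cache[[key]] <- out
  out
}

#' Periodic convolution with the agent--obstacle kernel
#'
#' Computes \eqn{\bar\rho = \rho * \phi} spectrally on the periodic grid.
#' The kernel is sampled at the grid nodes (minimum image) and rescaled so
#' its discrete integral equals the analytic \eqn{\int\phi = C_\phi\tau/4};
#' a constant field \code{c} therefore maps to the constant
#' \eqn{c\, C_\phi \tau/4}.
#'
#' @param field an Nx x Nx matrix.
#' @param params a [model_params()] object.
#' @param grid a [continuum_grid()].
#' @return The convolved field.
#' @export
convolve_phi <- function(field, params, grid) {
  kern <- phi_kernel(params, grid)
  ifft2_re(fft(field) * kern$Khat)
}

#' Obstacle density closure
#'
#' In the stiff-spring regime the obstacle density is a differential
#' functional of the convolved agent density:
#' \deqn{\rho_f/\rho_A = 1 + \frac{1}{\kappa}\Delta\bar\rho_g +
#'  \frac{1}{\kappa^2}\det H(\bar\rho_g) -
#'  \frac{\eta}{\kappa^2}\partial_t\Delta\bar\rho_g,}
#' with the \eqn{O((\eta/\kappa)^3)} remainder dropped.  Derivatives are
#' spectral; the time-derivative term is a backward difference against the
#' previous step's \eqn{\Delta\bar\rho_g} (zero on the first step) and can
#' be switched off with \code{dt_term = FALSE}.
#'
#' @param rho agent density field (Nx x Nx).
#' @param params a [model_params()] object.
#' @param grid a [continuum_grid()].
#' @param dt time step used for the backward difference (may be
#'   \code{NULL} when \code{prev_lap} is \code{NULL}).
#' @param prev_lap previous-step \eqn{\Delta\bar\rho_g} or \code{NULL}.
#' @param dt_term logical; include the \eqn{-(\eta/\kappa^2)
#'   \partial_t\Delta\bar\rho_g} term.
#' @return A list with \code{rho_f} and \code{lap_rho_bar} (to be passed as
#'   \code{prev_lap} on the next step).
#' @export
obstacle_density <- function(rho, params, grid, dt = NULL, prev_lap = NULL,
                             dt_term = TRUE) {
  rho_bar <- convolve_phi(rho, params, grid)
  fb <- fft(rho_bar)
  lap <- ifft2_re(-grid$K2 * fb)
  Hxx <- ifft2_re(-grid$KX^2 * fb)
  Hyy <- ifft2_re(-grid$KY^2 * fb)
  Hxy <- ifft2_re(-grid$KX1 * grid$KY1 * fb)
  detH <- Hxx * Hyy - Hxy^2
  kap <- params$kappa
  rf <- 1 + lap / kap + detH / kap^2
  if (dt_term && !is.null(prev_lap)) {
    if (is.null(dt)) stop("dt required for the time-derivative closure term")
    rf <- rf - (params$eta / kap^2) * (lap - prev_lap) / dt
  }
  list(rho_f = params$rhoA * rf, lap_rho_bar = lap)
}

#' Initial continuum state
#'
#' The agent density is a small perturbation of the uniform state,
#' \eqn{\rho_g = 1 + a\,\xi}, where \eqn{\xi} is a band-limited mean-zero
#' random field (Fourier modes with \eqn{|n_1|, |n_2| \le} \code{n_modes},
#' unit variance) whose coefficients are drawn from the seed in a fixed
#' order, so the same seed yields the same continuum field at any grid
#' resolution.  The density is renormalized to unit mass and the
#' orientation field is the constant unit vector at angle \code{theta0}.
#'
#' @param params a [model_params()] object.
#' @param grid a [continuum_grid()].
#' @param seed RNG seed.
#' @param amplitude perturbation amplitude (0 gives the exact uniform
#'   state).
#' @param n_modes band limit of the perturbation.
#' @param theta0 initial orientation angle.
#' @return An object of class \code{continuum_state}: a list with fields
#'   \code{rho}, \code{Ox}, \code{Oy}, \code{rho_f}, \code{prev_lap},
#'   \code{t}.
#' @export
init_continuum <- function(params, grid, seed, amplitude = 1e-2,
                           n_modes = 8, theta0 = pi / 4) {
  set.seed(seed)
  Nx <- grid$Nx
  xi <- matrix(0, Nx, Nx)
  if (amplitude > 0) {
    X <- matrix(grid$xc, Nx, Nx) / grid$L
    Y <- t(X)
    for (n1 in 0:n_modes) for (n2 in (-n_modes):n_modes) {
      if (n1 == 0 && n2 <= 0) next      # one representative per +/- k pair
      a <- rnorm(1); ph <- runif(1, 0, 2 * pi)
      xi <- xi + a * cos(2 * pi * (n1 * X + n2 * Y) + ph)
    }
    xi <- xi / sd(as.vector(xi))
  }
  rho <- 1 + amplitude * xi
  rho <- rho / (mean(rho) * grid$L^2)     # unit mass
  st <- list(rho = rho,
             Ox = matrix(cos(theta0), Nx, Nx),
             Oy = matrix(sin(theta0), Nx, Nx),
             rho_f = matrix(params$rhoA, Nx, Nx),
             prev_lap = NULL, t = 0)
  class(st) <- "continuum_state"
  st
}

shift_xp <- function(A) A[c(2:nrow(A), 1), , drop = FALSE]
shift_xm <- function(A) A[c(nrow(A), 1:(nrow(A) - 1)), , drop = FALSE]
shift_yp <- function(A) A[, c(2:ncol(A), 1), drop = FALSE]
shift_ym <- function(A) A[, c(ncol(A), 1:(ncol(A) - 1)), drop = FALSE]

lap5 <- function(A, h) {
  (shift_xp(A) + shift_xm(A) + shift_yp(A) + shift_ym(A) - 4 * A) / h^2
}

## advective face flux in one direction; `p`/`m` are +/- shifts along it
face_flux <- function(rho, u_cell, shift_p, shift_m, scheme) {
  uf <- 0.5 * (u_cell + shift_p(u_cell))       # velocity at face i+1/2
  if (scheme == "upwind1") {
    rl <- rho
    rr <- shift_p(rho)
  } else {                                      # second-order one-sided
    rl <- rho + 0.5 * (rho - shift_m(rho))
    rr_c <- shift_p(rho)
    rl_c2 <- shift_p(shift_p(rho))
    rr <- rr_c - 0.5 * (rl_c2 - rr_c)
  }
  uf * ifelse(uf > 0, rl, rr)
}

#' One explicit step of the continuum system
#'
#' Advances the coupled system
#' \deqn{\partial_t\rho_g + \nabla\cdot(U\rho_g) = 0, \qquad
#'  U = d_1\Omega - \frac{1}{\zeta}\nabla\bar\rho_f -
#'      \frac{\mu}{\zeta}\nabla\rho_g,}
#' \deqn{\rho_g\partial_t\Omega + \rho_g (V\cdot\nabla)\Omega
#'  + d_3 P_{\Omega^\perp}\nabla\rho_g
#'  = \gamma_s P_{\Omega^\perp}\Delta(\rho_g\Omega),}
#' by one explicit Euler step: the density in conservative finite-volume
#' flux form (advective part upwinded, the \eqn{\mu\rho\nabla\rho/\zeta}
#' part as a central diffusive flux), the obstacle-closure gradient
#' spectrally, and the orientation by projecting the full right-hand side
#' onto \eqn{\Omega^\perp} node-wise followed by renormalization to unit
#' length.  Nodes with \eqn{\rho_g < 10^{-8}} freeze their orientation
#' (vacuum).  Mass is conserved to round-off.
#'
#' @param state a [init_continuum()] state.
#' @param params a [model_params()] object.
#' @param grid a [continuum_grid()].
#' @param dt time step; the CFL conditions
#'   \eqn{dt\,\max|U|/h < 0.5} and
#'   \eqn{dt\,\max(\mu\rho_g/\zeta, \gamma_s)/h^2 < 0.25} are checked and a
#'   violation raises an error with a suggested step.
#' @param scheme advective reconstruction: \code{"upwind2"} (second-order
#'   one-sided, low dissipation, the default -- first-order upwinding at
#'   production resolutions adds numerical diffusion comparable to the
#'   growth rates of the weakly unstable band regime and suppresses those
#'   patterns) or \code{"upwind1"} (first-order, maximally robust).
#' @param dt_term include the time-derivative closure term (see
#'   [obstacle_density()]).
#' @return The advanced state.
#' @export
step_continuum <- function(state, params, grid, dt,
                           scheme = c("upwind2", "upwind1"),
                           dt_term = TRUE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be strictly positive")
  h <- grid$h
  rho <- state$rho
  Ox <- state$Ox; Oy <- state$Oy
  ac <- alignment_constants(params$ds / params$nu, params$u0, params$rA)
  mubar <- params$mu / params$zeta

  od <- obstacle_density(rho, params, grid, dt, state$prev_lap, dt_term)
  rho_f <- od$rho_f
  fr <- fft(rho_f)
  kern <- phi_kernel(params, grid)
  gbx <- ifft2_re(1i * grid$KX1 * fr * kern$Khat) / params$zeta
  gby <- ifft2_re(1i * grid$KY1 * fr * kern$Khat) / params$zeta

  Ux <- ac$d1 * Ox - gbx
  Uy <- ac$d1 * Oy - gby

  maxU <- max(abs(Ux), abs(Uy))
  cfl_a <- dt * maxU / h
  cfl_d <- dt * max(mubar * max(rho), ac$gamma_s) / h^2
  if (cfl_a >= 0.5 || cfl_d >= 0.25) {
    dt_sug <- 0.9 * min(0.5 * h / max(maxU, 1e-300),
                        0.25 * h^2 / max(mubar * max(rho), ac$gamma_s,
                                         1e-300))
    stop("CFL violation (advective ", format(cfl_a), ", diffusive ",
         format(cfl_d), "); suggested dt = ", format(dt_sug))
  }

  ## density: conservative fluxes
  Fx <- face_flux(rho, Ux, shift_xp, shift_xm, scheme) -
    mubar * 0.5 * (rho + shift_xp(rho)) * (shift_xp(rho) - rho) / h
  Fy <- face_flux(rho, Uy, shift_yp, shift_ym, scheme) -
    mubar * 0.5 * (rho + shift_yp(rho)) * (shift_yp(rho) - rho) / h
  rho_new <- rho - dt / h * (Fx - shift_xm(Fx)) - dt / h * (Fy - shift_ym(Fy))

  ## orientation
  drx <- (shift_xp(rho) - shift_xm(rho)) / (2 * h)
  dry <- (shift_yp(rho) - shift_ym(rho)) / (2 * h)
  Vx <- ac$d2 * Ox - gbx - mubar * drx
  Vy <- ac$d2 * Oy - gby - mubar * dry
  if (scheme == "upwind1") {
    upx <- function(A) ifelse(Vx > 0, (A - shift_xm(A)) / h,
                              (shift_xp(A) - A) / h)
    upy <- function(A) ifelse(Vy > 0, (A - shift_ym(A)) / h,
                              (shift_yp(A) - A) / h)
  } else {
    upx <- function(A) ifelse(Vx > 0,
      (3 * A - 4 * shift_xm(A) + shift_xm(shift_xm(A))) / (2 * h),
      (-3 * A + 4 * shift_xp(A) - shift_xp(shift_xp(A))) / (2 * h))
    upy <- function(A) ifelse(Vy > 0,
      (3 * A - 4 * shift_ym(A) + shift_ym(shift_ym(A))) / (2 * h),
      (-3 * A + 4 * shift_yp(A) - shift_yp(shift_yp(A))) / (2 * h))
  }
  rho_safe <- pmax(rho, 1e-8)
  rx <- -(Vx * upx(Ox) + Vy * upy(Ox)) +
    (ac$gamma_s * lap5(rho * Ox, h) - ac$d3 * drx) / rho_safe
  ry <- -(Vx * upx(Oy) + Vy * upy(Oy)) +
    (ac$gamma_s * lap5(rho * Oy, h) - ac$d3 * dry) / rho_safe
  s <- rx * (-Oy) + ry * Ox                 # component along Omega-perp
  Ox_new <- Ox + dt * s * (-Oy)
  Oy_new <- Oy + dt * s * Ox
  nrm <- sqrt(Ox_new^2 + Oy_new^2)
  Ox_new <- Ox_new / nrm
  Oy_new <- Oy_new / nrm
  frozen <- rho < 1e-8
  if (any(frozen)) {
    Ox_new[frozen] <- Ox[frozen]
    Oy_new[frozen] <- Oy[frozen]
  }

  state$rho <- rho_new
  state$Ox <- Ox_new; state$Oy <- Oy_new
  state$rho_f <- rho_f
  state$prev_lap <- od$lap_rho_bar
  state$t <- state$t + dt
  state
}

#' Blow-up and negativity monitor
#'
#' The closure density \eqn{\rho_f} may turn negative and the agent density
#' may concentrate without bound; both are intrinsic to the macroscopic
#' dynamics, and the simulation is stopped (keeping the last valid state)
#' when either occurs.
#'
#' @param state a [init_continuum()] state.
#' @param params a [model_params()] object.
#' @param blowup_threshold stop when \eqn{\max\rho_g} exceeds this multiple
#'   of its mean.
#' @return One of \code{"CONTINUE"}, \code{"STOP_NEGATIVE_RHO_F"},
#'   \code{"STOP_BLOWUP"}.
#' @export
blowup_check <- function(state, params, blowup_threshold = 50) {
  if (min(state$rho_f) < 0) return("STOP_NEGATIVE_RHO_F")
  if (max(state$rho) > blowup_threshold * mean(state$rho) ||
      min(state$rho) < 0)
    return("STOP_BLOWUP")
  "CONTINUE"
}

cfl_suggest <- function(params, grid, umax_est = NULL) {
  ac <- alignment_constants(params$ds / params$nu, params$u0, params$rA)
  if (is.null(umax_est)) umax_est <- ac$d1 + 0.5
  mubar <- params$mu / params$zeta
  0.8 * min(0.5 * grid$h / max(umax_est, 1e-12),
            0.25 * grid$h^2 / max(2 * mubar, ac$gamma_s, 1e-12))
}

#' Run the continuum simulation
#'
#' Integrates the system to the final time or until [blowup_check()] stops
#' it, whichever comes first.  The step is chosen from the CFL estimates
#' and halved on the fly whenever a step reports a CFL violation (velocities
#' steepen as the solution concentrates).
#'
#' @param params a [model_params()] object.
#' @param grid a [continuum_grid()].
#' @param T final time.
#' @param dt time step; \code{NULL} picks one from the CFL estimate.
#' @param seed RNG seed for the initial perturbation.
#' @param amplitude,n_modes,theta0 passed to [init_continuum()].
#' @param state optional pre-built initial state (overrides the seeded
#'   initialization).
#' @param save_every save a snapshot every this many steps.
#' @param scheme,dt_term passed to [step_continuum()].
#' @param blowup_threshold passed to [blowup_check()].
#' @return A list of class \code{continuum_run} with \code{final} (the last
#'   valid state), \code{snapshots}, \code{times}, \code{status}
#'   (termination status), \code{params}, \code{grid}, \code{seed},
#'   \code{dt}.
#' @export
run_continuum <- function(params, grid, T = 10, dt = NULL, seed = 1,
                          amplitude = 1e-2, n_modes = 8, theta0 = pi / 4,
                          state = NULL, save_every = Inf,
                          scheme = "upwind2", dt_term = TRUE,
                          blowup_threshold = 50) {
  if (is.null(state))
    state <- init_continuum(params, grid, seed, amplitude, n_modes, theta0)
  if (is.null(dt)) dt <- cfl_suggest(params, grid)
  snapshots <- list(state)
  times <- state$t
  status <- "CONTINUE"
  step_count <- 0L
  while (state$t < T - 1e-12) {
    dt_use <- min(dt, T - state$t)
    new_state <- NULL
    for (halving in 0:12) {
      new_state <- tryCatch(
        step_continuum(state, params, grid, dt_use, scheme, dt_term),
        error = function(e) {
          if (grepl("CFL violation", conditionMessage(e))) NULL else stop(e)
        })
      if (!is.null(new_state)) break
      dt_use <- dt_use / 2
      dt <- dt / 2
    }
    if (is.null(new_state)) { status <- "STOP_BLOWUP"; break }
    status <- blowup_check(new_state, params, blowup_threshold)
    if (status != "CONTINUE") break       # keep the last valid state
    state <- new_state
    step_count <- step_count + 1L
    if (is.finite(save_every) && step_count %% save_every == 0) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
    }
  }
  snapshots[[length(snapshots) + 1L]] <- state
  times <- c(times, state$t)
  structure(list(final = state, snapshots = snapshots, times = times,
                 status = status, params = params, grid = grid,
                 seed = seed, dt = dt),
            class = "continuum_run")
}
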