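#' Initial state of the discrete system
#'
#' Agents and anchors are drawn i.i.d. uniformly on the periodic square
#' \eqn{[0, L)^2}; all agent orientations start at a common angle
#' (\eqn{\pi/4} by default).  By default obstacles start at their anchors,
#' which realizes a uniform initial obstacle distribution with a relaxed
#' spring in a single draw; \code{obstacles_at_anchors = FALSE} draws the
#' obstacle positions independently instead.
#'
#' @param params a [model_params()] object (supplies \code{M}, \code{N},
#'   \code{L}).
#' @param seed RNG seed; identical seeds give bit-identical states.
#' @param theta0 common initial orientation angle.
#' @param obstacles_at_anchors logical, see Details.
#' @return An object of class \code{swarm_state}: a list with agent
#'   positions \code{Z} (M x 2), angles \code{theta}, obstacle positions
#'   \code{X} (N x 2), anchors \code{Y} (never modified by stepping) and
#'   time \code{t}.
#' @export
init_state <- function(params, seed, theta0 = pi / 4,
                       obstacles_at_anchors = TRUE) {
  set.seed(seed)
  L <- params$L
  Z <- matrix(runif(2 * params$M, 0, L), ncol = 2)
  Y <- matrix(runif(2 * params$N, 0, L), ncol = 2)
  X <- if (obstacles_at_anchors) Y
       else matrix(runif(2 * params$N, 0, L), ncol = 2)
  st <- list(Z = Z, theta = rep(theta0, params$M), X = X, Y = Y, t = 0)
  class(st) <- "swarm_state"
  st
}

#' Interaction sums of the discrete system
#'
#' Thin wrapper over the compiled pairwise kernel.  Returns the mean-flux
#' vectors \code{J} (self-inclusive neighbour sum of orientations within
#' \code{rA}), the agent--agent repulsion gradient sums, and the
#' agent--obstacle gradient sums seen by agents and by obstacles.  With
#' \code{use_cells = FALSE} the all-pairs reference path is used; cell-list
#' and all-pairs sums are identical (same arithmetic, different pair
#' enumeration).
#'
#' @param state a [init_state()] state.
#' @param params a [model_params()] object.
#' @param use_cells logical; use the uniform cell grid (edge
#'   \code{max(rA, rR, tau)}) when the domain is wide enough.
#' @return A list with matrices \code{J}, \code{grad_psi},
#'   \code{grad_phi_agents}, \code{grad_phi_obstacles}.
#' @export
discrete_forces <- function(state, params, use_cells = TRUE) {
  interaction_sums_cpp(state$Z, state$theta, state$X, params$L, params$rA,
                       params$rR, params$tau, params$mu, params$Cphi,
                       use_cells)
}

#' Mean alignment direction of each agent
#'
#' The mean flux \eqn{J_k = \sum_{j : |Z_k - Z_j| \le r_A} \alpha_j}
#' (minimum-image distance, \eqn{j = k} included) is normalized to the unit
#' vector \eqn{\bar\alpha_k = J_k / |J_k|}.  In the measure-zero event of
#' exact cancellation (\eqn{|J_k| < 10^{-12}}) the agent's own orientation
#' is kept.
#'
#' @inheritParams discrete_forces
#' @return An M x 2 matrix of unit vectors.
#' @export
mean_direction <- function(state, params, use_cells = TRUE) {
  J <- discrete_forces(state, params, use_cells)$J
  nrm <- sqrt(rowSums(J^2))
  deg <- nrm < 1e-12
  out <- J / ifelse(deg, 1, nrm)
  if (any(deg))
    out[deg, ] <- cbind(cos(state$theta[deg]), sin(state$theta[deg]))
  out
}

#' One Euler--Maruyama step of the discrete system
#'
#' Obstacles follow \eqn{dX_i = -(\kappa/\eta)(X_i - Y_i)\,dt -
#' (1/(\eta M))\sum_k \nabla\phi(X_i - Z_k)\,dt + \sqrt{2 d_0}\, dB_i};
#' agents follow \eqn{dZ_k = u_0\alpha_k\,dt - (1/(\zeta N))\sum_i
#' \nabla\phi(Z_k - X_i)\,dt - (1/(\zeta M))\sum_{l\ne k}
#' \nabla\psi(Z_k - Z_l)\,dt}.  Orientations are advanced in angle
#' coordinates, \eqn{d\theta_k = \nu \sin(\bar\theta_k - \theta_k)\,dt +
#' \sqrt{2 d_s}\, dW_k}: this is the angular component of the projected
#' alignment force, and Stratonovich projected noise on the circle is
#' additive in the angle, so the unit-length constraint is exact with no
#' renormalization drift.  Positions are wrapped periodically.
#'
#' @param state a [init_state()] state.
#' @param params a [model_params()] object.
#' @param dt time step (> 0).
#' @param use_cells logical, neighbour search strategy.
#' @return The updated state, with attribute \code{max_disp} (largest
#'   position displacement of the step, used for stability monitoring).
#' @export
step_discrete <- function(state, params, dt, use_cells = TRUE) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be strictly positive")
  M <- nrow(state$Z); N <- nrow(state$X); L <- params$L
  f <- discrete_forces(state, params, use_cells)

  vZ <- params$u0 * cbind(cos(state$theta), sin(state$theta))
  if (N > 0) vZ <- vZ - f$grad_phi_agents / (params$zeta * N)
  if (M > 1) vZ <- vZ - f$grad_psi / (params$zeta * M)

  dX <- NULL
  if (N > 0) {
    dxy <- state$X - state$Y
    dxy <- dxy - L * round(dxy / L)        # minimum-image spring extension
    vX <- -(params$kappa / params$eta) * dxy
    if (M > 0) vX <- vX - f$grad_phi_obstacles / (params$eta * M)
    dX <- vX * dt
    if (params$d0 > 0)
      dX <- dX + sqrt(2 * params$d0 * dt) * matrix(rnorm(2 * N), ncol = 2)
  }

  dZ <- vZ * dt
  if (!all(is.finite(dZ)) || (N > 0 && !all(is.finite(dX))))
    stop("non-finite state update: simulation diverged ",
         "(largest finite displacement ",
         format(max(abs(dZ[is.finite(dZ)]), 0)), ")")

  nrmJ <- sqrt(rowSums(f$J^2))
  thbar <- ifelse(nrmJ < 1e-12, state$theta, atan2(f$J[, 2], f$J[, 1]))
  dtheta <- params$nu * sin(thbar - state$theta) * dt
  if (params$ds > 0) dtheta <- dtheta + sqrt(2 * params$ds * dt) * rnorm(M)

  state$Z <- (state$Z + dZ) %% L
  if (N > 0) state$X <- (state$X + dX) %% L
  state$theta <- (state$theta + dtheta) %% (2 * pi)
  state$t <- state$t + dt
  attr(state, "max_disp") <- max(abs(dZ), if (N > 0) abs(dX) else 0)
  state
}

#' Run the discrete simulation
#'
#' Iterates [step_discrete()] to the final time, emitting snapshots.  The
#' per-step maximum displacement is monitored; the run aborts if it exceeds
#' the neighbour-cell edge \code{max(rA, rR, tau)} (time step too large for
#' the neighbour search to be exhaustive).
#'
#' @param params a [model_params()] object.
#' @param T final time.
#' @param dt time step.
#' @param seed RNG seed (mandatory; recorded in the result).
#' @param save_every save a snapshot every this many steps (\code{Inf}
#'   keeps only the final state; the initial state is always kept).
#' @param use_cells logical, neighbour search strategy.
#' @param theta0,obstacles_at_anchors passed to [init_state()].
#' @param callback optional \code{function(state, step)} invoked after each
#'   saved snapshot.
#' @return A list of class \code{swarm_run} with elements \code{final},
#'   \code{snapshots}, \code{times}, \code{params}, \code{seed}, \code{dt}.
#' @export
run_discrete <- function(params, T = 10, dt = 1e-3, seed = 1,
                         save_every = Inf, use_cells = TRUE,
                         theta0 = pi / 4, obstacles_at_anchors = TRUE,
                         callback = NULL) {
  state <- init_state(params, seed, theta0, obstacles_at_anchors)
  n_steps <- ceiling(T / dt)
  cell_edge <- max(params$rA, params$rR, params$tau)
  snapshots <- list(state)
  times <- 0
  for (s in seq_len(n_steps)) {
    state <- step_discrete(state, params, dt, use_cells)
    if (attr(state, "max_disp") > cell_edge)
      stop("per-step displacement ", format(attr(state, "max_disp")),
           " exceeds the neighbour cell edge ", format(cell_edge),
           ": reduce dt")
    if (is.finite(save_every) && s %% save_every == 0) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
      if (!is.null(callback)) callback(state, s)
    }
  }
  snapshots[[length(snapshots) + 1L]] <- state
  times <- c(times, state$t)
  structure(list(final = state, snapshots = snapshots, times = times,
                 params = params, seed = seed, dt = dt),
            class = "swarm_run")
}

#' Write a discrete snapshot as CSV
#'
#' Two files are written: agents (\code{t, id, x, y, theta}) and obstacles
#' (\code{t, id, x, y, anchor_x, anchor_y}).
#'
#' @param state a [init_state()] state.
#' @param agents_file,obstacles_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_discrete_snapshot <- function(state, agents_file, obstacles_file) {
  ag <- data.frame(t = state$t, id = seq_len(nrow(state$Z)),
                   x = state$Z[, 1], y = state$Z[, 2], theta = state$theta)
  write.csv(ag, agents_file, row.names = FALSE)
  ob <- data.frame(t = state$t, id = seq_len(nrow(state$X)),
                   x = state$X[, 1], y = state$X[, 2],
                   anchor_x = state$Y[, 1], anchor_y = state$Y[, 2])
  write.csv(ob, obstacles_file, row.names = FALSE)
  invisible(c(agents_file, obstacles_file))
}
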