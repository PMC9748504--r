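#' Von Mises equilibrium distribution of agent orientations
#'
#' In the fast-alignment regime the orientation distribution relaxes to
#' \eqn{m(\theta) = \exp(\cos\theta / \rho) / Z} where \eqn{\rho = d_s/\nu}
#' and \eqn{Z = \int_0^{2\pi} \exp(\cos\theta/\rho)\, d\theta}.  The
#' normalizer is evaluated by quadrature of the overflow-safe integrand
#' \eqn{\exp((\cos\theta - 1)/\rho)}.
#'
#' @param theta angle(s) in radians.
#' @param ratio the noise-to-alignment ratio \eqn{d_s/\nu}; must lie in
#'   \code{[1e-4, Inf)} -- below that the density is too concentrated for
#'   direct quadrature and asymptotic constants should be used instead.
#' @return Density values, vectorized over \code{theta}.
#' @export
von_mises_m <- function(theta, ratio) {
  check_ratio(ratio)
  exp((cos(theta) - 1) / ratio) / vm_normalizer(ratio)
}

check_ratio <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio d_s/nu must be a strictly positive number")
  if (ratio < 1e-4)
    stop("ratio d_s/nu below 1e-4: quadrature would overflow; ",
         "use the asymptotic limits c1 -> 1, c2 -> 1 instead")
  invisible(ratio)
}

## scaled normalizer: Z * exp(-1/ratio)
vm_normalizer <- function(ratio) {
  integrate(function(t) exp((cos(t) - 1) / ratio), 0, 2 * pi,
            rel.tol = 1e-12)$value
}

#' Alignment constants of the continuum model
#'
#' \code{compute_c1} evaluates \eqn{c_1 = \int_0^{2\pi} \cos\theta\,
#' m(\theta)\, d\theta}, the mean resultant of the von Mises equilibrium.
#' \code{compute_c2} evaluates the weighted-mean constant
#' \deqn{c_2 = \frac{\int_0^{\pi} \sin^2\theta \cos\theta\, m\, h\,
#'  d\theta}{\int_0^{\pi} \sin^2\theta\, m\, h\, d\theta},}
#' where \eqn{h = g/\sin\theta} and \eqn{g} solves the auxiliary boundary
#' value problem of [solve_h()].  \code{c3} equals the ratio \eqn{d_s/\nu}
#' itself.
#'
#' @param ratio the ratio \eqn{d_s/\nu}.
#' @param n_grid grid size passed to [solve_h()].
#' @return A number.
#' @export
compute_c1 <- function(ratio) {
  check_ratio(ratio)
  num <- integrate(function(t) cos(t) * exp((cos(t) - 1) / ratio), 0, 2 * pi,
                   rel.tol = 1e-12)$value
  num / vm_normalizer(ratio)
}

#' Auxiliary orientation profile h
#'
#' Solves the linear two-point boundary-value problem
#' \deqn{\frac{\nu}{d_s}\sin\theta\, g'(\theta) + g''(\theta) = \sin\theta,
#'  \qquad g(0) = g(\pi) = 0,}
#' by second-order central finite differences on a uniform grid and a
#' tridiagonal (Thomas) solve, and returns \eqn{h = g/\sin\theta} with the
#' endpoint values obtained by one-sided limits
#' (\eqn{h(0) = g'(0)}, \eqn{h(\pi) = -g'(\pi)}).  The homogeneous Dirichlet
#' conditions are forced by the requirement that \eqn{h} stay bounded where
#' \eqn{\sin\theta} vanishes.
#'
#' @param ratio the ratio \eqn{d_s/\nu}.
#' @param n_grid number of grid intervals (at least 200).
#' @return A list with \code{theta}, \code{g} and \code{h} (vectors of
#'   length \code{n_grid + 1}).
#' @export
solve_h <- function(ratio, n_grid = 2000) {
  check_ratio(ratio)
  if (n_grid < 200) stop("n_grid must be at least 200")
  k <- 1 / ratio
  th <- seq(0, pi, length.out = n_grid + 1)
  dh <- th[2] - th[1]
  ti <- th[2:n_grid]
  lower <- 1 / dh^2 - k * sin(ti) / (2 * dh)
  diagc <- rep(-2 / dh^2, n_grid - 1)
  upper <- 1 / dh^2 + k * sin(ti) / (2 * dh)
  g <- thomas_solve(lower, diagc, upper, sin(ti))
  gfull <- c(0, g, 0)
  h <- gfull / sin(th)
  h[1] <- (gfull[2] - gfull[1]) / dh
  h[n_grid + 1] <- -(gfull[n_grid + 1] - gfull[n_grid]) / dh
  list(theta = th, g = gfull, h = h)
}

thomas_solve <- function(lower, diagc, upper, rhs) {
  n <- length(diagc)
  cp <- numeric(n); dp <- numeric(n)
  denom <- diagc[1]
  if (denom == 0) stop("singular tridiagonal system (grid too coarse)")
  cp[1] <- upper[1] / denom; dp[1] <- rhs[1] / denom
  for (i in seq_len(n - 1) + 1L) {
    denom <- diagc[i] - lower[i] * cp[i - 1]
    if (denom == 0) stop("singular tridiagonal system (grid too coarse)")
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n); x[n] <- dp[n]
  for (i in rev(seq_len(n - 1))) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' @rdname compute_c1
#' @export
compute_c2 <- function(ratio, n_grid = 2000) {
  sol <- solve_h(ratio, n_grid)
  th <- sol$theta
  ## integrands written with g = h sin(theta) so no endpoint division occurs
  mscaled <- exp((cos(th) - 1) / ratio)   # common normalizer cancels
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * (th[2] - th[1])
  num <- trap(sin(th) * cos(th) * mscaled * sol$g)
  den <- trap(sin(th) * mscaled * sol$g)
  num / den
}

#' Orientational viscosity and drift coefficients
#'
#' \code{compute_gamma_s} evaluates the orientational viscosity
#' \eqn{\gamma_s = (r_A^2/8)(d_s/\nu + c_2)}; \code{compute_di} the drift
#' speeds \eqn{d_i = u_0 c_i}.
#'
#' @param rA alignment radius.
#' @param ratio the ratio \eqn{d_s/\nu}.
#' @param u0 agent speed.
#' @return \code{compute_gamma_s}: a number; \code{compute_di}: a named
#'   vector \code{c(d1, d2, d3)}.
#' @export
#' @examples
#' compute_gamma_s(0.15, 0.01)  # ~ 28e-4
compute_gamma_s <- function(rA, ratio) {
  (rA^2 / 8) * (ratio + compute_c2(ratio))
}

#' @rdname compute_gamma_s
#' @export
compute_di <- function(ratio, u0 = 1) {
  ci <- c(compute_c1(ratio), compute_c2(ratio), ratio)
  stats::setNames(u0 * ci, c("d1", "d2", "d3"))
}

#' Full set of Vicsek-derived continuum constants
#'
#' Computes and caches (per ratio) the constants \eqn{c_1, c_2, c_3}, the
#' drifts \eqn{d_i = u_0 c_i}, the orientational viscosity \eqn{\gamma_s}
#' and the von Mises normalizer \eqn{Z}.
#'
#' @param ratio the ratio \eqn{d_s/\nu}.
#' @param u0 agent speed.
#' @param rA alignment radius.
#' @return An object of class \code{alignment_constants}.
#' @export
alignment_constants <- function(ratio, u0 = 1, rA = 0.15) {
  check_ratio(ratio)
  key <- sprintf("ac_%.12e", ratio)
  base <- .swarmob_cache[[key]]
  if (is.null(base)) {
    c1 <- compute_c1(ratio)
    c2 <- compute_c2(ratio)
    base <- list(c1 = c1, c2 = c2, c3 = ratio,
                 Z = vm_normalizer(ratio) * exp(1 / ratio))
    .swarmob_cache[[key]] <- base
  }
  out <- c(base["c1"], base["c2"], base["c3"],
           list(ratio = ratio,
                d1 = u0 * base$c1, d2 = u0 * base$c2, d3 = u0 * base$c3,
                gamma_s = (rA^2 / 8) * (ratio + base$c2), Z = base$Z))
  class(out) <- "alignment_constants"
  out
}

#' @export
print.alignment_constants <- function(x, ...) {
  cat(sprintf(paste0("<alignment_constants> ds/nu = %g\n",
                     "  c1 = %.6f  c2 = %.6f  c3 = %.6f\n",
                     "  d1 = %.6f  d2 = %.6f  d3 = %.6f  gamma_s = %.6g\n"),
              x$ratio, x$c1, x$c2, x$c3, x$d1, x$d2, x$d3, x$gamma_s))
  invisible(x)
}
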