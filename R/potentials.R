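#' Repulsion kernels
#'
#' The agent--agent kernel \eqn{\psi} and the agent--obstacle kernel
#' \eqn{\phi} are compactly supported quadratic bumps,
#' \deqn{\psi(r) = \frac{6\mu}{\pi r_R^2}\Big(1 - \frac{r}{r_R}\Big)_+^2,
#'  \qquad
#'  \phi(r) = \frac{3 C_\phi}{2\pi\tau}\Big(1 - \frac{r}{\tau}\Big)_+^2,}
#' normalized so that \eqn{\int \psi \, dx = \mu} and
#' \eqn{\int |\nabla\phi| \, dx = C_\phi} (whence
#' \eqn{\int \phi \, dx = C_\phi \tau / 4}).
#'
#' @param r distance(s), must be non-negative.
#' @param params a [model_params()] object.
#' @return Kernel values, vectorized over \code{r}.
#' @export
#' @examples
#' p <- model_params(mu = 0.1, rR = 0.075)
#' psi_eval(p$rR / 2, p)
psi_eval <- function(r, params) {
  if (any(r < 0)) stop("distance r must be non-negative")
  s <- 1 - r / params$rR
  s[s < 0] <- 0
  6 * params$mu / (pi * params$rR^2) * s^2
}

#' @rdname psi_eval
#' @export
phi_eval <- function(r, params) {
  if (any(r < 0)) stop("distance r must be non-negative")
  s <- 1 - r / params$tau
  s[s < 0] <- 0
  3 * params$Cphi / (2 * pi * params$tau) * s^2
}

#' Gradients of the repulsion kernels
#'
#' Gradients of [psi_eval()] and [phi_eval()] as functions of a planar
#' offset.  Both kernels have a cusp in gradient magnitude at the origin;
#' the gradient at \code{x = 0} is defined as the zero vector (two coincident
#' points exert no net directed force).
#'
#' @param x a 2-vector, or an n-by-2 matrix of offsets.
#' @param params a [model_params()] object.
#' @return A gradient of the same shape as \code{x}.
#' @export
psi_grad <- function(x, params) {
  kernel_grad(x, params$rR, -12 * params$mu / (pi * params$rR^3))
}

#' @rdname psi_grad
#' @export
phi_grad <- function(x, params) {
  kernel_grad(x, params$tau, -3 * params$Cphi / (pi * params$tau^2))
}

kernel_grad <- function(x, radius, coef) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 2)
  r <- sqrt(rowSums(x^2))
  mag <- ifelse(r > 0 & r < radius, coef * (1 - r / radius) / r, 0)
  g <- x * mag
  if (vec) drop(g) else g
}

gauss_rule <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.swarmob_cache[[key]]))
    .swarmob_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .swarmob_cache[[key]]
}

#' Radial Fourier transform of the agent--obstacle kernel
#'
#' Computes \eqn{\hat\phi(z) = 2\pi \int_0^\tau J_0(z r)\, \phi(r)\, r\, dr},
#' the rotationally symmetric Fourier transform (convention
#' \eqn{\hat\phi(k) = \int e^{-ik\cdot x} \phi(x)\, dx}) evaluated by
#' Gauss--Legendre quadrature on the compact support.  Real-valued, with
#' \eqn{\hat\phi(0) = C_\phi \tau / 4}.
#'
#' @param z radial wavenumber(s), non-negative; vectorized.
#' @param params a [model_params()] object.
#' @param n_nodes number of quadrature nodes.
#' @return \eqn{\hat\phi(z)}, same length as \code{z}.
#' @export
phi_hat <- function(z, params, n_nodes = 200) {
  if (any(z < 0)) stop("wavenumber z must be non-negative")
  gl <- gauss_rule(n_nodes)
  tau <- params$tau
  x <- 0.5 * tau * (gl$x + 1)
  w <- 0.5 * tau * gl$w
  phir <- 3 * params$Cphi / (2 * pi * tau) * (1 - x / tau)^2
  as.vector(2 * pi * (besselJ(outer(z, x), 0) %*% (w * phir * x)))
}

#' Stability constant c0 and its maximizer
#'
#' Maximizes \eqn{z^2 \hat\phi(z)^2} over \eqn{z > 0}: a coarse scan over
#' \eqn{(0, 40/\tau]} followed by local refinement of the bracketing
#' interval.  The first lobe of the oscillating, decaying transform contains
#' the global maximum for this kernel family.  Uniform states are linearly
#' unstable iff \eqn{c_0 > \mu\kappa}.  By self-similarity of the kernel,
#' \eqn{c_0' = c_0 / C_\phi^2} is independent of both \eqn{\tau} and
#' \eqn{C_\phi}.
#'
#' @param params a [model_params()] object.
#' @param n_scan number of scan points.
#' @return A list with elements \code{c0}, \code{z_star} (the maximizing
#'   wavenumber) and \code{c0_prime}.
#' @export
#' @examples
#' compute_c0(model_params(Cphi = 5, tau = 0.15))$c0  # ~ 5.6
compute_c0 <- function(params, n_scan = 2000) {
  if (params$Cphi == 0)
    return(list(c0 = 0, z_star = NA_real_, c0_prime = NA_real_))
  zmax <- 40 / params$tau
  zs <- seq(zmax / n_scan, zmax, length.out = n_scan)
  f <- zs^2 * phi_hat(zs, params)^2
  i <- which.max(f)
  if (i == n_scan)
    stop("scan bracket does not contain an interior maximum of z^2 phi_hat^2")
  lo <- zs[max(1L, i - 1L)]; hi <- zs[min(n_scan, i + 1L)]
  opt <- optimize(function(z) z^2 * phi_hat(z, params)^2,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(c0 = opt$objective, z_star = opt$maximum,
       c0_prime = opt$objective / params$Cphi^2)
}

#' Bifurcation parameter
#'
#' \eqn{b_p = \mu\kappa / (C_\phi^2 c_0') = \mu\kappa / c_0}.  Uniform
#' states of the continuum system are linearly unstable iff \eqn{b_p < 1}.
#'
#' @param params a [model_params()] object.
#' @return The bifurcation parameter (a number).
#' @export
#' @examples
#' compute_bp(model_params(mu = 4e-3, kappa = 1000, Cphi = 5))  # ~ 0.7142
compute_bp <- function(params) {
  if (params$mu == 0) return(0)
  params$mu * params$kappa / compute_c0(params)$c0
}
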