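#' Measured pattern sizes from a density field
#'
#' Takes the 2-D discrete Fourier transform of the density, restricts the
#' spectrum to lattice modes \eqn{k = 2\pi(n_1, n_2)/L} within an angular
#' tolerance of the reference direction \eqn{\Omega_0} (respectively
#' \eqn{\Omega_0^\perp}), and returns the pattern size \eqn{S = 2\pi/|k|}
#' of the modulus-maximizing mode in each direction.  The zero mode is
#' excluded, and a direction is reported absent (\code{NA}) when its
#' maximal modulus does not exceed \code{noise_floor} times the mean
#' modulus of the non-zero spectrum -- a uniform field has no measurable
#' pattern in either direction.
#'
#' @param rho a positive Nx x Nx density field on the periodic grid.
#' @param Omega0 unit reference direction (the initial mean orientation).
#' @param angle_tol angular half-width in degrees of the directional cones.
#' @param noise_floor detection multiple over the mean spectral modulus.
#' @param L domain edge length.
#' @return A list with \code{S1} (parallel), \code{S2} (perpendicular),
#'   and the winning lattice modes \code{k_par}, \code{k_perp} (2-vectors
#'   of integers, or \code{NULL}).
#' @export
measured_sizes <- function(rho, Omega0 = c(cos(pi / 4), sin(pi / 4)),
                           angle_tol = 10, noise_floor = 5, L = 1) {
  if (any(rho < 0) || all(rho == 0)) stop("rho must be a non-negative, non-zero field")
  if (abs(sum(Omega0^2) - 1) > 1e-8) stop("Omega0 must be a unit vector")
  Nx <- nrow(rho)
  sp <- Mod(fft(rho))
  f <- 0:(Nx - 1)
  f[f > Nx / 2] <- f[f > Nx / 2] - Nx
  N1 <- matrix(f, Nx, Nx); N2 <- t(N1)
  nz <- !(N1 == 0 & N2 == 0)
  mean_mod <- mean(sp[nz])
  knorm <- sqrt(N1^2 + N2^2)
  ## unsigned angle between the mode and the Omega0 line
  cosang <- abs(N1 * Omega0[1] + N2 * Omega0[2]) / ifelse(knorm > 0, knorm, 1)
  ang <- acos(pmin(1, cosang)) * 180 / pi
  pick <- function(mask) {
    mask <- mask & nz
    if (!any(mask)) return(list(S = NA_real_, k = NULL))
    vals <- sp[mask]
    i <- which.max(vals)
    if (vals[i] <= noise_floor * mean_mod) return(list(S = NA_real_, k = NULL))
    list(S = L / knorm[mask][i], k = c(N1[mask][i], N2[mask][i]))
  }
  par <- pick(ang <= angle_tol)
  perp <- pick(ang >= 90 - angle_tol)
  list(S1 = par$S, S2 = perp$S, k_par = par$k, k_perp = perp$k)
}
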