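#' Dispersion building blocks F and G
#'
#' For a uniform state with density \eqn{\rho_0},
#' \deqn{F(z) = \frac{z^2\rho_0}{\zeta}\Big(\frac{1}{\kappa}
#'  z^2\hat\phi(z)^2 - \mu\Big), \qquad
#'  G(z) = 1 + \frac{\rho_0\eta}{\kappa^2\zeta} z^4 \hat\phi(z)^2 \ge 1.}
#' \eqn{F(z) > 0} exactly where \eqn{z^2\hat\phi(z)^2 > \mu\kappa}, the
#' instability condition.
#'
#' @param z radial wavenumber(s); vectorized.
#' @param params a [model_params()] object.
#' @param rho0 uniform reference density.
#' @return A vector of values.
#' @export
F_of <- function(z, params, rho0 = params$rho0) {
  ph <- phi_hat(z, params)
  z^2 * rho0 / params$zeta * (z^2 * ph^2 / params$kappa - params$mu)
}

#' @rdname F_of
#' @export
G_of <- function(z, params, rho0 = params$rho0) {
  ph <- phi_hat(z, params)
  1 + rho0 * params$eta / (params$kappa^2 * params$zeta) * z^4 * ph^2
}

disp_setup <- function(params, rho0, Omega0) {
  if (abs(sum(Omega0^2) - 1) > 1e-8) stop("Omega0 must be a unit vector")
  ac <- alignment_constants(params$ds / params$nu, params$u0, params$rA)
  list(ac = ac, rho0 = rho0, Omega0 = Omega0,
       Operp = c(-Omega0[2], Omega0[1]))
}

#' Growth rates of plane-wave perturbations
#'
#' Complex growth rates \eqn{\alpha} of perturbations
#' \eqn{e^{i k\cdot x + \alpha t}} of the uniform state
#' \eqn{(\rho_0, \Omega_0)}, solving
#' \deqn{(G(|k|)\alpha - F(|k|) + i d_1 k_0)
#'       (\alpha + i d_2 k_0 + |k|^2\gamma_s) + d_1 d_3 k_1^2 = 0,}
#' with \eqn{k_0 = k\cdot\Omega_0}, \eqn{k_1 = k\cdot\Omega_0^\perp}.  When
#' \eqn{k \parallel \Omega_0} the two factors decouple into the density
#' branch \eqn{\alpha_1 = (F - i d_1 k_0)/G} and the orientation branch
#' \eqn{\alpha_2 = -i d_2 k_0 - |k|^2\gamma_s}; otherwise the two roots of
#' the expanded complex quadratic are returned (numerically stable
#' formula).
#'
#' @param k wavevector (2-vector), non-zero.
#' @param params a [model_params()] object.
#' @param Omega0 unit orientation of the uniform state.
#' @param rho0 uniform reference density.
#' @return A complex vector of length 2.
#' @export
dispersion_roots <- function(k, params, Omega0 = c(cos(pi / 4), sin(pi / 4)),
                             rho0 = params$rho0) {
  kn <- sqrt(sum(k^2))
  if (kn == 0) stop("|k| must be positive")
  su <- disp_setup(params, rho0, Omega0)
  k0 <- sum(k * su$Omega0); k1 <- sum(k * su$Operp)
  Fv <- F_of(kn, params, rho0); Gv <- G_of(kn, params, rho0)
  ac <- su$ac
  if (abs(k1) < 1e-12 * kn) {
    return(c(complex(real = Fv / Gv, imaginary = -ac$d1 * k0 / Gv),
             complex(real = -kn^2 * ac$gamma_s, imaginary = -ac$d2 * k0)))
  }
  a <- Gv + 0i
  b <- Gv * (1i * ac$d2 * k0 + kn^2 * ac$gamma_s) + (-Fv + 1i * ac$d1 * k0)
  cc <- (-Fv + 1i * ac$d1 * k0) * (1i * ac$d2 * k0 + kn^2 * ac$gamma_s) +
    ac$d1 * ac$d3 * k1^2
  solve_quadratic(a, b, cc)
}

## numerically stable complex quadratic a x^2 + b x + c = 0
solve_quadratic <- function(a, b, cc) {
  sq <- sqrt(b^2 - 4 * a * cc)
  if (Re(Conj(b) * sq) < 0) sq <- -sq
  q <- -0.5 * (b + sq)
  if (Mod(q) == 0) return(c(0 + 0i, -b / a))
  c(q / a, cc / q)
}

#' Routh--Hurwitz stability test for a wavevector
#'
#' Evaluates the algebraic conditions equivalent (for the
#' complex-coefficient dispersion quadratic) to both growth rates having
#' negative real part:
#' \deqn{G|k|^2\gamma_s - F > 0 \quad\text{and}\quad
#'  H = (G|k|^2\gamma_s - F)^2 d_1 d_3 k_1^2
#'    - \gamma_s F |k|^2\big[(d_1 - d_2 G)^2 k_0^2 +
#'      (G|k|^2\gamma_s - F)^2\big] > 0.}
#'
#' @inheritParams dispersion_roots
#' @return \code{TRUE} if the mode is linearly stable.
#' @export
routh_hurwitz_stable <- function(k, params,
                                 Omega0 = c(cos(pi / 4), sin(pi / 4)),
                                 rho0 = params$rho0) {
  kn <- sqrt(sum(k^2))
  if (kn == 0) stop("|k| must be positive")
  su <- disp_setup(params, rho0, Omega0)
  k0 <- sum(k * su$Omega0); k1 <- sum(k * su$Operp)
  Fv <- F_of(kn, params, rho0); Gv <- G_of(kn, params, rho0)
  ac <- su$ac; gs <- ac$gamma_s
  P <- Gv * kn^2 * gs - Fv
  H <- P^2 * ac$d1 * ac$d3 * k1^2 -
    gs * Fv * kn^2 * ((ac$d1 - ac$d2 * Gv)^2 * k0^2 + P^2)
  (P > 0) && (H > 0)
}

#' Linear instability of the uniform state
#'
#' The uniform state is linearly unstable iff there exists \eqn{z > 0} with
#' \eqn{z^2\hat\phi(z)^2 > \mu\kappa}, i.e. iff \eqn{c_0 > \mu\kappa}
#' (\eqn{b_p < 1}).  The maximizer of \eqn{z^2\hat\phi(z)^2} is returned as
#' witness.
#'
#' @param params a [model_params()] object.
#' @return A list with \code{unstable} (logical) and \code{z_witness}.
#' @export
is_linearly_unstable <- function(params) {
  c0 <- compute_c0(params)
  list(unstable = c0$c0 > params$mu * params$kappa, z_witness = c0$z_star)
}

## vectorized real parts of the two dispersion branches over a z-grid,
## reusing a single phi_hat evaluation
branch_re <- function(zs, params, rho0, ac) {
  ph <- phi_hat(zs, params)
  Fv <- zs^2 * rho0 / params$zeta * (zs^2 * ph^2 / params$kappa - params$mu)
  Gv <- 1 + rho0 * params$eta / (params$kappa^2 * params$zeta) * zs^4 * ph^2
  gs <- ac$gamma_s
  ## parallel density branch
  par <- Fv / Gv
  ## perpendicular (k0 = 0): real-coefficient quadratic
  b <- Gv * zs^2 * gs - Fv
  cc <- -Fv * zs^2 * gs + ac$d1 * ac$d3 * zs^2
  disc <- b^2 - 4 * Gv * cc
  perp <- ifelse(disc >= 0, (-b + sqrt(pmax(disc, 0))) / (2 * Gv),
                 -b / (2 * Gv))
  list(par = par, perp = perp, F = Fv, G = Gv)
}

#' Predicted pattern sizes and growth rates
#'
#' Maximizes the real part of the dispersion growth rate over wavenumbers
#' parallel and perpendicular to \eqn{\Omega_0} (coarse scan over
#' \eqn{(0, 40/\tau]} plus local refinement) and converts the maximizing
#' wavenumbers into pattern sizes \eqn{S^{th} = 2\pi/|k^{th}|}.  A
#' direction with no positive growth reports \code{NA} size and its maximal
#' (negative) rate.
#'
#' @param params a [model_params()] object.
#' @param rho0 uniform reference density.
#' @param n_scan scan resolution.
#' @return An object of class \code{pattern_prediction}: list with
#'   \code{k_par_th}, \code{k_perp_th}, \code{S1_th}, \code{S2_th},
#'   \code{alpha_max_par}, \code{alpha_max_perp}.
#' @export
pattern_prediction <- function(params, rho0 = params$rho0, n_scan = 4000) {
  ac <- alignment_constants(params$ds / params$nu, params$u0, params$rA)
  zmax <- 40 / params$tau
  zs <- seq(zmax / n_scan, zmax, length.out = n_scan)
  br <- branch_re(zs, params, rho0, ac)

  refine <- function(values, fun) {
    i <- which.max(values)
    lo <- zs[max(1L, i - 1L)]; hi <- zs[min(n_scan, i + 1L)]
    opt <- optimize(fun, c(lo, hi), maximum = TRUE, tol = 1e-9)
    list(z = opt$maximum, val = opt$objective)
  }
  par_fun <- function(z) {
    b <- branch_re(z, params, rho0, ac); b$par
  }
  perp_fun <- function(z) {
    b <- branch_re(z, params, rho0, ac); b$perp
  }
  rp <- refine(br$par, par_fun)
  rq <- refine(br$perp, perp_fun)

  out <- list(
    k_par_th = if (rp$val > 0) rp$z else NA_real_,
    k_perp_th = if (rq$val > 0) rq$z else NA_real_,
    S1_th = if (rp$val > 0) 2 * pi / rp$z else NA_real_,
    S2_th = if (rq$val > 0) 2 * pi / rq$z else NA_real_,
    alpha_max_par = rp$val,
    alpha_max_perp = rq$val)
  class(out) <- "pattern_prediction"
  out
}

#' @export
print.pattern_prediction <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else format(signif(v, 5))
  cat("<pattern_prediction>\n",
      " parallel:      S1_th = ", fmt(x$S1_th),
      "  alpha_max = ", format(signif(x$alpha_max_par, 5)), "\n",
      " perpendicular: S2_th = ", fmt(x$S2_th),
      "  alpha_max = ", format(signif(x$alpha_max_perp, 5)), "\n", sep = "")
  invisible(x)
}

#' Linearized response of a density-seeded plane wave
#'
#' Evolves the linearized two-component system for the perturbation
#' amplitudes \eqn{(\tilde\rho, \omega)} (density and
#' \eqn{\Omega_0^\perp}-orientation) analytically from the initial data
#' \eqn{(\tilde\rho, \omega)(0) = (1, 0)} and returns the complex density
#' amplitude \eqn{\tilde\rho(t)}.  Both dispersion branches are excited by
#' a density-only perturbation; the observable log-slope of
#' \eqn{|\tilde\rho(t)|} over a finite window therefore reflects their
#' mixture, weighted by the eigenvector structure -- this is the correct
#' reference when measuring growth rates of seeded modes in the nonlinear
#' solver.
#'
#' @param k wavevector (2-vector).
#' @param params a [model_params()] object.
#' @param t time(s) at which to evaluate the response.
#' @param Omega0 unit orientation of the uniform state.
#' @param rho0 uniform reference density.
#' @return Complex \eqn{\tilde\rho(t)}, same length as \code{t}.
#' @export
linear_mode_response <- function(k, params, t,
                                 Omega0 = c(cos(pi / 4), sin(pi / 4)),
                                 rho0 = params$rho0) {
  kn <- sqrt(sum(k^2))
  if (kn == 0) stop("|k| must be positive")
  su <- disp_setup(params, rho0, Omega0)
  k0 <- sum(k * su$Omega0); k1 <- sum(k * su$Operp)
  Fv <- F_of(kn, params, rho0); Gv <- G_of(kn, params, rho0)
  ac <- su$ac
  A <- matrix(c((Fv - 1i * ac$d1 * k0) / Gv,
                -1i * ac$d3 * k1 / rho0,
                -1i * rho0 * ac$d1 * k1 / Gv,
                -(1i * ac$d2 * k0 + kn^2 * ac$gamma_s)),
              2, 2)
  ev <- eigen(A)
  coef <- solve(ev$vectors, c(1, 0))
  vapply(t, function(tt)
    sum(ev$vectors[1, ] * coef * exp(ev$values * tt)), complex(1))
}

#' Locate the instability threshold by bisection
#'
#' Bisects the agent--agent repulsion intensity \eqn{\mu} at fixed
#' \eqn{\kappa} on the sign of the maximal dispersion growth rate (scanned
#' over both directions) and reports the critical \eqn{\mu^*} together with
#' the bifurcation parameter at the sign change,
#' \eqn{b_p^* = \mu^*\kappa/c_0}.
#'
#' @param params a [model_params()] object (its \code{mu} is ignored).
#' @param mu_lo,mu_hi bisection bracket.
#' @param tol relative tolerance on \eqn{\mu}.
#' @param n_scan scan resolution.
#' @return A list with \code{mu_star} and \code{bp_star}.
#' @export
instability_threshold <- function(params, mu_lo = 1e-8, mu_hi = 1,
                                  tol = 1e-5, n_scan = 4000) {
  ac <- alignment_constants(params$ds / params$nu, params$u0, params$rA)
  zmax <- 40 / params$tau
  zs <- seq(zmax / n_scan, zmax, length.out = n_scan)
  ph <- phi_hat(zs, params)
  gs <- ac$gamma_s
  rho0 <- params$rho0
  Gv <- 1 + rho0 * params$eta / (params$kappa^2 * params$zeta) * zs^4 * ph^2
  max_rate <- function(mu) {
    Fv <- zs^2 * rho0 / params$zeta * (zs^2 * ph^2 / params$kappa - mu)
    par <- Fv / Gv
    b <- Gv * zs^2 * gs - Fv
    cc <- -Fv * zs^2 * gs + ac$d1 * ac$d3 * zs^2
    disc <- b^2 - 4 * Gv * cc
    perp <- ifelse(disc >= 0, (-b + sqrt(pmax(disc, 0))) / (2 * Gv),
                   -b / (2 * Gv))
    max(par, perp)
  }
  if (max_rate(mu_lo) <= 0 || max_rate(mu_hi) >= 0)
    stop("bisection bracket does not straddle the instability threshold")
  while ((mu_hi - mu_lo) / mu_hi > tol) {
    mid <- 0.5 * (mu_lo + mu_hi)
    if (max_rate(mid) > 0) mu_lo <- mid else mu_hi <- mid
  }
  mu_star <- 0.5 * (mu_lo + mu_hi)
  list(mu_star = mu_star,
       bp_star = mu_star * params$kappa / compute_c0(params)$c0)
}

#' Stability scan over the bifurcation parameter
#'
#' Sweeps \eqn{\mu} (hence \eqn{b_p = \mu\kappa/c_0}) at fixed remaining
#' parameters, tabulating the maximal growth rates and predicted pattern
#' sizes in the two directions.
#'
#' @param params a [model_params()] object (template; \code{mu} replaced).
#' @param mu_values values of the agent--agent repulsion intensity.
#' @return A data frame with columns \code{mu}, \code{bp},
#'   \code{alpha_max_par}, \code{alpha_max_perp}, \code{S1_th},
#'   \code{S2_th}.
#' @export
stability_scan <- function(params, mu_values) {
  c0 <- compute_c0(params)$c0
  rows <- lapply(mu_values, function(mu) {
    p <- params; p$mu <- mu
    validate_params(p)
    pr <- pattern_prediction(p)
    data.frame(mu = mu, bp = mu * params$kappa / c0,
               alpha_max_par = pr$alpha_max_par,
               alpha_max_perp = pr$alpha_max_perp,
               S1_th = pr$S1_th, S2_th = pr$S2_th)
  })
  do.call(rbind, rows)
}
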