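#' Model parameters for the agent--obstacle system
#'
#' Bundles the physical constants shared by the discrete simulator, the
#' continuum solver and the stability toolkit.  All lengths are expressed in
#' units of the periodic domain edge \code{L}.
#'
#' @param N number of obstacles.
#' @param M number of agents.
#' @param u0 agent self-propulsion speed.
#' @param rR agent--agent repulsion radius.
#' @param rA agent--agent alignment radius.
#' @param nu alignment rate.
#' @param ds orientational noise intensity.
#' @param d0 obstacle positional noise intensity.
#' @param tau agent--obstacle repulsion radius.
#' @param Cphi agent--obstacle repulsion intensity, the integral of
#'   \eqn{|\nabla\phi|}.
#' @param mu agent--agent repulsion intensity, the integral of \eqn{\psi}.
#' @param zeta agent friction coefficient.
#' @param eta obstacle friction coefficient.
#' @param kappa obstacle spring stiffness.
#' @param L periodic domain edge length.
#' @param rhoA anchor density (constant in space).
#' @param rho0 reference uniform agent density.
#'
#' @details
#' Rates and intensities (\code{u0}, \code{nu}, \code{ds}, \code{d0},
#' \code{mu}, \code{Cphi}) may be zero, which switches the corresponding
#' force off; radii, frictions, the spring stiffness and the domain edge
#' must be strictly positive because they enter denominators.  All
#' interaction radii must be below \code{L/2} so that the minimum-image
#' convention is unambiguous.
#'
#' @return An object of class \code{swarm_params} (a named list).
#' @seealso [discrete_default_params()], [continuum_default_params()],
#'   [read_params_config()], [scale_params()]
#' @export
#' @examples
#' p <- model_params(mu = 0.002, zeta = 0.5, kappa = 100)
#' gamma_ratio(p)   # eta / kappa
model_params <- function(N = 3000, M = 3000, u0 = 1, rR = 0.075, rA = 0.1,
                         nu = 2, ds = 0.02, d0 = 0, tau = 0.15, Cphi = 5,
                         mu = 0.002, zeta = 0.5, kappa = 100, eta = 1,
                         L = 1, rhoA = 1, rho0 = 1) {
  p <- list(N = N, M = M, u0 = u0, rR = rR, rA = rA, nu = nu, ds = ds,
            d0 = d0, tau = tau, Cphi = Cphi, mu = mu, zeta = zeta,
            kappa = kappa, eta = eta, L = L, rhoA = rhoA, rho0 = rho0)
  validate_params(p)
  class(p) <- "swarm_params"
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number")
  strict <- c("rR", "rA", "tau", "zeta", "eta", "kappa", "L", "rhoA")
  for (nm in strict)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  nonneg <- c("u0", "nu", "ds", "d0", "mu", "Cphi", "rho0")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  if (p$N < 0 || p$M < 0 || p$N != round(p$N) || p$M != round(p$M))
    stop("N and M must be non-negative integers")
  for (nm in c("rR", "rA", "tau"))
    if (p[[nm]] >= p$L / 2)
      stop("parameter '", nm, "' must be below L/2 (minimum-image convention)")
  invisible(p)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("<swarm_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 6), " = ", format(v)), sep = "\n")
  invisible(x)
}

#' Ratio of obstacle friction to spring stiffness
#'
#' \code{gamma_ratio} returns \eqn{\gamma = \eta/\kappa}, the small parameter
#' of the stiff-spring regime; \code{delta_ratio} returns
#' \eqn{\delta = d_0/\gamma}, the low-obstacle-noise parameter.
#'
#' @param params a [model_params()] object.
#' @return A number.
#' @export
gamma_ratio <- function(params) params$eta / params$kappa

#' @rdname gamma_ratio
#' @export
delta_ratio <- function(params) params$d0 / gamma_ratio(params)

#' Default parameter sets for the two model levels
#'
#' \code{discrete_default_params} returns the reference parameter set of the
#' discrete phase-diagram simulations (3000 agents and obstacles,
#' \code{rA = 0.1}, \code{nu = 2}, \code{ds = 0.02}).
#' \code{continuum_default_params} returns the matching continuum-level set,
#' where the alignment radius is \code{rA = 0.15} and only the ratio
#' \code{ds/nu = 0.01} matters.  The three swept parameters \code{mu},
#' \code{zeta} and \code{kappa} must be chosen by the caller (sensible
#' defaults are provided).
#'
#' @param mu,zeta,kappa the swept parameters.
#' @param ... further overrides passed to [model_params()].
#' @return A [model_params()] object.
#' @export
discrete_default_params <- function(mu = 0.002, zeta = 0.5, kappa = 100, ...) {
  args <- list(N = 3000, M = 3000, u0 = 1, rR = 0.075, rA = 0.1, nu = 2,
               ds = 0.02, d0 = 0, tau = 0.15, Cphi = 5,
               mu = mu, zeta = zeta, kappa = kappa, eta = 1)
  do.call(model_params, modifyList(args, list(...)))
}

#' @rdname discrete_default_params
#' @export
continuum_default_params <- function(mu = 0.002, zeta = 0.5, kappa = 100, ...) {
  args <- list(N = 3000, M = 3000, u0 = 1, rR = 0.075, rA = 0.15, nu = 2,
               ds = 0.02, d0 = 0, tau = 0.15, Cphi = 5,
               mu = mu, zeta = zeta, kappa = kappa, eta = 1)
  do.call(model_params, modifyList(args, list(...)))
}

#' Rescale parameters by the localization factor epsilon
#'
#' Applies the scaling under which the continuum model approximates the
#' discrete one: the interaction radii shrink, \code{rR' = eps * rR},
#' \code{rA' = eps * rA}, while alignment and orientational noise speed up,
#' \code{ds' = ds / eps}, \code{nu' = nu / eps}.  The ratio \code{ds/nu} is
#' invariant.
#'
#' @param params a [model_params()] object.
#' @param eps scaling factor in (0, 1].
#' @return A rescaled [model_params()] object.
#' @export
scale_params <- function(params, eps) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0)
  model_params(N = params$N, M = params$M, u0 = params$u0,
               rR = eps * params$rR, rA = eps * params$rA,
               nu = params$nu / eps, ds = params$ds / eps,
               d0 = params$d0, tau = params$tau, Cphi = params$Cphi,
               mu = params$mu, zeta = params$zeta, kappa = params$kappa,
               eta = params$eta, L = params$L, rhoA = params$rhoA,
               rho0 = params$rho0)
}

.config_keys <- c("N", "M", "u0", "rR", "rA", "nu", "tau", "Cphi", "ds",
                  "eta", "d0", "mu", "zeta", "kappa", "L", "rhoA", "rho0")

#' Read and write parameter configuration files
#'
#' Parameters are stored in a flat \code{key = value} text format with
#' \code{#} comments; key names follow the parameter tables
#' (\code{N, M, u0, rR, rA, nu, tau, Cphi, ds, eta, d0, mu, zeta, kappa})
#' plus the optional \code{L}, \code{rhoA}, \code{rho0}.  Unknown keys are
#' rejected.
#'
#' @param path file path.
#' @param base a [model_params()] object supplying defaults for keys absent
#'   from the file.
#' @return \code{read_params_config} returns a [model_params()] object;
#'   \code{write_params_config} returns \code{path} invisibly.
#' @export
read_params_config <- function(path, base = model_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (!key %in% .config_keys) stop("unknown config key: '", key, "'")
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    vals[[key]] <- val
  }
  p <- modifyList(unclass(base), vals)
  do.call(model_params, p)
}

#' @rdname read_params_config
#' @param params a [model_params()] object to serialize.
#' @export
write_params_config <- function(params, path) {
  keys <- .config_keys
  writeLines(sprintf("%s = %.17g", keys, unlist(params[keys])), path)
  invisible(path)
}
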