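#' Synthetic density fields and point clouds for metric tests
#'
#' \code{banded_field} builds a plane-wave density
#' \eqn{1 + a\cos(2\pi n\, x\cdot\Omega_0)}; \code{clustered_field} a
#' unit-mass sum of periodic Gaussian bumps; \code{uniform_cloud} an
#' i.i.d. uniform point cloud.  These emulate the banded / clustered /
#' homogeneous states used to exercise the pattern metrics and the
#' comparison pipeline without running a simulation.
#'
#' @param Nx grid resolution.
#' @param n integer mode number of the band.
#' @param amplitude band amplitude (must keep the field positive).
#' @param Omega0 unit direction of the band's wavevector.
#' @param L domain edge length.
#' @return A density matrix (fields) or an N x 2 matrix (cloud).
#' @export
banded_field <- function(Nx = 96, n = 3, amplitude = 0.5,
                         Omega0 = c(cos(pi / 4), sin(pi / 4)), L = 1) {
  xc <- (seq_len(Nx) - 0.5) * L / Nx
  X <- matrix(xc, Nx, Nx); Y <- t(X)
  1 + amplitude * cos(2 * pi * n * (X * Omega0[1] + Y * Omega0[2]) / L)
}

#' @rdname banded_field
#' @param centers k x 2 matrix of bump centers; default draws them from
#'   the seed.
#' @param width Gaussian bump width.
#' @param n_bumps number of bumps when \code{centers} is \code{NULL}.
#' @param seed RNG seed for random centers.
#' @export
clustered_field <- function(Nx = 96, centers = NULL, width = 0.04,
                            n_bumps = 5, seed = 1, L = 1) {
  if (is.null(centers)) {
    set.seed(seed)
    centers <- matrix(runif(2 * n_bumps, 0, L), ncol = 2)
  }
  xc <- (seq_len(Nx) - 0.5) * L / Nx
  X <- matrix(xc, Nx, Nx); Y <- t(X)
  rho <- matrix(0, Nx, Nx)
  for (b in seq_len(nrow(centers))) {
    dx <- X - centers[b, 1]; dx <- dx - L * round(dx / L)
    dy <- Y - centers[b, 2]; dy <- dy - L * round(dy / L)
    rho <- rho + exp(-(dx^2 + dy^2) / (2 * width^2))
  }
  rho / (mean(rho) * L^2)     # unit mass
}

#' @rdname banded_field
#' @param N number of points.
#' @export
uniform_cloud <- function(N, seed = 1, L = 1) {
  set.seed(seed)
  matrix(runif(2 * N, 0, L), ncol = 2)
}

#' Write the standard fixture set to a directory
#'
#' Emits the banded field, the clustered field and a uniform cloud as CSV
#' files, for inspection or external tooling.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return Invisibly, the written paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("banded_field.csv", "clustered_field.csv",
                            "uniform_cloud.csv"))
  utils::write.table(banded_field(), paths[1], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(clustered_field(seed = seed), paths[2], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(uniform_cloud(1000, seed = seed), paths[3], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
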