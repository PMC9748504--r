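---
title: "Models and numerics behind swarmob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind swarmob}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmob)
```

# The system

`swarmob` models self-propelled agents moving through a field of obstacles
that are tethered to fixed anchor points by Hookean springs, on the periodic
unit square.  Agents move at constant speed $u_0$ along a unit orientation
vector, align with neighbours within radius $r_A$ at rate $\nu$ against
rotational noise of intensity $d_s$ (Vicsek dynamics), and repel both each
other (kernel $\psi$, radius $r_R$, strength $\mu = \int\psi$) and the
obstacles (kernel $\phi$, radius $\tau$, strength
$C_\phi = \int|\nabla\phi|$).  Obstacles are passive: they are pushed by the
agents and pulled back to their anchors by springs of stiffness $\kappa$,
with frictions $\zeta$ (agents) and $\eta$ (obstacles).  The feedback —
agents reshape the obstacle field, which in turn steers the agents —
produces trails, travelling bands, clusters and honeycomb-like states
depending on where $(\kappa, \mu, \zeta)$ sit.

The package implements the system at two levels and the machinery to relate
them:

* a **discrete stochastic simulator** (Euler–Maruyama) for the coupled
  SDEs of $N$ obstacles and $M$ agents;
* a **continuum solver** for the hydrodynamic limit: a continuity equation
  for the agent density $\rho_g$ and a transport–diffusion equation for the
  mean orientation $\Omega$, closed by expressing the obstacle density
  $\rho_f$ as a differential functional of $\bar\rho_g = \rho_g * \phi$;
* the **linear stability toolkit** around uniform states, and
* a **discrete-vs-continuum comparison pipeline** (particle-in-cell density
  estimation, optimal grid selection, histogram signatures, earth mover's
  distance).

# Parameters that matter

All lengths are in units of the domain edge $L = 1$; time is in units of
$L/u_0$.  The reference discrete set is $N = M = 3000$, $u_0 = 1$,
$r_R = 0.075$, $r_A = 0.1$, $\nu = 2$, $d_s = 0.02$, $\tau = 0.15$,
$C_\phi = 5$, $\eta = 1$, $d_0 = 0$, with $\mu$, $\zeta$, $\kappa$ swept
(`discrete_default_params()`).  At the continuum level only the ratio
$d_s/\nu = 0.01$ enters, and the alignment radius is $r_A = 0.15$
(`continuum_default_params()`); the discrete $r_A = 0.1$ corresponds to the
localization scaling $r_A' = \varepsilon r_A$ at $\varepsilon \approx 0.5$.
The scaling under which the continuum limit is approached is implemented in
`scale_params()`: $r_R, r_A \propto \varepsilon$ and
$d_s, \nu \propto 1/\varepsilon$.

From $d_s/\nu$ the package derives the drift coefficients $d_i = u_0 c_i$
and the orientational viscosity $\gamma_s = (r_A^2/8)(d_s/\nu + c_2)$.
$c_1$ is the mean resultant of the von Mises equilibrium (checked against
the Bessel ratio $I_1/I_0$); $c_2$ requires the auxiliary function
$h = g/\sin\theta$, where $g$ solves
$(\nu/d_s)\sin\theta\, g' + g'' = \sin\theta$ on $[0, \pi]$.  As boundary
conditions we impose $g(0) = g(\pi) = 0$, forced by requiring $h$ to stay
bounded where $\sin\theta$ vanishes.  The solver uses second-order central differences on
a uniform grid (default 2000 intervals, grid-converged to $10^{-4}$ in
$c_2$) and a tridiagonal solve; endpoint values of $h$ come from one-sided
limits.  For $d_s/\nu < 10^{-4}$ the quadratures overflow and the code
refuses, pointing to the asymptotic limits $c_1, c_2 \to 1$.  At the
reference ratio $0.01$ this chain gives $\gamma_s \approx 2.81 \times
10^{-3}$.

# Linear stability and the bifurcation parameter

Linearizing the continuum system around $(\rho_0, \Omega_0)$ gives, for a
plane wave $e^{ik\cdot x + \alpha t}$, the factored dispersion relation

$$\big(G(|k|)\,\alpha - F(|k|) + i d_1 k_0\big)
  \big(\alpha + i d_2 k_0 + |k|^2\gamma_s\big) + d_1 d_3 k_1^2 = 0,$$

with $k_0 = k\cdot\Omega_0$, $k_1 = k\cdot\Omega_0^\perp$,
$F(z) = \frac{z^2\rho_0}{\zeta}\big(\frac{z^2\hat\phi(z)^2}{\kappa} -
\mu\big)$ and $G(z) = 1 + \frac{\rho_0\eta}{\kappa^2\zeta}
z^4\hat\phi(z)^2$.  The uniform state is unstable iff some $z$ has
$z^2\hat\phi(z)^2 > \mu\kappa$, i.e. iff

$$b_p = \frac{\mu\kappa}{c_0} < 1, \qquad
  c_0 = \max_{z>0} z^2 \hat\phi(z)^2 .$$

By the kernel's self-similarity $c_0/C_\phi^2$ is independent of $\tau$ and
$C_\phi$; for $C_\phi = 5$, $c_0 \approx 5.60$.  `compute_c0()` scans
$z \in (0, 40/\tau]$ at 2000 points and refines the bracketing interval
with bounded scalar optimization; the transform $\hat\phi(z) = 2\pi\int_0^\tau
J_0(zr)\phi(r)\,r\,dr$ is a 200-node Gauss–Legendre quadrature on the
compact support (checked against a fine-grid 2-D FFT to $10^{-6}$).

For $k \parallel \Omega_0$ the two factors decouple into a density branch
$\alpha_1 = (F - i d_1 k_0)/G$ and an orientation branch
$\alpha_2 = -i d_2 k_0 - |k|^2\gamma_s$.  Two algebraically inequivalent
readings of the parallel density branch, $(F - i d_1 k_0)/G$ versus
$F/G - i d_1 k_0$, share the same real part; the package derives everything
from the factored determinant, which fixes the first.  The non-parallel
quadratic is likewise built by expanding the determinant rather than
transcribed, so its $\rho_0$ dependence is the determinant's.  Stability of
the non-parallel quadratic is decided by the Routh–Hurwitz conditions for
complex-coefficient polynomials, $G|k|^2\gamma_s - F > 0$ together with a
positivity condition on a cubic combination $H(k)$; we verified both
symbolically and against a root-sign oracle on thousands of random draws
that these conditions are exactly equivalent to both roots having negative
real part.

Predicted pattern sizes are $S^{th} = 2\pi/|k^{th}|$ with $k^{th}$ the
growth-maximizing wavenumber in each direction (`pattern_prediction()`).
The maximal rates reported alongside the sizes are maxima of the real
part over each direction.  One caveat we record honestly: at $\kappa = 1000$, $\zeta = 0.5$,
$\mu = 4\times10^{-3}$ (the travelling-band corner) the perpendicular
branch is marginally positive ($\approx +0.08$, twenty times below the
parallel rate) rather than exactly non-positive, so the band regime is
diagnosed by parallel dominance; the *measured* $S_2$ of band states is
absent as expected.

# The continuum solver

The solver is a cell-centered finite-volume scheme on an $N_x \times N_x$
periodic grid (the scheme is this package's own design):

* **density**: conservative face fluxes; the advective velocity
  $d_1\Omega - \nabla\bar\rho_f/\zeta$ is averaged to faces and the face
  density reconstructed by second-order one-sided (upwind-biased)
  extrapolation by default (`scheme = "upwind2"`), with the nonlinear
  diffusion $\mu\rho\nabla\rho/\zeta$ as a central flux.  Mass is conserved
  to round-off by construction.
* **closure**: $\bar\rho_g$, its Laplacian, Hessian determinant, and
  $\nabla(\rho_f * \phi)$ are computed spectrally; the kernel is sampled on
  the grid (minimum image) and rescaled so its discrete integral equals the
  analytic $\int\phi = C_\phi\tau/4$.  The $-(\eta/\kappa^2)
  \partial_t\Delta\bar\rho_g$ term of the closure is kept by default (it is
  what produces the $G$ factor in the dispersion relation, so dropping it
  would decouple the solver from the stability analysis); it is discretized
  as a backward difference, zero on the first step, and can be disabled
  with `dt_term = FALSE`.  The $O((\eta/\kappa)^3)$ remainder is always
  dropped.
* **orientation**: the full right-hand side is projected onto
  $\Omega^\perp$ node-wise and the updated vector renormalized, so
  $|\Omega| = 1$ holds exactly at every node; nodes with
  $\rho_g < 10^{-8}$ freeze their orientation (the equation degenerates in
  vacuum).  Advection of $\Omega$ uses one-sided differences of the same
  order as the density scheme.
* **time stepping**: explicit Euler under the CFL conditions
  $\Delta t\,\max|U|/h < 0.5$ and
  $\Delta t\,\max(\mu\rho_g/\zeta, \gamma_s)/h^2 < 0.25$;
  `run_continuum()` halves the step adaptively when concentration steepens
  the velocities.

Why second-order upwinding by default: at the production resolutions used
here the modified-equation diffusion of first-order upwinding (about
$|U| h k^2/2$ per axis) exceeds the physical growth rates of the weakly
unstable band regime ($\alpha \sim 1$), so a first-order scheme visibly
damps the very patterns under study; the second-order variant's residual
dissipation is one to two orders smaller.  The first-order scheme remains
available (`scheme = "upwind1"`) as the maximally robust option.

Initial conditions are a band-limited random perturbation of the uniform
density (modes $|n| \le 8$, amplitude $10^{-2}$, unit-mass renormalized) with
constant orientation
at angle $\pi/4$.  The perturbation's Fourier coefficients are drawn from
the seed in a fixed order, so the same seed defines the same continuum
field at every resolution — this is what makes grid-refinement comparisons
meaningful.

Blow-up is intrinsic to the macroscopic model: concentrated clusters drive
$\Delta\bar\rho_g$ strongly negative and $\rho_f$ can turn negative, and
nothing prevents unbounded concentration of $\rho_g$.  `blowup_check()`
stops a run when $\rho_f < 0$ anywhere, when $\max\rho_g$ exceeds 50 times
its mean, or when the reconstruction undershoots into negative density; the
last valid state is retained and analysed.

**Validation.** Seeded single lattice modes are compared against the
linearized theory.  Because a density-only perturbation excites both
dispersion branches with eigenvector-dependent weights, the reference is
the analytic two-component response `linear_mode_response()` evaluated on
the same measurement window as the simulation, not a bare eigenvalue.  Six
cases (both directions, stable and unstable, $\kappa \in \{100, 1000\}$,
modes chosen inside the well-resolved band $|n| \le 4$ at $N_x = 64$)
agree within 10%, most within 5%.

# The discrete simulator

Euler–Maruyama with the orientation advanced in angle coordinates:
$d\theta_k = \nu\sin(\bar\theta_k - \theta_k)\,dt + \sqrt{2 d_s}\,dW_k$ is
the angular component of the projected alignment force, and Stratonovich
projected noise on the circle is additive in the angle, so the unit-norm
constraint is exact with no renormalization drift.  The mean flux
$J_k$ includes the agent itself; exact cancellation ($|J_k| < 10^{-12}$)
keeps the current orientation.  Neighbour search uses a uniform cell grid
with edge $\max(r_A, r_R, \tau)$ and the minimum-image convention (the
spring extension $X_i - Y_i$ is also minimum-image, so an obstacle wrapped
across the boundary is not torn by its tether); an all-pairs reference path
exists and is tested to agree exactly.  Runs abort if a single-step
displacement exceeds the cell edge (the neighbour search would no longer be
exhaustive).  Obstacles start at their anchors by default — one uniform
draw realizes both "uniform obstacles" and "uniform anchors" with a relaxed
spring — with an independent-draw flag available.  The default step
$dt = 10^{-3}$ keeps the stiffest reference rate $\kappa/\eta = 10^3$ at
$\kappa\,dt/\eta \le 1$; strongly $\varepsilon$-scaled runs (sharper
repulsion) need $dt = 5\times10^{-4}$.

Checks: free streaming and single-spring relaxation are exact; with all
interactions off the angular variance grows as $2 d_s t$; obstacles without
agents equilibrate to the Ornstein–Uhlenbeck variance $d_0\eta/\kappa$;
cell-list and all-pairs forces agree to $10^{-12}$.

# Comparing point clouds with densities

The pipeline compresses both solutions onto a common grid and compares
value distributions:

1. **Optimal grid**: sample $N$ points from the continuum density, deposit
   them with bilinear (cloud-in-cell) weights at candidate spacings
   $h \in \{1/n : n = 5..100\}$, interpolate back to the reference grid,
   and pick the $h$ minimizing the discrete $\ell^2$ error.  Clustered
   densities select fine grids, smooth ones coarse grids, and the error
   curve has an interior minimum.
2. **Signatures**: a field is reduced to $\{(p_k, \omega_k)\}$ with
   $p_k = k\,\|\rho\|_\infty/n_b$ and $\omega_k$ the number of grid cells
   with value in $[p_{k-1}, p_k)$.  Bins are half-open with the last bin
   closed — closed intervals on both ends would double-count edges, and a
   partition is required for $\sum\omega_k$ to equal the cell count.  The
   automatic bin count uses the Freedman–Diaconis width
   $2\,\mathrm{IQR}/n^{1/3}$ (a variant with $n^{3/2}$ in the denominator
   is kept behind `rule = "fd_3_2"` for sensitivity checks).  Micro and
   macro fields share one bin count, chosen from the macro field, for
   comparability.
3. **EMD**: the transportation problem with ground distance
   $|p_k - q_\ell|$, row/column capacities and total flow equal to the
   smaller total weight, solved exactly by the transportation simplex
   (north-west-corner start, MODI pivoting; unequal totals balanced by a
   zero-cost slack node); the distance is the optimal cost per unit flow.
   On balanced signatures this equals the closed-form 1-D Wasserstein-1
   distance (tested to $10^{-8}$) and is a true metric; on unbalanced ones
   it is the usual partial-transport relaxation.

One sampling realization is used per comparison (the patterns are robust
across realizations; a repeat option exists for error bars).

# What the synthetic generators do and do not emulate

`banded_field()`, `clustered_field()` and `uniform_cloud()` reproduce the
value-distribution shapes of band, cluster and homogeneous states
(plane waves, periodic Gaussian bumps, uniform points) for exercising the
metrics without simulation.  They do not emulate obstacle back-reaction,
travelling motion, or the intermediate trail/honeycomb morphologies, so
metric tests certify the measurement machinery, not the dynamics.
Similarly, the scaled-down problem sizes used in the test suite
($N_x = 64$–$96$, $N = M = 500$, final times 3–10) were chosen as the
smallest at which the qualitative regimes are unambiguous; phase-diagram
structure at the reference scale ($N = M = 3000$, $N_x = 150$) is
reproducible through `swarmob_cli()` but is not exercised by the tests.

# Known limitations

* The continuum closure is derived for stiff springs ($\eta/\kappa \ll 1$)
  and low obstacle noise; at $\kappa = 10$ the two levels genuinely
  disagree (the discrete model shows honeycombs and pinned states the
  continuum cannot produce) and the solver is not expected to match.
* Near and above the instability threshold the discrete dynamics is
  dominated by realization-to-realization variability; single-realization
  EMD comparisons there measure regime, not convergence.
* The unlimited second-order reconstruction can undershoot near blow-up;
  runs stop at the first negative density rather than limiting through it.
* Domain sizes other than $L = 1$ are supported by the API but untested
  extrapolation, as is any kernel family other than the quadratic bumps.
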