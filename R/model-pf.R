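#' Flaring protofilament as an elastica with spontaneous curvature
#'
#' At a depolymerising microtubule tip the protofilaments peel outward
#' with a preferred curvature `phi` (about 20 degrees per 8 nm tubulin
#' dimer).  An Ndc80 complex attached at arc position `s0` along the
#' curved flare and pulled along the microtubule axis straightens the
#' flare against its bending stiffness `alpha = kbt * Lp`.  Neglecting
#' thermal fluctuations, the energy-minimising shape `theta(s)` obeys the
#' elastica (pendulum) equation `theta'' = (F/alpha) sin(theta)` with
#' boundary conditions `theta(0) = 0` (clamped at the straight lattice)
#' and `theta'(s0) = phi` (natural curvature at the point of force
#' application).  The axial deflection is `z0(F) = integral of
#' cos(theta)` over `[0, s0]` and the protofilament stiffness is
#' `c_PF = (dz0/dF)^-1`, which stiffens as `F^(5/2)`:
#' `c_PF ~ 8 F^(5/2) / (3 phi^2 alpha^(3/2))` for `F >> alpha/s0^2`.
#'
#' @param s0 arc position of the Ndc80 attachment along the flare, nm.
#' @param flare_length total length `L` of the free curved flare, nm
#'   (must satisfy `s0 <= flare_length`; in vitro values are 10-80 nm).
#' @param lp persistence length of the protofilament, nm.
#' @param curvature preferred curvature `phi` in rad/nm (default: 20
#'   degrees per 8-nm dimer).
#' @param kbt thermal energy, pN nm.
#' @export
pf_flare <- function(s0 = 50, flare_length = 80, lp = 200,
                     curvature = (20 * pi / 180) / 8, kbt = kbt_default) {
  stopifnot(s0 > 0, lp > 0, curvature > 0, kbt > 0)
  if (s0 > flare_length)
    stop("pf_flare: attachment position s0 must not exceed the flare length")
  structure(list(s0 = s0, flare_length = flare_length, lp = lp,
                 curvature = curvature, kbt = kbt,
                 alpha = kbt * lp),
            class = c("pf_flare", "elastic_element"))
}

# Fixed-step RK4 for theta'' = k2 sin(theta), vectorised over initial
# curvatures.  Returns theta'(s0) for each candidate.
.pf_rk4_end <- function(td0, k2, n, h) {
  th <- rep(0, length(td0))
  td <- td0
  for (i in seq_len(n)) {
    k1t <- td;             k1d <- k2 * sin(th)
    k2t <- td + h / 2 * k1d; k2d <- k2 * sin(th + h / 2 * k1t)
    k3t <- td + h / 2 * k2d; k3d <- k2 * sin(th + h / 2 * k2t)
    k4t <- td + h * k3d;     k4d <- k2 * sin(th + h * k3t)
    th <- th + h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    td <- td + h / 6 * (k1d + 2 * k2d + 2 * k3d + k4d)
  }
  td
}

.pf_rk4_path <- function(td0, k2, n, h) {
  th <- numeric(n + 1)
  t1 <- 0
  td <- td0
  for (i in seq_len(n)) {
    k1t <- td;             k1d <- k2 * sin(t1)
    k2t <- td + h / 2 * k1d; k2d <- k2 * sin(t1 + h / 2 * k1t)
    k3t <- td + h / 2 * k2d; k3d <- k2 * sin(t1 + h / 2 * k2t)
    k4t <- td + h * k3d;     k4d <- k2 * sin(t1 + h * k3t)
    t1 <- t1 + h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    td <- td + h / 6 * (k1d + 2 * k2d + 2 * k3d + k4d)
    th[i + 1] <- t1
  }
  th
}

#' Protofilament shape under axial load
#'
#' Solves the elastica boundary-value problem by shooting on the unknown
#' base curvature `theta'(0)`.  The pendulum equation admits spurious
#' over-the-top solutions, so the solver scans candidate base curvatures
#' upward from zero and bisects the *first* sign change of
#' `theta'(s0) - phi`, which selects the minimal-bending physical
#' branch; the root is then polished to `|theta'(s0) - phi| < 1e-9`.
#'
#' @param force axial tension in pN (single value, >= 0).
#' @param beam a [pf_flare()] parameter object.
#' @param n_grid number of RK4 steps on `[0, s0]` (>= 400).
#' @return data.frame with columns `s` (nm) and `theta` (rad).
#' @export
pf_shape <- function(force, beam = pf_flare(), n_grid = 400) {
  stopifnot(length(force) == 1L, is.finite(force), force >= 0,
            n_grid >= 400)
  phi <- beam$curvature
  k2 <- force / beam$alpha
  h <- beam$s0 / n_grid
  s <- seq(0, beam$s0, length.out = n_grid + 1)
  if (k2 == 0)  # force-free: uniform preferred curvature, theta = phi s
    return(data.frame(s = s, theta = phi * s))
  cand <- phi * 10^seq(-30, 0.01, length.out = 200)
  g <- .pf_rk4_end(cand, k2, n_grid, h) - phi
  i <- which(g[-length(g)] <= 0 & g[-1] > 0)[1]
  if (is.na(i))
    stop(sprintf(paste0("pf_shape: shooting failed to bracket the base curvature ",
                        "(F = %g pN, s0 = %g nm, g-range [%g, %g])"),
                 force, beam$s0, min(g), max(g)))
  # bisect in log space: the root spans many decades with force
  # (td0 ~ phi / cosh(s0 sqrt(F/alpha)))
  r <- uniroot(function(y) .pf_rk4_end(exp(y), k2, n_grid, h) - phi,
               log(c(cand[i], cand[i + 1])), tol = 1e-13, maxiter = 100)
  if (abs(r$f.root) > 1e-9)
    stop(sprintf("pf_shape: shooting did not converge (residual %g rad/nm)",
                 r$f.root))
  data.frame(s = s, theta = .pf_rk4_path(exp(r$root), k2, n_grid, h))
}

# Composite Simpson rule over the uniform shooting grid.
.simpson <- function(y, h) {
  n <- length(y) - 1L
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) +
             2 * sum(y[seq(3, n - 1, 2)]))
}

#' Protofilament axial deflection
#'
#' `z0(F)`: position of the force-application point along the
#' microtubule axis, i.e. the integral of `cos(theta)` over the loaded
#' part of the flare.  Increases with force and saturates at `s0` when
#' the flare is pulled straight.
#'
#' @inheritParams pf_shape
#' @export
pf_extension <- function(force, beam = pf_flare(), n_grid = 400) {
  vapply(force, function(f) {
    sh <- pf_shape(f, beam, n_grid)
    .simpson(cos(sh$theta), beam$s0 / n_grid)
  }, numeric(1))
}

#' Protofilament stiffness
#'
#' `c_PF = (dz0/dF)^-1` by central differencing of [pf_extension()].
#'
#' @inheritParams pf_shape
#' @param rel_step relative force step of the central difference.
#' @export
pf_stiffness <- function(force, beam = pf_flare(), rel_step = 1e-3,
                         n_grid = 400) {
  vapply(force, function(f) {
    stopifnot(f > 0)
    zp <- pf_extension(f * (1 + rel_step), beam, n_grid)
    zm <- pf_extension(f * (1 - rel_step), beam, n_grid)
    2 * f * rel_step / (zp - zm)
  }, numeric(1))
}

#' Closed-form strong-force protofilament stiffness
#'
#' The linearised-elastica limit `c_PF = 8 F^(5/2) / (3 phi^2
#' alpha^(3/2))`, valid for `F >> alpha/s0^2` (0.3-2 pN for the default
#' geometries).
#'
#' @inheritParams pf_shape
#' @export
pf_stiffness_asymptotic <- function(force, beam = pf_flare()) {
  8 * force^2.5 / (3 * beam$curvature^2 * beam$alpha^1.5)
}

#' @export
extension.pf_flare <- function(object, force, ...) pf_extension(force, object)

#' @export
stiffness.pf_flare <- function(object, force, ...) pf_stiffness(force, object)
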