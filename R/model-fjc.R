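#' Ndc80 complex as a confined two-bond freely jointed chain
#'
#' The Ndc80 complex is a ~56 nm rod with a flexible kink that splits it
#' into a long arm (bead/kinetochore side, `a` = 40 nm) and a short arm
#' (microtubule side, `b` = 16 nm).  Treating the two arms as rigid rods
#' joined by a free hinge, and the micron-sized bead as an impenetrable
#' plane, the complex becomes a two-bond freely jointed chain (FJC)
#' confined to the upper half-space: the hinge must lie above the bead
#' surface (`z_a > 0`) and so must the microtubule-side end
#' (`z = z_a + z_b > 0`).  Tension `F` along the pulling axis adds a
#' stretching energy `-F (a cos(theta_a) + b cos(theta_b))`.
#'
#' The confined partition function reduces to a one-dimensional integral
#' with an analytic inner integral; writing `f = F/kbt`,
#' `Z(F)` is proportional to `D(f) / f^2` with
#' `D = 2 exp(f a) sinh(f b) - exp(f b) - f b + 1`.
#' Extension and stiffness follow from the first and second logarithmic
#' derivatives of `Z` and are evaluated in closed form with numerically
#' stable scaled exponentials (a series expansion takes over at very
#' small force, where the closed form is an indeterminate 0/0).
#'
#' In the strong-force limit (`F >> kbt/b` = 0.256 pN for the default
#' geometry) the extension saturates as `z = a + b - 2/(f)` and the
#' stiffness grows as `c = F^2 / (2 kbt)`: the kinked-rod architecture
#' alone produces quadratic strain stiffening.
#'
#' @param arm_long length of the bead-side arm `a` in nm.
#' @param arm_short length of the microtubule-side arm `b` in nm
#'   (must be shorter than `arm_long`).
#' @param kbt thermal energy in pN nm.
#' @return An object of class `ndc80_fjc` implementing the
#'   [extension()] / [stiffness()] contract.
#' @examples
#' nd <- fjc_ndc80()
#' fjc_extension(1, nd)            # ~47.8 nm at 1 pN
#' fjc_stiffness(10, nd)           # ~ F^2/(2 kbt) deep in the strong-force regime
#' @export
fjc_ndc80 <- function(arm_long = 40, arm_short = 16, kbt = kbt_default) {
  stopifnot(arm_long > arm_short, arm_short > 0, kbt > 0)
  structure(list(arm_long = arm_long, arm_short = arm_short, kbt = kbt),
            class = c("ndc80_fjc", "elastic_element"))
}

# Scaled derivatives of D(f) = 2 e^{fa} sinh(fb) - e^{fb} - fb + 1.
# Returns D, D', D'' each multiplied by exp(-f(a+b)); every term is a
# decaying exponential, so the expressions are stable for arbitrarily
# large force.
.fjc_scaled_D <- function(f, a, b) {
  e2fb <- exp(-2 * f * b)
  efa <- exp(-f * a)
  et <- exp(-f * (a + b))
  list(
    d0 = 1 - e2fb - efa - (f * b - 1) * et,
    d1 = a * (1 - e2fb) + b * (1 + e2fb) - b * efa - b * et,
    d2 = (a^2 + b^2) * (1 - e2fb) + 2 * a * b * (1 + e2fb) - b^2 * efa
  )
}

# Taylor coefficients of g(f) = D(f)/f^2 about f = 0; used where the
# direct evaluation of D suffers catastrophic cancellation.
.fjc_g_coef <- function(a, b) {
  c(g0 = 2 * a * b - b^2 / 2,
    g1 = a^2 * b + b^3 / 6,
    g2 = a^3 * b / 3 + a * b^3 / 3 - b^4 / 24,
    g3 = a^4 * b / 12 + a^2 * b^3 / 6 + b^5 / 120,
    g4 = a^5 * b / 60 + a^3 * b^3 / 18 + a * b^5 / 60 - b^6 / 720)
}

# Switch between series and closed form; f*(a+b) ~ 0.02 keeps both
# branches accurate to better than 1e-9 relative at the crossover.
.fjc_small <- function(f, a, b) f * (a + b) < 0.02

#' Confined FJC partition function
#'
#' Evaluates the configurational partition function of the confined
#' two-bond FJC (up to the constant azimuthal factor (2 pi)^2), i.e. the
#' double integral of `sin(theta_a) sin(theta_b) exp(f (a cos(theta_a) +
#' b cos(theta_b)))` over the half-space-allowed angles.  At `F = 0` this
#' is the confinement-only solid-angle fraction `2 - b/(2a)`.
#'
#' @param force tension in pN (>= 0, vectorised).
#' @param geom an [fjc_ndc80()] geometry.
#' @export
fjc_partition <- function(force, geom = fjc_ndc80()) {
  stopifnot(all(is.finite(force)))
  if (any(force < 0)) stop("fjc_partition: the model is defined for tension (force >= 0)")
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  co <- .fjc_g_coef(a, b)
  out <- numeric(length(f))
  small <- .fjc_small(f, a, b)
  if (any(small)) {
    fs <- f[small]
    out[small] <- (co[1] + co[2] * fs + co[3] * fs^2 + co[4] * fs^3 +
                     co[5] * fs^4) / (a * b)
  }
  if (any(!small)) {
    fl <- f[!small]
    d <- .fjc_scaled_D(fl, a, b)
    out[!small] <- d$d0 * exp(fl * (a + b)) / (fl^2 * a * b)
  }
  out
}

#' Extension of the confined two-bond FJC
#'
#' `z(F) = kbt d/dF log Z(F)`, evaluated in closed form.  Saturates at
#' `a + b` (56 nm by default); approaches it as `a + b - 2 kbt / F` for
#' strong force.
#'
#' @inheritParams fjc_partition
#' @export
fjc_extension <- function(force, geom = fjc_ndc80()) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  co <- .fjc_g_coef(a, b)
  z <- numeric(length(f))
  small <- .fjc_small(f, a, b)
  if (any(small)) {
    fs <- f[small]
    g <- co[1] + co[2] * fs + co[3] * fs^2 + co[4] * fs^3 + co[5] * fs^4
    gp <- co[2] + 2 * co[3] * fs + 3 * co[4] * fs^2 + 4 * co[5] * fs^3
    z[small] <- gp / g
  }
  if (any(!small)) {
    fl <- f[!small]
    d <- .fjc_scaled_D(fl, a, b)
    z[!small] <- d$d1 / d$d0 - 2 / fl
  }
  z
}

#' Stiffness of the confined two-bond FJC
#'
#' Closed-form `c(F) = (dz/dF)^-1` of the confined two-bond chain.  It
#' equals the inverse numerical derivative of [fjc_extension()] to
#' machine-level agreement and, by the fluctuation relation, equals
#' `kbt / Var(z)` under the Boltzmann measure (checked against Monte
#' Carlo sampling in the package tests).  For `F >> kbt/b` it approaches
#' `F^2 / (2 kbt)`.
#'
#' @inheritParams fjc_partition
#' @export
fjc_stiffness <- function(force, geom = fjc_ndc80()) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  co <- .fjc_g_coef(a, b)
  dzdf <- numeric(length(f))
  small <- .fjc_small(f, a, b)
  if (any(small)) {
    fs <- f[small]
    g <- co[1] + co[2] * fs + co[3] * fs^2 + co[4] * fs^3 + co[5] * fs^4
    gp <- co[2] + 2 * co[3] * fs + 3 * co[4] * fs^2 + 4 * co[5] * fs^3
    gpp <- 2 * co[3] + 6 * co[4] * fs + 12 * co[5] * fs^2
    dzdf[small] <- gpp / g - (gp / g)^2
  }
  if (any(!small)) {
    fl <- f[!small]
    d <- .fjc_scaled_D(fl, a, b)
    r1 <- d$d1 / d$d0
    dzdf[!small] <- d$d2 / d$d0 - r1^2 + 2 / fl^2
  }
  geom$kbt / dzdf
}

#' @export
extension.ndc80_fjc <- function(object, force, ...) fjc_extension(force, object)

#' @export
stiffness.ndc80_fjc <- function(object, force, ...) fjc_stiffness(force, object)

# Gauss-Legendre nodes/weights on [lo, hi] (Golub-Welsch).
.gauss_legendre <- function(n, lo, hi) {
  j <- seq_len(n - 1)
  bsub <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- bsub
  J[cbind(j + 1, j)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (hi - lo) / 2 * x + (hi + lo) / 2, w = (hi - lo) / 2 * w)
}

#' Mean angle between the two Ndc80 arms under tension
#'
#' Boltzmann average (and standard deviation) of the angle between the
#' two arm vectors of the confined chain, where 0 degrees means a fully
#' stretched, collinear complex.  The angle for a configuration is
#' `gamma = arccos(cos(theta_a) cos(theta_b) + sin(theta_a) sin(theta_b)
#' cos(dphi))`; the average is taken over `(theta_a, theta_b, dphi)`
#' with the half-space constraints by nested Gauss-Legendre quadrature.
#' Since the stretching energy is independent of the azimuth, the
#' `dphi` average is an unweighted mean over `[0, pi]`.
#'
#' @inheritParams fjc_partition
#' @param n_theta quadrature nodes per polar angle.
#' @param n_phi quadrature nodes for the azimuth difference.
#' @return named vector with elements `mean` and `sd`, in degrees.
#' @export
fjc_interarm_angle <- function(force, geom = fjc_ndc80(),
                               n_theta = 200, n_phi = 64) {
  stopifnot(length(force) == 1L, is.finite(force), force >= 0)
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  ga <- .gauss_legendre(n_theta, 0, 1)   # u_a = cos(theta_a), half space
  gp <- .gauss_legendre(n_phi, 0, pi)
  num1 <- num2 <- den <- 0
  for (i in seq_len(n_theta)) {
    ua <- ga$x[i]
    lo <- max(-1, -a * ua / b)           # z > 0 restricts u_b
    gb <- .gauss_legendre(n_theta, lo, 1)
    ub <- gb$x
    w <- ga$w[i] * gb$w * exp(f * (a * ua + b * ub - a - b))
    sa <- sqrt(1 - ua^2)
    sb <- sqrt(pmax(0, 1 - ub^2))
    cg <- outer(ua * ub, rep(1, n_phi)) + outer(sa * sb, cos(gp$x))
    gam <- acos(pmin(pmax(cg, -1), 1))
    m1 <- as.vector(gam %*% gp$w) / pi
    m2 <- as.vector(gam^2 %*% gp$w) / pi
    num1 <- num1 + sum(w * m1)
    num2 <- num2 + sum(w * m2)
    den <- den + sum(w)
  }
  mean_rad <- num1 / den
  var_rad <- num2 / den - mean_rad^2
  c(mean = mean_rad * 180 / pi, sd = sqrt(max(0, var_rad)) * 180 / pi)
}
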