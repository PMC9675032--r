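#' Entropic worm-like-chain stiffness of the microtubule
#'
#' The free microtubule between the surface-anchored seed and the
#' bead-linked tip fluctuates thermally; in the strong-force regime
#' (`F >> kbt/Lp ~ 1e-6 pN`) its worm-like-chain extension is
#' `z/L = 1 - sqrt(kbt / (4 F Lp))`, giving the entropic stiffness
#' `c_MT(F) = (4/L) sqrt(Lp/kbt) F^(3/2)`: an exact 3/2 stiffening
#' exponent.  The apparent persistence length of a grafted microtubule
#' is length dependent, `Lp = Lp_inf / (1 + (L0/L)^2)` with
#' `Lp_inf` = 6.3 mm and `L0` = 21 um, which makes `c_MT` nearly
#' independent of contour length for `L << L0`.
#'
#' @param length contour length of the free microtubule in nm
#'   (seed to tip; 10 um is a typical experimental value).
#' @param lp_inf asymptotic persistence length in nm.
#' @param l0 crossover length of the length-dependent persistence
#'   length, in nm.
#' @param kbt thermal energy in pN nm.
#' @return Object of class `mt_wlc` implementing [extension()] /
#'   [stiffness()].
#' @export
mt_wlc <- function(length = 1e4, lp_inf = 6.3e6, l0 = 2.1e4,
                   kbt = kbt_default) {
  if (length <= 0) stop("mt_wlc: contour length must be positive")
  stopifnot(lp_inf > 0, l0 >= 0, kbt > 0)
  structure(list(length = length, lp_inf = lp_inf, l0 = l0, kbt = kbt,
                 lp = lp_inf / (1 + (l0 / length)^2)),
            class = c("mt_wlc", "elastic_element"))
}

.mt_check_force <- function(force) {
  if (any(force < 1e-3))
    stop("mt_wlc: the entropic model holds for F >> kbt/Lp; supply force >= 1e-3 pN")
}

#' Microtubule worm-like-chain stiffness
#'
#' @param force tension in pN (vectorised, >= 1e-3).
#' @param params an [mt_wlc()] parameter object.
#' @export
mt_stiffness <- function(force, params = mt_wlc()) {
  .mt_check_force(force)
  4 / params$length * sqrt(params$lp / params$kbt) * force^1.5
}

#' Microtubule worm-like-chain extension
#'
#' @inheritParams mt_stiffness
#' @export
mt_extension <- function(force, params = mt_wlc()) {
  .mt_check_force(force)
  params$length * (1 - sqrt(params$kbt / (4 * force * params$lp)))
}

#' @export
stiffness.mt_wlc <- function(object, force, ...) mt_stiffness(force, object)

#' @export
extension.mt_wlc <- function(object, force, ...) mt_extension(force, object)
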