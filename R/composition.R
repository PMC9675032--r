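#' Serial combination of elastic elements
#'
#' Elements in series carry the same tension, so their compliances
#' (inverse stiffnesses) add: the softest element dominates, and adding
#' any element can only lower the combined stiffness.  Rigid elements
#' (infinite stiffness) drop out.
#'
#' @param elements list of elastic elements; plain positive numbers are
#'   accepted as constant springs, `Inf` as rigid.
#' @param force tension in pN (vectorised).
#' @return combined stiffness in pN/nm.
#' @examples
#' serial_stiffness(list(0.2, 0.2), 1)   # 0.1
#' @export
serial_stiffness <- function(elements, force) {
  if (!is.list(elements)) elements <- list(elements)
  compliance <- rep(0, length(force))
  for (el in elements) {
    cf <- if (is.numeric(el)) rep_len(el, length(force))
          else stiffness(el, force)
    if (any(cf < 0)) stop("serial_stiffness: negative element stiffness")
    if (any(cf == 0)) {
      warning("serial_stiffness: an element has zero stiffness; total is zero")
      return(rep(0, length(force)))
    }
    compliance <- compliance + 1 / cf
  }
  1 / compliance
}

#' Parallel combination with equal force sharing
#'
#' `n` identical linkers attached in parallel share the total force
#' equally, `F/n` each, so the cooperative stiffness is
#' `c_n(F) = n * c(F/n)`.  For a pure power law `c(F) = a F^m` this is
#' `c(F) * n^(1-m)`: parallel attachment *softens* the link whenever the
#' individual linker stiffens super-linearly (m > 1).
#'
#' @param linker an elastic element or a function `c(F)`.
#' @param n number of attached linkers (integer >= 1).
#' @param force total tension in pN (vectorised).
#' @export
parallel_stiffness <- function(linker, n, force) {
  stopifnot(length(n) == 1L, n >= 1, n == as.integer(n), all(force >= 0))
  cf <- if (is.function(linker)) linker(force / n)
        else stiffness(linker, force / n)
  n * cf
}

#' Composite Ndc80-microtubule link
#'
#' The full spring architecture of the optical-trap experiment: each of
#' `n` attached Ndc80 complexes is a serial chain of elastic elements
#' (Ndc80 FJC, protofilament flare, optionally PEG tether and a bond
#' placeholder); the `n` chains act in parallel with equal force
#' sharing; the parallel block is in series with the fluctuating
#' microtubule; and the optical trap, holding the bead from the opposite
#' side, adds in parallel:
#' `c_tot(F) = c_trap + (1 / (n c(F/n)) + 1 / c_MT(F))^-1`.
#'
#' @param linker_elements list of elements forming one Ndc80-PF chain.
#' @param mt an [mt_wlc()] element (or NULL to omit the microtubule).
#' @param n number of attached linker chains.
#' @param trap_stiffness trap stiffness in pN/nm (force independent).
#' @export
composite_link <- function(linker_elements, mt = mt_wlc(), n = 1,
                           trap_stiffness = 0.025) {
  stopifnot(n >= 1, n == as.integer(n), trap_stiffness >= 0)
  if (inherits(linker_elements, "elastic_element"))
    linker_elements <- list(linker_elements)
  stopifnot(is.list(linker_elements), length(linker_elements) >= 1)
  structure(list(linker_elements = linker_elements, mt = mt,
                 n = as.integer(n), trap_stiffness = trap_stiffness),
            class = "composite_link")
}

#' @export
print.composite_link <- function(x, ...) {
  cat(sprintf("<composite_link> n = %d parallel chains of %d element(s), %s, c_trap = %g pN/nm\n",
              x$n, length(x$linker_elements),
              if (is.null(x$mt)) "no MT" else sprintf("MT L = %g nm", x$mt$length),
              x$trap_stiffness))
  invisible(x)
}

# Stiffness of one linker chain at per-linker force F.
.chain_stiffness <- function(link, force) {
  serial_stiffness(link$linker_elements, force)
}

#' Trap-free link stiffness
#'
#' Stiffness of the `n`-parallel linker block in series with the
#' microtubule, without the trap contribution.
#'
#' @param link a [composite_link()].
#' @param force total tension in pN (vectorised).
#' @param n override the attachment count of `link`.
#' @export
link_stiffness <- function(link, force, n = link$n) {
  cn <- n * .chain_stiffness(link, force / n)
  if (is.null(link$mt)) cn
  else 1 / (1 / cn + 1 / stiffness(link$mt, force))
}

#' Total measured stiffness of the trap experiment
#'
#' `c_tot(F) = c_trap + (1/(n c(F/n)) + 1/c_MT(F))^-1`; this is the
#' quantity the interval equipartition estimator measures.
#'
#' @inheritParams link_stiffness
#' @export
total_stiffness <- function(link, force, n = link$n) {
  link$trap_stiffness + link_stiffness(link, force, n = n)
}

# Log-log interpolator of the single-chain stiffness; keeps the
# exhaustive n-search over the envelope cheap without altering the
# elastica/quadrature evaluations it summarises (~1e-6 relative).
.chain_interp <- function(link, f_min, f_max, n_nodes = 80) {
  fg <- exp(seq(log(f_min), log(f_max), length.out = n_nodes))
  cg <- .chain_stiffness(link, fg)
  sp <- splinefun(log(fg), log(cg), method = "monoH.FC")
  function(f) exp(sp(log(f)))
}

#' Stiffness-minimising attachment number (catch-bond envelope)
#'
#' For each force, searches exhaustively over the integer number of
#' attached Ndc80 complexes `n` for the one minimising the trap-free
#' link stiffness.  The envelope of the fixed-n stiffness curves is
#' attained by this `n_min(F)`; because the parallel block softens with
#' `n` only up to a point (the microtubule in series stiffens the
#' remainder), `n_min(F)` is finite, non-decreasing and roughly linear
#' in force, the signature of a catch-bond-like force-dependent
#' attachment.
#'
#' @param link a [composite_link()]; its own `n` is ignored.
#' @param forces force grid in pN (positive).
#' @param n_max upper bound of the search window.
#' @param interpolate evaluate the single-chain stiffness through a
#'   log-log spline table (fast); set FALSE for direct evaluation.
#' @return data.frame with columns `force`, `n_min`, `stiffness`
#'   (the envelope value, trap free).
#' @export
envelope_nmin <- function(link, forces = seq(0.5, 6, by = 0.25),
                          n_max = 50, interpolate = TRUE) {
  stopifnot(all(forces > 0), n_max >= 1)
  ns <- seq_len(n_max)
  chain <- if (interpolate)
    .chain_interp(link, min(forces) / n_max * 0.99, max(forces) * 1.01)
  else function(f) .chain_stiffness(link, f)
  cmt <- if (is.null(link$mt)) rep(Inf, length(forces))
         else stiffness(link$mt, forces)
  res <- vapply(seq_along(forces), function(i) {
    cn <- ns * chain(forces[i] / ns)
    ctot <- 1 / (1 / cn + 1 / cmt[i])
    j <- which.min(ctot)          # which.min takes the first = smallest n on ties
    c(ns[j], ctot[j])
  }, numeric(2))
  if (any(res[1, ] == n_max))
    warning("envelope_nmin: minimiser hit n_max; enlarge the search window")
  data.frame(force = forces, n_min = as.integer(res[1, ]),
             stiffness = res[2, ])
}

#' Effective stiffening exponent under a prescribed n(F)
#'
#' Computes the cooperative stiffness `n(F) * c(F / n(F))` under a
#' force-dependent attachment profile and returns its local log-log
#' slope at `force`.  For a decreasing (slip-bond) profile and a
#' power-law linker of exponent `m` the slope exceeds `m` at large
#' force (`c_n = F^m n^(1-m)`), whereas a linearly increasing
#' (catch-bond) profile yields slope 1 regardless of `m`.
#'
#' @param n_of_force function returning the (real-valued) attachment
#'   number at a given force.
#' @param linker an elastic element or a function `c(F)`.
#' @param force force at which to evaluate the slope (vectorised).
#' @param rel_step relative step of the central log-derivative.
#' @export
slip_bond_exponent <- function(n_of_force, linker, force, rel_step = 1e-3) {
  cn <- function(f) {
    n <- n_of_force(f)
    cf <- if (is.function(linker)) linker(f / n) else stiffness(linker, f / n)
    n * cf
  }
  local_loglog_slope(cn, force, rel_step)
}

#' Equipartition stiffness of the composite link
#'
#' What the interval estimator actually measures: the thermal-ensemble
#' stiffness `kbt / Var(x)` of the bead fluctuating in the full
#' anharmonic well formed by the trap and the nonlinear link, with the
#' microtubule tip held so that the mean trap force equals `force`.
#' For a stiffening link this lies a few percent *below* the tangent
#' stiffness [total_stiffness()], because the thermal excursions
#' sample the softer low-force side of the well more compliantly; the
#' two coincide in the harmonic limit.  Computed by direct Boltzmann
#' integration over the bead coordinate (independent of any dynamics).
#'
#' @param link a [composite_link()].
#' @param force mean trap force(s) at the operating point, pN.
#' @param f_max upper end of the tabulated link force range, pN
#'   (defaults to comfortably above `max(force)`).
#' @param n_sigma half-width of the integration window in units of the
#'   local tangent standard deviation.
#' @export
equipartition_stiffness <- function(link, force, f_max = max(force) * 1.5 + 3,
                                    n_sigma = 8) {
  kbt <- if (!is.null(link$mt)) link$mt$kbt else kbt_default
  ctrap <- link$trap_stiffness
  stopifnot(ctrap > 0, all(force > 0))
  tab <- .link_table(link, f_max = f_max)
  s <- tab$s; f <- tab$f
  V <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(s)))
  Vsp <- splinefun(s, V, method = "hyman")
  sl_end <- (f[length(f)] - f[length(f) - 1]) / (s[length(s)] - s[length(s) - 1])
  vpot <- function(q) {
    out <- numeric(length(q))
    mid <- q > s[1] & q <= s[length(s)]
    out[mid] <- Vsp(q[mid])
    hi <- q > s[length(s)]
    dq <- q[hi] - s[length(s)]
    out[hi] <- V[length(V)] + f[length(f)] * dq + sl_end * dq^2 / 2
    out
  }
  vapply(force, function(Fi) {
    x_star <- Fi / ctrap
    tip <- x_star + stats::approx(f, s, xout = Fi)$y
    half <- n_sigma * sqrt(kbt / total_stiffness(link, Fi))
    xs <- seq(x_star - half, x_star + half, length.out = 3001)
    U <- ctrap * xs^2 / 2 + vpot(tip - xs)
    w <- exp(-(U - min(U)) / kbt)
    w <- w / sum(w)
    m <- sum(w * xs)
    kbt / sum(w * (xs - m)^2)
  }, numeric(1))
}
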