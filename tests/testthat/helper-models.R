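# Shared builders for the composite-link fixtures used across tests.
# Everything is generated in code at test time; no stored data.

default_fjc <- fjc_ndc80()            # a = 40, b = 16 nm, kbt = 4.1

# The reference composite used by the recovery and envelope tests:
# FJC Ndc80 in series with a 50-nm protofilament flare, n parallel
# chains in series with a 10-um microtubule.
reference_link <- function(n = 3, trap = 0.025, s0 = 50) {
  composite_link(list(fjc_ndc80(), pf_flare(s0 = s0)),
                 mt = mt_wlc(), n = n, trap_stiffness = trap)
}

# Direct 1-D quadrature of the confined partition function (independent
# of the closed-form implementation path).
quad_partition <- function(force, geom = fjc_ndc80()) {
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  integrand <- function(u) {
    lo <- pmax(-1, -a * u / b)
    inner <- if (f > 0) (exp(f * b) - exp(f * b * lo)) / (f * b) else 1 - lo
    exp(f * a * u) * inner
  }
  integrate(integrand, 0, 1, rel.tol = 1e-12)$value
}

# log-derivative of the quadrature partition function: independent
# extension oracle.
quad_extension <- function(force, geom = fjc_ndc80(), h = 1e-5) {
  (log(quad_partition(force * (1 + h), geom)) -
     log(quad_partition(force * (1 - h), geom))) /
    (2 * force * h) * geom$kbt
}
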