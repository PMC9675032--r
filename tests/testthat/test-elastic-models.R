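# Single-element elasticity models: confined two-bond FJC, worm-like
# microtubule, protofilament elastica, two-state PEG chain.

test_that("confined FJC partition function matches quadrature and Monte Carlo", {
  geom <- default_fjc
  # closed form vs independent 1-D quadrature over a wide force range
  for (F in c(0.02, 0.1, 0.256, 1, 5, 20)) {
    expect_equal(fjc_partition(F, geom), quad_partition(F, geom),
                 tolerance = 1e-8)
  }
  # F = 0: confinement-only solid-angle fraction 2 - b/(2a)
  z0 <- fjc_partition(0, geom)
  expect_equal(z0, 2 - geom$arm_short / (2 * geom$arm_long),
               tolerance = 1e-10)
  # rejection-sampling oracle at F = 0: fraction of the (u_a, u_b)
  # square surviving the half-space constraints, times its area 2
  set.seed(41)
  n <- 2e6
  ua <- runif(n, 0, 1); ub <- runif(n, -1, 1)
  frac <- mean(geom$arm_long * ua + geom$arm_short * ub > 0)
  expect_equal(z0, 2 * frac, tolerance = 4 * 2 / sqrt(n) / z0)
  # strictly increasing in force
  Fg <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fjc_partition(Fg, geom)) > 0))
})

test_that("FJC extension matches the quadrature oracle and its asymptote", {
  geom <- default_fjc
  for (F in c(0.05, 0.256, 1, 2, 10)) {
    expect_equal(fjc_extension(F, geom), quad_extension(F, geom),
                 tolerance = 1e-7)
  }
  # strong force: z -> a + b - 2 kbt / F (total length 56 nm)
  expect_equal(fjc_extension(1e4, geom), 56, tolerance = 1e-4)
  expect_equal(fjc_extension(50, geom), 56 - 2 * geom$kbt / 50,
               tolerance = 2e-3)
  # z(1 pN) = 47.8 nm up to the strong-force correction
  expect_equal(fjc_extension(1, geom), 47.8155, tolerance = 1e-4)
  # monotone in force
  Fg <- exp(seq(log(0.01), log(30), length.out = 60))
  expect_true(all(diff(fjc_extension(Fg, geom)) > 0))
})

test_that("FJC stiffness equals the inverse derivative of the extension", {
  geom <- default_fjc
  Fg <- exp(seq(log(0.1), log(20), length.out = 40))
  h <- 1e-4
  dz <- (fjc_extension(Fg * (1 + h), geom) -
           fjc_extension(Fg * (1 - h), geom)) / (2 * Fg * h)
  expect_equal(fjc_stiffness(Fg, geom), 1 / dz, tolerance = 1e-4)
})

test_that("FJC stiffness has the printed crossover and quadratic limit", {
  geom <- default_fjc
  # crossover force kbt/b prints as 0.256 pN
  expect_equal(round(geom$kbt / geom$arm_short, 3), 0.256)
  # strong force: c -> F^2 / (2 kbt), within 1% at 10 pN
  expect_equal(fjc_stiffness(10, geom), 10^2 / (2 * geom$kbt),
               tolerance = 0.01)
  # small-force branch continuous across the series/closed-form switch
  f_sw <- 0.05 / (geom$arm_long + geom$arm_short) * geom$kbt
  expect_equal(fjc_stiffness(f_sw * 0.999, geom),
               fjc_stiffness(f_sw * 1.001, geom), tolerance = 1e-3)
})

test_that("FJC stiffness agrees with the fluctuation formula from sampling", {
  geom <- default_fjc
  for (F in c(0.5, 1)) {
    s <- sample_fjc(F, geom, n_samples = 2e5, seed = 17)
    v <- var(s$z)
    se <- v * sqrt(2 / nrow(s))
    c_mc <- geom$kbt / v
    c_cf <- fjc_stiffness(F, geom)
    expect_lt(abs(v - geom$kbt / c_cf), 3 * se)
    expect_equal(c_mc, c_cf, tolerance = 0.02)
  }
})

test_that("inter-arm angle is 44 +/- 23 degrees at 1 pN and closes correctly", {
  ang <- fjc_interarm_angle(1)
  expect_equal(unname(round(ang["mean"])), 44)
  expect_equal(unname(ang["sd"]), 23, tolerance = 0.05)
  # stretched limit
  expect_lt(fjc_interarm_angle(500)["mean"], 5)
  # F = 0 fixed by the Monte Carlo oracle
  ang0 <- fjc_interarm_angle(0)
  s0 <- sample_fjc(0, n_samples = 2e5, seed = 23)
  se <- sd(s0$angle) / sqrt(nrow(s0))
  expect_lt(abs(mean(s0$angle) - ang0["mean"]), 3 * se)
})

test_that("microtubule WLC stiffness: closed form, 3/2 exponent, length dependence", {
  mt <- mt_wlc(length = 1e4)
  # direct closed-form evaluation with Lp = 6.3e6/(1 + 4.41)
  lp <- 6.3e6 / (1 + (2.1e4 / 1e4)^2)
  expect_equal(mt_stiffness(1, mt), 4 / 1e4 * sqrt(lp / 4.1), tolerance = 1e-12)
  expect_equal(mt_stiffness(1, mt), 0.2132, tolerance = 1e-3)
  # exact 3/2 log-log slope at any force
  for (F in c(0.2, 1, 5))
    expect_equal(local_loglog_slope(function(f) mt_stiffness(f, mt), F),
                 1.5, tolerance = 1e-6)
  # near length independence for L << L0: 3 um vs 10 um within 10%
  r <- mt_stiffness(1, mt_wlc(length = 3e3)) / mt_stiffness(1, mt)
  expect_equal(r, sqrt(5.41e8 / 4.5e8), tolerance = 1e-6)
  expect_lt(abs(r - 1), 0.1)
  # consistency with the extension
  Fg <- c(0.5, 2, 8)
  h <- 1e-5
  dz <- (mt_extension(Fg * (1 + h), mt) - mt_extension(Fg * (1 - h), mt)) /
    (2 * Fg * h)
  expect_equal(mt_stiffness(Fg, mt), 1 / dz, tolerance = 1e-6)
  expect_error(mt_stiffness(1e-6, mt), "F >> kbt/Lp")
  expect_error(mt_wlc(length = -5), "positive")
})

test_that("protofilament shape: force-free curvature, linearised limit, energy", {
  beam <- pf_flare(s0 = 50, lp = 200)
  phi <- beam$curvature
  # F = 0: uniform preferred curvature, theta = phi s exactly
  sh0 <- pf_shape(0, beam)
  expect_equal(sh0$theta, phi * sh0$s, tolerance = 1e-12)
  # strong force: matches the closed-form linearised BVP
  # theta(s) = (phi/k) sinh(ks)/cosh(k s0), within 1% at 50 pN
  sh <- pf_shape(50, beam)
  k <- sqrt(50 / beam$alpha)
  lin <- phi / k * sinh(k * sh$s) / cosh(k * beam$s0)
  expect_lt(max(abs(sh$theta - lin)) / max(lin), 0.01)
  # shooting solution minimises the discretised bending + stretch
  # energy: direct numerical minimisation over theta grids agrees in
  # energy to 1e-4 relative
  F <- 5
  n <- 80
  h <- beam$s0 / n
  energy <- function(theta) {
    td <- diff(theta) / h
    z0 <- sum((cos(theta[-1]) + cos(theta[-(n + 1)])) / 2) * h
    sum(beam$alpha / 2 * (td - phi)^2 * h) - z0 * F
  }
  shc <- pf_shape(F, beam, n_grid = 400)
  th_shoot <- approx(shc$s, shc$theta, xout = seq(0, beam$s0, length.out = n + 1))$y
  opt <- optim(th_shoot * 0.9 + phi * seq(0, beam$s0, length.out = n + 1) * 0.1,
               function(p) energy(c(0, p[-1])), method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(energy(th_shoot), opt$value, tolerance = 1e-4)
  expect_lte(energy(th_shoot), opt$value + abs(opt$value) * 1e-4)
})

test_that("protofilament extension and stiffness obey the 5/2 asymptotics", {
  beam <- pf_flare(s0 = 50, lp = 200)
  # straightened limit z0 -> s0
  expect_equal(pf_extension(500, beam), beam$s0, tolerance = 1e-3)
  # z0 increases with force, bounded by s0
  z <- pf_extension(c(0.1, 1, 5, 20), beam)
  expect_true(all(diff(z) > 0))
  expect_true(all(z <= beam$s0))
  # local log-log slope -> 5/2 in the strong-force regime
  sl <- local_loglog_slope(function(f) pf_stiffness(f, beam), c(20, 30, 50),
                           rel_step = 0.02)
  expect_equal(sl, rep(2.5, 3), tolerance = 0.02)
  # closed form 8 F^(5/2) / (3 phi^2 alpha^(3/2)) within 5% at 30 pN
  expect_equal(pf_stiffness(30, beam), pf_stiffness_asymptotic(30, beam),
               tolerance = 0.05)
  expect_error(pf_flare(s0 = 90, flare_length = 80), "exceed")
})

test_that("PEG chain reproduces the printed force-free stiffness and stiffens", {
  peg <- peg_chain()
  expect_equal(round(peg_stiffness(0, peg), 2), 1.38)
  # strictly increasing under tension on [0, 50] pN
  cc <- peg_stiffness(seq(0, 50, length.out = 200), peg)
  expect_true(all(diff(cc) > 0))
  # far stiffer than measured link stiffnesses (>= 10 x 0.1 pN/nm)
  expect_gt(peg_stiffness(0, peg), 1.0)
  # stiffness consistent with the analytic extension derivative
  Fg <- c(0.5, 2, 10)
  h <- 1e-4
  dz <- (peg_extension(Fg * (1 + h), peg) - peg_extension(Fg * (1 - h), peg)) /
    (2 * Fg * h)
  expect_equal(peg_stiffness(Fg, peg), 1 / dz, tolerance = 1e-5)
})

test_that("every element satisfies the extension/stiffness consistency contract", {
  els <- list(fjc_ndc80(), mt_wlc(), pf_flare(), peg_chain(),
              constant_spring(0.3), powerlaw_spring(0.02, 1.5, 0.01))
  Fg <- c(0.1, 1, 5, 20)
  h <- 1e-4
  for (el in els) {
    dz <- (extension(el, Fg * (1 + h)) - extension(el, Fg * (1 - h))) /
      (2 * Fg * h)
    expect_equal(stiffness(el, Fg), 1 / dz, tolerance = 1e-3,
                 label = class(el)[1])
    expect_true(all(diff(extension(el, sort(c(Fg, Fg * 1.5)))) >= 0),
                label = class(el)[1])
  }
})
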