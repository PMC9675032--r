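# Interval equipartition estimator: segmentation, detrending,
# exclusion rules, state labels, binning, TSV round trips.

make_trace <- function(x, rate = 1e4, ctrap = 0.025, label = "t") {
  bead_trace(x, sampling_rate = rate, trap_stiffness = ctrap, label = label)
}

test_that("interval bookkeeping is exact", {
  # 1 s at 10 kHz, dt = 0.1 s: 10 ranges of 1000 points
  seg <- segment_trace(make_trace(rnorm(10000)), dt = 0.1)
  expect_equal(nrow(seg), 10)
  expect_true(all(seg[, "end"] - seg[, "start"] + 1 == 1000))
  # shorter than one interval: zero ranges, no crash
  expect_equal(nrow(segment_trace(make_trace(rnorm(500)), dt = 0.1)), 0)
  # trailing partial interval dropped: 0.55 s -> 5 ranges
  seg2 <- segment_trace(make_trace(rnorm(5500)), dt = 0.1)
  expect_equal(nrow(seg2), 5)
  expect_equal(max(seg2), 5000)
  # interval count = floor(duration/dt) for assorted durations
  for (npts in c(1000, 1999, 25000)) {
    expect_equal(nrow(segment_trace(make_trace(rnorm(npts)), dt = 0.1)),
                 npts %/% 1000)
  }
  expect_error(segment_trace(make_trace(rnorm(100), rate = 50), dt = 0.1),
               "at least 10")
})

test_that("interval stiffness inverts the residual variance", {
  t <- seq(0, 0.0999, by = 1e-4)
  # exact line: infinite-stiffness signal, not a crash
  est <- interval_stiffness(5 + 3 * t, t)
  expect_identical(est$stiffness, Inf)
  # i.i.d. Gaussian residuals of variance 41 about a line: c ~ 0.1
  set.seed(101)
  r <- rnorm(1e5, sd = sqrt(41))
  est2 <- interval_stiffness(2 + 7 * seq_along(r) * 1e-4 + r,
                             seq_along(r) * 1e-4, kbt = 4.1)
  expect_equal(est2$stiffness, 4.1 / mean((r - mean(r))^2) ,
               tolerance = 0.01)
  expect_equal(est2$stiffness, 0.1, tolerance = 4 * sqrt(2 / 1e5))
  expect_equal(est2$slope, 7, tolerance = 0.1)
})

test_that("estimator recovers the stiffness of an exact OU trace", {
  # exact-discretisation OU oracle: total stiffness 0.10, friction
  # 8.4e-6, 10 kHz, dt = 0.1 s; mean of c_k over 100 intervals
  tr <- simulate_ou_trace(0.10, duration = 10, seed = 3)
  s <- trace_stiffness(tr)
  expect_equal(nrow(s), 100)
  expect_equal(mean(s$stiffness), 0.10, tolerance = 0.05)
  # at stall-like stiffness (~0.25 pN/nm) the thermal slope scatter
  # leaves the overwhelming majority of intervals labelled stalled
  s25 <- trace_stiffness(simulate_ou_trace(0.25, duration = 10, seed = 5))
  expect_gt(mean(s25$state == "stalled"), 0.9)
})

test_that("a deterministic ramp does not change interval stiffness", {
  tr <- simulate_ou_trace(0.10, duration = 5, seed = 8)
  base <- trace_stiffness(tr, max_excursion = NULL)
  for (slope in c(25, -300)) {
    tr2 <- tr
    tr2$position <- tr$position + slope * tr$time
    drifted <- trace_stiffness(tr2, max_excursion = NULL)
    expect_equal(drifted$stiffness, base$stiffness, tolerance = 1e-9)
    expect_equal(drifted$slope, base$slope + slope, tolerance = 1e-6)
  }
})

test_that("scaling positions by lambda scales forces by lambda and stiffness by 1/lambda^2", {
  tr <- simulate_ou_trace(0.08, duration = 2, mean_x = 60, seed = 12)
  s1 <- trace_stiffness(tr, max_excursion = NULL)
  lam <- 1.7
  tr2 <- tr
  tr2$position <- tr$position * lam
  s2 <- trace_stiffness(tr2, max_excursion = NULL)
  expect_equal(s2$force, lam * s1$force, tolerance = 1e-12)
  expect_equal(s2$stiffness, s1$stiffness / lam^2, tolerance = 1e-12)
})

test_that("force assignment is the exact product of trap stiffness and mean position", {
  expect_equal(interval_force(100, 0.025), 2.5)
  expect_equal(interval_force(0, 0.025), 0)
  expect_equal(interval_force(-40, 0.03), -1.2)
  # stalled simulation at a commanded 4 pN: mean interval force ~ 4
  link <- reference_link()
  sim <- simulate_trace(sim_config(duration = 12, link = link,
                                   stall_force = 4), seed = 31)
  s <- trace_stiffness(sim$trace)
  stalled <- s$state == "stalled" & s$t_start > sim$events$stall + 0.5
  expect_gt(sum(stalled), 20)
  expect_equal(mean(s$force[stalled]), 4, tolerance = 0.05)
})

test_that("excursion and detachment exclusions follow the stated rules", {
  # one interval parked at 250 nm -> excluded with reason "excursion";
  # 199 nm retained
  set.seed(7)
  x <- c(rnorm(1000, 199, 1), rnorm(1000, 250, 1))
  s <- suppressWarnings(trace_stiffness(make_trace(x), v_stall = 1e6))
  expect_false(s$excluded[1])
  expect_true(s$excluded[2])
  expect_match(s$reason[2], "excursion")
  # abrupt return from > 50 nm to the trap centre marks detachment
  sd_trap <- sqrt(4.1 / 0.025)
  x2 <- c(rnorm(3000, 120, 3), rnorm(2000, 0, sd_trap))
  s2 <- suppressWarnings(trace_stiffness(make_trace(x2)))
  expect_true(all(s2$state[4:5] == "detached"))
  expect_true(all(s2$state[1:3] != "detached"))
})

test_that("programmed detachment labels all later intervals detached", {
  link <- reference_link()
  sim <- simulate_trace(sim_config(duration = 6, link = link,
                                   stall_force = 2.5, detach_time = 3),
                        seed = 19)
  s <- trace_stiffness(sim$trace)
  late <- s$t_start >= 3.1          # one interval of relaxation slack
  expect_true(all(s$state[late] == "detached"))
  expect_true(all(s$state[s$t_end <= 2.9] != "detached"))
  # after detachment the trace reports the bare trap stiffness
  det <- s$state == "detached" & s$t_start >= 3.2
  expect_equal(mean(s$stiffness[det]), 0.025, tolerance = 0.05)
})

test_that("state classification matches the commanded schedule", {
  # shrink -> stall -> rescue -> regrow
  link <- reference_link()
  cfg <- sim_config(duration = 18, link = link, stall_force = 4,
                    v_shrink = 30, v_grow = 25, rescue_time = 12)
  sim <- simulate_trace(cfg, seed = 57)
  s <- trace_stiffness(sim$trace)
  truth_idx <- round((s$t_start + 0.05) * cfg$rate)
  truth_mode <- sim$truth$mode[pmin(truth_idx, nrow(sim$truth))]
  agree <- mean(s$state == truth_mode)
  expect_gt(agree, 0.9)
  # constant trace: all stalled
  set.seed(3)
  s0 <- trace_stiffness(make_trace(rnorm(5000, 20, 2)))
  expect_true(all(s0$state == "stalled"))
  # window larger than the series falls back to a single label
  expect_warning(
    classify_mt_state(trace_stiffness(make_trace(rnorm(2000)),
                                      max_excursion = NULL),
                      smoothing_window = 99),
    "window")
})

test_that("state-resolved binning pools experiments as independent units", {
  # single experiment, one state, one bin: plain mean, missing SEM
  set.seed(5)
  s <- suppressWarnings(trace_stiffness(make_trace(rnorm(3000, 30, 5))))
  tab <- state_resolved_binning(list(s))
  expect_equal(tab$mean_stiffness,
               mean(s$stiffness), tolerance = 1e-12)
  expect_true(is.na(tab$sem_stiffness))
  expect_equal(tab$n_experiments, 1L)
  # shrink and regrow phases from a state-independent linker law fall
  # on the same binned stiffness-force curve (within 2 combined SEM)
  link <- composite_link(powerlaw_spring(0.03, 1), mt = NULL, n = 1,
                         trap_stiffness = 0.025)
  sims <- lapply(c(71, 72, 73), function(sd)
    simulate_trace(sim_config(duration = 14, link = link, stall_force = 3.2,
                              v_shrink = 35, v_grow = 35, rescue_time = 7.5),
                   seed = sd))
  series <- lapply(sims, function(x) trace_stiffness(x$trace))
  tab2 <- state_resolved_binning(series)
  shr <- tab2[tab2$state == "shrinking", ]
  gro <- tab2[tab2$state == "growing", ]
  common <- intersect(shr$bin_lo, gro$bin_lo)
  common <- common[vapply(common, function(b) {
    shr$n_experiments[shr$bin_lo == b] > 1 && gro$n_experiments[gro$bin_lo == b] > 1
  }, logical(1))]
  expect_gte(length(common), 2)
  for (b in common) {
    i <- shr$bin_lo == b; j <- gro$bin_lo == b
    d <- abs(shr$mean_stiffness[i] - gro$mean_stiffness[j])
    tol <- 2 * sqrt(shr$sem_stiffness[i]^2 + gro$sem_stiffness[j]^2)
    expect_lt(d, max(tol, 0.1 * shr$mean_stiffness[i]))
  }
})

test_that("trace TSV and interval table round-trip losslessly", {
  tr <- simulate_ou_trace(0.1, duration = 0.5, mean_x = 25, seed = 2,
                          label = "rt-check")
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$position, tr$position, tolerance = 1e-6)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$trap_stiffness, tr$trap_stiffness)
  expect_equal(back$label, "rt-check")
  # missing header key is reported by name
  lines <- readLines(path)
  writeLines(lines[!grepl("trap_stiffness", lines)], path)
  expect_error(read_trace(path), "trap_stiffness_pn_per_nm")
  # interval table export
  s <- trace_stiffness(tr)
  p2 <- tempfile(fileext = ".tsv")
  write_interval_table(s, p2)
  tab <- read.table(p2, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(s))
  expect_equal(tab$stiffness_pn_per_nm, s$stiffness, tolerance = 1e-12)
})
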