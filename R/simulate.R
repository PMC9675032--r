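#' Configuration of a synthetic optical-trap experiment
#'
#' Collects everything the overdamped-Langevin simulator needs to
#' emulate a 10-kHz quadrant-detector recording of a bead held in a
#' harmonic trap and coupled through a nonlinear link to a microtubule
#' tip that shrinks, stalls, regrows and detaches.  The defaults mirror
#' the experimental conditions: Stokes drag of a 1-um bead in water,
#' trap stiffness in the 0.02-0.04 pN/nm range, 10-kHz output rate.
#'
#' @param duration trace length in s.
#' @param link a [composite_link()] describing the bead-microtubule
#'   connection (its `n` is the fixed attachment count), or `NULL` for
#'   a trap-only (detached) bead.
#' @param trap_stiffness trap stiffness, pN/nm.
#' @param gamma bead friction coefficient, pN s/nm.
#' @param kbt thermal energy, pN nm.
#' @param rate output sampling rate, Hz.
#' @param step integration step, s; must satisfy
#'   `step <= 0.1 gamma / c_max` (checked before integration).
#' @param v_shrink,v_grow tip speeds during depolymerisation / growth,
#'   nm/s.
#' @param stall_force tip stalls when the link force reaches this, pN
#'   (`NA`: never).
#' @param rescue_time,catastrophe_time,detach_time schedule triggers in
#'   s (`NA`: never).
#' @param detach_force force-triggered detachment, pN (`NA`: never).
#' @param trigger_tau time constant (s) of the exponential moving
#'   average of the link force on which the stall and force-detachment
#'   triggers act; the instantaneous link force carries the full
#'   thermal fluctuation (of order 1 pN), so force thresholds must see
#'   a filtered signal to have their commanded meaning.
#' @param initial_force starting link tension, pN (bead starts at its
#'   force-balance position).
#' @param boxcar_window detector model: number of integration substeps
#'   averaged per output sample (1 = instantaneous decimation, the
#'   default; the full `step`-to-output window emulates an integrating
#'   detector and visibly damps the measured variance once the corner
#'   frequency approaches the output Nyquist frequency).
#' @param noise_sd additive white detector noise per output sample, nm.
#' @param label experiment identifier.
#' @export
sim_config <- function(duration = 10, link = NULL, trap_stiffness = 0.025,
                       gamma = 8.4e-6, kbt = kbt_default, rate = 1e4,
                       step = 1e-6, v_shrink = 25, v_grow = 15,
                       stall_force = NA, rescue_time = NA,
                       catastrophe_time = NA, detach_time = NA,
                       detach_force = NA, initial_force = 0.5,
                       trigger_tau = 0.01, boxcar_window = 1, noise_sd = 0,
                       label = "sim") {
  stopifnot(duration > 0, trap_stiffness > 0, gamma > 0, rate > 0, step > 0)
  substeps <- round(1 / (rate * step))
  if (abs(substeps * rate * step - 1) > 1e-9)
    stop("sim_config: the output rate must divide 1/step")
  stopifnot(boxcar_window >= 1, boxcar_window <= substeps)
  structure(list(duration = duration, link = link,
                 trap_stiffness = trap_stiffness, gamma = gamma, kbt = kbt,
                 rate = rate, step = step, substeps = substeps,
                 v_shrink = v_shrink, v_grow = v_grow,
                 stall_force = stall_force, rescue_time = rescue_time,
                 catastrophe_time = catastrophe_time,
                 detach_time = detach_time, detach_force = detach_force,
                 initial_force = initial_force, trigger_tau = trigger_tau,
                 boxcar_window = as.integer(boxcar_window),
                 noise_sd = noise_sd, label = label),
            class = "sim_config")
}

# Tabulate the trap-free link force-extension relation by integrating
# the compliance 1/c_link over a log force grid, and prepend a linear
# slack ramp down to zero force.
.link_table <- function(link, f_min = 0.005, f_max = 12, n_nodes = 400) {
  fg <- exp(seq(log(f_min), log(f_max), length.out = n_nodes))
  cg <- link_stiffness(link, fg)
  comp <- 1 / cg
  s <- c(0, cumsum((comp[-1] + comp[-n_nodes]) / 2 * diff(fg)))
  s_slack <- -f_min / cg[1]
  list(s = c(s_slack, s), f = c(0, fg), fg = fg, cg = cg)
}

#' Simulate a bead trace with ground truth
#'
#' Integrates the overdamped Langevin dynamics of the bead in the trap,
#' pulled through the tabulated force-extension relation of the
#' composite link by a microtubule tip following the configured
#' shrink/stall/rescue/detach schedule.  Each substep advances the
#' locally linearised dynamics with the exact Ornstein-Uhlenbeck
#' (exponential) update, which is unconditionally stable and keeps the
#' stationary bead variance unbiased at any step size -- essential,
#' since the equipartition estimator this simulator validates reads
#' the stiffness directly off that variance.  The link table is built
#' by integrating the composite compliance (relative accuracy ~1e-3 or
#' better over the tabulated range).  Output is decimated (or
#' boxcar-averaged) to the detector rate.  A fixed seed gives a
#' bit-identical trace.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return object of class `simulated_trace`: list with `trace` (a
#'   [bead_trace()]), `truth` (data.frame: `time`, `tip`, `mode`,
#'   `n_attached`, `link_force`, `stiffness` -- the true local total
#'   stiffness at the operating point), `events` (achieved stall /
#'   rescue / catastrophe / detachment times, `NA` where not reached)
#'   and `config`.
#' @export
simulate_trace <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_out <- floor(config$duration * config$rate)
  has_link <- !is.null(config$link)
  if (has_link) {
    # Tabulate up to the largest force the schedule can reach (stall or
    # detachment trigger plus a thermal-fluctuation margin); the maximum
    # table slope then bounds the stiffness actually encountered, which
    # is what the step-stability criterion must hold against.
    f_reach <- suppressWarnings(
      min(config$stall_force + 2, config$detach_force + 1, na.rm = TRUE))
    if (!is.finite(f_reach)) {
      # no force-limiting trigger: bound the force by the total tip
      # travel the schedule allows (all of it going into link stretch)
      prov <- .link_table(config$link, f_max = 30)
      s_cap <- stats::approx(prov$f, prov$s,
                             xout = config$initial_force)$y +
        max(config$v_shrink, 0) * config$duration
      f_reach <- stats::approx(prov$s, prov$f, xout = s_cap, rule = 2)$y + 1
    }
    f_top <- max(6, f_reach, 2 * config$initial_force, na.rm = TRUE)
    tab <- .link_table(config$link, f_max = f_top)
    c_max <- config$trap_stiffness + max(tab$cg)
  } else {
    tab <- list(s = c(0, 1), f = c(0, 0), fg = c(1), cg = c(1))
    c_max <- config$trap_stiffness
  }
  if (config$step > 0.1 * config$gamma / c_max)
    stop(sprintf(paste0("simulate_trace: integration step %g s violates the ",
                        "stability bound 0.1*gamma/c_max = %g s"),
                 config$step, 0.1 * config$gamma / c_max))
  if (has_link) {
    x0 <- config$initial_force / config$trap_stiffness
    s0 <- stats::approx(tab$f, tab$s, xout = config$initial_force)$y
    tip0 <- x0 + s0
  } else {
    x0 <- 0; tip0 <- 0
  }
  raw <- .with_seed(seed,
    sim_langevin_cpp(n_out, config$substeps, config$step, config$gamma,
                     config$trap_stiffness, config$kbt, x0, tip0,
                     tab$s, tab$f, has_link,
                     config$v_shrink, config$v_grow,
                     as.numeric(config$stall_force),
                     as.numeric(config$rescue_time),
                     as.numeric(config$catastrophe_time),
                     as.numeric(config$detach_time),
                     as.numeric(config$detach_force), config$trigger_tau,
                     config$boxcar_window, config$noise_sd))
  trace <- bead_trace(raw$x, sampling_rate = config$rate,
                      trap_stiffness = config$trap_stiffness,
                      label = config$label)
  mode_lab <- c("shrinking", "stalled", "growing", "detached")[raw$mode + 1]
  attached <- raw$mode != 3L
  c_link_true <- rep(0, n_out)
  if (has_link && any(attached)) {
    c_link_true[attached] <- stats::approx(tab$fg, tab$cg,
                                           xout = pmax(raw$link_force[attached],
                                                       min(tab$fg)),
                                           rule = 2)$y
  }
  truth <- data.frame(time = trace$time, tip = raw$tip, mode = mode_lab,
                      n_attached = ifelse(attached & has_link,
                                          config$link$n, 0L),
                      link_force = raw$link_force,
                      stiffness = config$trap_stiffness + c_link_true)
  structure(list(trace = trace, truth = truth,
                 events = list(stall = raw$t_stall, rescue = raw$t_rescue,
                               catastrophe = raw$t_catastrophe,
                               detach = raw$t_detach),
                 config = config),
            class = "simulated_trace")
}

#' @export
print.simulated_trace <- function(x, ...) {
  ev <- unlist(x$events)
  cat(sprintf("<simulated_trace '%s'> %.3g s; events: %s\n",
              x$config$label, x$config$duration,
              paste(names(ev)[is.finite(ev)],
                    signif(ev[is.finite(ev)], 3), sep = "@",
                    collapse = ", ")))
  invisible(x)
}

#' Exact Ornstein-Uhlenbeck trace at a fixed operating point
#'
#' A stationary bead held at a constant total stiffness is an
#' Ornstein-Uhlenbeck process; its values on a uniform sampling grid
#' follow the exact AR(1) recursion
#' `x[i+1] = phi x[i] + sqrt(kbt/c (1 - phi^2)) xi`,
#' `phi = exp(-c dt / gamma)`, with no discretisation error.  This is
#' the reference generator for validating the equipartition interval
#' estimator.
#'
#' @param total_stiffness total restoring stiffness at the operating
#'   point, pN/nm.
#' @param duration trace length, s.
#' @param mean_x mean bead displacement, nm.
#' @param gamma friction coefficient, pN s/nm.
#' @param rate sampling rate, Hz.
#' @param trap_stiffness trap stiffness recorded in the metadata,
#'   pN/nm.
#' @param kbt thermal energy, pN nm.
#' @param seed RNG seed.
#' @param label trace label.
#' @export
simulate_ou_trace <- function(total_stiffness, duration, mean_x = 0,
                              gamma = 8.4e-6, rate = 1e4,
                              trap_stiffness = 0.025, kbt = kbt_default,
                              seed = NULL, label = "ou") {
  stopifnot(total_stiffness > 0, duration > 0)
  n <- floor(duration * rate)
  phi <- exp(-total_stiffness / (gamma * rate))
  sd_eq <- sqrt(kbt / total_stiffness)
  .with_seed(seed, {
    innov <- rnorm(n, sd = sd_eq * sqrt(1 - phi^2))
    x <- numeric(n)
    x[1] <- rnorm(1, sd = sd_eq)
    for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + innov[i]
    bead_trace(x + mean_x, sampling_rate = rate,
               trap_stiffness = trap_stiffness, label = label)
  })
}

#' Generate a set of synthetic experiments
#'
#' Produces `n_experiments` simulated traces that echo the four typical
#' single-experiment behaviours seen in the trap assay: stiffening to a
#' stall ended by detachment, stiffening ended by detachment before any
#' stall, stiffening to a stall rescued into regrowth, and
#' non-stiffening (laterally attached) recordings modelled by a
#' constant-stiffness link.  Stall and early-detachment forces are
#' drawn per experiment; child seeds derive deterministically from the
#' master seed, so an identical master seed reproduces the identical
#' set.
#'
#' @param base a [sim_config()] whose `link` carries the linker law
#'   shared by the stiffening behaviours.
#' @param n_experiments number of traces.
#' @param seed master seed.
#' @param behaviors character vector recycled over experiments; any of
#'   `"stall_detach"`, `"early_detach"`, `"rescue"`, `"none"`.
#' @param stall_range range the per-experiment stall force is drawn
#'   from, pN.
#' @param lateral_stiffness constant link stiffness of the
#'   non-stiffening behaviour, pN/nm.
#' @return list of `simulated_trace` objects.
#' @export
make_experiment_set <- function(base, n_experiments, seed = 1,
                                behaviors = c("stall_detach", "rescue",
                                              "early_detach", "none"),
                                stall_range = c(3, 5),
                                lateral_stiffness = 0.05) {
  stopifnot(n_experiments >= 1)
  behaviors <- rep_len(behaviors, n_experiments)
  .with_seed(seed, {
    child_seeds <- sample.int(2147483646L, n_experiments)
    stalls <- runif(n_experiments, stall_range[1], stall_range[2])
    lapply(seq_len(n_experiments), function(i) {
      cfg <- base
      cfg$label <- sprintf("%s-%02d-%s", base$label, i, behaviors[i])
      cfg$stall_force <- stalls[i]
      switch(behaviors[i],
        stall_detach = {
          cfg$detach_time <- 0.8 * cfg$duration
        },
        rescue = {
          cfg$rescue_time <- 0.6 * cfg$duration
        },
        early_detach = {
          cfg$stall_force <- NA
          cfg$detach_force <- runif(1, 1.5, 2.5)
        },
        none = {
          cfg$link <- composite_link(constant_spring(lateral_stiffness),
                                     mt = NULL, n = 1,
                                     trap_stiffness = cfg$trap_stiffness)
          cfg$detach_force <- runif(1, 2, 3)
        },
        stop("make_experiment_set: unknown behavior ", behaviors[i]))
      simulate_trace(cfg, seed = child_seeds[i])
    })
  })
}

#' Write / read the ground-truth sidecar of a simulated trace
#'
#' Event times and the per-sample truth table round-trip through plain
#' TSV next to the trace file.
#'
#' @param sim a `simulated_trace`.
#' @param path sidecar file path.
#' @export
write_truth <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ev <- unlist(sim$events)
  writeLines(sprintf("# %s=%.15g", names(ev), ev), con)
  write.table(sim$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  ev_chr <- sub("^# [^=]+=", "", hdr)
  ev_chr[ev_chr == "NA"] <- NA_character_
  ev <- as.list(as.numeric(ev_chr))
  names(ev) <- sub("^# ([^=]+)=.*$", "\\1", hdr)
  truth <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                      sep = "\t")
  list(events = ev, truth = truth)
}
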