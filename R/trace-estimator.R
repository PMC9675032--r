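#' Bead-position trace from an optical-trap experiment
#'
#' Container for a uniformly sampled 1-D bead displacement recording
#' (quadrant-detector signal projected on the microtubule axis, origin
#' at the trap centre), together with the trap metadata needed by the
#' stiffness estimator.
#'
#' @param position bead displacement in nm.
#' @param sampling_rate sampling rate in Hz (10 kHz is typical).
#' @param trap_stiffness trap stiffness in pN/nm (from PSD calibration,
#'   treated as a given input here).
#' @param time optional time stamps in s; reconstructed from
#'   `sampling_rate` when missing, and checked for uniformity (1 ppm)
#'   when given.
#' @param label free-text experiment identifier.
#' @export
bead_trace <- function(position, sampling_rate, trap_stiffness,
                       time = NULL, label = "") {
  stopifnot(is.numeric(position), length(position) >= 1,
            sampling_rate > 0, trap_stiffness > 0)
  if (is.null(time)) {
    time <- (seq_along(position) - 1) / sampling_rate
  } else {
    stopifnot(length(time) == length(position))
    if (length(time) > 2) {
      dt <- diff(time)
      if (diff(range(dt)) > 1e-6 * mean(dt))
        stop("bead_trace: sampling grid is not uniform within 1 ppm")
    }
  }
  structure(list(time = time, position = position,
                 sampling_rate = sampling_rate,
                 trap_stiffness = trap_stiffness, label = label),
            class = "bead_trace")
}

#' @export
print.bead_trace <- function(x, ...) {
  cat(sprintf("<bead_trace '%s'> %d samples at %g Hz (%.3f s), c_trap = %g pN/nm\n",
              x$label, length(x$position), x$sampling_rate,
              length(x$position) / x$sampling_rate, x$trap_stiffness))
  invisible(x)
}

#' Split a trace into fixed-length estimation intervals
#'
#' Contiguous, non-overlapping intervals of `round(dt * sampling_rate)`
#' samples; a trailing partial interval is dropped so that every
#' interval holds the same number of points (1000 at 10 kHz with the
#' default 0.1 s).
#'
#' @param trace a [bead_trace()].
#' @param dt interval length in s; `dt * sampling_rate` must be >= 10.
#' @return integer matrix with columns `start`, `end` (inclusive sample
#'   indices); zero rows if the trace is shorter than one interval.
#' @export
segment_trace <- function(trace, dt = 0.1) {
  n_pts <- round(dt * trace$sampling_rate)
  if (n_pts < 10) stop("segment_trace: need at least 10 samples per interval")
  n_int <- length(trace$position) %/% n_pts
  if (n_int == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  start <- (seq_len(n_int) - 1L) * n_pts + 1L
  cbind(start = start, end = start + n_pts - 1L)
}

#' Equipartition stiffness of one interval
#'
#' The quasi-equilibrium bead position drifts slowly while the
#' microtubule tip moves; it is estimated by an ordinary least-squares
#' line `f_k(t)` through the interval, and the stiffness is the thermal
#' energy over the mean squared residual (plain mean, divisor N):
#' `c_k = kbt / <(x_k(t) - f_k(t))^2>`.
#'
#' @param x bead positions in the interval, nm (>= 10 finite values).
#' @param t matching times in s.
#' @param kbt thermal energy, pN nm.
#' @return list with `slope` (nm/s), `intercept` (nm), `mean_x` (nm),
#'   `msr` (mean squared residual, nm^2) and `stiffness` (pN/nm;
#'   `Inf` when the samples lie exactly on a line).
#' @export
interval_stiffness <- function(x, t, kbt = kbt_default) {
  stopifnot(length(x) == length(t), length(x) >= 10,
            all(is.finite(x)), all(is.finite(t)))
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  mean_x <- mean(x)
  resid <- x - mean_x - slope * tc
  msr <- mean(resid^2)
  # a numerically exact line (residuals at rounding level) signals
  # infinite stiffness rather than a nonsense division
  degenerate <- msr <= 1e-20 * max(1, mean(x^2))
  list(slope = slope, intercept = mean_x - slope * mean(t), mean_x = mean_x,
       msr = msr, stiffness = if (degenerate) Inf else kbt / msr)
}

#' Force on the link from the mean bead displacement
#'
#' `F_k = c_trap * <x_k>`: positive when the bead is displaced from the
#' trap centre toward the microtubule tip, i.e. when the link is under
#' tension.
#'
#' @param mean_x mean bead displacement in nm.
#' @param trap_stiffness trap stiffness in pN/nm.
#' @export
interval_force <- function(mean_x, trap_stiffness) {
  stopifnot(all(is.finite(mean_x)), is.finite(trap_stiffness))
  trap_stiffness * mean_x
}

#' Time-traced stiffness of a bead trace
#'
#' Runs the interval scheme over a whole recording: segments the trace,
#' detrends each interval linearly, converts residual variance to a
#' stiffness and mean displacement to a force, then applies the
#' excursion/detachment exclusions and labels the microtubule state of
#' every interval.  This is the estimator that turns one experiment into
#' a stiffness-force relation.
#'
#' @param trace a [bead_trace()].
#' @param dt interval length, s.
#' @param kbt thermal energy, pN nm.
#' @param max_excursion excursion exclusion threshold, nm (see
#'   [apply_exclusions()]); `NULL` skips exclusion and state labelling.
#' @param v_stall,smoothing_window state-classification parameters (see
#'   [classify_mt_state()]).
#' @return A `stiffness_series`: data.frame with one row per interval
#'   (columns `k`, `t_start`, `t_end`, `slope`, `intercept`, `mean_x`,
#'   `n_points`, `stiffness`, `force`, `state`, `excluded`, `reason`)
#'   and attributes `trap_stiffness`, `kbt`, `dt`, `label`.
#' @export
trace_stiffness <- function(trace, dt = 0.1, kbt = kbt_default,
                            max_excursion = 200, v_stall = 5,
                            smoothing_window = 5) {
  seg <- segment_trace(trace, dt)
  n_int <- nrow(seg)
  cols <- c("k", "t_start", "t_end", "slope", "intercept", "mean_x",
            "n_points", "stiffness", "force")
  if (n_int == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$state <- character(0); out$excluded <- logical(0); out$reason <- character(0)
    return(.as_series(out, trace, dt, kbt))
  }
  rows <- lapply(seq_len(n_int), function(i) {
    idx <- seg[i, 1]:seg[i, 2]
    est <- interval_stiffness(trace$position[idx], trace$time[idx], kbt)
    data.frame(k = i, t_start = trace$time[seg[i, 1]],
               t_end = trace$time[seg[i, 2]] + 1 / trace$sampling_rate,
               slope = est$slope, intercept = est$intercept,
               mean_x = est$mean_x, n_points = length(idx),
               stiffness = est$stiffness,
               force = interval_force(est$mean_x, trace$trap_stiffness))
  })
  out <- do.call(rbind, rows)
  out$state <- NA_character_
  out$excluded <- !is.finite(out$stiffness)
  out$reason <- ifelse(out$excluded, "infinite-stiffness", "")
  out <- .as_series(out, trace, dt, kbt)
  if (!is.null(max_excursion)) {
    out <- apply_exclusions(out, max_excursion = max_excursion)
    out <- classify_mt_state(out, v_stall = v_stall,
                             smoothing_window = smoothing_window)
  }
  out
}

.as_series <- function(df, trace, dt, kbt) {
  structure(df, class = c("stiffness_series", "data.frame"),
            trap_stiffness = trace$trap_stiffness, kbt = kbt, dt = dt,
            label = trace$label)
}

.append_reason <- function(reason, add) {
  ifelse(reason == "", add, paste(reason, add, sep = ";"))
}

#' Excursion and detachment exclusions
#'
#' Two rules: (i) intervals whose mean displacement exceeds
#' `max_excursion` (beyond which detector and trap calibrations are no
#' longer linear) are flagged excluded; (ii) an abrupt return of the
#' mean position, within one interval, from beyond `detach_from` nm to
#' within two trap-level standard deviations (`2 sqrt(kbt/c_trap)`) of
#' the trap centre marks a detachment, and every interval from that
#' point on is labelled `detached` (after detachment the bead reports
#' the bare trap, not the link).  Flags are additive; reasons are
#' recorded.
#'
#' @param series a `stiffness_series` from [trace_stiffness()].
#' @param max_excursion excursion threshold, nm.
#' @param detach_from minimum pre-return displacement, nm.
#' @export
apply_exclusions <- function(series, max_excursion = 200, detach_from = 50) {
  stopifnot(inherits(series, "stiffness_series"))
  if (nrow(series) == 0) return(series)
  far <- abs(series$mean_x) > max_excursion
  series$excluded <- series$excluded | far
  series$reason[far] <- .append_reason(series$reason[far], "excursion")
  sd_trap <- sqrt(attr(series, "kbt") / attr(series, "trap_stiffness"))
  near0 <- abs(series$mean_x) < 2 * sd_trap
  if (nrow(series) >= 2) {
    came_far <- c(FALSE, abs(series$mean_x[-nrow(series)]) > detach_from)
    hit <- which(near0 & came_far)
    if (length(hit) > 0) {
      k0 <- hit[1]
      det <- seq(k0, nrow(series))
      series$state[det] <- "detached"
      series$reason[det] <- .append_reason(series$reason[det], "detached")
    }
  }
  series
}

#' Label the microtubule state of each interval
#'
#' The trend slope of the quasi-equilibrium bead position, smoothed by a
#' running median over `smoothing_window` intervals, classifies each
#' interval: slope above `+v_stall` means the bead is being pulled away
#' from the trap centre by a shrinking microtubule, below `-v_stall`
#' the tension is relaxing under regrowth, and in between the
#' microtubule is stalled.  Intervals already labelled `detached` keep
#' that label.
#'
#' @param series a `stiffness_series`.
#' @param v_stall slope threshold in nm/s.
#' @param smoothing_window running-median window (intervals; made odd
#'   internally).
#' @export
classify_mt_state <- function(series, v_stall = 5, smoothing_window = 5) {
  stopifnot(inherits(series, "stiffness_series"))
  n <- nrow(series)
  if (n == 0) return(series)
  live <- is.na(series$state) | series$state != "detached"
  sl <- series$slope[live]
  if (length(sl) == 0) return(series)
  w <- min(smoothing_window, length(sl))
  if (smoothing_window > length(sl)) {
    warning("classify_mt_state: smoothing window exceeds the series; using the overall mean slope")
    sm <- rep(mean(sl), length(sl))
  } else {
    if (w %% 2 == 0) w <- w + 1
    sm <- if (w >= 3 && length(sl) >= w) runmed(sl, w, endrule = "median") else sl
  }
  lab <- ifelse(sm > v_stall, "shrinking",
                ifelse(sm < -v_stall, "growing", "stalled"))
  series$state[live] <- lab
  series
}

#' State-resolved binned stiffness-force relations
#'
#' Bins the (force, stiffness) pairs of a set of experiments in 1-pN
#' force bins, separately for shrinking, stalled and growing intervals.
#' Each experiment is first reduced to its own per-bin means and then
#' treated as one independent unit, so the standard errors reflect
#' between-experiment scatter.
#'
#' @param series_list list of `stiffness_series` (one per experiment).
#' @param bin_width force bin width, pN.
#' @param states states to resolve.
#' @return data.frame with columns `state`, `bin_lo`, `bin_hi`,
#'   `mean_force`, `sem_force`, `mean_stiffness`, `sem_stiffness`,
#'   `n_experiments`, `n_intervals`.  SEMs are `NA` with a single
#'   contributing experiment; empty bins are omitted.
#' @export
state_resolved_binning <- function(series_list, bin_width = 1,
                                   states = c("shrinking", "stalled", "growing")) {
  if (inherits(series_list, "stiffness_series")) series_list <- list(series_list)
  per_exp <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    use <- !s$excluded & !is.na(s$state) & s$state %in% states &
      is.finite(s$stiffness)
    if (!any(use)) next
    d <- s[use, c("force", "stiffness", "state")]
    d$bin <- floor(d$force / bin_width)
    agg <- do.call(rbind, lapply(split(d, list(d$state, d$bin), drop = TRUE),
      function(g) data.frame(state = g$state[1], bin = g$bin[1],
                             force = mean(g$force),
                             stiffness = mean(g$stiffness), n = nrow(g))))
    agg$experiment <- i
    per_exp[[length(per_exp) + 1]] <- agg
  }
  if (length(per_exp) == 0)
    return(data.frame(state = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), mean_force = numeric(0),
                      sem_force = numeric(0), mean_stiffness = numeric(0),
                      sem_stiffness = numeric(0),
                      n_experiments = integer(0), n_intervals = integer(0)))
  all <- do.call(rbind, per_exp)
  out <- do.call(rbind, lapply(split(all, list(all$state, all$bin), drop = TRUE),
    function(g) {
      ne <- nrow(g)
      data.frame(state = g$state[1], bin_lo = g$bin[1] * bin_width,
                 bin_hi = (g$bin[1] + 1) * bin_width,
                 mean_force = mean(g$force),
                 sem_force = if (ne > 1) sd(g$force) / sqrt(ne) else NA_real_,
                 mean_stiffness = mean(g$stiffness),
                 sem_stiffness = if (ne > 1) sd(g$stiffness) / sqrt(ne) else NA_real_,
                 n_experiments = ne, n_intervals = sum(g$n))
    }))
  out <- out[order(out$state, out$bin_lo), ]
  rownames(out) <- NULL
  out
}

#' Write / read a bead trace as annotated TSV
#'
#' Plain-text interchange format: '#'-prefixed header lines
#' `# sampling_rate_hz=`, `# trap_stiffness_pn_per_nm=`, `# label=`,
#' followed by tab-separated columns `time_s` and `position_nm`.  The
#' reader tolerates a missing time column (reconstructed from the rate)
#' and reports malformed or missing header keys by name.  Round-trip is
#' lossless to 1e-6 nm.
#'
#' @param trace a [bead_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", trace$sampling_rate),
               sprintf("# trap_stiffness_pn_per_nm=%.10g", trace$trap_stiffness),
               sprintf("# label=%s", trace$label),
               "time_s\tposition_nm"), con)
  writeLines(sprintf("%.9f\t%.6f", trace$time, trace$position), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_key <- function(key, required = TRUE) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(hit) == 0) {
      if (required) stop(sprintf("read_trace: missing header key '%s' in %s",
                                 key, path))
      return(NULL)
    }
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  rate <- as.numeric(get_key("sampling_rate_hz"))
  ctrap <- as.numeric(get_key("trap_stiffness_pn_per_nm"))
  if (!is.finite(rate) || !is.finite(ctrap))
    stop("read_trace: non-numeric sampling_rate_hz or trap_stiffness_pn_per_nm header")
  label <- get_key("label", required = FALSE)
  body <- lines[!grepl("^#", lines)]
  dat <- read.table(text = body, header = TRUE, sep = "\t")
  if ("position_nm" %in% names(dat)) {
    pos <- dat$position_nm
    tim <- if ("time_s" %in% names(dat)) dat$time_s else NULL
  } else if (ncol(dat) == 1) {          # time column omitted entirely
    pos <- dat[[1]]
    tim <- NULL
  } else stop("read_trace: no position_nm column found")
  bead_trace(pos, sampling_rate = rate, trap_stiffness = ctrap,
             time = tim, label = if (is.null(label)) "" else label)
}

#' Export an interval table as TSV
#'
#' @param series a `stiffness_series`.
#' @param path file path.
#' @export
write_interval_table <- function(series, path) {
  df <- data.frame(k = series$k, t_start_s = series$t_start,
                   slope_nm_per_s = series$slope, mean_x_nm = series$mean_x,
                   force_pn = series$force,
                   stiffness_pn_per_nm = series$stiffness,
                   state = series$state, excluded = series$excluded,
                   reason = series$reason)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
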