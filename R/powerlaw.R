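#' Robust power-law fit of a stiffness-force relation
#'
#' Fits `c(F) = a F^m + c0` by minimising the Huber loss of the
#' residuals, which keeps occasional gross stiffness outliers (e.g.
#' transient multi-linker events) from dragging the exponent.  The
#' Huber threshold is `huber_k` times a robust residual scale
#' (1.4826 MAD of the residuals of an initial least-squares pass); when
#' the data are clean enough that no residual exceeds the threshold the
#' fit coincides with ordinary least squares.  For each candidate
#' exponent the linear parameters `(a, c0)` are profiled out exactly
#' (iteratively reweighted least squares in the Huber case), and the
#' profiled loss is minimised over `m` alone, bracketed by the
#' `m_starts` grid; parameters are bounded (`a > 0`,
#' `0 < m <= m_max`, `0 <= c0 <= c0_max` -- the offset bound reflects
#' that `c0` absorbs the trap stiffness, 0.01-0.025 pN/nm).
#'
#' @param force forces in pN (all > 0).
#' @param stiffness stiffnesses in pN/nm.
#' @param huber_k Huber threshold in robust-scale units.
#' @param m_starts exponent multi-start grid.
#' @param m_max,c0_max parameter bounds.
#' @return object of class `powerlaw_fit`: list with `amplitude`,
#'   `exponent`, `offset`, `loss`, `delta` (Huber threshold; `Inf`
#'   means plain least squares), `converged`, `n`.
#' @export
fit_power_law <- function(force, stiffness, huber_k = 1.345,
                          m_starts = c(0.5, 1, 1.5, 2, 3),
                          m_max = 5, c0_max = 0.05) {
  keep <- is.finite(force) & is.finite(stiffness)
  force <- force[keep]; stiffness <- stiffness[keep]
  if (length(force) < 4)
    stop("fit_power_law: need at least 4 finite (force, stiffness) points")
  if (any(force <= 0)) stop("fit_power_law: forces must be positive")
  if (diff(range(force)) == 0)
    stop("fit_power_law: all points at a single force; exponent not identifiable")

  huber_loss <- function(r, delta) {
    if (!is.finite(delta)) return(sum(r^2) / 2)
    ar <- abs(r)
    sum(ifelse(ar <= delta, r^2 / 2, delta * (ar - delta / 2)))
  }
  # For fixed exponent m the model is linear in (a, c0); solve that
  # inner problem exactly (IRLS for the Huber case), respecting the
  # bound constraints by solving on the active set.
  inner_fit <- function(m, delta) {
    fm <- force^m
    solve_wls <- function(w, fix_c0 = NULL) {
      if (is.null(fix_c0)) {
        sw <- sum(w); sx <- sum(w * fm); sxx <- sum(w * fm^2)
        sy <- sum(w * stiffness); sxy <- sum(w * fm * stiffness)
        det <- sxx * sw - sx^2
        if (abs(det) < 1e-300) return(c(NA_real_, NA_real_))
        a <- (sxy * sw - sx * sy) / det
        c0 <- (sy - a * sx) / sw
        c(a, c0)
      } else {
        a <- sum(w * fm * (stiffness - fix_c0)) / sum(w * fm^2)
        c(a, fix_c0)
      }
    }
    p <- solve_wls(rep(1, length(fm)))
    for (it in seq_len(60)) {
      # clamp to the feasible region, re-solving on the active set
      fix <- NULL
      if (p[2] < 0) fix <- 0 else if (p[2] > c0_max) fix <- c0_max
      if (!is.null(fix)) p <- solve_wls(rep(1, length(fm)), fix)
      if (!is.finite(delta)) break
      r <- stiffness - (p[1] * fm + p[2])
      w <- pmin(1, delta / pmax(abs(r), 1e-300))
      p_new <- solve_wls(w)
      if (is.na(p_new[1])) break
      if (p_new[2] < 0) p_new <- solve_wls(w, 0)
      else if (p_new[2] > c0_max) p_new <- solve_wls(w, c0_max)
      if (max(abs(p_new - p)) < 1e-12 * max(abs(p), 1e-12)) { p <- p_new; break }
      p <- p_new
    }
    p[1] <- max(p[1], 1e-10)
    p[2] <- min(max(p[2], 0), c0_max)
    list(par = p, loss = huber_loss(stiffness - (p[1] * fm + p[2]), delta))
  }
  run <- function(delta) {
    prof <- function(m) inner_fit(m, delta)$loss
    grid <- sort(unique(pmin(pmax(m_starts, 1e-3), m_max)))
    losses <- vapply(grid, prof, numeric(1))
    i <- which.min(losses)
    lo <- if (i == 1) 1e-6 else grid[i - 1]
    hi <- if (i == length(grid)) m_max else grid[i + 1]
    opt <- optimize(prof, c(lo, hi), tol = 1e-9)
    m <- opt$minimum
    fit <- inner_fit(m, delta)
    list(par = c(fit$par[1], m, fit$par[2]), value = fit$loss)
  }
  ls_fit <- run(Inf)
  r0 <- stiffness - (ls_fit$par[1] * force^ls_fit$par[2] + ls_fit$par[3])
  # iterate the robust scale once on the Huber fit's own residuals
  delta <- Inf
  fit <- ls_fit
  for (pass in 1:2) {
    scale <- mad(r0, center = 0)
    if (scale < 1e-10 * max(abs(stiffness), 1e-12)) break
    delta <- huber_k * scale
    if (!is.finite(delta)) break
    fit <- run(delta)
    r0 <- stiffness - (fit$par[1] * force^fit$par[2] + fit$par[3])
  }
  structure(list(amplitude = fit$par[1], exponent = fit$par[2],
                 offset = fit$par[3], loss = fit$value, delta = delta,
                 converged = all(is.finite(fit$par)), n = length(force)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("c(F) = %.4g F^%.3f + %.4g  [pN/nm; %d points, loss %.4g%s]\n",
              x$amplitude, x$exponent, x$offset, x$n, x$loss,
              if (!isTRUE(x$converged)) "; NOT converged" else ""))
  invisible(x)
}

#' Per-experiment stiffening exponents
#'
#' Applies the robust power-law fit to every experiment individually and
#' summarises the exponents by their median.  Only experiments with at
#' least `min_intervals` usable intervals (>= 1 s attached at the
#' default 0.1-s interval) qualify.  Optionally, experiments without
#' recognisable stiffening -- interpreted as lateral attachments -- are
#' screened out by a one-sided Spearman correlation of stiffness with
#' force.
#'
#' @param series_list list of `stiffness_series`.
#' @param min_intervals minimum number of non-excluded intervals.
#' @param stiffening_screen drop experiments without a significant
#'   positive stiffness-force correlation.
#' @param screen_alpha one-sided Spearman p-value threshold.
#' @param ... passed to [fit_power_law()].
#' @return list with `exponents` (one per qualifying experiment, named
#'   by label where available), `median`, `fits` and `n_skipped`.
#' @export
per_experiment_exponents <- function(series_list, min_intervals = 10,
                                     stiffening_screen = TRUE,
                                     screen_alpha = 0.05, ...) {
  if (inherits(series_list, "stiffness_series")) series_list <- list(series_list)
  fits <- list(); expo <- numeric(0); skipped <- 0L
  for (s in series_list) {
    use <- !s$excluded & is.finite(s$stiffness) &
      (is.na(s$state) | s$state != "detached") & s$force > 0
    if (sum(use) < min_intervals) { skipped <- skipped + 1L; next }
    f <- s$force[use]; cc <- s$stiffness[use]
    if (stiffening_screen) {
      ct <- suppressWarnings(
        cor.test(f, cc, method = "spearman", alternative = "greater"))
      if (!is.finite(ct$p.value) || ct$p.value >= screen_alpha) {
        skipped <- skipped + 1L; next
      }
    }
    fit <- fit_power_law(f, cc, ...)
    lbl <- attr(s, "label")
    nm <- if (!is.null(lbl) && nzchar(lbl)) lbl else sprintf("exp%d", length(expo) + 1L)
    expo[nm] <- fit$exponent
    fits[[nm]] <- fit
  }
  list(exponents = expo,
       median = if (length(expo)) median(expo) else NA_real_,
       fits = fits, n_skipped = skipped)
}

#' Bin a stiffness-force relation
#'
#' Left-closed right-open force bins `[k w, (k+1) w)` starting at zero;
#' per-bin means and standard errors of force and stiffness.  Empty
#' bins are omitted; SEM is `NA` for single-point bins.
#'
#' @param force forces, pN.
#' @param stiffness stiffnesses, pN/nm.
#' @param width bin width, pN.
#' @export
bin_stiffness <- function(force, stiffness, width = 1) {
  keep <- is.finite(force) & is.finite(stiffness)
  force <- force[keep]; stiffness <- stiffness[keep]
  stopifnot(length(force) >= 1)
  b <- floor(force / width)
  out <- do.call(rbind, lapply(split(seq_along(force), b), function(i) {
    data.frame(bin_lo = b[i[1]] * width, bin_hi = (b[i[1]] + 1) * width,
               mean_force = mean(force[i]),
               sem_force = if (length(i) > 1) sd(force[i]) / sqrt(length(i)) else NA_real_,
               mean_stiffness = mean(stiffness[i]),
               sem_stiffness = if (length(i) > 1) sd(stiffness[i]) / sqrt(length(i)) else NA_real_,
               n = length(i))
  }))
  out <- out[order(out$bin_lo), ]
  rownames(out) <- NULL
  out
}

#' Local log-log slope of a stiffness curve
#'
#' Central difference of `log c` versus `log F`; the local stiffening
#' exponent of any positive curve (3/2 for the microtubule, 2 for the
#' strong-force Ndc80 chain, 5/2 for the protofilament flare).
#'
#' @param curve function of force returning a positive value.
#' @param force evaluation force(s), pN.
#' @param rel_step relative force step.
#' @export
local_loglog_slope <- function(curve, force, rel_step = 1e-3) {
  vapply(force, function(f) {
    hi <- curve(f * (1 + rel_step)); lo <- curve(f * (1 - rel_step))
    if (!all(is.finite(c(hi, lo))) || hi <= 0 || lo <= 0)
      stop("local_loglog_slope: curve must be positive near the evaluation force")
    (log(hi) - log(lo)) / (log(1 + rel_step) - log(1 - rel_step))
  }, numeric(1))
}
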