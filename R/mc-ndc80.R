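# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Inverse-CDF draw from the exponentially tilted density ~ exp(s*u) on
# [lo, hi]; stable for any tilt (written with decaying exponentials)
# and vectorised over the tilt parameter.
.rtilted <- function(n, s, lo, hi) {
  r <- runif(n)
  s <- rep_len(s, n)
  w <- s * (hi - lo)
  out <- lo + r * (hi - lo)
  big <- abs(w) >= 1e-8
  out[big] <- hi + log(r[big] + (1 - r[big]) * exp(-w[big])) / s[big]
  out
}

#' Monte Carlo sampler of the confined two-bond FJC
#'
#' Draws exact Boltzmann samples of the confined chain: the polar
#' cosines of the two arms are drawn from their exponentially tilted
#' marginals by inverse-CDF sampling, and the only remaining
#' constraint, `z = a cos(theta_a) + b cos(theta_b) > 0`, is enforced
#' by rejection (the half-space constraint on the hinge,
#' `cos(theta_a) > 0`, is built into the proposal).  Azimuths are
#' uniform.  The sampler is the independent oracle for the closed-form
#' partition function, extension, stiffness (via `kbt / Var(z)`) and
#' inter-arm angle.
#'
#' @param force tension in pN (>= 0).
#' @param geom an [fjc_ndc80()] geometry.
#' @param n_samples number of retained samples (>= 1000).
#' @param seed RNG seed for reproducibility.
#' @return data.frame with columns `z` (nm) and `angle` (degrees;
#'   0 = fully stretched), with attribute `acceptance`.
#' @export
sample_fjc <- function(force, geom = fjc_ndc80(), n_samples = 1e5,
                       seed = NULL) {
  stopifnot(length(force) == 1L, force >= 0, n_samples >= 1e3)
  a <- geom$arm_long; b <- geom$arm_short
  f <- force / geom$kbt
  .with_seed(seed, {
    z <- numeric(0); ang <- numeric(0)
    tried <- 0L; got <- 0L
    while (got < n_samples) {
      m <- as.integer(1.3 * (n_samples - got)) + 100L
      ua <- .rtilted(m, f * a, 0, 1)
      ub <- .rtilted(m, f * b, -1, 1)
      ok <- a * ua + b * ub > 0
      tried <- tried + m
      if (tried > 100 * n_samples && sum(ok) == 0)
        stop("sample_fjc: acceptance below 1e-4; use importance sampling")
      ua <- ua[ok]; ub <- ub[ok]
      dphi <- runif(length(ua), 0, 2 * pi)
      cg <- ua * ub + sqrt(1 - ua^2) * sqrt(pmax(0, 1 - ub^2)) * cos(dphi)
      z <- c(z, a * ua + b * ub)
      ang <- c(ang, acos(pmin(pmax(cg, -1), 1)) * 180 / pi)
      got <- length(z)
    }
    out <- data.frame(z = z[seq_len(n_samples)],
                      angle = ang[seq_len(n_samples)])
    attr(out, "acceptance") <- got / tried
    out
  })
}

# Rotate rows of (x,y,z) matrices by per-replica axis-angle (Rodrigues).
.rotate_rows <- function(tx, ty, tz, ux, uy, uz, ang) {
  ca <- cos(ang); sa <- sin(ang)
  dot <- ux * tx + uy * ty + uz * tz
  cx <- uy * tz - uz * ty
  cy <- uz * tx - ux * tz
  cz <- ux * ty - uy * tx
  list(x = tx * ca + cx * sa + ux * dot * (1 - ca),
       y = ty * ca + cy * sa + uy * dot * (1 - ca),
       z = tz * ca + cz * sa + uz * dot * (1 - ca))
}

#' Semiflexible (worm-like) Ndc80 arms by Metropolis Monte Carlo
#'
#' Relaxes the rigid-rod idealisation of the two Ndc80 arms: each arm
#' becomes a discrete worm-like chain of `n_seg` segments with bending
#' stiffness `kbt * lp_arm / l` per joint, joined by a free hinge, under
#' tension `F` and the same half-space constraints as the FJC
#' (`z_hinge > 0`, `z > 0`).  Sampling mixes local segment-cone moves
#' (which relax the internal arm shape) with Gibbs-type rigid rotations
#' of a whole arm whose new global orientation is drawn directly from
#' the exponentially tilted Boltzmann marginal of the arm's end-to-end
#' vector -- rejection-free up to the half-space constraints, which
#' keeps the chain rapidly mixing even in the stiff-arm limit.  Several
#' independent replicas run in parallel and the stiffness follows from
#' the fluctuation identity `c = kbt / Var(z)`.  In the rigid limit (`lp_arm` much longer than
#' the arms) the result converges to the closed-form FJC stiffness; at
#' coiled-coil persistence lengths (>~ 100 nm) it stays close to it,
#' quantifying that arm semiflexibility is a minor correction.
#'
#' @param force tension in pN.
#' @param arm_long,arm_short arm lengths, nm.
#' @param lp_arm persistence length of both arms, nm.
#' @param n_seg segments per arm (>= 8).
#' @param kbt thermal energy, pN nm.
#' @param n_replicas independent Metropolis replicas.
#' @param n_iter post-burn-in iterations per replica.
#' @param burnin burn-in iterations.
#' @param thin retain one sample per `thin` iterations.
#' @param seed RNG seed.
#' @return list with `stiffness` (pN/nm), `stderr`, `mean_z`, `var_z`,
#'   `acceptance`, `n_samples`, and `geweke_z` (equilibration
#'   diagnostic; a warning is raised when |z| > 3).
#' @export
wormlike_stiffness <- function(force, arm_long = 40, arm_short = 16,
                               lp_arm = 150, n_seg = 8, kbt = kbt_default,
                               n_replicas = 100, n_iter = 15000,
                               burnin = 3000, thin = 25, seed = NULL) {
  stopifnot(n_seg >= 8, force >= 0, lp_arm > 0)
  la <- arm_long / n_seg; lb <- arm_short / n_seg
  ns <- 2L * n_seg
  idx_a <- seq_len(n_seg); idx_b <- n_seg + seq_len(n_seg)
  len <- c(rep(la, n_seg), rep(lb, n_seg))
  kappa <- kbt * lp_arm / c(rep(la, n_seg), rep(lb, n_seg)) # per-joint bending
  beta <- 1 / kbt
  # cone width for local moves: ~ thermal bend angle, clamped
  sig <- pmin(0.6, pmax(0.02, sqrt(1 / (beta * kappa))))
  .with_seed(seed, {
    R <- n_replicas
    tx <- matrix(0, R, ns); ty <- matrix(0, R, ns); tz <- matrix(1, R, ns)
    z_of <- function() tz %*% len
    za_of <- function() la * rowSums(tz[, idx_a, drop = FALSE])
    acc <- 0; prop <- 0
    keep_z <- matrix(NA_real_, R, 0)
    samples <- vector("list", 0)
    total <- burnin + n_iter
    for (it in seq_len(total)) {
      if (it %% 3 != 0) {
        # local cone move on one random segment per replica
        j <- sample.int(ns, R, replace = TRUE)
        ij <- cbind(seq_len(R), j)
        ox <- tx[ij]; oy <- ty[ij]; oz <- tz[ij]
        s <- sig[j]
        nx <- ox + s * rnorm(R); ny <- oy + s * rnorm(R); nz <- oz + s * rnorm(R)
        nrm <- sqrt(nx^2 + ny^2 + nz^2)
        nx <- nx / nrm; ny <- ny / nrm; nz <- nz / nrm
        # bending energy change with the (same-arm) neighbours
        dE <- numeric(R)
        for (off in c(-1L, 1L)) {
          jn <- j + off
          same_arm <- jn >= 1 & jn <= ns &
            ((j <= n_seg) == (jn <= n_seg))  # no coupling across the hinge
          if (any(same_arm)) {
            ijn <- cbind(seq_len(R)[same_arm], jn[same_arm])
            doto <- ox[same_arm] * tx[ijn] + oy[same_arm] * ty[ijn] +
              oz[same_arm] * tz[ijn]
            dotn <- nx[same_arm] * tx[ijn] + ny[same_arm] * ty[ijn] +
              nz[same_arm] * tz[ijn]
            dE[same_arm] <- dE[same_arm] + kappa[j[same_arm]] * (doto - dotn)
          }
        }
        dz <- len[j] * (nz - oz)
        dE <- dE - force * dz
        za_new <- za_of() + ifelse(j <= n_seg, la * (nz - oz), 0)
        z_new <- z_of() + dz
        ok <- (runif(R) < exp(-beta * dE)) & za_new > 0 & z_new > 0
        if (any(ok)) {
          ijk <- ij[ok, , drop = FALSE]
          tx[ijk] <- nx[ok]; ty[ijk] <- ny[ok]; tz[ijk] <- nz[ok]
        }
        acc <- acc + sum(ok); prop <- prop + R
      } else {
        # Gibbs rotation of one whole arm: the stretching energy of an
        # arm depends on its end-to-end vector only through the polar
        # cosine u of its direction, with weight exp(beta*F*L_ree*u);
        # drawing the new orientation from exactly that tilted density
        # makes the Metropolis ratio unity, so the move is accepted
        # unless it violates a half-space constraint.
        use_a <- (it %% 2 == 0)
        cols <- if (use_a) idx_a else idx_b
        li <- if (use_a) la else lb
        rx <- li * rowSums(tx[, cols, drop = FALSE])
        ry <- li * rowSums(ty[, cols, drop = FALSE])
        rz <- li * rowSums(tz[, cols, drop = FALSE])
        lree <- sqrt(rx^2 + ry^2 + rz^2)
        lree[lree < 1e-12] <- 1e-12
        dx <- rx / lree; dy <- ry / lree; dz <- rz / lree
        u_new <- .rtilted(R, beta * force * lree, -1, 1)
        phi_new <- runif(R, 0, 2 * pi)
        sn <- sqrt(pmax(0, 1 - u_new^2))
        ex <- sn * cos(phi_new); ey <- sn * sin(phi_new); ez <- u_new
        # rotation taking d -> e (Rodrigues about d x e)
        cx <- dy * ez - dz * ey
        cy <- dz * ex - dx * ez
        cz <- dx * ey - dy * ex
        s_ang <- sqrt(cx^2 + cy^2 + cz^2)
        c_ang <- dx * ex + dy * ey + dz * ez
        ang <- atan2(s_ang, c_ang)
        deg <- s_ang < 1e-12          # (anti)parallel: no unique axis
        ax <- ifelse(deg, 1, cx / pmax(s_ang, 1e-12))
        ay <- ifelse(deg, 0, cy / pmax(s_ang, 1e-12))
        az <- ifelse(deg, 0, cz / pmax(s_ang, 1e-12))
        ang[deg & c_ang > 0] <- 0     # parallel: identity
        # antiparallel with deg: rotate pi about an axis orthogonal to d
        anti <- deg & c_ang < 0
        if (any(anti)) {
          hx <- -dy[anti]; hy <- dx[anti]
          hz <- rep(0, sum(anti))
          hn <- sqrt(hx^2 + hy^2)
          small <- hn < 1e-12
          hx[small] <- 1; hy[small] <- 0; hn[small] <- 1
          ax[anti] <- hx / hn; ay[anti] <- hy / hn; az[anti] <- hz
          ang[anti] <- pi
        }
        rot <- .rotate_rows(tx[, cols, drop = FALSE],
                            ty[, cols, drop = FALSE],
                            tz[, cols, drop = FALSE], ax, ay, az, ang)
        ntz_cols <- rot$z
        if (use_a) {
          za_new <- la * rowSums(ntz_cols)
          z_new <- za_new + lb * rowSums(tz[, idx_b, drop = FALSE])
        } else {
          za_new <- za_of()
          z_new <- za_new + lb * rowSums(ntz_cols)
        }
        ok <- za_new > 0 & z_new > 0
        if (any(ok)) {
          tx[ok, cols] <- rot$x[ok, , drop = FALSE]
          ty[ok, cols] <- rot$y[ok, , drop = FALSE]
          tz[ok, cols] <- ntz_cols[ok, , drop = FALSE]
        }
        acc <- acc + sum(ok); prop <- prop + R
      }
      if (it > burnin && (it - burnin) %% thin == 0)
        samples[[length(samples) + 1]] <- as.vector(z_of())
    }
    zmat <- do.call(cbind, samples)   # R x n_kept
    zs <- as.vector(zmat)
    vz <- var(zs)
    # between-replica spread of the per-replica variance -> stderr
    vrep <- apply(zmat, 1, var)
    se_v <- sd(vrep) / sqrt(R)
    # Geweke-style diagnostic on the time course of the replica-mean z
    traj <- colMeans(zmat)
    n1 <- max(2, floor(length(traj) * 0.1))
    n2 <- max(2, floor(length(traj) * 0.5))
    g1 <- traj[seq_len(n1)]; g2 <- traj[seq(length(traj) - n2 + 1, length(traj))]
    gz <- (mean(g1) - mean(g2)) /
      sqrt(var(g1) / n1 + var(g2) / n2)
    if (is.finite(gz) && abs(gz) > 3)
      warning(sprintf("wormlike_stiffness: equilibration suspect (Geweke z = %.2f)", gz))
    list(stiffness = kbt / vz, stderr = kbt * se_v / vz^2,
         mean_z = mean(zs), var_z = vz, acceptance = acc / prop,
         n_samples = length(zs), geweke_z = gz)
  })
}
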