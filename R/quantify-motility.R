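# Migration-memory estimators: ensemble KS-test detection on cos(theta)
# distributions and per-cell Kalman-smoothed cos(theta) thresholding.

#' Ensemble migration memory by sliding-window Kolmogorov-Smirnov test
#'
#' Pools per-step source alignments (cos theta) of all tracks in sliding
#' windows of \code{window} time points and compares each window against a
#' no-stimulus reference distribution with a two-sided KS test. Memory ends
#' at the first post-washout window whose distribution is statistically
#' indistinguishable from the reference (test fails to reject at
#' \code{alpha}) in \code{consecutive} consecutive windows.
#'
#' @param ensemble a [track_ensemble()] (the stimulated/washout tracks).
#' @param reference a [track_ensemble()] recorded in continuous stimulus
#'   absence, or a numeric vector of reference cos theta values.
#' @param source_direction 2-vector toward the source.
#' @param t_stim_end washout time (min).
#' @param window window size in time points.
#' @param alpha significance level.
#' @param consecutive accepting windows required.
#' @param min_samples windows with fewer pooled steps are widened (flagged).
#' @return a [memory_estimate()] (modality "migration", ensemble) with the
#'   per-window p-values in attribute \code{pvalues}.
#' @export
migration_memory <- function(ensemble, reference,
                             source_direction = c(1, 0), t_stim_end,
                             window = 5L, alpha = 0.05, consecutive = 2L,
                             min_samples = 20L) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  ref_vals <- if (inherits(reference, "track_ensemble"))
    unlist(lapply(reference$tracks, function(tr)
      cos_theta_series(tr, source_direction)$cos_theta)) else
        as.numeric(reference)
  ref_vals <- ref_vals[is.finite(ref_vals)]
  ct <- lapply(ensemble$tracks, cos_theta_series,
               source_direction = source_direction)
  t_steps <- ct[[1]]$t
  vals <- vapply(ct, function(d) d$cos_theta, numeric(length(t_steps)))
  widened <- FALSE
  n_t <- length(t_steps)
  pv <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    w <- window
    repeat {
      lo <- max(1, i - w + 1)
      pool <- as.numeric(vals[lo:i, ])
      pool <- pool[is.finite(pool)]
      if (length(pool) >= min_samples || w >= n_t) break
      w <- w + 2L; widened <- TRUE
    }
    pv[i] <- suppressWarnings(
      stats::ks.test(pool, ref_vals)$p.value)
  }
  post <- which(t_steps >= t_stim_end)
  accept <- pv[post] > alpha
  t_end <- Inf
  r <- rle(accept)
  hit <- which(r$values & r$lengths >= consecutive)
  if (length(hit)) {
    first <- sum(r$lengths[seq_len(hit[1] - 1)]) + 1L
    # timestamp at the window centre: the pooled statistic represents the
    # middle of the trailing window, not its right edge
    dt <- if (length(t_steps) > 1) t_steps[2] - t_steps[1] else 0
    t_end <- t_steps[post[first]] - (window - 1) * dt / 2
  }
  est <- memory_estimate("migration", t_stim_end, t_end,
                         rule = sprintf("KS window=%d alpha=%g", window,
                                        alpha),
                         ensemble = TRUE)
  attr(est, "pvalues") <- data.frame(t = t_steps, p = pv)
  attr(est, "widened") <- widened
  est
}

#' Constant-velocity Kalman smoothing of a track
#'
#' Linear Kalman filter + Rauch smoother with state (x, y, vx, vy),
#' constant-velocity transition and position observations.
#'
#' @param track data frame with \code{t}, \code{x}, \code{y} (uniform dt).
#' @param process_sd process noise s.d. on velocity (um/min per step).
#' @param measurement_sd observation noise s.d. on positions (um).
#' @return the track with smoothed \code{x}, \code{y} (and \code{vx},
#'   \code{vy}).
#' @export
kalman_smooth_track <- function(track, process_sd = 0.1,
                                measurement_sd = 0.5) {
  n <- nrow(track)
  dt <- diff(track$t)[1]
  A <- rbind(c(1, 0, dt, 0), c(0, 1, 0, dt), c(0, 0, 1, 0), c(0, 0, 0, 1))
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Q <- diag(c(1e-6, 1e-6, process_sd^2, process_sd^2)) * dt
  Rm <- diag(measurement_sd^2, 2)
  xf <- matrix(0, 4, n); Pf <- array(0, c(4, 4, n))
  xp <- matrix(0, 4, n); Pp <- array(0, c(4, 4, n))
  x <- c(track$x[1], track$y[1], 0, 0)
  P <- diag(c(measurement_sd^2, measurement_sd^2, 1, 1))
  for (i in seq_len(n)) {
    if (i > 1) { x <- A %*% x; P <- A %*% P %*% t(A) + Q }
    xp[, i] <- x; Pp[, , i] <- P
    z <- c(track$x[i], track$y[i])
    S <- H %*% P %*% t(H) + Rm
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z - H %*% x)
    P <- (diag(4) - K %*% H) %*% P
    xf[, i] <- x; Pf[, , i] <- P
  }
  xs <- xf; Ps <- Pf
  for (i in (n - 1):1) {
    G <- Pf[, , i] %*% t(A) %*% solve(Pp[, , i + 1])
    xs[, i] <- xf[, i] + G %*% (xs[, i + 1] - xp[, i + 1])
  }
  data.frame(t = track$t, x = xs[1, ], y = xs[2, ],
             vx = xs[3, ], vy = xs[4, ])
}

#' Per-cell migration memory from the smoothed cos(theta) profile
#'
#' Positions are Kalman-smoothed, per-step source alignment computed, and
#' memory ends at the first post-washout time where \code{consecutive}
#' consecutive cos(theta) values fall below \code{threshold}.
#'
#' @param track data frame with \code{t}, \code{x}, \code{y}.
#' @param source_direction 2-vector toward the source.
#' @param t_stim_end washout time (min).
#' @param threshold cos(theta) threshold (default 0.75).
#' @param consecutive consecutive sub-threshold samples (default 3).
#' @param process_sd,measurement_sd Kalman noise parameters.
#' @return a [memory_estimate()] (modality "migration", per cell).
#' @export
single_cell_cos_memory <- function(track, source_direction = c(1, 0),
                                   t_stim_end, threshold = 0.75,
                                   consecutive = 3L, process_sd = 0.1,
                                   measurement_sd = 0.5) {
  sm <- kalman_smooth_track(track, process_sd, measurement_sd)
  ct <- cos_theta_series(sm, source_direction)
  post <- which(ct$t >= t_stim_end)
  below <- ct$cos_theta[post] < threshold
  below[is.na(below)] <- TRUE
  t_end <- Inf
  r <- rle(below)
  hit <- which(r$values & r$lengths >= consecutive)
  if (length(hit)) {
    first <- sum(r$lengths[seq_len(hit[1] - 1)]) + 1L
    t_end <- ct$t[post[first]]
  }
  memory_estimate("migration", t_stim_end, t_end,
                  rule = sprintf("Kalman cos(theta) < %g x%d", threshold,
                                 consecutive))
}
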