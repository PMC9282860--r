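# Modified Ornstein-Uhlenbeck (mOU) migration models and track statistics.
# The velocity of a migrating cell follows
#   dv = -v/tau dt + (sqrt(2 D)/tau) (dW + b(t) e_bias dt)
# which interpolates between a random walk (tau -> 0), a persistent random
# walk (b = 0) and biased persistent walks (b > 0, constant or scheduled).

#' Migration model parameters
#'
#' @param tau persistence time (min).
#' @param D diffusion coefficient (um^2/min).
#' @param bias dimensionless bias magnitude b (0 = unbiased).
#' @param bias_direction unit 2-vector of the gradient direction.
#' @param bias_schedule optional matrix/data.frame with columns
#'   \code{t_on}, \code{t_off}: bias is active inside any interval
#'   (constant bias when omitted).
#' @param dt sampling interval (min).
#' @param duration track length (min).
#' @return object of class \code{motility_params}.
#' @export
motility_params <- function(tau = 11.105, D = 0.425, bias = 0,
                            bias_direction = c(1, 0),
                            bias_schedule = NULL,
                            dt = 2, duration = 300) {
  if (tau < 0 || D < 0) stop("motility_params: tau and D must be >= 0")
  nrm <- sqrt(sum(bias_direction^2))
  if (nrm < 1e-12) stop("motility_params: bias_direction must be nonzero")
  structure(list(tau = tau, D = D, bias = bias,
                 bias_direction = bias_direction / nrm,
                 bias_schedule = bias_schedule,
                 dt = dt, duration = duration),
            class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat(sprintf("mOU migration model: tau=%.4g min, D=%.4g um^2/min, b=%.4g\n",
              x$tau, x$D, x$bias))
  cat(sprintf("  dt=%.3g min, duration=%.5g min\n", x$dt, x$duration))
  invisible(x)
}

#' Ensemble of migration tracks
#'
#' @param tracks list of data frames with columns \code{t}, \code{x},
#'   \code{y} and optionally \code{phase}.
#' @param dt shared sampling interval.
#' @param meta provenance list.
#' @return object of class \code{track_ensemble}.
#' @export
track_ensemble <- function(tracks, dt, meta = list()) {
  stopifnot(length(tracks) >= 1)
  for (tr in tracks) {
    if (any(diff(tr$t) <= 0)) stop("track_ensemble: non-increasing time")
    if (max(abs(diff(tr$t) - dt)) > 1e-8)
      stop("track_ensemble: non-uniform sampling")
  }
  structure(list(tracks = tracks, dt = dt, meta = meta),
            class = "track_ensemble")
}

#' @export
print.track_ensemble <- function(x, ...) {
  n <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("track ensemble: %d tracks, dt=%.3g min, %d-%d samples\n",
              length(x$tracks), x$dt, min(n), max(n)))
  invisible(x)
}

bias_active <- function(params, t) {
  if (is.null(params$bias_schedule)) return(rep(TRUE, length(t)))
  sched <- as.data.frame(params$bias_schedule)
  act <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sched)))
    act <- act | (t >= sched$t_on[i] & t < sched$t_off[i])
  act
}

#' Simulate mOU migration tracks
#'
#' Euler--Maruyama on the velocity per Cartesian component with noise
#' amplitude \code{sqrt(2 D)/tau}; positions by trapezoidal integration of
#' the velocity. The integration step is refined internally when the
#' sampling interval is coarse relative to \code{tau} (recorded positions
#' keep the requested \code{dt}).
#'
#' @param params a [motility_params()].
#' @param n_tracks number of independent tracks.
#' @param seed RNG seed.
#' @param v0 initial velocity: \code{"stationary"} draws from the
#'   zero-bias stationary distribution, or a fixed 2-vector.
#' @return a [track_ensemble()].
#' @export
simulate_mou <- function(params, n_tracks = 300, seed = 1L,
                         v0 = "stationary") {
  stopifnot(inherits(params, "motility_params"))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  dt <- params$dt
  n_sub <- max(1L, ceiling(dt / max(params$tau / 25, 1e-3)))
  dts <- dt / n_sub
  n_rec <- floor(params$duration / dt)
  t_rec <- (0:n_rec) * dt
  sig <- if (params$tau > 0) sqrt(2 * params$D) / params$tau else 0
  e_b <- params$bias_direction
  tracks <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    v <- if (identical(v0, "stationary")) {
      if (params$tau > 0) stats::rnorm(2, 0, sqrt(params$D / params$tau))
      else c(0, 0)
    } else as.numeric(v0)
    x <- c(0, 0)
    xs <- matrix(NA_real_, n_rec + 1, 2)
    xs[1, ] <- x
    for (i in seq_len(n_rec)) {
      t_now <- (i - 1) * dt
      b_on <- bias_active(params, t_now)
      for (s in seq_len(n_sub)) {
        drift <- if (params$tau > 0) -v / params$tau else -v / 1e-12
        noise <- sig * (stats::rnorm(2, 0, sqrt(dts)) +
                          (if (b_on) params$bias * e_b * dts else c(0, 0)))
        v_new <- v + drift * dts + noise
        x <- x + 0.5 * (v + v_new) * dts
        v <- v_new
      }
      xs[i + 1, ] <- x
    }
    ph <- ifelse(bias_active(params, t_rec), "bias", "none")
    tracks[[k]] <- data.frame(t = t_rec, x = xs[, 1], y = xs[, 2],
                              phase = ph)
  }
  track_ensemble(tracks, dt, meta = list(params = params, seed = seed))
}

#' Ensemble mean squared displacement
#'
#' Time-from-origin definition: \code{MSD(t) = < |x_i(t) - x_i(0)|^2 >}
#' averaged over tracks (not time-averaged within tracks). Ragged ensembles
#' are truncated to the shortest track.
#'
#' @param ensemble a [track_ensemble()].
#' @return data frame with \code{lag} (min) and \code{msd} (um^2).
#' @export
msd <- function(ensemble) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  n_min <- min(vapply(ensemble$tracks, nrow, integer(1)))
  if (n_min < 2) stop("msd: need at least 2 time points")
  sq <- vapply(ensemble$tracks, function(tr)
    (tr$x[1:n_min] - tr$x[1])^2 + (tr$y[1:n_min] - tr$y[1])^2,
    numeric(n_min))
  data.frame(lag = ensemble$tracks[[1]]$t[1:n_min] -
               ensemble$tracks[[1]]$t[1],
             msd = rowMeans(sq))
}

# central-difference velocities at interior samples
track_velocities <- function(tr, dt) {
  n <- nrow(tr)
  cbind((tr$x[3:n] - tr$x[1:(n - 2)]) / (2 * dt),
        (tr$y[3:n] - tr$y[1:(n - 2)]) / (2 * dt))
}

#' Ensemble velocity autocorrelation function
#'
#' \code{VACF(t) = < v_i(t) . v_i(0) >} with velocities estimated by
#' central differences at interior samples.
#'
#' @param ensemble a [track_ensemble()].
#' @return data frame with \code{lag} and \code{vacf} (um^2/min^2).
#' @export
vacf <- function(ensemble) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  n_min <- min(vapply(ensemble$tracks, nrow, integer(1)))
  if (n_min < 3) stop("vacf: need at least 3 time points")
  dots <- vapply(ensemble$tracks, function(tr) {
    v <- track_velocities(tr[1:n_min, ], ensemble$dt)
    v %*% v[1, ]
  }, numeric(n_min - 2))
  data.frame(lag = (seq_len(n_min - 2) - 1) * ensemble$dt,
             vacf = rowMeans(dots))
}

#' Fit migration parameters from MSD and VACF
#'
#' \code{D} from a linear fit \code{MSD = 4 D t} (slope of an affine fit
#' over long lags, which removes the ballistic offset \code{-4 D tau});
#' \code{tau} from a mono-exponential fit \code{phi0 exp(-t/tau)} to the
#' VACF over lags where it remains above a fraction of its initial value.
#'
#' @param ensemble a [track_ensemble()] with at least 20 tracks.
#' @param msd_window optional lag window \code{c(lo, hi)} for the MSD fit;
#'   default \code{[min(2 tau_hat, T/6), T/2]} after a pilot \code{tau}
#'   estimate.
#' @param vacf_floor VACF fit uses lags with
#'   \code{vacf > vacf_floor * vacf(0)}.
#' @return object of class \code{motility_fit}: \code{D}, \code{tau},
#'   \code{phi0}, \code{r_squared_msd}, \code{seoe_vacf} (standard error of
#'   estimate), fit windows, and a \code{poor_fit} flag when the MSD is not
#'   close to linear over the window.
#' @export
fit_motility <- function(ensemble, msd_window = NULL, vacf_floor = 0.05) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  if (length(ensemble$tracks) < 20)
    stop("fit_motility: need at least 20 tracks")
  vc <- vacf(ensemble)
  # fit window: lags where the VACF is still above the floor, skipping the
  # first two lags (central-difference velocities smooth the short-lag
  # correlation away from a pure exponential)
  head_pos <- which(vc$vacf > vacf_floor * vc$vacf[1])
  first_neg <- which(vc$vacf <= 0)
  if (length(first_neg)) head_pos <- head_pos[head_pos < min(first_neg)]
  head_pos <- head_pos[vc$lag[head_pos] >= 2 * ensemble$dt]
  if (length(head_pos) < 3)
    head_pos <- utils::tail(order(vc$vacf, decreasing = TRUE), 3)
  lf <- stats::lm(log(vacf) ~ lag, data = vc[head_pos, ])
  tau_hat <- -1 / stats::coef(lf)[["lag"]]
  # refined nonlinear fit
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(vacf ~ phi0 * exp(-lag / tau),
                      data = vc[head_pos, ],
                      start = list(phi0 = vc$vacf[1],
                                   tau = max(tau_hat, ensemble$dt))),
    error = function(e) NULL)
  if (!is.null(nls_fit)) {
    tau_hat <- stats::coef(nls_fit)[["tau"]]
    phi0 <- stats::coef(nls_fit)[["phi0"]]
    seoe <- sqrt(mean(stats::residuals(nls_fit)^2))
  } else {
    phi0 <- exp(stats::coef(lf)[["(Intercept)"]])
    seoe <- sqrt(mean((vc$vacf[head_pos] -
                         phi0 * exp(-vc$lag[head_pos] / tau_hat))^2))
  }
  ms <- msd(ensemble)
  T_max <- max(ms$lag)
  # below ~3 persistence times the ballistic shoulder still curves the
  # MSD and biases an affine fit low; cap the lower edge so a window
  # always remains
  if (is.null(msd_window))
    msd_window <- c(min(3 * abs(tau_hat), T_max / 2), T_max)
  sel <- ms$lag >= msd_window[1] & ms$lag <= msd_window[2]
  if (sum(sel) < 3) sel <- ms$lag >= stats::median(ms$lag)
  lm_msd <- stats::lm(msd ~ lag, data = ms[sel, ])
  D_hat <- stats::coef(lm_msd)[["lag"]] / 4
  r2 <- summary(lm_msd)$r.squared
  structure(list(D = D_hat, tau = tau_hat, phi0 = phi0,
                 r_squared_msd = r2, seoe_vacf = seoe,
                 msd_window = msd_window,
                 vacf_lags = range(vc$lag[head_pos]),
                 poor_fit = r2 < 0.9,
                 msd_curve = ms, vacf_curve = vc),
            class = "motility_fit")
}

#' @export
print.motility_fit <- function(x, ...) {
  cat(sprintf("motility fit: D = %.4g um^2/min (MSD R^2 = %.3f)\n",
              x$D, x$r_squared_msd))
  cat(sprintf("              tau = %.4g min (VACF SEOE = %.3g)\n",
              x$tau, x$seoe_vacf))
  if (x$poor_fit) cat("  WARNING: MSD not linear over fit window\n")
  invisible(x)
}

#' Directionality of a track
#'
#' Net displacement over total path length within a window, in [0, 1].
#'
#' @param track data frame with \code{t}, \code{x}, \code{y}.
#' @param window optional time window \code{c(t0, t1)}.
#' @return scalar ratio; \code{NA} for zero path length.
#' @export
directionality <- function(track, window = NULL) {
  if (!is.null(window))
    track <- track[track$t >= window[1] & track$t <= window[2], ]
  if (nrow(track) < 2) stop("directionality: need >= 2 points in window")
  disp <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
                 (track$y[nrow(track)] - track$y[1])^2)
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  if (path < 1e-12) return(NA_real_)
  disp / path
}

#' Per-step alignment with the source direction
#'
#' Cosine of the angle between each displacement step and the gradient
#' (source) direction. Zero-length steps yield \code{NA}.
#'
#' @param track data frame with \code{t}, \code{x}, \code{y}.
#' @param source_direction 2-vector pointing toward the source.
#' @return data frame with step midpoint time \code{t} and \code{cos_theta}.
#' @export
cos_theta_series <- function(track, source_direction = c(1, 0)) {
  e <- source_direction / sqrt(sum(source_direction^2))
  dx <- diff(track$x); dy <- diff(track$y)
  len <- sqrt(dx^2 + dy^2)
  ct <- ifelse(len < 1e-12, NA_real_, (dx * e[1] + dy * e[2]) / len)
  data.frame(t = track$t[-1], cos_theta = ct)
}
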