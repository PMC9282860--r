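#' Kymograph container
#'
#' Space-time matrix of one membrane species or derived quantity:
#' rows are membrane bins (angles), columns are time points.
#'
#' @param mat numeric matrix, \code{n_bins x n_times}.
#' @param times strictly increasing time vector (min).
#' @param angles bin centre angles (radians).
#' @param species name of the quantity.
#' @param meta list of free-form metadata (parameters, seed, ...).
#' @return object of class \code{kymograph}.
#' @export
kymograph <- function(mat, times, angles, species = "Ep", meta = list()) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(times))
    stop("kymograph: ncol(mat) must equal length(times)")
  if (nrow(mat) != length(angles))
    stop("kymograph: nrow(mat) must equal length(angles)")
  if (any(diff(times) <= 0)) stop("kymograph: times must be increasing")
  structure(list(mat = mat, times = times, angles = angles,
                 species = species, meta = meta),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph of %s: %d bins x %d times, t in [%g, %g] min\n",
              x$species, nrow(x$mat), ncol(x$mat),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$times, x$angles, t(x$mat),
                  xlab = "time (min)", ylab = "membrane angle (rad)",
                  main = paste("kymograph:", x$species), ...)
  invisible(x)
}

# periodic central-difference Laplacian matrix on the bin ring
ring_laplacian <- function(n_bins, dx) {
  L <- matrix(0, n_bins, n_bins)
  idx <- seq_len(n_bins)
  L[cbind(idx, idx)] <- -2
  L[cbind(idx, idx %% n_bins + 1)] <- 1
  L[cbind(idx, (idx - 2) %% n_bins + 1)] <- 1
  L / dx^2
}

#' Stochastic reaction-diffusion simulation on the membrane ring
#'
#' Integrates the four-species network on the periodic bin lattice with an
#' explicit Euler--Maruyama scheme: reactions per bin, lateral diffusion of
#' Ep and RGa by periodic central differences, and additive white noise
#' \code{sigma_noise * dW} on the Ep equation only. PTPN2 is either treated
#' at quasi-steady state (default, the regime the small \code{epsilon}
#' justifies) or integrated as a full slow variable.
#'
#' @param params a [signaling_params()].
#' @param grid a [membrane_grid()].
#' @param protocol a [stimulus_protocol()]; the EGF field is evaluated at the
#'   bin centres each step.
#' @param t_end end time (min), from 0.
#' @param dt time step (min).
#' @param seed integer seed for the noise stream (ignored when
#'   \code{noise_on = FALSE}).
#' @param noise_on logical; add noise to Ep.
#' @param n2a_mode \code{"qss"} or \code{"ode"}.
#' @param init optional list \code{(Ep, EEp, RGa, N2a)} of initial bin
#'   vectors; default is the uniform basal steady state.
#' @param save_every store every k-th step (thinning of the kymographs).
#' @param alpha2_factor multiplier applied to the autocatalytic rate
#'   \code{alpha2} from stimulus washout onward (receptor-kinase inhibition
#'   in silico; 1 = no inhibition).
#' @return list of class \code{rd_simulation}: kymographs for
#'   \code{Ep}, \code{EEp}, \code{RGa}, \code{N2a} and the evaluated
#'   \code{EGF} field, plus the clip-event fraction.
#' @export
simulate_rd <- function(params, grid = membrane_grid(),
                        protocol, t_end, dt = 0.01,
                        seed = 1L, noise_on = TRUE,
                        n2a_mode = c("qss", "ode"),
                        init = NULL, save_every = 50L,
                        alpha2_factor = 1) {
  stopifnot(inherits(params, "signaling_params"),
            inherits(grid, "membrane_grid"),
            inherits(protocol, "stimulus_protocol"))
  n2a_mode <- match.arg(n2a_mode)
  if (dt <= 0) stop("simulate_rd: dt must be > 0")
  dx <- grid$bin_length
  cfl <- dt * max(params$D_Ep, params$D_RGa, params$D_EEp) / dx^2
  if (cfl > 0.5)
    stop(sprintf("simulate_rd: diffusive CFL number %.3g > 0.5; reduce dt",
                 cfl))
  n <- grid$n_bins
  theta <- grid$bin_centers
  n_steps <- ceiling(t_end / dt)
  save_every <- max(1L, as.integer(save_every))
  keep <- seq(0L, n_steps, by = save_every)
  times <- keep * dt
  if (is.null(init)) {
    hss <- homogeneous_steady_state(params, EGFt = 0)
    state <- list(Ep = rep(hss$Ep, n), EEp = rep(hss$EEp, n),
                  RGa = rep(hss$RGa, n), N2a = rep(hss$N2a, n))
  } else state <- lapply(init[c("Ep", "EEp", "RGa", "N2a")], rep_len, n)
  L <- ring_laplacian(n, dx)
  DEp <- params$D_Ep; DRG <- params$D_RGa; DEE <- params$D_EEp
  sig <- if (noise_on) params$sigma_noise else 0
  if (noise_on) {
    oldseed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldseed))
      assign(".Random.seed", oldseed, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  t_wash <- stimulus_end_time(protocol)
  out <- lapply(c(Ep = "Ep", EEp = "EEp", RGa = "RGa", N2a = "N2a",
                  EGF = "EGF"),
                function(nm) matrix(NA_real_, n, length(keep)))
  store <- function(k_idx, egf) {
    out$Ep[, k_idx] <<- state$Ep; out$EEp[, k_idx] <<- state$EEp
    out$RGa[, k_idx] <<- state$RGa; out$N2a[, k_idx] <<- state$N2a
    out$EGF[, k_idx] <<- egf
  }
  clip_events <- 0; k_idx <- 1L
  store(k_idx, egf_at(protocol, theta, 0))
  p_run <- params
  sqdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    if (alpha2_factor != 1 && !is.na(t_wash))
      p_run$alpha2 <- if (t >= t_wash) params$alpha2 * alpha2_factor
                      else params$alpha2
    egf <- egf_at(protocol, theta, t)
    N2a_eff <- if (n2a_mode == "qss")
      n2a_qss(state$Ep, state$EEp, p_run) else state$N2a
    f <- reaction_terms(state$Ep, state$EEp, state$RGa, N2a_eff, p_run, egf)
    Ep_new <- state$Ep + dt * (f$f_Ep + DEp * drop(L %*% state$Ep))
    if (sig > 0) Ep_new <- Ep_new + sig * sqdt * stats::rnorm(n)
    EEp_new <- state$EEp + dt * (f$f_EEp + DEE * drop(L %*% state$EEp))
    RGa_new <- state$RGa + dt * (f$f_RGa + DRG * drop(L %*% state$RGa))
    N2a_new <- if (n2a_mode == "qss") n2a_qss(pmax(Ep_new, 0),
                                              pmax(EEp_new, 0), p_run)
               else state$N2a + dt * f$f_N2a
    if (anyNA(Ep_new) || anyNA(RGa_new))
      stop("simulate_rd: NaN at step ", s)
    # clip into the invariant box, counting events
    lo <- pmax(Ep_new, 0); hiE <- pmin(lo, p_run$Et - pmin(EEp_new, p_run$Et))
    clip_events <- clip_events +
      sum(Ep_new != hiE) + sum(EEp_new < 0 | EEp_new > p_run$Et) +
      sum(RGa_new < 0 | RGa_new > p_run$RGt) +
      sum(N2a_new < 0 | N2a_new > p_run$N2t)
    state$Ep <- hiE
    state$EEp <- pmin(pmax(EEp_new, 0), p_run$Et)
    state$RGa <- pmin(pmax(RGa_new, 0), p_run$RGt)
    state$N2a <- pmin(pmax(N2a_new, 0), p_run$N2t)
    if (s %% save_every == 0L) {
      k_idx <- k_idx + 1L
      store(k_idx, egf_at(protocol, theta, s * dt))
    }
  }
  meta <- list(params = params, seed = seed, noise_on = noise_on, dt = dt,
               n2a_mode = n2a_mode, alpha2_factor = alpha2_factor)
  kys <- lapply(names(out), function(nm)
    kymograph(out[[nm]], times, theta, species = nm, meta = meta))
  names(kys) <- names(out)
  structure(c(kys, list(protocol = protocol,
                        clip_fraction = clip_events / (n_steps * 4 * n))),
            class = "rd_simulation")
}

#' @export
print.rd_simulation <- function(x, ...) {
  cat("reaction-diffusion simulation\n")
  print(x$Ep)
  cat(sprintf("  clip fraction: %.3g\n", x$clip_fraction))
  invisible(x)
}

#' Polarization index and in-silico memory duration
#'
#' The polarization index of an Ep kymograph is
#' \code{p(t) = (max - min) / (mean + floor)} across bins; memory duration is
#' the time from stimulus washout until \code{p(t)} first stays below
#' \code{threshold} for \code{consecutive} samples.
#'
#' @param kymo Ep [kymograph()].
#' @param protocol the [stimulus_protocol()] that drove it (defines washout).
#' @param threshold polarization threshold on \code{p(t)}.
#' @param consecutive samples required below threshold.
#' @param floor mean regularisation.
#' @return list with \code{p} (time series), \code{times},
#'   \code{t_stimulus_end}, and \code{memory} (min; \code{NA} if the protocol
#'   has no washout, \code{Inf} if p never relaxes within the window).
#' @export
polarization_metrics <- function(kymo, protocol, threshold = 0.2,
                                 consecutive = 3L, floor = 1e-6) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$mat
  p <- (apply(m, 2, max) - apply(m, 2, min)) / (colMeans(m) + floor)
  t_end_stim <- stimulus_end_time(protocol)
  if (is.na(t_end_stim) || t_end_stim >= max(kymo$times))
    return(list(p = p, times = kymo$times, t_stimulus_end = t_end_stim,
                memory = NA_real_))   # no washout observed: undefined
  post <- which(kymo$times >= t_end_stim)
  below <- p[post] < threshold
  memory <- Inf
  run <- rle(below)
  if (any(run$values & run$lengths >= consecutive)) {
    hits <- which(run$values & run$lengths >= consecutive)
    first <- sum(run$lengths[seq_len(hits[1] - 1)]) + 1L
    memory <- kymo$times[post[first]] - t_end_stim
  }
  if (all(!below) && !length(post)) memory <- NA_real_
  list(p = p, times = kymo$times, t_stimulus_end = t_end_stim,
       memory = memory)
}
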