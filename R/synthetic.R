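# Ground-truth generators for every pipeline input: stimulus protocols,
# parametric kymographs, fluorescence records, mask series and
# phase-labelled track ensembles. Every artifact carries the ground truth
# needed to score the estimators run on it.

#' Named stimulus-protocol templates
#'
#' \itemize{
#'   \item \code{single_gradient_1h}: 60-min wrapped-Gaussian gradient on
#'     t in [5, 65) min, washout afterwards.
#'   \item \code{migration_5h}: 5-h dynamic gradient (amplitude and width
#'     relax to a ~50 percent shallower profile), then washout.
#'   \item \code{triple_field}: dynamic gradient (5-245 min), 30-min
#'     interruption, same-direction static gradient (275-335 min),
#'     30-min interruption, opposite-direction dynamic gradient
#'     (365-605 min).
#'   \item \code{opposing_gradients}: two simultaneous wrapped Gaussians
#'     from opposite sides with unequal amplitudes.
#' }
#'
#' @param template template name.
#' @param theta0 primary gradient direction (radians).
#' @param A peak amplitude (concentration units of the signaling model).
#' @param width angular s.d. (radians).
#' @param t_total protocol end (min); default template-specific.
#' @param amplitude_ratio second/first amplitude for
#'   \code{opposing_gradients}.
#' @return a [stimulus_protocol()].
#' @export
make_stimulus_protocol <- function(template = c("single_gradient_1h",
                                                "migration_5h",
                                                "triple_field",
                                                "opposing_gradients"),
                                   theta0 = pi, A = 0.1, width = 1.0,
                                   t_total = NULL, amplitude_ratio = 0.5) {
  template <- match.arg(template)
  segs <- switch(template,
    single_gradient_1h = list(
      list(t_start = 5, t_end = 65, kind = "gaussian_gradient",
           A = A, width = width, theta0 = theta0)),
    migration_5h = list(
      list(t_start = 5, t_end = 305, kind = "gaussian_gradient",
           A = c(A, A / 2), width = c(width, width * 1.5),
           theta0 = theta0)),
    triple_field = list(
      list(t_start = 5, t_end = 245, kind = "gaussian_gradient",
           A = c(A, A / 2), width = c(width, width * 1.5),
           theta0 = theta0),
      list(t_start = 275, t_end = 335, kind = "gaussian_gradient",
           A = A, width = width, theta0 = theta0),
      list(t_start = 365, t_end = 605, kind = "gaussian_gradient",
           A = c(A, A / 2), width = c(width, width * 1.5),
           theta0 = theta0 + pi)),
    opposing_gradients = list(
      list(t_start = 5, t_end = 65, kind = "gaussian_gradient",
           A = A, width = width, theta0 = theta0,
           A2 = A * amplitude_ratio, width2 = width,
           theta0_2 = theta0 + pi)))
  t_end_default <- switch(template, single_gradient_1h = 245,
                          migration_5h = 845, triple_field = 905,
                          opposing_gradients = 245)
  if (is.null(t_total)) t_total <- t_end_default
  last <- segs[[length(segs)]]$t_end
  if (t_total > last)
    segs <- c(segs, list(list(t_start = last, t_end = t_total,
                              kind = "none")))
  stimulus_protocol(segs)
}

#' Parametric polarized kymograph with known memory duration
#'
#' Builds an EGFRp field on the bin ring whose polarization follows the
#' stimulus and persists as a plateau for exactly \code{memory_min} after
#' washout (then relaxes with a short tail). The spatial profile is a
#' wrapped cosine lobe at \code{theta0}.
#'
#' @param n_bins,times geometry and sampling.
#' @param t_on,t_off stimulus interval (min).
#' @param memory_min post-washout plateau duration (min).
#' @param theta0 polarization angle.
#' @param baseline,amplitude field levels.
#' @param rise_tau,fall_tau onset and post-memory relaxation scales (min).
#' @return list with the [kymograph()] and a \code{ground_truth} list.
#' @export
make_parametric_kymograph <- function(n_bins = 20,
                                      times = seq(0, 245, by = 1),
                                      t_on = 5, t_off = 65,
                                      memory_min = 40, theta0 = pi,
                                      baseline = 0.05, amplitude = 0.8,
                                      rise_tau = 3, fall_tau = 2) {
  th <- 2 * pi * (seq_len(n_bins) - 0.5) / n_bins
  lobe <- pmax(cos(th - theta0), 0)
  amp_t <- vapply(times, function(t) {
    if (t < t_on) 0
    else if (t < t_off) 1 - exp(-(t - t_on) / rise_tau)
    else if (t < t_off + memory_min) 1
    else exp(-(t - t_off - memory_min) / fall_tau)
  }, numeric(1))
  m <- baseline + amplitude * outer(lobe, amp_t)
  list(kymo = kymograph(m, times, th, species = "EGFRp",
                        meta = list(parametric = TRUE)),
       ground_truth = list(polarization_angle = theta0,
                           memory_signaling = memory_min,
                           t_stim_end = t_off, regime = "criticality"))
}

#' Synthetic fluorescence record from a kymograph
#'
#' Constructs PTB/EGFR channels whose ratiometric combination returns the
#' input EGFRp field exactly (up to multiplicative log-normal noise):
#' uniform EGFR membrane distribution, PTB channel proportional to the
#' local EGFRp, constant totals with a fixed endosomal PTB fraction.
#'
#' @param kymo an EGFRp [kymograph()] (values >= 0), or the result of
#'   [make_parametric_kymograph()].
#' @param noise_level s.d. of the multiplicative log-normal channel noise
#'   (0 = exact round trip).
#' @param seed RNG seed.
#' @param ptb_total,egfr_total whole-cell totals (arbitrary units).
#' @param endo_fraction endosomal PTB fraction of PTB_T.
#' @param baseline additive EGFRp offset entering the channels.
#' @param with_egf attach a wrapped-Gaussian EGF channel aligned with the
#'   ground-truth polarization angle.
#' @param egf_jitter_bins s.d. (bins) of the EGF-direction jitter.
#' @return list with the [cell_fluorescence_record()] and
#'   \code{ground_truth}.
#' @export
make_fluorescence_record <- function(kymo, noise_level = 0, seed = 1L,
                                     ptb_total = 1000, egfr_total = 2000,
                                     endo_fraction = 0.1, baseline = 0.02,
                                     with_egf = FALSE,
                                     egf_jitter_bins = 0) {
  gt <- list(polarization_angle = NA_real_, memory_signaling = NA_real_)
  if (is.list(kymo) && !inherits(kymo, "kymograph")) {
    gt <- utils::modifyList(gt, kymo$ground_truth)
    kymo <- kymo$kymo
  }
  stopifnot(inherits(kymo, "kymograph"))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(kymo$mat); nt <- ncol(kymo$mat)
  ep <- pmax(kymo$mat, 0) + baseline
  PTB_T <- rep(ptb_total, nt)
  EGFR_T <- rep(egfr_total, nt)
  PTB_endo <- endo_fraction * PTB_T
  EGFR_PM <- matrix(egfr_total / (2 * n), n, nt)   # uniform membrane pool
  # invert the ratiometric definition so the ratio returns ep exactly
  PTB_PM <- ep * sweep(EGFR_PM, 2, (PTB_T - PTB_endo) / EGFR_T, "*")
  if (noise_level > 0) {
    PTB_PM <- PTB_PM * exp(stats::rnorm(n * nt, 0, noise_level))
    EGFR_PM <- EGFR_PM * exp(stats::rnorm(n * nt, 0, noise_level))
  }
  EGF_PM <- NULL
  if (with_egf) {
    th <- kymo$angles
    mu <- gt$polarization_angle
    if (is.na(mu)) mu <- th[which.max(rowMeans(kymo$mat))]
    mu <- mu + egf_jitter_bins * (2 * pi / n) * stats::rnorm(1)
    prof <- exp(-((th - mu + pi) %% (2 * pi) - pi)^2 / (2 * 1^2))
    EGF_PM <- outer(prof, rep(1, nt)) *
      (1 + 0.05 * matrix(stats::rnorm(n * nt), n, nt))
    EGF_PM[EGF_PM < 0] <- 0
    gt$egf_angle <- mu %% (2 * pi)
  }
  rec <- cell_fluorescence_record(PTB_PM, EGFR_PM, PTB_T, EGFR_T,
                                  PTB_endo, EGF_PM, kymo$times)
  gt$seed <- seed; gt$noise_level <- noise_level
  list(record = rec, ground_truth = gt)
}

#' Synthetic binary mask series with known morphology memory
#'
#' \code{circle}: a static disc. \code{polarized_blob}: a disc with a
#' cosine-lobed protrusion whose amplitude follows the stimulus plus a
#' post-washout memory plateau of \code{memory_min}. \code{from_simulation}
#' wraps a [simulate_cell()] result.
#'
#' @param mode generator mode.
#' @param memory_min morphology-memory plateau (min).
#' @param times frame times (min).
#' @param t_on,t_off stimulus interval (min).
#' @param theta0 protrusion direction (radians).
#' @param R radius (um); \code{lobe_amp} protrusion amplitude (um).
#' @param pixel_size pixel edge (um).
#' @param seed RNG seed (small boundary jitter when > 0 noise).
#' @param noise_amp boundary jitter amplitude (um).
#' @param sim a \code{cell_shape_series} for \code{from_simulation}.
#' @return list with \code{masks}, \code{times} and \code{ground_truth}.
#' @export
make_shape_series <- function(mode = c("circle", "polarized_blob",
                                       "from_simulation"),
                              memory_min = 40,
                              times = seq(0, 245, by = 1),
                              t_on = 5, t_off = 65, theta0 = 0,
                              R = 2, lobe_amp = 2, pixel_size = 0.1,
                              rise_tau = 20, recover_tau = 4,
                              seed = 1L, noise_amp = 0, sim = NULL) {
  mode <- match.arg(mode)
  if (mode == "from_simulation") {
    stopifnot(inherits(sim, "cell_shape_series"))
    return(list(masks = sim$masks, times = sim$times,
                ground_truth = list(source = "simulation")))
  }
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  ext <- R + lobe_amp + 1
  ax <- seq(-ext, ext, by = pixel_size)
  masks <- vector("list", length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    a <- if (mode == "circle") 0 else {
      if (t < t_on) 0
      else if (t < t_off + memory_min)
        1 - exp(-(t - t_on) / rise_tau)    # gradual polarization
      else (1 - exp(-(t_off + memory_min - t_on) / rise_tau)) *
        exp(-(t - t_off - memory_min) / recover_tau)
    }
    jit <- if (noise_amp > 0) noise_amp * stats::rnorm(1) else 0
    # narrow finger-like protrusion: concave shoulders lower the solidity
    th_fun <- function(th) R + pmax(a * lobe_amp + jit, 0) *
      pmax(cos(th - theta0), 0)^9
    px <- outer(ax, rep(1, length(ax)))
    py <- outer(rep(1, length(ax)), ax)
    th <- atan2(py, px)
    r <- sqrt(px^2 + py^2)
    mask <- r <= th_fun(th)
    attr(mask, "x") <- ax; attr(mask, "y") <- ax
    masks[[i]] <- mask
  }
  list(masks = masks, times = times,
       ground_truth = list(memory_morphology =
                             if (mode == "circle") NA_real_ else memory_min,
                           t_stim_end = t_off, theta0 = theta0,
                           mode = mode))
}

#' Phase-switched mOU track ensembles with known migration memory
#'
#' Concatenates mOU segments (one [motility_params()] per phase) with
#' velocity carried continuously across switches; phase labels and the
#' ground-truth memory interval are recorded.
#'
#' @param phases list of \code{list(duration = minutes, params =
#'   motility_params)}; bias settings inside each phase's params apply for
#'   that phase.
#' @param n number of tracks.
#' @param seed RNG seed.
#' @param dt sampling interval (min); must be shared by all phases.
#' @param t_stim_end optional washout time (min); when given, the
#'   ground-truth migration memory is the biased time extending past it.
#' @return list with the [track_ensemble()] (tracks carry a \code{phase}
#'   column named after the phase index and bias state) and
#'   \code{ground_truth}.
#' @export
make_tracks <- function(phases, n = 50, seed = 1L, dt = 2,
                        t_stim_end = NULL) {
  stopifnot(length(phases) >= 1)
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  durations <- vapply(phases, `[[`, numeric(1), "duration")
  t_switch <- cumsum(durations)
  tracks <- vector("list", n)
  for (k in seq_len(n)) {
    ts <- 0; xs <- matrix(c(0, 0), 1)
    v <- {
      p1 <- phases[[1]]$params
      if (p1$tau > 0) stats::rnorm(2, 0, sqrt(p1$D / p1$tau)) else c(0, 0)
    }
    x <- c(0, 0)
    labels <- character(0)
    for (ip in seq_along(phases)) {
      p <- phases[[ip]]$params
      n_steps <- round(phases[[ip]]$duration / dt)
      n_sub <- max(1L, ceiling(dt / max(p$tau / 25, 1e-3)))
      dts <- dt / n_sub
      sig <- if (p$tau > 0) sqrt(2 * p$D) / p$tau else 0
      e_b <- p$bias_direction
      for (i in seq_len(n_steps)) {
        for (s in seq_len(n_sub)) {
          drift <- if (p$tau > 0) -v / p$tau else -v * 1e12
          v_new <- v + drift * dts +
            sig * (stats::rnorm(2, 0, sqrt(dts)) + p$bias * e_b * dts)
          x <- x + 0.5 * (v + v_new) * dts
          v <- v_new
        }
        ts <- c(ts, ts[length(ts)] + dt)
        xs <- rbind(xs, x)
        labels <- c(labels, sprintf("phase%d%s", ip,
                                    if (p$bias > 0) "_bias" else ""))
      }
    }
    tracks[[k]] <- data.frame(t = ts, x = xs[, 1], y = xs[, 2],
                              phase = c("start", labels))
  }
  ens <- track_ensemble(tracks, dt,
                        meta = list(phases = phases, seed = seed))
  bias_flags <- vapply(phases, function(p) p$params$bias > 0, logical(1))
  gt <- list(t_switch = t_switch, bias_phases = bias_flags,
             t_stim_end = t_stim_end)
  # ground-truth migration memory: biased time extending past washout
  if (!is.null(t_stim_end) && any(bias_flags))
    gt$memory_migration <- max(max(t_switch[bias_flags]) - t_stim_end, 0)
  list(ensemble = ens, ground_truth = gt)
}
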