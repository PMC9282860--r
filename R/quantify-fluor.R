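# Single-cell fluorescence quantification: ratiometric membrane kymographs,
# whole-membrane time courses, activation classification, polarization
# memory, inverse-sigmoid decay fits, delay embedding and gradient
# alignment.

#' Per-cell fluorescence record
#'
#' Ratiometric measurables of one cell: per-bin plasma-membrane PTB and
#' EGFR channels (20 bins), whole-cell totals, endosomal PTB, and
#' optionally the local EGF channel around the perimeter.
#'
#' @param PTB_PM,EGFR_PM matrices \code{n_bins x n_times}.
#' @param PTB_T,EGFR_T,PTB_endo per-time totals (vectors).
#' @param EGF_PM optional \code{n_bins x n_times} local ligand channel.
#' @param times time vector (min).
#' @param bin_areas optional per-bin membrane areas (default equal).
#' @return object of class \code{cell_fluorescence_record}.
#' @export
cell_fluorescence_record <- function(PTB_PM, EGFR_PM, PTB_T, EGFR_T,
                                     PTB_endo, EGF_PM = NULL, times,
                                     bin_areas = NULL) {
  PTB_PM <- as.matrix(PTB_PM); EGFR_PM <- as.matrix(EGFR_PM)
  stopifnot(all(dim(PTB_PM) == dim(EGFR_PM)),
            ncol(PTB_PM) == length(times),
            length(PTB_T) == length(times),
            length(EGFR_T) == length(times),
            length(PTB_endo) == length(times))
  if (any(PTB_PM < 0) || any(EGFR_PM < 0) || any(PTB_T < 0) ||
      any(EGFR_T < 0) || any(PTB_endo < 0))
    stop("cell_fluorescence_record: negative fluorescence")
  if (any(PTB_endo > PTB_T + 1e-9))
    stop("cell_fluorescence_record: PTB_endo exceeds PTB_T")
  if (is.null(bin_areas)) bin_areas <- rep(1, nrow(PTB_PM))
  structure(list(PTB_PM = PTB_PM, EGFR_PM = EGFR_PM, PTB_T = PTB_T,
                 EGFR_T = EGFR_T, PTB_endo = PTB_endo, EGF_PM = EGF_PM,
                 times = times, bin_areas = bin_areas),
            class = "cell_fluorescence_record")
}

#' @export
print.cell_fluorescence_record <- function(x, ...) {
  cat(sprintf("cell fluorescence record: %d bins x %d times%s\n",
              nrow(x$PTB_PM), length(x$times),
              if (!is.null(x$EGF_PM)) " (+EGF channel)" else ""))
  invisible(x)
}

# raw per-bin ratiometric phosphorylation fraction
egfrp_raw <- function(rec) {
  denom_t <- rec$PTB_T - rec$PTB_endo
  num <- sweep(rec$PTB_PM, 2, denom_t, "/")
  den <- sweep(rec$EGFR_PM, 2, rec$EGFR_T, "/")
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Ratiometric phosphorylation kymograph of one cell
#'
#' Per-bin fraction of phosphorylated receptor,
#' \code{(PTB_PM / (PTB_T - PTB_endo)) / (EGFR_PM / EGFR_T)}, normalised
#' per cell against the pre-stimulus temporal mean and the global maximum
#' so the kymograph spans roughly [0, 1].
#'
#' @param rec a [cell_fluorescence_record()].
#' @param baseline_window pre-stimulus window (min) for the baseline mean.
#' @param normalize apply the min-max normalization (default TRUE).
#' @return a [kymograph()] of normalised EGFRp; bins with zero denominators
#'   are NA.
#' @export
egfrp_kymograph <- function(rec, baseline_window = c(0, 5),
                            normalize = TRUE) {
  stopifnot(inherits(rec, "cell_fluorescence_record"))
  raw <- egfrp_raw(rec)
  if (normalize) {
    base_idx <- rec$times >= baseline_window[1] &
      rec$times <= baseline_window[2]
    if (!any(base_idx)) stop("egfrp_kymograph: empty baseline window")
    b <- mean(raw[, base_idx], na.rm = TRUE)
    M <- max(raw, na.rm = TRUE)
    if (M - b < 1e-12) raw <- raw * 0 else raw <- (raw - b) / (M - b)
  }
  n <- nrow(raw)
  kymograph(raw, rec$times, 2 * pi * (seq_len(n) - 0.5) / n,
            species = "EGFRp", meta = list(normalized = normalize))
}

#' Whole-membrane phosphorylation and liganded-receptor time courses
#'
#' Sums the per-bin channels before taking the ratio, normalises to the
#' pre-stimulus baseline and the global maximum (profile in [~0, 1]), and
#' returns the liganded-receptor fraction \code{EGF_PM / EGFR_PM} when the
#' EGF channel is present.
#'
#' @param rec a [cell_fluorescence_record()].
#' @param baseline_window pre-stimulus interval (min); must be covered.
#' @return data frame with \code{t}, \code{egfrp} (normalised),
#'   \code{egfrp_raw}, and \code{egf_bound} (NA without EGF channel).
#' @export
egfrp_timecourse <- function(rec, baseline_window = c(0, 5)) {
  stopifnot(inherits(rec, "cell_fluorescence_record"))
  if (min(rec$times) > baseline_window[1] ||
      max(rec$times) < baseline_window[2])
    stop("egfrp_timecourse: record does not cover the baseline window")
  num <- colSums(rec$PTB_PM) / (rec$PTB_T - rec$PTB_endo)
  den <- colSums(rec$EGFR_PM) / rec$EGFR_T
  prof <- num / den
  base_idx <- rec$times >= baseline_window[1] &
    rec$times <= baseline_window[2]
  b <- mean(prof[base_idx])
  M <- max(prof)
  norm <- if (M - b < 1e-12) prof * 0 else (prof - b) / (M - b)
  egf_bound <- if (!is.null(rec$EGF_PM))
    colSums(rec$EGF_PM) / colSums(rec$EGFR_PM) else NA_real_
  data.frame(t = rec$times, egfrp = norm, egfrp_raw = prof,
             egf_bound = egf_bound)
}

#' Classify cells as non-activated, activated or pre-activated
#'
#' Pre-activated cells (already-high uniform phosphorylation) are detected
#' by a 2-component Gaussian mixture on the pooled pre-stimulus per-bin
#' values: any cell with more than 30 percent of its pre-stimulus bin
#' values above the component-intersection threshold is pre-activated.
#' Remaining cells are split into activated vs non-activated by a second
#' mixture on per-cell mean phosphorylation over the whole
#' pre-stimulus-plus-stimulation window.
#'
#' @param records list of [cell_fluorescence_record()].
#' @param baseline_window pre-stimulus window (min).
#' @param response_window window (min) for the activated/non-activated
#'   mean.
#' @param pre_activated_fraction bin fraction above threshold that flags
#'   pre-activation.
#' @return data frame with one row per cell: \code{label}, the per-cell
#'   statistics, the thresholds used and a \code{degenerate} flag when a
#'   mixture collapsed and the midpoint fallback was used.
#' @export
classify_activation <- function(records, baseline_window = c(0, 5),
                                response_window = c(0, 65),
                                pre_activated_fraction = 0.30) {
  stopifnot(length(records) >= 2)
  raws <- lapply(records, egfrp_raw)
  pre_vals <- lapply(seq_along(records), function(i) {
    idx <- records[[i]]$times >= baseline_window[1] &
      records[[i]]$times <= baseline_window[2]
    as.numeric(raws[[i]][, idx])
  })
  pooled <- unlist(pre_vals)
  thr1 <- gmm_intersection(pooled)
  frac_above <- vapply(pre_vals, function(v)
    mean(v > thr1$threshold, na.rm = TRUE), numeric(1))
  pre_act <- frac_above > pre_activated_fraction
  mean_resp <- vapply(seq_along(records), function(i) {
    idx <- records[[i]]$times >= response_window[1] &
      records[[i]]$times <= response_window[2]
    mean(raws[[i]][, idx], na.rm = TRUE)
  }, numeric(1))
  rest <- which(!pre_act)
  label <- rep("pre-activated", length(records))
  thr2 <- list(threshold = NA_real_, degenerate = TRUE)
  if (length(rest) >= 2) {
    thr2 <- gmm_intersection(mean_resp[rest])
    label[rest] <- ifelse(mean_resp[rest] > thr2$threshold,
                          "activated", "non-activated")
  } else if (length(rest)) label[rest] <- "activated"
  data.frame(cell = seq_along(records), label = label,
             pre_stim_fraction_above = frac_above,
             mean_response = mean_resp,
             threshold_pre = thr1$threshold,
             threshold_act = thr2$threshold,
             degenerate = thr1$degenerate | thr2$degenerate)
}

# Mclust resolves its model-selection helpers in the caller's frame, so
# they must be imported into the package namespace
#' @importFrom mclust Mclust mclustBIC
NULL

# intersection of a 2-component Gaussian mixture fitted to values;
# falls back to the midpoint of component means (flagged) when the
# intersection is outside the data range or the fit is degenerate
gmm_intersection <- function(v) {
  v <- v[is.finite(v)]
  if (length(unique(round(v, 12))) < 3 || stats::sd(v) < 1e-12)
    return(list(threshold = mean(v), degenerate = TRUE))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(v, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(threshold = stats::median(v), degenerate = TRUE))
  mu <- fit$parameters$mean
  s2 <- fit$parameters$variance$sigmasq
  if (length(s2) == 1) s2 <- rep(s2, 2)
  pr <- fit$parameters$pro
  o <- order(mu); mu <- mu[o]; s2 <- s2[o]; pr <- pr[o]
  if (abs(mu[2] - mu[1]) < 1e-10)
    return(list(threshold = mu[1], degenerate = TRUE))
  f <- function(x) pr[1] * stats::dnorm(x, mu[1], sqrt(s2[1])) -
    pr[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
  root <- tryCatch(stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root,
                   error = function(e) NA_real_)
  if (is.na(root) || root < min(v) || root > max(v))
    return(list(threshold = mean(mu), degenerate = TRUE))
  list(threshold = root, degenerate = FALSE)
}

#' Memory estimate container
#'
#' @param modality one of \code{"signaling"}, \code{"morphology"},
#'   \code{"migration"}.
#' @param t_stimulus_end washout time (min).
#' @param t_memory_end detected end of memory, \code{Inf} for
#'   never-relaxing (memory at least as long as the observation window),
#'   \code{NA} for undetected/undefined.
#' @param rule short identifier of the detection rule.
#' @param ensemble logical: ensemble-level (vs per-cell) estimate.
#' @return object of class \code{memory_estimate} with a \code{duration}
#'   field.
#' @export
memory_estimate <- function(modality, t_stimulus_end, t_memory_end,
                            rule = "", ensemble = FALSE) {
  duration <- t_memory_end - t_stimulus_end
  if (is.finite(duration) && duration < 0) duration <- 0
  structure(list(modality = modality, t_stimulus_end = t_stimulus_end,
                 t_memory_end = t_memory_end, duration = duration,
                 rule = rule, ensemble = ensemble),
            class = "memory_estimate")
}

#' @export
print.memory_estimate <- function(x, ...) {
  dur <- if (is.na(x$duration)) "undetected"
  else if (is.infinite(x$duration)) ">= observation window"
  else sprintf("%.4g min", x$duration)
  cat(sprintf("%s memory: %s (washout at %g min, rule: %s)\n",
              x$modality, dur, x$t_stimulus_end, x$rule))
  invisible(x)
}

#' Signaling memory duration from the polarized-area fraction
#'
#' The fraction of membrane area in bins above (mean + s.d.) of the
#' normalised kymograph defines the polarized-area fraction FPA(t); memory
#' ends at the first post-washout time where FPA stays below its own
#' time-average minus one s.d. for \code{consecutive} samples.
#'
#' @param kymo normalised EGFRp [kymograph()] (see [egfrp_kymograph()]).
#' @param t_stim_end washout time (min).
#' @param consecutive samples required below threshold (default 3).
#' @param bin_areas optional per-bin areas.
#' @param threshold_window time window over which the FPA reference
#'   statistics (mean - sd) are taken; default the pre-washout interval
#'   \code{[0, t_stim_end]}, where the cell is driven to its polarized
#'   state.
#' @return a [memory_estimate()] (modality "signaling") with the FPA
#'   series in attribute \code{fpa}.
#' @export
polarization_memory <- function(kymo, t_stim_end, consecutive = 3L,
                                bin_areas = NULL,
                                threshold_window = c(0, t_stim_end)) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$mat
  if (is.null(bin_areas)) bin_areas <- rep(1, nrow(m))
  thr <- mean(m, na.rm = TRUE) + stats::sd(as.numeric(m), na.rm = TRUE)
  above <- m > thr
  fpa <- colSums(above * bin_areas, na.rm = TRUE) / sum(bin_areas)
  ref <- fpa[kymo$times >= threshold_window[1] &
               kymo$times <= threshold_window[2]]
  # no polarized membrane area at any reference time: nothing to lose
  if (all(ref < 1e-12)) {
    est <- memory_estimate("signaling", t_stim_end, t_stim_end,
                           rule = "no polarized area in reference window")
    attr(est, "fpa") <- data.frame(t = kymo$times, fpa = fpa)
    return(est)
  }
  fpa_thr <- mean(ref) - stats::sd(ref)
  post <- which(kymo$times >= t_stim_end)
  below <- fpa[post] < fpa_thr
  t_end <- Inf
  r <- rle(below)
  hit <- which(r$values & r$lengths >= consecutive)
  if (length(hit)) {
    first <- sum(r$lengths[seq_len(hit[1] - 1)]) + 1L
    t_end <- kymo$times[post[first]]
  }
  est <- memory_estimate("signaling", t_stim_end, t_end,
                         rule = "FPA < mean(FPA) - sd for 3 samples")
  attr(est, "fpa") <- data.frame(t = kymo$times, fpa = fpa)
  attr(est, "fpa_threshold") <- fpa_thr
  est
}

#' Inverse-sigmoid fit of a post-washout decay profile
#'
#' Fits \code{f(t) = a0 / (a^n + t^n)} by nonlinear least squares, with
#' \code{a} optionally fixed. The half-life (time at which half the initial
#' amplitude is lost) equals \code{a} exactly.
#'
#' @param t,y decay profile (t from washout, min).
#' @param fix_a fix the scale parameter at this value (NULL = free).
#' @param start optional start values.
#' @return object of class \code{sigmoid_fit}: \code{a0}, \code{a},
#'   \code{n}, \code{half_life}, \code{r_squared}, \code{converged}.
#' @export
fit_inverse_sigmoid <- function(t, y, fix_a = NULL, start = NULL) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 8) stop("fit_inverse_sigmoid: need >= 8 samples")
  if (is.null(start)) {
    y0 <- max(mean(y[seq_len(min(3, length(y)))]), 1e-9)
    t_half <- t[which.min(abs(y - y0 / 2))]
    start <- list(a0 = y0 * max(t_half, 1)^2, a = max(t_half, 1), n = 2)
  }
  converged <- TRUE
  if (is.null(fix_a)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a0 / (a^n + t^n), data = data.frame(t = t, y = y),
                        start = start,
                        lower = c(1e-12, 1e-6, 0.05), control =
                          minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    a_fix <- fix_a
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a0 / (a_fix^n + t^n),
                        data = data.frame(t = t, y = y),
                        start = start[c("a0", "n")],
                        lower = c(1e-12, 0.05), control =
                          minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(structure(list(a0 = NA_real_, a = NA_real_, n = NA_real_,
                          half_life = NA_real_, r_squared = NA_real_,
                          converged = FALSE),
                     class = "sigmoid_fit"))
  }
  cf <- stats::coef(fit)
  a_hat <- if (is.null(fix_a)) cf[["a"]] else fix_a
  resid <- stats::residuals(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  # half-life: smallest t with f(t) = f(0)/2; equals a for this family
  f0 <- cf[["a0"]] / a_hat^cf[["n"]]
  hl <- tryCatch(stats::uniroot(function(tt)
    cf[["a0"]] / (a_hat^cf[["n"]] + tt^cf[["n"]]) - f0 / 2,
    c(1e-9, max(t) * 100), tol = 1e-12)$root,
    error = function(e) a_hat)
  structure(list(a0 = cf[["a0"]], a = a_hat, n = cf[["n"]],
                 half_life = hl, r_squared = r2, converged = converged),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) { cat("inverse-sigmoid fit: NOT converged\n") }
  else cat(sprintf(
    "inverse-sigmoid fit: a0=%.4g a=%.4g n=%.4g (half-life %.4g min, R^2=%.3f)\n",
    x$a0, x$a, x$n, x$half_life, x$r_squared))
  invisible(x)
}

#' Time-delay embedding of a scalar series
#'
#' Savitzky--Golay smoothing followed by delay embedding
#' \code{X(t_i) = [x(t_i), x(t_i + d), ..., x(t_i + (m-1) d)]}. The delay
#' \code{d} defaults to the first lag at which the autocorrelation drops
#' below 1/e; the dimension \code{m} to the smallest with a false-nearest-
#' neighbour fraction below 5 percent (capped).
#'
#' @param series numeric vector.
#' @param d,m embedding delay (samples) and dimension; NULL = automatic.
#' @param smooth list with Savitzky-Golay \code{window} (odd) and
#'   \code{order}; NULL disables smoothing.
#' @param m_max dimension cap for the FNN search.
#' @param fnn_tol acceptable FNN fraction.
#' @return object of class \code{embedding_result}: \code{embedded} matrix
#'   (rows = \code{N - (m-1) d}), \code{d}, \code{m}, \code{fnn}
#'   (fractions per dimension), \code{capped} flag.
#' @export
takens_embedding <- function(series, d = NULL, m = NULL,
                             smooth = list(window = 11, order = 3),
                             m_max = 5, fnn_tol = 0.05) {
  x <- as.numeric(series)
  if (!is.null(smooth)) x <- savitzky_golay(x, smooth$window, smooth$order)
  N <- length(x)
  if (is.null(d)) {
    ac <- stats::acf(x, lag.max = min(N - 2, 200), plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    below <- which(ac < exp(-1))
    d <- if (length(below)) below[1] - 1L else max(1L, floor(N / 10))
    d <- max(1L, d)
  }
  fnn <- fnn_fractions(x, d, m_max)
  capped <- FALSE
  if (is.null(m)) {
    okm <- which(fnn < fnn_tol)
    if (length(okm)) m <- max(2L, okm[1]) else { m <- m_max; capped <- TRUE }
  }
  if (N <= (m - 1) * d + 10)
    stop("takens_embedding: series too short for m=", m, ", d=", d)
  rows <- N - (m - 1) * d
  emb <- vapply(0:(m - 1), function(j) x[(1 + j * d):(rows + j * d)],
                numeric(rows))
  structure(list(embedded = emb, d = d, m = m, fnn = fnn, capped = capped,
                 smoothed = x),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("delay embedding: d=%d samples, m=%d (%d points)%s\n",
              x$d, x$m, nrow(x$embedded),
              if (x$capped) " [FNN did not settle; dimension capped]" else ""))
  invisible(x)
}

# Savitzky-Golay smoothing by local polynomial least squares
savitzky_golay <- function(x, window = 11, order = 3) {
  n <- length(x)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  if (window < order + 2) return(x)
  half <- (window - 1) %/% 2
  k <- -half:half
  A <- outer(k, 0:order, "^")
  H <- solve(crossprod(A), t(A))
  w <- H[1, ]                      # centre-point smoother coefficients
  out <- x
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half
    if (lo >= 1 && hi <= n) out[i] <- sum(w * x[lo:hi])
    else {
      kk <- max(1, lo):min(n, hi)
      A2 <- outer(kk - i, 0:order, "^")
      out[i] <- (solve(crossprod(A2), t(A2)) %*% x[kk])[1]
    }
  }
  out
}

# false-nearest-neighbour fraction per embedding dimension; a neighbour is
# false if the next delay coordinate separates it strongly relative to the
# current distance (rtol) or to the attractor size (atol)
fnn_fractions <- function(x, d, m_max, rtol = 10, atol = 2) {
  N <- length(x)
  sdx <- stats::sd(x)
  out <- rep(NA_real_, m_max)
  for (m in 1:m_max) {
    rows <- N - m * d                 # need one extra coordinate
    if (rows < 10) break
    emb <- vapply(0:(m - 1), function(j) x[(1 + j * d):(rows + j * d)],
                  numeric(rows))
    if (m == 1) emb <- matrix(emb, ncol = 1)
    nxt <- x[(1 + m * d):(rows + m * d)]
    dd <- as.matrix(stats::dist(emb))
    diag(dd) <- Inf
    nn <- apply(dd, 1, which.min)
    dn <- dd[cbind(seq_len(rows), nn)]
    dn[dn < 1e-12] <- 1e-12
    false_nn <- (abs(nxt - nxt[nn]) / dn > rtol) |
      (abs(nxt - nxt[nn]) / sdx > atol)
    out[m] <- mean(false_nn)
  }
  out
}

#' Gradient alignment between local EGF and receptor phosphorylation
#'
#' Fits a wrapped Gaussian to the time-averaged spatial EGF projection
#' around the perimeter and reports the angle between the EGF maximum and
#' the phosphorylation maximum (bin distance times \code{2 pi / n_bins}).
#'
#' @param rec a [cell_fluorescence_record()] with the EGF channel.
#' @param kymo the cell's normalised EGFRp [kymograph()].
#' @param average_window time window (min) for the spatial projections
#'   (default: whole record).
#' @return list with the fitted Gaussian (centre bin, width, amplitude),
#'   \code{egf_max_bin}, \code{egfrp_max_bin} and \code{angle} (radians,
#'   in [0, pi]); \code{angle} is NA for a flat EGF profile.
#' @export
gradient_alignment <- function(rec, kymo, average_window = NULL) {
  stopifnot(inherits(rec, "cell_fluorescence_record"))
  if (is.null(rec$EGF_PM)) stop("gradient_alignment: record has no EGF channel")
  idx <- if (is.null(average_window)) seq_along(rec$times) else
    which(rec$times >= average_window[1] & rec$times <= average_window[2])
  egf <- rowMeans(rec$EGF_PM[, idx, drop = FALSE])
  n <- length(egf)
  if (max(egf) - min(egf) < 1e-9 * max(abs(egf), 1))
    return(list(fit = NULL, egf_max_bin = NA, egfrp_max_bin = NA,
                angle = NA_real_))
  th <- 2 * pi * (seq_len(n) - 0.5) / n
  i0 <- which.max(egf)
  df <- data.frame(th = th, egf = egf)
  fit <- tryCatch(minpack.lm::nlsLM(
    egf ~ base + A * exp(-((th - mu + pi) %% (2 * pi) - pi)^2 / (2 * s^2)),
    data = df,
    start = list(base = min(egf), A = diff(range(egf)), mu = th[i0], s = 1),
    lower = c(-Inf, 1e-9, -2 * pi, 0.05)),
    error = function(e) NULL)
  mu <- if (!is.null(fit)) stats::coef(fit)[["mu"]] %% (2 * pi) else th[i0]
  ep_mean <- rowMeans(kymo$mat[, idx, drop = FALSE], na.rm = TRUE)
  j0 <- which.max(ep_mean)
  bin_dist <- min(abs(i0 - j0), n - abs(i0 - j0))
  list(fit = if (!is.null(fit)) as.list(stats::coef(fit)) else NULL,
       mu = mu, egf_max_bin = i0, egfrp_max_bin = j0,
       angle = bin_dist * 2 * pi / n)
}
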