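# Morphology quantification from binary mask series: solidity, directed
# protrusion area, and the morphology memory-duration estimator.

# convex hull area of a binary mask (matrix with x/y coordinate attributes
# or plain matrix in pixel units)
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- attr(mask, "x"); y <- attr(mask, "y")
  if (is.null(x)) x <- seq_len(nrow(mask))
  if (is.null(y)) y <- seq_len(ncol(mask))
  cbind(x[idx[, 1]], y[idx[, 2]])
}

mask_pixel_area <- function(mask) {
  x <- attr(mask, "x")
  h <- if (is.null(x)) 1 else x[2] - x[1]
  h^2
}

# solidity = cell area / convex-hull area, both from the sub-pixel mask
# outline (marching-squares contour at level 0.5), so a filled convex
# shape gives 1 up to discretization
mask_solidity <- function(mask) {
  if (!any(mask)) stop("mask_solidity: empty mask")
  x <- attr(mask, "x"); y <- attr(mask, "y")
  if (is.null(x)) x <- seq_len(nrow(mask))
  if (is.null(y)) y <- seq_len(ncol(mask))
  h <- x[2] - x[1]
  # light blur before contouring: the convex hull would otherwise wrap the
  # outermost staircase corners of the pixelated outline, biasing the
  # solidity of smooth shapes low
  mm <- blur_numeric(mask * 1, 1)
  # pad so boundary-touching masks still close
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mm
  xp <- c(x[1] - h, x, x[length(x)] + h)
  yp <- c(y[1] - h, y, y[length(y)] + h)
  cl <- grDevices::contourLines(xp, yp, m, levels = 0.5)
  if (!length(cl)) stop("mask_solidity: no outline found")
  areas <- vapply(cl, function(cc) polygon_area(cbind(cc$x, cc$y)),
                  numeric(1))
  main <- which.max(areas)
  pts <- cbind(cl[[main]]$x, cl[[main]]$y)
  hull <- grDevices::chull(pts)
  a_hull <- polygon_area(pts[hull, , drop = FALSE])
  max(min(areas[main] / a_hull, 1), 0)
}

mask_centroid <- function(mask) {
  pts <- mask_coords(mask)
  colMeans(pts)
}

#' Shape metrics of a mask series: solidity and directed protrusion area
#'
#' Solidity is cell area over convex-hull area. The directed protrusion
#' area compares consecutive (Gaussian-smoothed) masks: new area gained in
#' front of the axis through the reference centroid perpendicular to the
#' gradient counts as frontal protrusion, behind it as rear protrusion,
#' combined as \code{A_prot_front/A_front - A_prot_back/A_back} and
#' smoothed along time. An area threshold (per protrusion event) is applied
#' for experimental-style masks and skipped for simulation masks.
#'
#' @param masks list of logical matrices (with optional \code{x}/\code{y}
#'   attributes giving physical coordinates) — one per frame.
#' @param times frame times (min).
#' @param gradient_direction 2-vector pointing toward the source.
#' @param pixel_size pixel edge (um) when masks lack coordinates.
#' @param area_threshold minimum protrusion area per frame pair (um^2);
#'   0 disables (simulation masks).
#' @param smooth_sigma_t s.d. (frames) of the 1-D Gaussian smoothing of
#'   the protrusion series.
#' @param smooth_sigma_px s.d. (pixels) of the 2-D Gaussian mask smoothing
#'   before differencing; 0 disables.
#' @return data frame with \code{t}, \code{solidity},
#'   \code{protrusion} (directed protrusion area series, first frame NA).
#' @export
shape_metrics <- function(masks, times, gradient_direction = c(1, 0),
                          pixel_size = NULL, area_threshold = 0,
                          smooth_sigma_t = 2, smooth_sigma_px = 1) {
  stopifnot(length(masks) == length(times))
  sol <- vapply(masks, mask_solidity, numeric(1))
  e <- gradient_direction / sqrt(sum(gradient_direction^2))
  n <- length(masks)
  prot <- rep(NA_real_, n)
  for (i in 2:n) {
    m0 <- masks[[i - 1]]; m1 <- masks[[i]]
    if (smooth_sigma_px > 0) {
      m0 <- gauss_blur_mask(m0, smooth_sigma_px)
      m1 <- gauss_blur_mask(m1, smooth_sigma_px)
    }
    px <- mask_pixel_area(masks[[i]])
    cen <- mask_centroid(masks[[i - 1]])
    pts <- mask_coords(masks[[i]])
    proj_all <- (pts[, 1] - cen[1]) * e[1] + (pts[, 2] - cen[2]) * e[2]
    gained <- m1 & !m0
    gpts <- mask_coords(structure(gained, x = attr(masks[[i]], "x"),
                                  y = attr(masks[[i]], "y")))
    if (nrow(gpts)) {
      gproj <- (gpts[, 1] - cen[1]) * e[1] + (gpts[, 2] - cen[2]) * e[2]
      a_front_new <- sum(gproj > 0) * px
      a_back_new <- sum(gproj <= 0) * px
      if (a_front_new < area_threshold) a_front_new <- 0
      if (a_back_new < area_threshold) a_back_new <- 0
    } else a_front_new <- a_back_new <- 0
    a_front <- max(sum(proj_all > 0) * px, 1e-9)
    a_back <- max(sum(proj_all <= 0) * px, 1e-9)
    prot[i] <- a_front_new / a_front - a_back_new / a_back
  }
  if (smooth_sigma_t > 0 && sum(!is.na(prot)) > 3)
    prot[-1] <- gauss_smooth_1d(prot[-1], smooth_sigma_t)
  data.frame(t = times, solidity = sol, protrusion = prot)
}

# separable Gaussian blur of a numeric matrix (sigma in pixels)
blur_numeric <- function(m, sigma) {
  k <- stats::dnorm(-ceiling(3 * sigma):ceiling(3 * sigma), sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[is.na(m)] <- 0
  m
}

# binarised 2-D Gaussian blur of a logical mask (separable kernel)
gauss_blur_mask <- function(mask, sigma) {
  out <- blur_numeric(mask * 1, sigma) >= 0.5
  attr(out, "x") <- attr(mask, "x"); attr(out, "y") <- attr(mask, "y")
  out
}

gauss_smooth_1d <- function(v, sigma) {
  k <- stats::dnorm(-ceiling(3 * sigma):ceiling(3 * sigma), sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  pad <- c(rep(v[1], length(k) %/% 2), v, rep(v[n], length(k) %/% 2))
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(length(k) %/% 2 + 1):(length(k) %/% 2 + n)])
}

#' Morphology memory duration from the solidity profile
#'
#' Polarized (protrusive) shapes have low solidity. The threshold is the
#' gradient-phase mean minus one s.d.; memory persists while the
#' post-washout solidity stays below it, and ends at the last time it is
#' still below before recovering.
#'
#' @param solidity numeric vector.
#' @param times frame times (min).
#' @param t_stim_end washout time (min).
#' @param t_stim_start gradient onset (min) for the threshold window.
#' @param consecutive consecutive above-threshold samples ending the
#'   below-threshold (polarized) run.
#' @return a [memory_estimate()] (modality "morphology"). The adopted
#'   reading of the rule: memory lasts while the post-washout solidity
#'   remains in the below-threshold run it is in at washout; it ends at the
#'   last below-threshold time before a sustained recovery.
#' @export
morphology_memory <- function(solidity, times, t_stim_end,
                              t_stim_start = 0, consecutive = 3L) {
  grad_idx <- times >= t_stim_start & times < t_stim_end
  if (!any(grad_idx)) stop("morphology_memory: no gradient-phase samples")
  thr <- mean(solidity[grad_idx]) - stats::sd(solidity[grad_idx])
  post <- which(times >= t_stim_end)
  below <- solidity[post] < thr
  rule <- "solidity < mean - sd (gradient phase)"
  if (!any(solidity[grad_idx] < thr) && !any(below))
    return(memory_estimate("morphology", t_stim_end, NA_real_, rule = rule))
  if (!below[1])
    return(memory_estimate("morphology", t_stim_end, t_stim_end,
                           rule = rule))
  # end of the washout-containing polarized run: first sustained recovery
  above <- !below
  r <- rle(above)
  hit <- which(r$values & r$lengths >= consecutive)
  if (!length(hit)) return(memory_estimate("morphology", t_stim_end, Inf,
                                           rule = rule))
  first_rec <- sum(r$lengths[seq_len(hit[1] - 1)]) + 1L
  t_end <- times[post[first_rec - 1]]
  memory_estimate("morphology", t_stim_end, t_end, rule = rule)
}
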