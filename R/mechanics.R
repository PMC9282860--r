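# Level-set model of signal-driven cell-shape change and migration.
# The cell boundary is the zero level set of a potential Psi on a fixed 2-D
# Cartesian grid (Psi < 0 inside). A viscoelastic cortex (Voigt element:
# spring kc in parallel with dashpot tau_c) in series with a viscous
# cytoplasm (tau_a) converts the boundary pressure profile into a normal
# membrane velocity; membrane signaling (Ep) sets the protrusion/retraction
# pressures.

#' Mechanical parameters of the cell model
#'
#' @param kc cortex elastic constant (nN/um^3).
#' @param tau_c cortex viscosity (nN min/um^3).
#' @param tau_a cytoplasm viscosity (nN min/um^3).
#' @param Kprot,Kretr protrusion / retraction pressure scales (nN/um^2).
#' @param Karea area-conservation pressure scale (nN/um^4).
#' @param Kten cortical tension scale (nN/um).
#' @param R rest radius (um).
#' @param pts_per_um grid resolution (points per um).
#' @param dt time step (min).
#' @return object of class \code{mech_params}.
#' @export
mech_params <- function(kc = 0.1, tau_c = 0.08, tau_a = 0.1,
                        Kprot = 0.08, Kretr = 0.05, Karea = 0.02,
                        Kten = 0.1, R = 2, pts_per_um = 5, dt = 0.01) {
  p <- list(kc = kc, tau_c = tau_c, tau_a = tau_a, Kprot = Kprot,
            Kretr = Kretr, Karea = Karea, Kten = Kten, R = R,
            pts_per_um = pts_per_um, dt = dt)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("mech_params: all parameters must be positive numbers")
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    "cell mechanics: kc=%.3g tau_c=%.3g tau_a=%.3g | Kprot=%.3g Kretr=%.3g Karea=%.3g Kten=%.3g\n",
    x$kc, x$tau_c, x$tau_a, x$Kprot, x$Kretr, x$Karea, x$Kten))
  cat(sprintf("  R=%.3g um, %g pts/um, dt=%.3g min\n",
              x$R, x$pts_per_um, x$dt))
  invisible(x)
}

#' Signed-distance level-set field for a circular cell
#'
#' @param center circle centre \code{c(x, y)} (um, lab frame).
#' @param R radius (um).
#' @param extent half-width of the square grid (um), centred on
#'   \code{center}.
#' @param pts_per_um grid resolution.
#' @return object of class \code{levelset_field}: matrix \code{psi}
#'   (negative inside), axis coordinates \code{x}, \code{y}, spacing
#'   \code{h}.
#' @export
init_signed_distance <- function(center = c(0, 0), R = 2, extent = 8,
                                 pts_per_um = 5) {
  h <- 1 / pts_per_um
  if (extent < R + 5 * h)
    stop("init_signed_distance: grid margin below 5 cells")
  x <- seq(center[1] - extent, center[1] + extent, by = h)
  y <- seq(center[2] - extent, center[2] + extent, by = h)
  psi <- sqrt(outer((x - center[1])^2, (y - center[2])^2, "+")) - R
  structure(list(psi = psi, x = x, y = y, h = h), class = "levelset_field")
}

# matrix shift with edge replication (axis 1 = x index, 2 = y index)
shift_mat <- function(m, di = 0, dj = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- pmin(pmax(seq_len(n1) + di, 1L), n1)
  j <- pmin(pmax(seq_len(n2) + dj, 1L), n2)
  m[i, j, drop = FALSE]
}

grad_central <- function(m, h)
  list(gx = (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / (2 * h),
       gy = (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / (2 * h))

# curvature div(grad psi / |grad psi|) by central differences
curvature_field <- function(psi, h) {
  g <- grad_central(psi, h)
  nrm <- sqrt(g$gx^2 + g$gy^2)
  nrm[nrm < 1e-9] <- 1e-9
  nx <- g$gx / nrm; ny <- g$gy / nrm
  (shift_mat(nx, 1, 0) - shift_mat(nx, -1, 0)) / (2 * h) +
    (shift_mat(ny, 0, 1) - shift_mat(ny, 0, -1)) / (2 * h)
}

# bilinear interpolation of grid matrix at points (px, py)
bilinear <- function(m, x, y, px, py) {
  h <- x[2] - x[1]
  fi <- (px - x[1]) / h; fj <- (py - y[1]) / h
  i0 <- pmin(pmax(floor(fi), 0), length(x) - 2); wi <- fi - i0
  j0 <- pmin(pmax(floor(fj), 0), length(y) - 2); wj <- fj - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  m[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    m[cbind(i0 + 1, j0)] * wi * (1 - wj) +
    m[cbind(i0, j0 + 1)] * (1 - wi) * wj +
    m[cbind(i0 + 1, j0 + 1)] * wi * wj
}

# closed-contour extraction; errors on empty or multi-component zero sets
extract_contour <- function(field, strict = TRUE) {
  cl <- grDevices::contourLines(field$x, field$y, field$psi, levels = 0)
  if (!length(cl))
    stop("extract_contour: empty zero level set")
  if (length(cl) > 1L) {
    # sub-resolution satellite blobs (grid noise) are dropped; a genuine
    # pinch-off (second component of comparable size) aborts the run
    ar <- vapply(cl, function(cc) polygon_area(cbind(cc$x, cc$y)),
                 numeric(1))
    main <- which.max(ar)
    if (strict && any(ar[-main] > 0.01 * ar[main]))
      stop("extract_contour: zero set has ", length(cl),
           " components (topology change)")
    cl <- cl[main]
  }
  cx <- cl[[1]]$x; cy <- cl[[1]]$y
  n <- length(cx)
  if (n > 1 && cx[1] == cx[n] && cy[1] == cy[n]) { cx <- cx[-n]; cy <- cy[-n] }
  cbind(x = cx, y = cy)
}

polygon_area <- function(pt) {
  x <- pt[, 1]; y <- pt[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(pt) {
  x <- pt[, 1]; y <- pt[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

#' Contour geometry of a level-set field
#'
#' @param field a [init_signed_distance()] field (or any
#'   \code{levelset_field}).
#' @return list with contour \code{points} (n x 2), outward unit
#'   \code{normals}, \code{kappa} (curvature at the points), enclosed
#'   \code{area} and \code{centroid}.
#' @export
contour_geometry <- function(field) {
  pt <- extract_contour(field)
  g <- grad_central(field$psi, field$h)
  nx <- bilinear(g$gx, field$x, field$y, pt[, 1], pt[, 2])
  ny <- bilinear(g$gy, field$x, field$y, pt[, 1], pt[, 2])
  nrm <- sqrt(nx^2 + ny^2); nrm[nrm < 1e-9] <- 1e-9
  kap <- curvature_field(field$psi, field$h)
  list(points = pt,
       normals = cbind(nx / nrm, ny / nrm),
       kappa = bilinear(kap, field$x, field$y, pt[, 1], pt[, 2]),
       area = polygon_area(pt),
       centroid = polygon_centroid(pt))
}

#' Boundary pressures from membrane signaling
#'
#' Protrusion acts where local Ep exceeds the contour mean, retraction where
#' it falls below, each normalised by the respective dynamic range;
#' a uniform area-conservation pressure restores the initial area and
#' cortical tension opposes curvature deviations from the rest circle.
#'
#' @param Ep_contour Ep sampled at the contour points.
#' @param geometry result of [contour_geometry()].
#' @param A0 reference (initial) area.
#' @param mech a [mech_params()].
#' @return list of per-point scalar pressures \code{Pprot} (>= 0),
#'   \code{Pretr} (<= 0), \code{Parea}, \code{Pten} and their sum
#'   \code{Ptotal}, all acting along the outward normal.
#' @export
boundary_pressures <- function(Ep_contour, geometry, A0, mech) {
  stopifnot(inherits(mech, "mech_params"))
  m <- mean(Ep_contour); hi <- max(Ep_contour); lo <- min(Ep_contour)
  Pprot <- rep(0, length(Ep_contour))
  if (hi - m > 1e-9) {
    up <- Ep_contour > m
    Pprot[up] <- mech$Kprot * (Ep_contour[up] - m) / (hi - m)
  }
  Pretr <- rep(0, length(Ep_contour))
  if (m - lo > 1e-9) {
    dn <- Ep_contour < m
    Pretr[dn] <- -mech$Kretr * (m - Ep_contour[dn]) / (m - lo)
  }
  Parea <- rep(mech$Karea * (A0 - geometry$area), length(Ep_contour))
  Pten <- mech$Kten * (geometry$kappa - 1 / mech$R)
  list(Pprot = Pprot, Pretr = Pretr, Parea = Parea, Pten = Pten,
       Ptotal = Pprot + Pretr + Parea - Pten)
}

# ENO2 one-sided differences (x direction = rows); returns list(minus, plus)
eno2_diff <- function(m, h, axis) {
  s <- function(d) if (axis == 1) shift_mat(m, d, 0) else shift_mat(m, 0, d)
  d2 <- (s(1) - 2 * m + s(-1)) / h^2
  d2p <- if (axis == 1) shift_mat(d2, 1, 0) else shift_mat(d2, 0, 1)
  d2m <- if (axis == 1) shift_mat(d2, -1, 0) else shift_mat(d2, 0, -1)
  minmod <- function(a, b) ifelse(a * b <= 0, 0, ifelse(abs(a) < abs(b), a, b))
  list(minus = (m - s(-1)) / h + (h / 2) * minmod(d2m, d2),
       plus  = (s(1) - m) / h - (h / 2) * minmod(d2, d2p))
}

upwind1_diff <- function(m, h, axis) {
  s <- function(d) if (axis == 1) shift_mat(m, d, 0) else shift_mat(m, 0, d)
  list(minus = (m - s(-1)) / h, plus = (s(1) - m) / h)
}

# Godunov |grad psi| for speed F (matrix), with ENO2 or first-order scheme
godunov_grad <- function(psi, h, F, scheme = "eno2") {
  dfun <- if (scheme == "eno2") eno2_diff else upwind1_diff
  dx <- dfun(psi, h, 1); dy <- dfun(psi, h, 2)
  pos <- F > 0
  gx2 <- ifelse(pos, pmax(pmax(dx$minus, 0)^2, pmin(dx$plus, 0)^2),
                pmax(pmin(dx$minus, 0)^2, pmax(dx$plus, 0)^2))
  gy2 <- ifelse(pos, pmax(pmax(dy$minus, 0)^2, pmin(dy$plus, 0)^2),
                pmax(pmin(dy$minus, 0)^2, pmax(dy$plus, 0)^2))
  sqrt(gx2 + gy2)
}

#' One explicit step of the coupled level-set / viscoelastic dynamics
#'
#' Advances the potential by the Hamilton--Jacobi advection
#' \code{dPsi/dt + F |grad Psi| = 0} and the cortex state by
#' \code{dl/dt = -kc/tau_c l + Ptotal/tau_c - v . grad l}, where the normal
#' speed is \code{F = -kc/tau_c l + (1/tau_c + 1/tau_a) Ptotal}. \code{F}
#' and \code{Ptotal} must already be extended off the interface (constant
#' along normals).
#'
#' @param field \code{levelset_field}.
#' @param l cortex elongation matrix (same shape as \code{field$psi}).
#' @param F_ext,P_ext extended normal speed and total pressure matrices.
#' @param mech a [mech_params()].
#' @param scheme \code{"eno2"} (default) or \code{"upwind1"}.
#' @param dt time step; defaults to \code{mech$dt}. Internally halved
#'   (up to 4 times) if the advective CFL condition is violated.
#' @return list \code{(field, l)} after one step of length \code{dt}.
#' @export
mechanics_step <- function(field, l, F_ext, P_ext, mech,
                           scheme = c("eno2", "upwind1"), dt = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(dt)) dt <- mech$dt
  h <- field$h
  vmax <- max(abs(F_ext))
  n_sub <- 1L
  while (vmax * dt / n_sub > h && n_sub < 16L) n_sub <- n_sub * 2L
  if (vmax * dt / n_sub > h)
    stop("mechanics_step: CFL violation persists after 4 halvings")
  dts <- dt / n_sub
  g <- grad_central(field$psi, h)
  nrm <- sqrt(g$gx^2 + g$gy^2); nrm[nrm < 1e-9] <- 1e-9
  u <- F_ext * g$gx / nrm      # advection velocity components for l
  w <- F_ext * g$gy / nrm
  for (s in seq_len(n_sub)) {
    gg <- godunov_grad(field$psi, h, F_ext, scheme)
    psi_new <- field$psi - dts * F_ext * gg
    dlx <- upwind1_diff(l, h, 1); dly <- upwind1_diff(l, h, 2)
    adv <- ifelse(u > 0, u * dlx$minus, u * dlx$plus) +
      ifelse(w > 0, w * dly$minus, w * dly$plus)
    l <- l + dts * (-mech$kc / mech$tau_c * l + P_ext / mech$tau_c - adv)
    field$psi <- psi_new
  }
  list(field = field, l = l)
}

# periodic-spline upsampling of a closed contour; re-distancing to the raw
# grid-edge polyline cuts corners (inward bias ~ kappa * chord^2 / 8 per
# pass), so the polyline is refined before distances are taken
resample_contour <- function(pt, factor = 4) {
  n <- nrow(pt)
  if (n < 8) return(pt)
  step <- sqrt(diff(c(pt[, 1], pt[1, 1]))^2 +
                 diff(c(pt[, 2], pt[1, 2]))^2)
  keep <- c(TRUE, step[-length(step)] > 1e-9)   # drop duplicate vertices
  pt <- pt[keep, , drop = FALSE]
  n <- nrow(pt)
  if (n < 8) return(pt)
  s <- c(0, cumsum(sqrt(diff(c(pt[, 1], pt[1, 1]))^2 +
                          diff(c(pt[, 2], pt[1, 2]))^2)))
  xs <- c(pt[, 1], pt[1, 1]); ys <- c(pt[, 2], pt[1, 2])
  s_new <- seq(0, s[n + 1], length.out = n * factor + 1)[-(n * factor + 1)]
  cbind(x = stats::spline(s, xs, xout = s_new, method = "periodic")$y,
        y = stats::spline(s, ys, xout = s_new, method = "periodic")$y)
}

# exact signed re-distancing from the (refined) contour polyline
reinitialize_psi <- function(field, contour_pts) {
  contour_pts <- resample_contour(contour_pts)
  gx <- rep(field$x, times = length(field$y))
  gy <- rep(field$y, each = length(field$x))
  n <- nrow(contour_pts)
  x1 <- contour_pts[, 1]; y1 <- contour_pts[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dxs <- x2 - x1; dys <- y2 - y1
  len2 <- pmax(dxs^2 + dys^2, 1e-12)
  dmin <- rep(Inf, length(gx))
  for (k in seq_len(n)) {
    t <- pmin(pmax(((gx - x1[k]) * dxs[k] + (gy - y1[k]) * dys[k]) /
                     len2[k], 0), 1)
    d2 <- (gx - (x1[k] + t * dxs[k]))^2 + (gy - (y1[k] + t * dys[k]))^2
    dmin <- pmin(dmin, d2)
  }
  d <- sqrt(dmin)
  sgn <- ifelse(field$psi < 0, -1, 1)
  field$psi <- matrix(sgn * d, nrow(field$psi), ncol(field$psi))
  field
}

# map contour-point values onto the grid by nearest contour point,
# within a narrow band |psi| <= band (um); 0 outside the band
extend_from_contour <- function(field, contour_pts, values, band) {
  out <- matrix(0, nrow(field$psi), ncol(field$psi))
  idx <- which(abs(field$psi) <= band, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  px <- field$x[idx[, 1]]; py <- field$y[idx[, 2]]
  nn <- vapply(seq_along(px), function(i)
    which.min((contour_pts[, 1] - px[i])^2 + (contour_pts[, 2] - py[i])^2),
    integer(1))
  out[idx] <- values[nn]
  out
}

#' Simulate signal-driven cell-shape change and migration
#'
#' Couples an Ep kymograph (the membrane signaling state) to the level-set
#' mechanical model: at each step the kymograph value of the angular sector
#' containing each contour point (angles measured from the current centroid,
#' lab frame) sets the protrusion/retraction pressures, and the boundary is
#' advected with the viscoelastic normal velocity. The grid is a moving
#' window re-centred on the cell when it approaches a border. Deterministic
#' given the kymograph.
#'
#' @param kymo Ep [kymograph()] covering \code{[0, t_end]}.
#' @param mech a [mech_params()].
#' @param t_end simulated time (min); defaults to the kymograph range.
#' @param frame_dt interval between stored frames (min).
#' @param extent half-width of the moving grid window (um).
#' @param band extension band half-width (um); default 6 grid cells.
#' @param reinit_every re-distancing period (steps).
#' @param scheme advection scheme, see [mechanics_step()].
#' @return object of class \code{cell_shape_series}: per-frame binary
#'   \code{masks} (list of logical matrices with \code{x}/\code{y} attrs),
#'   \code{times}, \code{centroids} (lab frame, um), \code{areas},
#'   \code{contours}, and the centroid \code{track} as a data frame.
#' @export
simulate_cell <- function(kymo, mech = mech_params(), t_end = NULL,
                          frame_dt = 1, extent = 6, band = NULL,
                          reinit_every = 50L, scheme = "eno2") {
  stopifnot(inherits(kymo, "kymograph"), inherits(mech, "mech_params"))
  if (is.null(t_end)) t_end <- max(kymo$times)
  if (max(kymo$times) < t_end - 1e-9)
    stop("simulate_cell: kymograph does not cover [0, t_end]")
  h <- 1 / mech$pts_per_um
  if (is.null(band)) band <- 6 * h
  dt <- mech$dt
  n_bins <- nrow(kymo$mat)
  field <- init_signed_distance(c(0, 0), mech$R, extent, mech$pts_per_um)
  l <- matrix(0, nrow(field$psi), ncol(field$psi))
  A0 <- pi * mech$R^2
  n_steps <- ceiling(t_end / dt)
  frame_every <- max(1L, round(frame_dt / dt))
  frames <- list(); f_idx <- 0L
  geom <- contour_geometry(field)
  kymo_col <- function(t) {
    # linear interpolation between stored kymograph columns
    it <- findInterval(t, kymo$times, all.inside = TRUE)
    w <- (t - kymo$times[it]) / (kymo$times[it + 1] - kymo$times[it])
    kymo$mat[, it] * (1 - w) + kymo$mat[, it + 1] * pmin(pmax(w, 0), 1)
  }
  record <- function(t, geom) {
    f_idx <<- f_idx + 1L
    mask <- field$psi < 0
    attr(mask, "x") <- field$x; attr(mask, "y") <- field$y
    frames[[f_idx]] <<- list(t = t, mask = mask, centroid = geom$centroid,
                             area = geom$area, contour = geom$points)
  }
  record(0, geom)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    if (s %% reinit_every == 0L) {
      pt <- extract_contour(field)
      field <- reinitialize_psi(field, pt)
    }
    geom <- contour_geometry(field)
    # sector lookup: angle from current centroid, lab frame
    ang <- atan2(geom$points[, 2] - geom$centroid[2],
                 geom$points[, 1] - geom$centroid[1]) %% (2 * pi)
    sector <- pmin(floor(ang / (2 * pi / n_bins)) + 1L, n_bins)
    Ep_c <- kymo_col(t)[sector]
    pr <- boundary_pressures(Ep_c, geom, A0, mech)
    l_c <- bilinear(l, field$x, field$y, geom$points[, 1], geom$points[, 2])
    F_c <- -mech$kc / mech$tau_c * l_c +
      (1 / mech$tau_c + 1 / mech$tau_a) * pr$Ptotal
    F_ext <- extend_from_contour(field, geom$points, F_c, band)
    P_ext <- extend_from_contour(field, geom$points, pr$Ptotal, band)
    st <- mechanics_step(field, l, F_ext, P_ext, mech, scheme = scheme)
    field <- st$field; l <- st$l
    # moving window: translate grid by whole cells when cell drifts off-centre
    cen <- geom$centroid
    gc <- c(mean(range(field$x)), mean(range(field$y)))
    if (max(abs(cen - gc)) > extent / 3) {
      di <- round((cen[1] - gc[1]) / h); dj <- round((cen[2] - gc[2]) / h)
      big <- max(field$psi)
      ps <- matrix(big, nrow(field$psi), ncol(field$psi))
      ln <- matrix(0, nrow(field$psi), ncol(field$psi))
      i_src <- seq_len(nrow(ps)) + di; j_src <- seq_len(ncol(ps)) + dj
      ok_i <- i_src >= 1 & i_src <= nrow(ps)
      ok_j <- j_src >= 1 & j_src <= ncol(ps)
      ps[which(ok_i), which(ok_j)] <- field$psi[i_src[ok_i], j_src[ok_j]]
      ln[which(ok_i), which(ok_j)] <- l[i_src[ok_i], j_src[ok_j]]
      field$psi <- ps; l <- ln
      field$x <- field$x + di * h; field$y <- field$y + dj * h
      pt <- extract_contour(field)
      field <- reinitialize_psi(field, pt)
    }
    if (s %% frame_every == 0L) record(s * dt, contour_geometry(field))
  }
  times <- vapply(frames, `[[`, numeric(1), "t")
  cents <- t(vapply(frames, `[[`, numeric(2), "centroid"))
  areas <- vapply(frames, `[[`, numeric(1), "area")
  structure(list(masks = lapply(frames, `[[`, "mask"),
                 times = times,
                 centroids = cents, areas = areas,
                 contours = lapply(frames, `[[`, "contour"),
                 track = data.frame(t = times, x = cents[, 1],
                                    y = cents[, 2]),
                 mech = mech, A0 = A0),
            class = "cell_shape_series")
}

#' @export
print.cell_shape_series <- function(x, ...) {
  disp <- sqrt(sum((x$centroids[nrow(x$centroids), ] - x$centroids[1, ])^2))
  cat(sprintf("cell shape series: %d frames over %g min\n",
              length(x$times), max(x$times)))
  cat(sprintf("  area drift: %.2f%%; net centroid displacement: %.2f um\n",
              100 * (x$areas[length(x$areas)] - x$areas[1]) / x$areas[1],
              disp))
  invisible(x)
}

#' @export
plot.cell_shape_series <- function(x, ...) {
  graphics::plot(x$track$x, x$track$y, type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "centroid trajectory", ...)
  last <- x$contours[[length(x$contours)]]
  graphics::polygon(last[, 1], last[, 2], border = "red")
  invisible(x)
}

#' Mean centroid speed of a simulated cell
#'
#' @param sim a [simulate_cell()] result.
#' @param t_range optional window \code{c(t0, t1)} (min).
#' @return mean frame-to-frame centroid speed (um/min).
#' @export
mean_centroid_speed <- function(sim, t_range = NULL) {
  keep <- if (is.null(t_range)) rep(TRUE, length(sim$times)) else
    sim$times >= t_range[1] & sim$times <= t_range[2]
  tr <- sim$centroids[keep, , drop = FALSE]
  tt <- sim$times[keep]
  if (nrow(tr) < 2) return(NA_real_)
  mean(sqrt(diff(tr[, 1])^2 + diff(tr[, 2])^2) / diff(tt))
}
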