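# Level-set cell mechanics: signed distance, contour geometry, pressure
# laws, stepping, and short coupled simulations.

test_that("signed distance field has the defining properties", {
  f <- init_signed_distance(c(0, 0), R = 2, extent = 8, pts_per_um = 5)
  i0 <- which.min(abs(f$x)); j0 <- which.min(abs(f$y))
  expect_equal(f$psi[i0, j0], -2)
  # zero on the circle to within half a grid cell
  pt <- ghostnav:::extract_contour(f)
  r <- sqrt(pt[, 1]^2 + pt[, 2]^2)
  expect_lt(max(abs(r - 2)), f$h / 2)
  # unit gradient away from the centre (kink) and the grid border
  g <- ghostnav:::grad_central(f$psi, f$h)
  nrm <- sqrt(g$gx^2 + g$gy^2)
  rr <- sqrt(outer(f$x^2, f$y^2, "+"))
  interior <- rr > 1.5 &
    row(f$psi) > 2 & row(f$psi) < nrow(f$psi) - 1 &
    col(f$psi) > 2 & col(f$psi) < ncol(f$psi) - 1
  expect_lt(max(abs(nrm[interior] - 1)), 5e-3)
  expect_error(init_signed_distance(c(0, 0), R = 2, extent = 2.5),
               "margin")
})

test_that("contour geometry recovers circle and ellipse analytics", {
  f <- init_signed_distance(c(0, 0), R = 2, extent = 8, pts_per_um = 5)
  g <- contour_geometry(f)
  expect_true(all(abs(g$kappa - 0.5) < 0.02 * 0.5 + 0.01))
  expect_lt(abs(g$area - 4 * pi) / (4 * pi), 0.01)
  expect_lt(max(abs(g$centroid)), 1e-6)
  # outward normals point away from the centre
  rad <- g$points / sqrt(rowSums(g$points^2))
  expect_gt(min(rowSums(rad * g$normals)), 0.99)
  # ellipse 2:1 vertex curvatures match a/b^2 and b/a^2
  a <- 2; b <- 1
  h <- 0.04
  x <- seq(-4, 4, by = h); y <- seq(-4, 4, by = h)
  psi <- sqrt(outer(x^2 / a^2, y^2 / b^2, "+")) - 1
  fe <- structure(list(psi = psi, x = x, y = y, h = h),
                  class = "levelset_field")
  fe <- ghostnav:::reinitialize_psi(fe, ghostnav:::extract_contour(fe))
  ge <- contour_geometry(fe)
  at_x_vertex <- abs(abs(ge$points[, 1]) - a) < 0.05
  at_y_vertex <- abs(ge$points[, 1]) < 0.15      # flat ends around x = 0
  expect_lt(abs(mean(ge$kappa[at_x_vertex]) - a / b^2) / (a / b^2), 0.05)
  expect_lt(abs(mean(ge$kappa[at_y_vertex]) - b / a^2) / (b / a^2), 0.05)
})

test_that("boundary pressures follow the printed laws", {
  f <- init_signed_distance(c(0, 0), R = 2, extent = 8, pts_per_um = 5)
  g <- contour_geometry(f)
  m <- mech_params()
  n_pt <- nrow(g$points)
  # mechanical equilibrium: uniform signal, rest area, rest curvature
  pr <- boundary_pressures(rep(0.7, n_pt), g, g$area, m)
  expect_lt(max(abs(pr$Ptotal)), 2e-3)
  # protrusion peaks at the signal maximum, retraction at the minimum
  th <- atan2(g$points[, 2], g$points[, 1])
  ep <- 0.5 + 0.3 * cos(th)
  pr2 <- boundary_pressures(ep, g, g$area, m)
  expect_equal(which.max(pr2$Pprot), which.max(cos(th)))
  expect_equal(which.min(pr2$Pretr), which.min(cos(th)))
  expect_true(all(pr2$Pprot >= 0) && all(pr2$Pretr <= 0))
  expect_equal(max(pr2$Pprot), m$Kprot)
  expect_equal(min(pr2$Pretr), -m$Kretr)
  # 10% area deficit: uniform outward pressure Karea * dA
  pr3 <- boundary_pressures(rep(0.7, n_pt), g, g$area / 0.9, m)
  expect_equal(mean(pr3$Parea), m$Karea * 0.1 * g$area / 0.9,
               tolerance = 1e-10)
  expect_lt(diff(range(pr3$Parea)), 1e-12)
})

test_that("mechanics stepping matches hand-integrated limits", {
  m <- mech_params()
  f <- init_signed_distance(c(0, 0), R = 2, extent = 8, pts_per_um = 5)
  l <- matrix(0, nrow(f$psi), ncol(f$psi))
  # zero pressure and relaxed cortex: nothing moves
  z <- matrix(0, nrow(f$psi), ncol(f$psi))
  st <- mechanics_step(f, l, z, z, m)
  expect_equal(st$field$psi, f$psi)
  expect_equal(st$l, l)
  # constant outward pressure: radius grows at (1/tau_c + 1/tau_a) P per
  # unit time while the cortex is unstretched
  P <- 0.05
  g <- contour_geometry(f)
  gain <- (1 / m$tau_c + 1 / m$tau_a)
  Fc <- rep(gain * P, nrow(g$points))
  Fe <- ghostnav:::extend_from_contour(f, g$points, Fc, 1.2)
  Pe <- ghostnav:::extend_from_contour(f, g$points, rep(P, nrow(g$points)),
                                       1.2)
  field2 <- f; l2 <- l
  for (i in 1:10) {
    st <- mechanics_step(field2, l2, Fe, Pe, m)
    field2 <- st$field; l2 <- st$l
  }
  r_grown <- sqrt(contour_geometry(field2)$area / pi) - sqrt(g$area / pi)
  # l is charging up over these steps, so growth is slightly below the
  # unstretched-cortex rate
  expect_close(r_grown, gain * P * 10 * m$dt, 0.15)
  # sustained pressure: cortex saturates at P/kc, speed approaches P/tau_a
  lband <- abs(f$psi) <= 1.2
  l_inf <- P / m$kc
  l3 <- matrix(0, nrow(f$psi), ncol(f$psi))
  field3 <- f
  for (i in 1:400) {   # 4 min >> cortex time constant tau_c/kc = 0.8 min
    g3 <- contour_geometry(field3)
    l_c <- ghostnav:::bilinear(l3, field3$x, field3$y, g3$points[, 1],
                               g3$points[, 2])
    Fc <- -m$kc / m$tau_c * l_c + gain * P
    Fe <- ghostnav:::extend_from_contour(field3, g3$points, Fc, 1.2)
    Pe <- ghostnav:::extend_from_contour(field3, g3$points,
                                         rep(P, length(Fc)), 1.2)
    st <- mechanics_step(field3, l3, Fe, Pe, m)
    field3 <- st$field; l3 <- st$l
    if (i %% 50 == 0)
      field3 <- ghostnav:::reinitialize_psi(
        field3, ghostnav:::extract_contour(field3))
  }
  g3 <- contour_geometry(field3)
  l_c <- ghostnav:::bilinear(l3, field3$x, field3$y, g3$points[, 1],
                             g3$points[, 2])
  expect_close(mean(l_c), l_inf, 0.1)
  F_now <- -m$kc / m$tau_c * mean(l_c) + gain * P
  expect_close(F_now, P / m$tau_a, 0.15)
})

test_that("uniform signal keeps the simulated cell round and still", {
  k <- kymograph(matrix(0.5, 20, 16), seq(0, 15), 2 * pi * (1:20 - 0.5) / 20)
  cs <- simulate_cell(k, mech_params(), t_end = 15)
  sol <- vapply(cs$masks, ghostnav:::mask_solidity, numeric(1))
  expect_true(all(sol > 0.98))
  drift <- sqrt(sum((cs$centroids[nrow(cs$centroids), ] -
                       cs$centroids[1, ])^2))
  expect_lt(drift, 0.05)
  expect_lt(max(abs(cs$areas - cs$areas[1])) / cs$areas[1], 0.01)
})

test_that("polarized signal moves the cell toward the signal maximum", {
  tt <- seq(0, 20, 0.5)
  th <- 2 * pi * (1:20 - 0.5) / 20
  m <- 0.2 + 0.6 * outer(pmax(cos(th), 0), rep(1, length(tt)))
  k <- kymograph(m, tt, th)
  cs <- simulate_cell(k, mech_params(), t_end = 20)
  disp <- cs$centroids[nrow(cs$centroids), ] - cs$centroids[1, ]
  expect_gt(disp[1], 0.5)              # moves along +x (the Ep maximum)
  expect_lt(abs(disp[2]), 0.3 * disp[1])
})

test_that("halving the time step barely moves the final centroid", {
  tt <- seq(0, 12, 0.5)
  th <- 2 * pi * (1:20 - 0.5) / 20
  m <- 0.2 + 0.6 * outer(pmax(cos(th), 0), rep(1, length(tt)))
  k <- kymograph(m, tt, th)
  c1 <- simulate_cell(k, mech_params(dt = 0.01), t_end = 12)
  c2 <- simulate_cell(k, mech_params(dt = 0.005), t_end = 12)
  d1 <- c1$centroids[nrow(c1$centroids), ]
  d2 <- c2$centroids[nrow(c2$centroids), ]
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d1^2)), 0.05)
})

test_that("rotating the kymograph rotates the trajectory", {
  tt <- seq(0, 12, 0.5)
  th <- 2 * pi * (1:20 - 0.5) / 20
  base <- 0.2 + 0.6 * pmax(cos(th), 0)
  k1 <- kymograph(outer(base, rep(1, length(tt))), tt, th)
  shift <- 5    # quarter turn of the 20-bin ring
  k2 <- kymograph(outer(base[((seq_len(20) - 1 - shift) %% 20) + 1],
                        rep(1, length(tt))), tt, th)
  c1 <- simulate_cell(k1, mech_params(), t_end = 12)
  c2 <- simulate_cell(k2, mech_params(), t_end = 12)
  d1 <- c1$centroids[nrow(c1$centroids), ] - c1$centroids[1, ]
  d2 <- c2$centroids[nrow(c2$centroids), ] - c2$centroids[1, ]
  rot <- matrix(c(0, 1, -1, 0), 2, 2)  # +90 degrees
  expect_lt(sqrt(sum((rot %*% d1 - d2)^2)), 0.15 * sqrt(sum(d1^2)) + 0.05)
})
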