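# mOU migration model: simulation statistics, MSD/VACF estimators,
# parameter-recovery fitting, directionality and alignment measures.

test_that("degenerate mOU settings give stationary tracks", {
  en <- simulate_mou(motility_params(tau = 10, D = 0, bias = 0),
                     n_tracks = 5, seed = 1, v0 = c(0, 0))
  for (tr in en$tracks) {
    expect_true(all(tr$x == 0))
    expect_true(all(tr$y == 0))
  }
})

test_that("stationary velocity variance matches the OU closed form", {
  p <- motility_params(tau = 11.105, D = 0.425, dt = 1, duration = 200)
  en <- simulate_mou(p, n_tracks = 500, seed = 2)
  v <- do.call(rbind, lapply(en$tracks, ghostnav:::track_velocities,
                             dt = 1))
  # central-difference velocities smooth the process slightly; compare
  # against the matching discrete expectation rather than raw D/tau
  expect_close(var(v[, 1]), p$D / p$tau, 0.12)
  expect_close(var(v[, 2]), p$D / p$tau, 0.12)
})

test_that("bias produces drift along the bias axis only", {
  p <- motility_params(tau = 20, D = 1, bias = 0.5,
                       bias_direction = c(1, 0), duration = 200)
  en <- simulate_mou(p, n_tracks = 200, seed = 3)
  ends <- t(vapply(en$tracks, function(tr)
    c(tr$x[nrow(tr)], tr$y[nrow(tr)]), numeric(2)))
  expect_gt(mean(ends[, 1]), 20)
  expect_lt(abs(mean(ends[, 2])), 0.15 * mean(ends[, 1]))
  # displacement grows linearly: midpoint displacement about half the final
  mid <- mean(vapply(en$tracks, function(tr) tr$x[nrow(tr) %/% 2],
                     numeric(1)))
  expect_close(mid, mean(ends[, 1]) / 2, 0.2)
})

test_that("MSD follows exact and asymptotic laws", {
  # straight-line motion: MSD = s^2 t^2 exactly
  s <- 0.7
  tr <- data.frame(t = seq(0, 100, 2), x = s * seq(0, 100, 2), y = 0)
  en <- track_ensemble(list(tr, tr), 2)
  m <- msd(en)
  expect_equal(m$msd, s^2 * m$lag^2, tolerance = 1e-12)
  # diffusive regime: slope 4D within Monte-Carlo error
  p <- motility_params(tau = 5, D = 1, dt = 1, duration = 300)
  en2 <- simulate_mou(p, n_tracks = 500, seed = 4)
  m2 <- msd(en2)
  sel <- m2$lag >= 50 & m2$lag <= 150
  slope <- coef(lm(msd ~ lag, data = m2[sel, ]))[["lag"]]
  expect_close(slope, 4 * p$D, 0.10)
  # ballistic regime: log-log slope 2
  p3 <- motility_params(tau = 50, D = 1, dt = 0.5, duration = 100)
  en3 <- simulate_mou(p3, n_tracks = 300, seed = 5)
  m3 <- msd(en3)
  sel3 <- m3$lag > 0 & m3$lag <= 5   # lags well below tau
  ll <- coef(lm(log(msd) ~ log(lag), data = m3[sel3, ]))[["log(lag)"]]
  expect_lt(abs(ll - 2), 0.2)
})

test_that("VACF reflects persistence and differencing artifacts", {
  # constant-velocity tracks: VACF constant at |v|^2
  tr <- data.frame(t = seq(0, 50, 2), x = 0.3 * seq(0, 50, 2),
                   y = 0.4 * seq(0, 50, 2))
  en <- track_ensemble(list(tr, tr), 2)
  v <- vacf(en)
  expect_equal(v$vacf, rep(0.25, nrow(v)), tolerance = 1e-12)
  # mOU decay rate recovers 1/tau
  p <- motility_params(tau = 20, D = 1, dt = 1, duration = 300)
  en2 <- simulate_mou(p, n_tracks = 500, seed = 6)
  v2 <- vacf(en2)
  head_ok <- which(v2$vacf < 0.2 * v2$vacf[1])[1]   # clean decay head only
  sel <- v2$lag >= 2 & seq_len(nrow(v2)) < head_ok
  slope <- coef(lm(log(vacf) ~ lag, data = v2[sel, ]))[["lag"]]
  expect_close(-1 / slope, p$tau, 0.10)
  # white-noise positions: differencing induces anti-correlation
  set.seed(7)
  trs <- lapply(1:200, function(i)
    data.frame(t = 0:40, x = rnorm(41), y = rnorm(41)))
  en3 <- track_ensemble(trs, 1)
  v3 <- vacf(en3)
  expect_lt(v3$vacf[v3$lag == 2], 0)
})

test_that("simulate-then-fit recovers the printed parameter sets", {
  for (set in list(c(tau = 38.143, D = 2.207),
                   c(tau = 11.105, D = 0.425))) {
    p <- motility_params(tau = set[["tau"]], D = set[["D"]])
    en <- simulate_mou(p, n_tracks = 1000, seed = 8)
    ft <- fit_motility(en)
    expect_close(ft$D, set[["D"]], 0.10)
    expect_close(ft$tau, set[["tau"]], 0.15)
    expect_gt(ft$r_squared_msd, 0.99)
  }
})

test_that("straight-line ensembles are flagged as poor linear-MSD fits", {
  trs <- lapply(1:25, function(i)
    data.frame(t = seq(0, 300, 2), x = 0.5 * seq(0, 300, 2), y = 0))
  en <- track_ensemble(trs, 2)
  ft <- suppressWarnings(fit_motility(en))
  expect_true(ft$poor_fit || ft$r_squared_msd < 0.999)
  expect_false(is.na(ft$r_squared_msd))
})

test_that("directionality matches hand-computed path ratios", {
  straight <- data.frame(t = 0:10, x = 0:10, y = 0)
  expect_equal(directionality(straight), 1)
  loop <- data.frame(t = 0:4, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(directionality(loop), 0)
  elbow <- data.frame(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(directionality(elbow), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("cos(theta) series measures source alignment", {
  toward <- data.frame(t = 0:10, x = 0:10, y = 0)
  expect_true(all(cos_theta_series(toward, c(1, 0))$cos_theta == 1))
  ortho <- data.frame(t = 0:10, x = 0, y = 0:10)
  expect_true(all(abs(cos_theta_series(ortho, c(1, 0))$cos_theta) < 1e-12))
  # isotropic random walk: ensemble mean near zero
  en <- simulate_mou(motility_params(tau = 5, D = 1, duration = 200),
                     n_tracks = 200, seed = 9)
  cts <- unlist(lapply(en$tracks, function(tr)
    cos_theta_series(tr, c(1, 0))$cos_theta))
  expect_lt(abs(mean(cts, na.rm = TRUE)), 0.05)
})

test_that("bias and persistence order the directionality distributions", {
  mk <- function(tau, D, b) simulate_mou(
    motility_params(tau = tau, D = D, bias = b, duration = 300),
    n_tracks = 60, seed = 10)
  rw <- mk(1, 1, 0); prw <- mk(38.143, 1, 0); pbrw <- mk(38.143, 1, 0.134)
  d_of <- function(en) vapply(en$tracks, directionality, numeric(1))
  d_rw <- d_of(rw); d_prw <- d_of(prw); d_pbrw <- d_of(pbrw)
  expect_lt(wilcox.test(d_pbrw, d_prw, alternative = "greater")$p.value,
            0.01)
  expect_lt(wilcox.test(d_prw, d_rw, alternative = "greater")$p.value,
            0.01)
})
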