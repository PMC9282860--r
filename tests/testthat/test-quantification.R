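# Single-cell quantification: ratiometric kymographs, time courses,
# activation classes, memory estimators, sigmoid fits, delay embedding,
# gradient alignment.

test_that("ratiometric kymograph is flat for proportional channels", {
  nt <- 50; nb <- 20
  egfr <- matrix(runif(nb * nt, 50, 150), nb, nt)
  rec <- cell_fluorescence_record(PTB_PM = 0.3 * egfr, EGFR_PM = egfr,
                                  PTB_T = rep(1000, nt),
                                  EGFR_T = rep(2000, nt),
                                  PTB_endo = rep(100, nt),
                                  times = seq(0, nt - 1))
  k <- egfrp_kymograph(rec)
  expect_lt(max(abs(k$mat), na.rm = TRUE), 1e-9)
})

test_that("kymograph localises the polarization angle and is scale free", {
  pk <- make_parametric_kymograph(theta0 = pi / 2)
  fr <- make_fluorescence_record(pk, noise_level = 0.05, seed = 3)
  k <- egfrp_kymograph(fr$record)
  stim <- k$times >= 5 & k$times <= 65
  prof <- rowMeans(k$mat[, stim])
  ang <- k$angles[which.max(prof)]
  dtheta <- abs((ang - pi / 2 + pi) %% (2 * pi) - pi)
  expect_lte(dtheta, 2 * pi / 20 + 1e-9)     # within one bin
  # joint rescaling of all channels leaves the kymograph unchanged
  r2 <- fr$record
  r2$PTB_PM <- r2$PTB_PM * 2; r2$EGFR_PM <- r2$EGFR_PM * 2
  r2$PTB_T <- r2$PTB_T * 2; r2$EGFR_T <- r2$EGFR_T * 2
  r2$PTB_endo <- r2$PTB_endo * 2
  expect_equal(egfrp_kymograph(r2)$mat, k$mat, tolerance = 1e-12)
})

test_that("membrane time course normalises to [0, 1] and tracks the source", {
  pk <- make_parametric_kymograph()
  fr <- make_fluorescence_record(pk, noise_level = 0)
  tc <- egfrp_timecourse(fr$record)
  expect_equal(max(tc$egfrp), 1)
  expect_lt(abs(mean(tc$egfrp[tc$t <= 5])), 1e-9)
  # constant record gives an identically zero normalised profile
  nt <- 30
  rec <- cell_fluorescence_record(matrix(10, 20, nt), matrix(50, 20, nt),
                                  rep(1000, nt), rep(2000, nt),
                                  rep(100, nt), times = seq(0, nt - 1))
  expect_true(all(egfrp_timecourse(rec)$egfrp == 0))
  # round trip against the generating signaling simulation
  run <- cached_rd_run()
  fr2 <- make_fluorescence_record(run$sim$Ep, noise_level = 0.02, seed = 5)
  tc2 <- egfrp_timecourse(fr2$record)
  expect_gt(cor(tc2$egfrp_raw, colMeans(run$sim$Ep$mat)), 0.95)
})

test_that("activation classes separate constructed populations", {
  set.seed(11)
  mk_rec <- function(level, polarized) {
    pk <- make_parametric_kymograph(baseline = level,
                                    amplitude = if (polarized) 0.8 else 0,
                                    times = seq(0, 100))
    make_fluorescence_record(pk, noise_level = 0.05,
                             seed = sample.int(1e6, 1))$record
  }
  recs <- c(lapply(1:6, function(i) mk_rec(0.03, FALSE)),   # non-activated
            lapply(1:6, function(i) mk_rec(0.03, TRUE)),    # activated
            lapply(1:6, function(i) mk_rec(0.9, FALSE)))    # pre-activated
  truth <- rep(c("non-activated", "activated", "pre-activated"), each = 6)
  cl <- classify_activation(recs)
  expect_gte(mean(cl$label == truth), 0.95)
  # identical cells: degenerate mixture is flagged, no crash
  same <- lapply(1:4, function(i) mk_rec(0.03, FALSE))
  same <- lapply(same, function(r) { r$PTB_PM[] <- 10; r })
  cl2 <- classify_activation(same)
  expect_true(all(cl2$degenerate) || length(unique(cl2$label)) == 1)
})

test_that("pre-activation threshold is a strict 30 percent rule", {
  # synthetic records engineered so a known fraction of pre-stimulus bin
  # values sits above an obvious mixture threshold
  nt <- 20; nb <- 20
  set.seed(12)
  mk <- function(frac_hot) {
    base <- matrix(rnorm(nb * nt, 0.1, 0.02), nb, nt)
    hot <- matrix(FALSE, nb, nt)
    hot[sample(nb * nt, round(frac_hot * nb * nt))] <- TRUE  # exact count
    vals <- ifelse(hot, matrix(rnorm(nb * nt, 1, 0.05), nb, nt), base)
    egfr <- matrix(100, nb, nt)
    cell_fluorescence_record(
      PTB_PM = vals * 100 * 900 / 2000, EGFR_PM = egfr,
      PTB_T = rep(1000, nt), EGFR_T = rep(2000, nt),
      PTB_endo = rep(100, nt), times = seq(0, nt - 1) / 4)
  }
  recs <- c(lapply(c(0.31, 0.29), mk),
            lapply(1:10, function(i) mk(0.05)))
  cl <- classify_activation(recs, baseline_window = c(0, 5),
                            response_window = c(0, 5))
  expect_equal(cl$label[1], "pre-activated")
  expect_false(cl$label[2] == "pre-activated")
})

test_that("signaling memory duration is recovered from the FPA rule", {
  pk <- make_parametric_kymograph(memory_min = 40)
  fr <- make_fluorescence_record(pk, noise_level = 0.05, seed = 1)
  est <- polarization_memory(egfrp_kymograph(fr$record), t_stim_end = 65)
  dt <- diff(pk$kymo$times[1:2])
  expect_lte(abs(est$duration - 40), 2 * dt)
  # unpolarized kymograph: no memory
  flat <- kymograph(matrix(0.1, 20, 100), seq(0, 99),
                    2 * pi * (1:20 - 0.5) / 20)
  est2 <- polarization_memory(flat, t_stim_end = 65)
  expect_true(est2$duration == 0 || is.na(est2$duration))
  # permanently polarized: sentinel ">= window"
  pk3 <- make_parametric_kymograph(memory_min = 1e5,
                                   times = seq(0, 245))
  fr3 <- make_fluorescence_record(pk3, noise_level = 0.05, seed = 2)
  est3 <- polarization_memory(egfrp_kymograph(fr3$record), t_stim_end = 65)
  expect_true(is.infinite(est3$duration))
})

test_that("solidity matches geometric oracles", {
  cc <- make_shape_series("circle", times = seq(0, 4, 2))
  sm <- shape_metrics(cc$masks, cc$t)
  expect_true(all(abs(sm$solidity - 1) < 0.011))
  # plus-shaped cross of 5 unit squares: hull is the area-7 octagon
  h <- 0.02; ax <- seq(-1.5 + h / 2, 1.5 - h / 2, by = h)
  px <- outer(ax, rep(1, length(ax))); py <- outer(rep(1, length(ax)), ax)
  plus <- (abs(px) <= 0.5 & abs(py) <= 1.5) |
    (abs(px) <= 1.5 & abs(py) <= 0.5)
  attr(plus, "x") <- ax; attr(plus, "y") <- ax
  expect_close(ghostnav:::mask_solidity(plus), 5 / 7, 0.03)
})

test_that("directed protrusion area is positive for source-ward motion", {
  h <- 0.1; ax <- seq(-4, 4, by = h)
  mk_disc <- function(cx) {
    m <- sqrt(outer((ax - cx)^2, ax^2, "+")) <= 2
    attr(m, "x") <- ax; attr(m, "y") <- ax
    m
  }
  masks <- lapply(seq(0, 1, by = 0.1), mk_disc)   # rigid translation +x
  sm <- shape_metrics(masks, seq_along(masks) - 1,
                      gradient_direction = c(1, 0))
  expect_true(all(sm$protrusion[-1] > 0))
})

test_that("morphology memory follows the solidity threshold rule", {
  # constant solidity: nothing ever crosses, no memory detected
  est <- morphology_memory(rep(0.95, 100), seq(0, 99), t_stim_end = 65)
  expect_true(is.na(est$duration))
  # 40-min synthetic plateau
  sh <- make_shape_series("polarized_blob", memory_min = 40,
                          times = seq(0, 180, 2), noise_amp = 0.03)
  sm <- shape_metrics(sh$masks, sh$t, gradient_direction = c(1, 0))
  est2 <- morphology_memory(sm$solidity, sm$t, t_stim_end = 65)
  expect_lte(abs(est2$duration - 40), 6)
  # instant recovery at washout
  sh3 <- make_shape_series("polarized_blob", memory_min = 0,
                           times = seq(0, 180, 2), recover_tau = 0.5)
  sm3 <- shape_metrics(sh3$masks, sh3$t, gradient_direction = c(1, 0))
  est3 <- morphology_memory(sm3$solidity, sm3$t, t_stim_end = 65)
  expect_lte(est3$duration, 4)
})

test_that("inverse sigmoid fits recover generating parameters", {
  tt <- seq(0, 180, 1)
  y <- 1000 / (10^2.88 + tt^2.88)
  ft <- fit_inverse_sigmoid(tt, y)
  expect_close(ft$a0, 1000, 1e-6)
  expect_close(ft$a, 10, 1e-6)
  expect_close(ft$n, 2.88, 1e-6)
  # half-life identity: time to half the initial value equals a
  expect_equal(ft$half_life, ft$a, tolerance = 1e-6)
  # noisy ensemble with the scale fixed: Hill coefficient within 0.15
  set.seed(13)
  t2 <- seq(0, 120, 1)
  ns <- vapply(1:50, function(i) {
    f <- 19 / (10^1.28 + t2^1.28)
    fit_inverse_sigmoid(t2, f + rnorm(length(t2), 0, 0.05 * f[1]),
                        fix_a = 10)$n
  }, numeric(1))
  expect_lte(abs(median(ns) - 1.28), 0.15)
})

test_that("delay embedding chooses sensible delay and dimension", {
  T_per <- 100
  x <- sin(2 * pi * (1:600) / T_per)
  emb <- takens_embedding(x, smooth = NULL)
  expect_gte(emb$d, T_per / 8)
  expect_lte(emb$d, T_per / 3)
  expect_equal(emb$m, 2)
  # m = 2 embedding of a sine closes into a loop: no large gaps relative
  # to the attractor diameter
  pts <- emb$embedded
  diam <- max(dist(pts[seq(1, nrow(pts), by = 5), ]))
  nn_gap <- max(apply(as.matrix(dist(pts[1:200, ])) +
                        diag(Inf, 200), 1, min))
  expect_lt(nn_gap / diam, 0.05)
  # white noise: false neighbours stay high, dimension capped and flagged
  set.seed(14)
  embn <- takens_embedding(rnorm(400), smooth = NULL)
  expect_true(embn$capped)
  # exemplar settings accepted by override
  emb3 <- takens_embedding(x, d = 26, m = 3, smooth = NULL)
  expect_equal(emb3$d, 26)
  expect_equal(emb3$m, 3)
  expect_equal(nrow(emb3$embedded), 600 - 2 * 26)
})

test_that("ensemble migration memory detects the bias extension", {
  # fast-decorrelating walker so the bias switch-off is sharp
  mp_b <- motility_params(tau = 2, D = 1, bias = 2, dt = 2)
  mp_n <- motility_params(tau = 2, D = 1, bias = 0, dt = 2)
  tk <- make_tracks(list(list(duration = 100, params = mp_b),
                         list(duration = 50, params = mp_b),
                         list(duration = 250, params = mp_n)),
                    n = 40, seed = 15, t_stim_end = 100)
  ref <- simulate_mou(mp_n, n_tracks = 40, seed = 16)
  est <- migration_memory(tk$ensemble, ref, t_stim_end = 100)
  expect_lte(abs(est$duration - 50), 10)   # within one 5-point window
  # unbiased throughout: essentially immediate acceptance
  tk0 <- make_tracks(list(list(duration = 400, params = mp_n)),
                     n = 40, seed = 17, t_stim_end = 100)
  est0 <- migration_memory(tk0$ensemble, ref, t_stim_end = 100)
  expect_lte(est0$duration, 10)
  # permanently biased: sentinel
  tkP <- make_tracks(list(list(duration = 400, params = mp_b)),
                     n = 40, seed = 18, t_stim_end = 100)
  estP <- migration_memory(tkP$ensemble, ref, t_stim_end = 100)
  expect_true(is.infinite(estP$duration))
})

test_that("per-cell cos(theta) memory matches its construction", {
  # straight to the source forever: sentinel
  tr <- data.frame(t = seq(0, 200, 2), x = seq(0, 200, 2), y = 0)
  est <- single_cell_cos_memory(tr, c(1, 0), t_stim_end = 100)
  expect_true(is.infinite(est$duration))
  # orthogonal turn exactly at washout: memory within 3 samples
  turn <- data.frame(t = seq(0, 200, 2),
                     x = pmin(seq(0, 200, 2), 100),
                     y = pmax(seq(0, 200, 2) - 100, 0))
  est2 <- single_cell_cos_memory(turn, c(1, 0), t_stim_end = 100)
  expect_lte(est2$duration, 5 * 2)   # Kalman smoothing spreads the turn
  # strongly biased walkers with a 25-min (12.5-sample) bias extension;
  # the 3-consecutive rule itself waits a couple of samples once the
  # alignment is gone, so the tolerance is counted in samples
  mp_b <- motility_params(tau = 2, D = 0.5, bias = 2, dt = 2)
  mp_n <- motility_params(tau = 2, D = 0.5, bias = 0, dt = 2)
  tk <- make_tracks(list(list(duration = 50, params = mp_b),
                         list(duration = 25, params = mp_b),
                         list(duration = 100, params = mp_n)),
                    n = 50, seed = 19, dt = 2, t_stim_end = 50)
  # noise-free synthetic positions: light measurement covariance
  durs <- vapply(tk$ensemble$tracks, function(tr)
    single_cell_cos_memory(tr, c(1, 0), t_stim_end = 50,
                           process_sd = 0.5,
                           measurement_sd = 0.1)$duration,
    numeric(1))
  expect_lte(abs(median(durs[is.finite(durs)]) - 25), 3 * 2)
})

test_that("gradient alignment measures the angular offset of maxima", {
  th0 <- 2 * pi * (10 - 0.5) / 20      # a bin centre (ties break cleanly)
  pk <- make_parametric_kymograph(theta0 = th0)
  fr <- make_fluorescence_record(pk, noise_level = 0.02, seed = 20,
                                 with_egf = TRUE)
  k <- egfrp_kymograph(fr$record)
  al <- gradient_alignment(fr$record, k, average_window = c(5, 65))
  expect_equal(al$angle, 0)
  # shifting the phosphorylation maximum 5 bins gives pi/2
  k5 <- k
  k5$mat <- k$mat[((seq_len(20) - 1 + 5) %% 20) + 1, ]
  al5 <- gradient_alignment(fr$record, k5, average_window = c(5, 65))
  expect_equal(al5$angle, pi / 2)
  # flat EGF profile: undefined alignment
  r0 <- fr$record; r0$EGF_PM[] <- 1
  expect_true(is.na(gradient_alignment(r0, k)$angle))
  # jittered ensemble stays tightly aligned
  angs <- vapply(1:20, function(s) {
    fr_i <- make_fluorescence_record(make_parametric_kymograph(theta0 = pi),
                                     noise_level = 0.05, seed = s,
                                     with_egf = TRUE, egf_jitter_bins = 1)
    gradient_alignment(fr_i$record,
                       egfrp_kymograph(fr_i$record))$angle
  }, numeric(1))
  expect_lte(median(angs), pi / 10)
})

test_that("estimators are invariant to global intensity rescaling", {
  pk <- make_parametric_kymograph(memory_min = 40)
  fr <- make_fluorescence_record(pk, noise_level = 0.05, seed = 21)
  scale_rec <- function(r, f) {
    r$PTB_PM <- r$PTB_PM * f; r$EGFR_PM <- r$EGFR_PM * f
    r$PTB_T <- r$PTB_T * f; r$EGFR_T <- r$EGFR_T * f
    r$PTB_endo <- r$PTB_endo * f
    r
  }
  a <- polarization_memory(egfrp_kymograph(fr$record), 65)$duration
  b <- polarization_memory(egfrp_kymograph(scale_rec(fr$record, 37.5)),
                           65)$duration
  expect_identical(a, b)
  ta <- egfrp_timecourse(fr$record)$egfrp
  tb <- egfrp_timecourse(scale_rec(fr$record, 37.5))$egfrp
  expect_equal(ta, tb, tolerance = 1e-12)
})
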