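# Reaction-diffusion signaling model: reaction terms, steady states,
# stochastic simulation invariants and polarization metrics.

test_that("reaction terms match hand-computed values and sign structure", {
  p <- signaling_params(Et = 1.26)
  # fully dephosphorylated receptor pool: only the autonomous term remains
  f <- reaction_terms(0, 0, 0.3, 0.5, p, EGFt = 0)
  expect_equal(f$f_Ep, 0.001 * 1.26^2, tolerance = 1e-12)
  # no ligand, no bound receptor: the liganded pool cannot grow
  expect_equal(reaction_terms(0.4, 0, 0.3, 0.5, p, EGFt = 0)$f_EEp, 0)
  # fully active PTPRG with phosphorylated receptor present must decay
  f3 <- reaction_terms(0.4, 0.1, p$RGt, 0.5, p, EGFt = 0.2)$f_RGa
  expect_lt(f3, 0)
  # vectorised over bins
  fv <- reaction_terms(c(0, 0.1), c(0, 0), c(0.3, 0.3), c(0.5, 0.5), p, 0)
  expect_length(fv$f_Ep, 2)
  expect_error(reaction_terms(-0.1, 0, 0.3, 0.5, p, 0), "negative")
})

test_that("PTPN2 quasi-steady state follows its closed form", {
  p <- signaling_params()
  expect_equal(n2a_qss(0, 0, p), 0.5)              # k1/(k1+k2) * N2t
  expect_equal(n2a_qss(1, 0, p), 1.6 / 2.1, tolerance = 1e-12)
  # approaches N2t monotonically from below
  s <- n2a_qss(c(0.5, 1, 5, 50, 500), 0, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s < p$N2t))
  # splitting the load between pools is equivalent
  expect_equal(n2a_qss(0.4, 0.6, p), n2a_qss(1, 0, p))
})

test_that("homogeneous steady state solves the uniform fixed point", {
  for (Et in c(1.1, 1.26, 1.85)) {
    h <- homogeneous_steady_state(signaling_params(Et = Et))
    expect_equal(h$EEp, 0)          # no ligand, no liganded receptor
    expect_lt(h$residual, 1e-10)
  }
  # high branch differs from low branch in the coexistence window
  p <- signaling_params(Et = 1.26)
  expect_gt(homogeneous_steady_state(p, branch = "high")$Ep,
            10 * homogeneous_steady_state(p, branch = "low")$Ep)
})

test_that("the uniform steady state is stationary under zero-noise simulation", {
  p <- signaling_params(Et = 1.26)
  prot <- stimulus_protocol(list(list(t_start = 0, t_end = 100,
                                      kind = "none")))
  sim <- simulate_rd(p, membrane_grid(), prot, t_end = 100, dt = 0.01,
                     noise_on = FALSE, save_every = 1000)
  h <- homogeneous_steady_state(p)
  expect_lt(max(abs(sim$Ep$mat - h$Ep)), 1e-8)
  expect_lt(max(abs(sim$RGa$mat - h$RGa)), 1e-8)
  # homogeneous dynamics stay homogeneous to high precision
  expect_lt(max(apply(sim$Ep$mat, 2, function(col) diff(range(col)))),
            1e-9)
})

test_that("stochastic simulation respects conservation bounds and seeding", {
  p <- signaling_params(Et = 1.26)
  prot <- default_gradient_protocol()
  s1 <- simulate_rd(p, membrane_grid(), prot, t_end = 20, seed = 4,
                    save_every = 200)
  s2 <- simulate_rd(p, membrane_grid(), prot, t_end = 20, seed = 4,
                    save_every = 200)
  expect_identical(s1$Ep$mat, s2$Ep$mat)    # reproducible given seed
  expect_true(all(s1$Ep$mat >= 0))
  expect_true(all(s1$Ep$mat + s1$EEp$mat <= p$Et + 1e-12))
  expect_true(all(s1$RGa$mat >= 0 & s1$RGa$mat <= p$RGt))
  expect_true(all(s1$N2a$mat >= 0 & s1$N2a$mat <= p$N2t))
})

test_that("time step must respect the diffusive CFL bound", {
  p <- signaling_params(D_Ep = 25)   # exaggerated diffusion
  prot <- stimulus_protocol(list(list(t_start = 0, t_end = 1,
                                      kind = "none")))
  expect_error(simulate_rd(p, membrane_grid(), prot, t_end = 1, dt = 0.01),
               "CFL")
})

test_that("PTPN2 QSS and full-epsilon simulations agree", {
  p <- signaling_params(Et = 1.26)
  # steady (unstimulated) conditions: the slow feedback sits exactly on
  # its quasi-steady manifold
  none <- stimulus_protocol(list(list(t_start = 0, t_end = 30,
                                      kind = "none")))
  a0 <- simulate_rd(p, membrane_grid(), none, t_end = 30, noise_on = FALSE,
                    n2a_mode = "qss", save_every = 500)
  b0 <- simulate_rd(p, membrane_grid(), none, t_end = 30, noise_on = FALSE,
                    n2a_mode = "ode", save_every = 500)
  expect_lt(max(abs(a0$Ep$mat - b0$Ep$mat)), 1e-8)
  # under a transient gradient the slow variable lags its quasi-steady
  # value; the Ep fields still agree to within ~10% RMS
  prot <- default_gradient_protocol()
  a <- simulate_rd(p, membrane_grid(), prot, t_end = 40, noise_on = FALSE,
                   n2a_mode = "qss", save_every = 200)
  b <- simulate_rd(p, membrane_grid(), prot, t_end = 40, noise_on = FALSE,
                   n2a_mode = "ode", save_every = 200)
  rms <- sqrt(mean((a$Ep$mat - b$Ep$mat)^2))
  scale <- sqrt(mean(a$Ep$mat^2))
  expect_lt(rms / scale, 0.12)
})

test_that("polarization metrics report index and memory durations", {
  prot <- default_gradient_protocol()
  # spatially uniform kymograph: no polarization, zero memory
  flat <- kymograph(matrix(0.4, 20, 101), seq(0, 100),
                    2 * pi * (1:20 - 0.5) / 20)
  pm <- polarization_metrics(flat, prot)
  expect_true(all(pm$p == 0))
  expect_equal(pm$memory, 0)
  # built-in 40-min plateau is recovered to one sample interval
  pk <- make_parametric_kymograph(memory_min = 40, fall_tau = 0.25)
  pm2 <- polarization_metrics(pk$kymo, prot, threshold = 0.2)
  expect_lt(abs(pm2$memory - 40), 2 * diff(pk$kymo$times[1:2]) + 1e-9)
  # protocol without washout: memory undefined
  always <- stimulus_protocol(list(list(t_start = 0, t_end = 100,
                                        kind = "uniform", A = 0.1)))
  expect_true(is.na(polarization_metrics(flat, always)$memory))
})

test_that("in-silico receptor-kinase inhibition abolishes the memory phase", {
  # with the autocatalytic rate suppressed from washout onward, the
  # front/back asymmetry collapses promptly instead of lingering
  p <- signaling_params(Et = 1.26)
  prot <- default_gradient_protocol()
  k_ctrl <- simulate_compartments(p, prot, t_end = 245, noise_on = FALSE)
  p_lap <- p
  k_lap <- simulate_rd(p_lap, membrane_grid(), prot, t_end = 100,
                       noise_on = FALSE, alpha2_factor = 0.05,
                       save_every = 200)
  pm_ctrl <- polarization_metrics(k_ctrl, prot, threshold = 0.2,
                                  floor = 0.1)
  asym_lap <- apply(k_lap$Ep$mat, 2, function(col) diff(range(col)))
  t_lap <- k_lap$Ep$times
  # 10 min after washout the inhibited run has essentially no asymmetry
  expect_lt(max(asym_lap[t_lap >= 75]), 0.02)
  expect_gt(pm_ctrl$memory, 20)
})
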