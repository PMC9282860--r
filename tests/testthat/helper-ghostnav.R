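# shared fixtures: cheap default objects used across test files

default_gradient_protocol <- function(theta0 = pi, A = 0.1, width = 1.0,
                                      t_total = 245) {
  make_stimulus_protocol("single_gradient_1h", theta0 = theta0, A = A,
                         width = width, t_total = t_total)
}

# short criticality RD run (cached per session: the suite reuses it)
cached_rd_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- default_gradient_protocol()
      cache <<- list(
        sim = simulate_rd(signaling_params(Et = 1.26), membrane_grid(),
                          prot, t_end = 65, dt = 0.01, seed = 11,
                          save_every = 100),
        protocol = prot)
    }
    cache
  }
})

expect_close <- function(actual, expected, rel_tol) {
  expect_true(abs(actual - expected) <= rel_tol * abs(expected),
              label = sprintf("%.6g vs expected %.6g (rel tol %g)",
                              actual, expected, rel_tol))
}
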