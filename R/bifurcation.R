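# Two-compartment (front/back) projection of the membrane network, its
# bifurcation structure in the receptor total Et, and the weakly nonlinear
# (Stuart-Landau) amplitude expansion that classifies the pitchfork.

# reaction terms of the reduced 2-variable system (EEp = 0, PTPN2 at QSS)
# u1 = Ep, u2 = RGa, plus their analytic partial derivatives
reduced_F <- function(u1, u2, params, EGFt = 0, EEp = 0) {
  n2 <- n2a_qss(u1, EEp, params)
  f <- reaction_terms(u1, EEp, u2, n2, params, EGFt)
  c(f$f_Ep, f$f_RGa)
}

reduced_jacobian <- function(u1, u2, params, EGFt = 0) {
  p <- params
  E0 <- p$Et - u1
  s <- u1
  den <- p$k1 + p$k2 + p$beta2 * s
  n2 <- p$N2t * (p$k1 + p$beta2 * s) / den
  dn2 <- p$N2t * p$beta2 * p$k2 / den^2
  dF1du1 <- -(p$alpha1 * E0 + p$alpha2 * u1) + E0 * (p$alpha2 - p$alpha1) -
    p$gamma1 * u2 - p$gamma2 * (n2 + u1 * dn2) -
    2 * p$kon * EGFt * u1
  dF1du2 <- -p$gamma1 * u1
  dF2du1 <- -p$beta1 * u2
  dF2du2 <- -(p$k1 + p$k2) - p$beta1 * u1
  matrix(c(dF1du1, dF1du2, dF2du1, dF2du2), 2, 2, byrow = TRUE)
}

reduced_dFdEt <- function(u1, u2, params) {
  E0 <- params$Et - u1
  c(2 * params$alpha1 * E0 + params$alpha2 * u1, 0)
}

#' Front/back compartment model right-hand side
#'
#' One-dimensional projection of the membrane network onto two exchanging
#' compartments (front f, back b). Each compartment carries the reduced
#' two-variable dynamics (\code{u1} = Ep-like, \code{u2} = RGa-like; PTPN2 at
#' quasi-steady state) and the compartments exchange linearly,
#' mimicking lateral diffusion. When ligand is present each compartment can
#' additionally carry a liganded-receptor pool (6-component state).
#'
#' @param state numeric vector \code{c(u1f, u2f, u1b, u2b)} or
#'   \code{c(u1f, u2f, u1b, u2b, EEpf, EEpb)}.
#' @param params a [signaling_params()].
#' @param exchange length-2 exchange coefficients \code{c(dEp, dRGa)}
#'   (1/min); default the dimensionless lateral-coupling value 0.02 for both.
#' @param EGFt_front,EGFt_back total EGF seen by each compartment.
#' @return derivative vector, same length and order as \code{state}.
#' @export
compartment_rhs <- function(state, params, exchange = c(0.02, 0.02),
                            EGFt_front = 0, EGFt_back = 0) {
  stopifnot(inherits(params, "signaling_params"),
            length(state) %in% c(4L, 6L))
  u1f <- state[1]; u2f <- state[2]; u1b <- state[3]; u2b <- state[4]
  has_lig <- length(state) == 6L
  EEpf <- if (has_lig) state[5] else 0
  EEpb <- if (has_lig) state[6] else 0
  n2f <- n2a_qss(u1f, EEpf, params)
  n2b <- n2a_qss(u1b, EEpb, params)
  ff <- reaction_terms(u1f, EEpf, u2f, n2f, params, EGFt_front)
  fb <- reaction_terms(u1b, EEpb, u2b, n2b, params, EGFt_back)
  d <- c(ff$f_Ep - exchange[1] * (u1f - u1b),
         ff$f_RGa - exchange[2] * (u2f - u2b),
         fb$f_Ep - exchange[1] * (u1b - u1f),
         fb$f_RGa - exchange[2] * (u2b - u2f))
  if (has_lig) d <- c(d, ff$f_EEp, fb$f_EEp)
  d
}

# analytic 4x4 Jacobian of the ligand-free compartment system
compartment_jacobian <- function(state, params, exchange = c(0.02, 0.02)) {
  Jf <- reduced_jacobian(state[1], state[2], params)
  Jb <- reduced_jacobian(state[3], state[4], params)
  dE <- exchange[1]; dR <- exchange[2]
  J <- matrix(0, 4, 4)
  J[1:2, 1:2] <- Jf - diag(c(dE, dR))
  J[3:4, 3:4] <- Jb - diag(c(dE, dR))
  J[1, 3] <- dE; J[2, 4] <- dR; J[3, 1] <- dE; J[4, 2] <- dR
  J
}

# The ligand-free homogeneous steady-state curve admits a closed-form
# parametrization: the Ep balance is quadratic in (Et - Ep), so for every
# uniform phosphorylation level Ep there is exactly one receptor total Et
# on the curve.
hss_Et_of_Ep <- function(Ep, params) {
  p <- params
  h <- p$gamma1 * rga_ss(Ep, p) * Ep + p$gamma2 * n2a_qss(Ep, 0, p) * Ep
  # alpha1 z^2 + alpha2 Ep z - h = 0, z = Et - Ep (positive root)
  z <- (-p$alpha2 * Ep + sqrt(p$alpha2^2 * Ep^2 + 4 * p$alpha1 * h)) /
    (2 * p$alpha1)
  Ep + z
}

# odd-mode determinant at a given uniform state (Ep level)
odd_det_at <- function(Ep, params, exchange) {
  A <- reduced_jacobian(Ep, rga_ss(Ep, params), params)
  det(A - 2 * diag(c(exchange[1], exchange[2])))
}

#' Odd-mode pitchfork criterion for the compartment model
#'
#' At a symmetric steady state the 4x4 Jacobian has block structure
#' \code{[[A, B], [B, A]]}; perturbations split into an even mode
#' (\code{A + B}) and an odd, symmetry-breaking mode (\code{A - B}).
#' A pitchfork of the symmetric state occurs where the odd-mode determinant
#' \code{det(A - B)} crosses zero along the homogeneous branch.
#'
#' @param params a [signaling_params()] (its \code{Et} is used).
#' @param Et optional receptor total overriding \code{params$Et}.
#' @param exchange exchange coefficients as in [compartment_rhs()].
#' @param branch homogeneous branch to evaluate on: \code{"low"},
#'   \code{"middle"} or \code{"high"} phosphorylation.
#' @return the odd-mode determinant (scalar); attribute \code{state} carries
#'   the steady state used.
#' @export
odd_mode_pb_test <- function(params, Et = NULL, exchange = c(0.02, 0.02),
                             branch = c("low", "middle", "high")) {
  branch <- match.arg(branch)
  if (!is.null(Et)) params$Et <- Et
  roots <- hss_all_roots(params)
  if (!length(roots)) stop("odd_mode_pb_test: no homogeneous steady state")
  Ep <- switch(branch,
               low = min(roots),
               high = max(roots),
               middle = if (length(roots) >= 3) sort(roots)[2] else
                 stop("odd_mode_pb_test: no middle branch at this Et"))
  d <- odd_det_at(Ep, params, exchange)
  attr(d, "state") <- c(u1 = Ep, u2 = rga_ss(Ep, params))
  d
}

# all uniform Ep roots at the params' Et (ligand-free)
hss_all_roots <- function(params) {
  resid <- function(Ep) hss_Et_of_Ep(Ep, params) - params$Et
  g <- seq(1e-8, params$Et, length.out = 800)
  r <- vapply(g, resid, numeric(1))
  idx <- which(sign(r)[-1] * sign(r)[-length(r)] < 0)
  vapply(idx, function(i)
    stats::uniroot(resid, c(g[i], g[i + 1]), tol = 1e-14)$root, numeric(1))
}

# Newton solve of the 4-ODE fixed point from a starting guess
newton_fp <- function(x0, params, exchange, tol = 1e-12, maxit = 60) {
  x <- x0
  for (i in seq_len(maxit)) {
    F <- compartment_rhs(pmax(x, 0), params, exchange)
    J <- compartment_jacobian(pmax(x, 0), params, exchange)
    step <- tryCatch(solve(J, F), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    x <- x - step
    if (max(abs(F)) < tol) break
  }
  if (max(abs(compartment_rhs(pmax(x, 0), params, exchange))) > 1e-8)
    return(NULL)
  pmax(x, 0)
}

#' Bifurcation diagram of the compartment model in the receptor total
#'
#' Scans the homogeneous (symmetric) branch with linear stability and the
#' inhomogeneous (polarized, front/back-asymmetric) branch by
#' pseudo-arclength continuation of fixed points of the four-variable
#' compartment system, with no ligand. The pitchfork \code{Et_PB} is located
#' from the zero crossing of the odd-mode determinant; the stabilising
#' saddle-node \code{Et_SN} from the fold (Et extremum) of the asymmetric
#' branch.
#'
#' @param params a [signaling_params()]; its \code{Et} is ignored.
#' @param Et_range length-2 range to scan.
#' @param Et_step scan step for the symmetric branch.
#' @param exchange exchange coefficients, see [compartment_rhs()].
#' @return object of class \code{bifurcation_diagram}: data frame
#'   \code{branches} (Et, branch, u1f, u1b, stable) plus \code{Et_PB},
#'   \code{Et_SN}.
#' @export
scan_bifurcation_diagram <- function(params, Et_range = c(1.0, 2.2),
                                     Et_step = 1e-3,
                                     exchange = c(0.02, 0.02)) {
  stopifnot(inherits(params, "signaling_params"))
  # --- symmetric curve, parametrized by the uniform Ep level: the Ep
  # balance is quadratic in (Et - Ep), so Et(Ep) is closed-form and the
  # whole S-shaped branch (low / middle / high) is swept in one pass.
  Ep_grid <- exp(seq(log(1e-4), log(3), length.out =
                       max(400L, ceiling(diff(Et_range) / Et_step))))
  Et_of <- vapply(Ep_grid, hss_Et_of_Ep, numeric(1), params = params)
  keep <- Et_of >= Et_range[1] & Et_of <= Et_range[2]
  Ep_grid <- Ep_grid[keep]; Et_of <- Et_of[keep]
  stab <- vapply(seq_along(Ep_grid), function(i) {
    p <- params; p$Et <- Et_of[i]
    st <- c(Ep_grid[i], rga_ss(Ep_grid[i], p), Ep_grid[i],
            rga_ss(Ep_grid[i], p))
    max(Re(eigen(compartment_jacobian(st, p, exchange),
                 only.values = TRUE)$values))
  }, numeric(1))
  odd <- vapply(seq_along(Ep_grid), function(i) {
    p <- params; p$Et <- Et_of[i]
    odd_det_at(Ep_grid[i], p, exchange)
  }, numeric(1))
  hss_df <- data.frame(Et = Et_of, branch = "HSS",
                       u1f = Ep_grid, u1b = Ep_grid, stable = stab < 0)
  # pitchfork: odd-mode determinant zero crossing along the curve
  Et_PB <- NA_real_; Ep_PB <- NA_real_
  cross <- which(odd[-1] * odd[-length(odd)] < 0)
  if (length(cross)) {
    i <- cross[1]
    f <- function(Ep) {
      p <- params; p$Et <- hss_Et_of_Ep(Ep, params)
      odd_det_at(Ep, p, exchange)
    }
    Ep_PB <- stats::uniroot(f, c(Ep_grid[i], Ep_grid[i + 1]),
                            tol = 1e-12)$root
    Et_PB <- hss_Et_of_Ep(Ep_PB, params)
  }
  # --- asymmetric (polarized) branch: locate a fixed point from structured
  # polarized guesses, then pseudo-arclength continuation both ways
  ihss_df <- NULL; Et_SN <- NA_real_
  start <- NULL; p_st <- params
  for (Et0 in c(1.32, 1.3, 1.35, 1.28, 1.4)) {
    if (Et0 < Et_range[1] || Et0 > Et_range[2]) next
    p_st$Et <- Et0
    for (g1 in c(0.5, 0.6, 0.4)) for (g2 in c(0.03, 0.08)) {
      fp <- newton_fp(c(g1, rga_ss(g1, p_st), g2, rga_ss(g2, p_st)),
                      p_st, exchange)
      if (!is.null(fp) && abs(fp[1] - fp[3]) > 1e-3) { start <- fp; break }
    }
    if (!is.null(start)) break
  }
  if (!is.null(start)) {
    trace_dir <- function(y0, tang0) {
      y <- y0; tang <- tang0; ds <- 2e-3
      pts <- list()
      for (it in 1:20000) {
        y_pred <- y + ds * tang
        yk <- y_pred; ok <- FALSE
        for (ni in 1:30) {
          p_k <- params; p_k$Et <- yk[5]
          Fk <- compartment_rhs(pmax(yk[1:4], 0), p_k, exchange)
          g <- sum(tang * (yk - y_pred))
          if (max(abs(Fk)) < 1e-11 && abs(g) < 1e-10) { ok <- TRUE; break }
          Jk <- compartment_jacobian(pmax(yk[1:4], 0), p_k, exchange)
          dEt <- c(reduced_dFdEt(yk[1], yk[2], p_k)[1], 0,
                   reduced_dFdEt(yk[3], yk[4], p_k)[1], 0)
          M <- rbind(cbind(Jk, dEt), tang)
          step <- tryCatch(solve(M, c(Fk, g)), error = function(e) NULL)
          if (is.null(step) || anyNA(step)) break
          yk <- yk - step
        }
        if (!ok) { ds <- ds / 2; if (ds < 1e-7) break else next }
        tang_new <- (yk - y) / max(sqrt(sum((yk - y)^2)), 1e-12)
        tang <- tang_new
        y <- yk
        p_k <- params; p_k$Et <- y[5]
        ev <- max(Re(eigen(compartment_jacobian(pmax(y[1:4], 0), p_k,
                                                exchange),
                           only.values = TRUE)$values))
        pts[[length(pts) + 1]] <- c(y, ev < 0)
        ds <- min(ds * 1.4, 3e-3)
        if (y[5] > Et_range[2] + Et_step || y[5] < Et_range[1] - Et_step ||
            abs(y[1] - y[3]) < 5e-5 || max(y[1:4]) > 5) break
      }
      pts
    }
    p1 <- trace_dir(c(start, p_st$Et), c(0, 0, 0, 0, -1))
    p2 <- trace_dir(c(start, p_st$Et), c(0, 0, 0, 0, 1))
    pts <- c(rev(p1), list(c(start, p_st$Et, NA)), p2)
    m <- do.call(rbind, pts)
    ihss_df <- data.frame(Et = m[, 5], branch = "IHSS",
                          u1f = pmax(m[, 1], m[, 3]),
                          u1b = pmin(m[, 1], m[, 3]),
                          stable = as.logical(m[, 6]))
    # saddle-node that stabilises the polarized states: onset of the stable
    # section of the asymmetric branch (lowest Et at which a stable
    # polarized fixed point exists)
    if (any(ihss_df$stable, na.rm = TRUE))
      Et_SN <- min(ihss_df$Et[which(ihss_df$stable)], na.rm = TRUE)
  }
  structure(list(branches = rbind(hss_df, ihss_df),
                 odd_det = data.frame(Et = Et_of, Ep = Ep_grid, det = odd),
                 Et_PB = Et_PB, Ep_PB = Ep_PB, Et_SN = Et_SN,
                 exchange = exchange, params = params),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("bifurcation diagram (front/back compartment model)\n")
  cat(sprintf("  Et range scanned: [%g, %g]\n",
              min(x$branches$Et), max(x$branches$Et)))
  cat(sprintf("  pitchfork Et_PB = %s\n", format(x$Et_PB)))
  cat(sprintf("  saddle-node Et_SN = %s%s\n", format(x$Et_SN),
              if (!is.na(x$Et_PB) && !is.na(x$Et_SN) && x$Et_SN < x$Et_PB)
                "  (subcritical: coexistence window below the PB)" else ""))
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  b <- x$branches
  graphics::plot(b$Et, b$u1f, type = "n", xlab = "Et",
                 ylab = "Ep (front/back)", ...)
  for (br in split(b, b$branch)) {
    graphics::points(br$Et, br$u1f, pch = 20, cex = 0.3,
                     col = ifelse(br$stable, "black", "grey60"))
    graphics::points(br$Et, br$u1b, pch = 20, cex = 0.3,
                     col = ifelse(br$stable, "magenta", "pink"))
  }
  if (!is.na(x$Et_SN)) graphics::abline(v = x$Et_SN, lty = 3)
  if (!is.na(x$Et_PB)) graphics::abline(v = x$Et_PB, lty = 2)
  invisible(x)
}

#' Stochastic realization of the compartment model
#'
#' Euler--Maruyama integration of the front/back projection with additive
#' noise on the two Ep-like variables and a stimulus protocol evaluated at
#' the front (\code{theta0}) and back (\code{theta0 + pi}) angles. Used for
#' regime phenotyping: the four dynamical regimes of the receptor total map
#' onto distinct post-washout behaviour of the front-back asymmetry.
#'
#' @param params a [signaling_params()].
#' @param protocol a [stimulus_protocol()].
#' @param t_end,dt integration window and step (min).
#' @param exchange exchange coefficients.
#' @param seed RNG seed.
#' @param noise_on add noise (amplitude \code{params$sigma_noise}).
#' @param save_every thinning factor for the stored trajectory.
#' @return a 2-bin Ep [kymograph()] (front = bin 1, back = bin 2), with the
#'   full trajectory in \code{meta$trajectory}.
#' @export
simulate_compartments <- function(params, protocol, t_end, dt = 0.01,
                                  exchange = c(0.02, 0.02), seed = 1L,
                                  noise_on = TRUE, save_every = 50L) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  h <- homogeneous_steady_state(params, EGFt = 0)
  x <- c(h$Ep, h$RGa, h$Ep, h$RGa, 0, 0)
  theta_f <- NULL
  for (s in protocol$segments)
    if (s$kind == "gaussian_gradient") { theta_f <- s$theta0; break }
  if (is.null(theta_f)) theta_f <- pi
  n_steps <- ceiling(t_end / dt)
  keep <- seq(0L, n_steps, by = save_every)
  out <- matrix(NA_real_, 6, length(keep))
  out[, 1] <- x
  if (noise_on) {
    oldseed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldseed))
      assign(".Random.seed", oldseed, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  sig <- if (noise_on) params$sigma_noise else 0
  sqdt <- sqrt(dt)
  k_idx <- 1L
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    egf <- egf_at(protocol, c(theta_f, theta_f + pi), t)
    d <- compartment_rhs(x, params, exchange, egf[1], egf[2])
    x <- x + dt * d
    if (sig > 0) x[c(1, 3)] <- x[c(1, 3)] + sig * sqdt * stats::rnorm(2)
    x[1:4] <- pmax(x[1:4], 0)
    x[c(1, 3)] <- pmin(x[c(1, 3)], params$Et)
    x[c(2, 4)] <- pmin(x[c(2, 4)], params$RGt)
    x[5:6] <- pmin(pmax(x[5:6], 0), params$Et)
    if (s %% save_every == 0L) {
      k_idx <- k_idx + 1L
      out[, k_idx] <- x
    }
  }
  kymograph(out[c(1, 3), , drop = FALSE], keep * dt, c(theta_f, theta_f + pi),
            species = "Ep",
            meta = list(params = params, exchange = exchange, seed = seed,
                        trajectory = out))
}

#' Dimensionless parameters of the reduced membrane network
#'
#' Rescales the two-variable reduced system (Ep-like, RGa-like; PTPN2 at
#' quasi-steady state, no ligand) with \code{t0 = 1/(k1+k2)},
#' \code{E0 = k1/beta2}, \code{RG0 = (k1+k2)/gamma1} and
#' \code{x0 = sqrt(D_Ep * t0)}, then quadratically expands the PTPN2
#' dephosphorylation term about the dimensionless steady state \code{Es} so
#' the Ep balance becomes polynomial:
#' \code{dEp/dtau = q9 + q10 Ep + q11 Ep^2 - RGa Ep + Laplacian}.
#'
#' @param params a [signaling_params()].
#' @param Es expansion point, the dimensionless Ep steady state; computed
#'   from the homogeneous steady state when omitted.
#' @return object of class \code{dimensionless_params} with the raw
#'   coefficients \code{q1..q4}, Taylor coefficients \code{q7, q8, q9_taylor},
#'   recombined \code{q9, q10, q11}, \code{r1, r2}, \code{k}, diffusion ratio
#'   \code{Dratio} and the scalings.
#' @export
nondimensionalize <- function(params, Es = NULL) {
  p <- params
  if (!(p$k1 + p$k2 > 0 && p$beta2 > 0 && p$gamma1 > 0 && p$D_Ep > 0))
    stop("nondimensionalize: need k1+k2, beta2, gamma1, D_Ep > 0")
  t0 <- 1 / (p$k1 + p$k2)
  E0 <- p$k1 / p$beta2
  RG0 <- (p$k1 + p$k2) / p$gamma1
  x0 <- sqrt(p$D_Ep * t0)
  if (is.null(Es)) {
    h <- homogeneous_steady_state(p, EGFt = 0)
    Es <- h$Ep / E0
  }
  k <- p$k2 / p$k1
  q1 <- p$alpha1 * p$Et^2 * t0 / E0
  q2 <- (p$alpha2 - 2 * p$alpha1) * p$Et * t0
  q3 <- (p$alpha1 - p$alpha2) * E0 * t0
  q4 <- p$gamma2 * p$N2t * t0
  r1 <- p$k1 * p$RGt * p$gamma1 / (p$k1 + p$k2)^2
  r2 <- p$beta1 * p$k1 / ((p$k1 + p$k2) * p$beta2)
  ck <- 1 + k
  den <- ck + Es
  q7 <- Es * q4 / den - Es * q4 * ck / den^2
  q8 <- Es * q4 / den + q4 * ck * (1 - Es) / den^2
  q9_taylor <- q4 * ck / den^2
  structure(list(q1 = q1, q2 = q2, q3 = q3, q4 = q4,
                 q7 = q7, q8 = q8, q9_taylor = q9_taylor,
                 q9 = q1 - q7, q10 = q2 - q8, q11 = q3 - q9_taylor,
                 r1 = r1, r2 = r2, k = k,
                 Dratio = p$D_RGa / p$D_Ep, Es = Es,
                 t0 = t0, E0 = E0, RG0 = RG0, x0 = x0),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("dimensionless reduced-network parameters\n")
  cat(sprintf("  q9 = %.4g, q10 = %.4g, q11 = %.4g\n", x$q9, x$q10, x$q11))
  cat(sprintf("  r1 = %.4g, r2 = %.4g, k = %.4g, Dratio = %.4g, Es = %.4g\n",
              x$r1, x$r2, x$k, x$Dratio, x$Es))
  invisible(x)
}

#' Stuart-Landau amplitude coefficients of the polarization mode
#'
#' Fifth-order amplitude equation \code{dphi/dt = c1 phi + c2 phi^3 -
#' c3 phi^5} for the leading spatial harmonic at wavenumber \code{km} of the
#' dimensionless reduced system. Positive \code{c2} and \code{c3} classify
#' the pitchfork as subcritical, i.e. stabilised through saddle-nodes.
#'
#' @param dp a [nondimensionalize()] result.
#' @param km wavenumber of the leading (mode-1) harmonic on the ring,
#'   default \code{1/R}.
#' @param R membrane radius used only for the default \code{km}.
#' @return object of class \code{amplitude_coeffs}: \code{c1, c2, c3},
#'   harmonic amplitudes \code{u2_2, v2_2, u3_3, v3_3}, \code{km} and the
#'   \code{subcritical} flag.
#' @export
stuart_landau_coeffs <- function(dp, km = NULL, R = 2) {
  stopifnot(inherits(dp, "dimensionless_params"))
  if (is.null(km)) km <- 1 / R
  q9 <- dp$q9; q10 <- dp$q10; q11 <- dp$q11
  r1 <- dp$r1; r2 <- dp$r2; D <- dp$Dratio
  dens <- c(q10 - 4 * km^2, q10 - 9 * km^2,
            1 + 4 * D * km^2, 1 + 9 * D * km^2)
  if (any(abs(dens) < 1e-10))
    stop("stuart_landau_coeffs: resonant denominator near zero")
  u2_2 <- (1 - q11) / (q10 - 4 * km^2)
  v2_2 <- -r2 / (1 + 4 * D * km^2)
  u3_3 <- (u2_2 + v2_2 - 2 * q11 * u2_2) / (q10 - 9 * km^2)
  v3_3 <- -r2 * (u2_2 + v2_2) / (1 + 9 * D * km^2)
  c1 <- q10 - km^2 - r1 + q9 * (1 - 2 * q11) / q10
  c2 <- (1 - q11) * (2 * q11 - 1) * (2 / q10 - 1 / (q10 - 4 * km^2)) +
    r2 * (2 + 1 / (1 + 4 * D * km^2))
  c3 <- 2 * q11 * u2_2 * u3_3 - u2_2 * v3_3
  structure(list(c1 = c1, c2 = c2, c3 = c3, km = km,
                 u2_2 = u2_2, v2_2 = v2_2, u3_3 = u3_3, v3_3 = v3_3,
                 subcritical = (c2 > 0 && c3 > 0)),
            class = "amplitude_coeffs")
}

#' @export
print.amplitude_coeffs <- function(x, ...) {
  cat(sprintf("Stuart-Landau coefficients at km = %.4g\n", x$km))
  cat(sprintf("  c1 = %.4g, c2 = %.4g, c3 = %.4g -> %s pitchfork\n",
              x$c1, x$c2, x$c3,
              if (x$subcritical) "subcritical" else "supercritical"))
  invisible(x)
}

#' Equilibria of the quintic amplitude equation
#'
#' Roots of \code{c1 phi + c2 phi^3 - c3 phi^5 = 0} and the fold (saddle-node
#' of amplitudes) \code{c1} value for subcritical coefficients.
#'
#' @param coeffs an [stuart_landau_coeffs()] result (or list with c1,c2,c3).
#' @return list with non-negative equilibrium amplitudes \code{phi},
#'   their stability, and \code{c1_fold = -c2^2/(4 c3)}.
#' @export
amplitude_equilibria <- function(coeffs) {
  c1 <- coeffs$c1; c2 <- coeffs$c2; c3 <- coeffs$c3
  # phi^2 solves c3 z^2 - c2 z - c1 = 0
  disc <- c2^2 + 4 * c3 * c1
  z <- if (disc >= 0) (c2 + c(-1, 1) * sqrt(disc)) / (2 * c3) else numeric(0)
  z <- z[z > 0]
  phi <- c(0, sqrt(z))
  dV <- function(ph) c1 + 3 * c2 * ph^2 - 5 * c3 * ph^4
  list(phi = phi, stable = vapply(phi, dV, numeric(1)) < 0,
       c1_fold = -c2^2 / (4 * c3))
}
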