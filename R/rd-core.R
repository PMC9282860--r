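#' Reaction rates of the EGFR--phosphatase network
#'
#' Mass-action rates for the four species at one membrane location:
#' ligandless phosphorylated receptor \code{Ep}, liganded phosphorylated
#' receptor \code{EEp}, active PTPRG \code{RGa} and active PTPN2 \code{N2a}.
#' The Ep balance carries autonomous (\code{alpha1}), autocatalytic
#' (\code{alpha2}) and liganded-receptor-driven (\code{alpha3}) activation of
#' the non-phosphorylated pool \code{Et - Ep - EEp}, dephosphorylation by both
#' phosphatases, ligand binding loss and half of the unbinding flux (an
#' unbinding dimer returns one phosphorylated monomer). Vectorised over bins.
#'
#' @param Ep,EEp,RGa,N2a species concentrations (scalars or equal-length
#'   vectors).
#' @param params a [signaling_params()].
#' @param EGFt local total EGF concentration (>= 0).
#' @return list with rate components \code{f_Ep}, \code{f_EEp}, \code{f_RGa},
#'   \code{f_N2a}. Pure function; the PTPN2 rate carries the \code{epsilon}
#'   timescale prefactor.
#' @export
reaction_terms <- function(Ep, EEp, RGa, N2a, params, EGFt = 0) {
  stopifnot(inherits(params, "signaling_params"))
  if (any(Ep < 0) || any(EEp < 0) || any(RGa < 0) || any(N2a < 0) ||
      any(EGFt < 0))
    stop("reaction_terms: negative species or ligand concentration")
  p <- params
  E0 <- p$Et - Ep - EEp             # non-phosphorylated receptor
  free_lig <- EGFt - EEp            # bin-local free ligand
  f_Ep <- E0 * (p$alpha1 * E0 + p$alpha2 * Ep + p$alpha3 * EEp) -
    p$gamma1 * RGa * Ep - p$gamma2 * N2a * Ep -
    p$kon * free_lig * Ep^2 + 0.5 * p$koff * EEp
  f_EEp <- p$kon * free_lig * (Ep^2 + E0^2) - p$koff * EEp
  f_RGa <- p$k1 * (p$RGt - RGa) - p$k2 * RGa - p$beta1 * RGa * (Ep + EEp)
  f_N2a <- p$epsilon * (p$k1 * (p$N2t - N2a) - p$k2 * N2a +
                          p$beta2 * (Ep + EEp) * (p$N2t - N2a))
  list(f_Ep = f_Ep, f_EEp = f_EEp, f_RGa = f_RGa, f_N2a = f_N2a)
}

#' Quasi-steady state of active PTPN2
#'
#' The PTPN2 feedback is roughly two orders of magnitude slower than the
#' phosphorylation cycle; setting its rate to zero gives the quasi-steady
#' state used by the reaction-diffusion simulations.
#'
#' @param Ep,EEp receptor concentrations (vectors allowed).
#' @param params a [signaling_params()].
#' @return active PTPN2 concentration in \code{(0, N2t)}.
#' @export
n2a_qss <- function(Ep, EEp = 0, params) {
  stopifnot(inherits(params, "signaling_params"))
  if (any(Ep < 0) || any(EEp < 0)) stop("n2a_qss: negative concentration")
  s <- Ep + EEp
  params$N2t * (params$k1 + params$beta2 * s) /
    (params$k1 + params$k2 + params$beta2 * s)
}

# steady-state RGa given receptor load, from the RGa balance
rga_ss <- function(s, params)
  params$k1 * params$RGt / (params$k1 + params$k2 + params$beta1 * s)

# residual of the Ep balance along the uniform slow manifold (EEp, RGa, N2a
# eliminated); used for HSS root finding at EGFt = 0
hss_residual <- function(Ep, params) {
  RGa <- rga_ss(Ep, params)
  N2a <- n2a_qss(Ep, 0, params)
  reaction_terms(Ep, 0, RGa, N2a, params, EGFt = 0)$f_Ep
}

#' Homogeneous steady state of the network
#'
#' Finds the spatially uniform fixed point by eliminating \code{RGa} and
#' \code{N2a} through their own balances and root-finding the remaining Ep
#' equation. With no ligand the liganded pool is exactly zero. When several
#' uniform states coexist (the bistable window of the receptor totals) the
#' state continued from the low-phosphorylation branch is returned unless
#' \code{branch = "high"}.
#'
#' @param params a [signaling_params()].
#' @param EGFt uniform total EGF (only \code{EGFt = 0} admits the closed
#'   elimination; positive values are solved by damped fixed-point iteration
#'   on \code{EEp}).
#' @param branch \code{"low"} or \code{"high"} phosphorylation branch.
#' @param tol residual tolerance on the reaction rates.
#' @return list with \code{Ep}, \code{EEp}, \code{RGa}, \code{N2a} and the
#'   maximal absolute reaction-rate \code{residual}.
#' @export
homogeneous_steady_state <- function(params, EGFt = 0,
                                     branch = c("low", "high"),
                                     tol = 1e-10) {
  stopifnot(inherits(params, "signaling_params"))
  branch <- match.arg(branch)
  solve_Ep <- function(egf_eff, EEp) {
    # roots of the Ep balance with EEp held fixed, RGa/N2a eliminated
    resid <- function(Ep) {
      RGa <- rga_ss(Ep + EEp, params)
      N2a <- n2a_qss(Ep, EEp, params)
      reaction_terms(Ep, EEp, RGa, N2a, params, EGFt = egf_eff)$f_Ep
    }
    hi <- params$Et - EEp
    grid <- seq(0, hi, length.out = 400)
    r <- vapply(grid, resid, numeric(1))
    sgn <- sign(r)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(idx)) {
      # no interior sign change: pick grid minimiser of |resid| (tangency)
      return(grid[which.min(abs(r))])
    }
    roots <- vapply(idx, function(i)
      stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-14)$root,
      numeric(1))
    if (branch == "low") min(roots) else max(roots)
  }
  if (EGFt <= 0) {
    Ep <- solve_Ep(0, 0)
    EEp <- 0
  } else {
    EEp <- 0
    for (it in 1:400) {
      Ep <- solve_Ep(EGFt, EEp)
      E0 <- params$Et - Ep - EEp
      # EEp balance: kon*(EGFt-EEp)*(Ep^2+E0^2) = koff*EEp
      g <- function(e) {
        E0e <- params$Et - Ep - e
        params$kon * (EGFt - e) * (Ep^2 + E0e^2) - params$koff * e
      }
      up <- min(params$Et - Ep, EGFt)
      EEp_new <- if (g(0) <= 0) 0 else
        stats::uniroot(g, c(0, up), tol = 1e-14)$root
      if (abs(EEp_new - EEp) < 1e-13) { EEp <- EEp_new; break }
      EEp <- 0.5 * EEp + 0.5 * EEp_new
    }
    Ep <- solve_Ep(EGFt, EEp)
  }
  RGa <- rga_ss(Ep + EEp, params)
  N2a <- n2a_qss(Ep, EEp, params)
  f <- reaction_terms(Ep, EEp, RGa, N2a, params, EGFt = max(EGFt, 0))
  res <- max(abs(unlist(f)))
  if (res > max(tol, 1e-8))
    warning(sprintf("homogeneous_steady_state: residual %.3g above tolerance",
                    res))
  list(Ep = Ep, EEp = EEp, RGa = RGa, N2a = N2a, residual = res)
}
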