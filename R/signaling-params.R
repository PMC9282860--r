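#' Parameters of the EGFR--PTPRG--PTPN2 membrane signaling network
#'
#' Constructs the rate-constant set of the receptor--phosphatase network.
#' Ligandless phosphorylated receptor (\code{Ep}) is dephosphorylated by the
#' membrane phosphatase PTPRG (\code{RGa}) and the ER-bound phosphatase PTPN2
#' (\code{N2a}); liganded receptor (\code{EEp}) drives autocatalytic activation.
#' Defaults are the calibrated set used throughout the package.
#'
#' @param alpha1,alpha2,alpha3 autonomous, autocatalytic and ligand-driven
#'   receptor activation rate constants (1/time per concentration).
#' @param beta1,beta2 receptor-mediated regulation rates of PTPRG and PTPN2.
#' @param gamma1,gamma2 reactivities of PTPRG / PTPN2 toward the receptor.
#' @param k1,k2 phosphatase activation / inactivation rate constants.
#' @param kon,koff EGF binding / unbinding rate constants.
#' @param epsilon timescale separation of the PTPN2 feedback (dimensionless,
#'   in (0, 1]).
#' @param Et,RGt,N2t conserved totals of EGFR, PTPRG, PTPN2.
#' @param D_Ep,D_RGa lateral diffusion coefficients of Ep and RGa
#'   (um^2/min). \code{D_EEp} is the liganded-receptor diffusion (default 0,
#'   liganded receptors are effectively immobile).
#' @param D_EEp liganded receptor diffusion coefficient.
#' @param sigma_noise amplitude of the additive white noise applied to the
#'   Ep equation in stochastic simulations.
#' @return object of class \code{signaling_params} (a validated list).
#' @examples
#' p <- signaling_params(Et = 1.26)
#' p$alpha2
#' @export
signaling_params <- function(alpha1 = 0.001, alpha2 = 0.3, alpha3 = 0.7,
                             beta1 = 11, beta2 = 1.1,
                             gamma1 = 1.9, gamma2 = 0.1,
                             k1 = 0.5, k2 = 0.5,
                             kon = 0.05, koff = 0.28,
                             epsilon = 0.01,
                             Et = 1.26, RGt = 1, N2t = 1,
                             D_Ep = 0.008, D_RGa = 0.008, D_EEp = 0,
                             sigma_noise = 0.02) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            beta1 = beta1, beta2 = beta2,
            gamma1 = gamma1, gamma2 = gamma2,
            k1 = k1, k2 = k2, kon = kon, koff = koff,
            epsilon = epsilon, Et = Et, RGt = RGt, N2t = N2t,
            D_Ep = D_Ep, D_RGa = D_RGa, D_EEp = D_EEp,
            sigma_noise = sigma_noise)
  rates <- c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "gamma1",
             "gamma2", "k1", "k2", "kon", "koff", "D_Ep", "D_RGa", "D_EEp",
             "sigma_noise")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0)
      stop("signaling_params: '", nm, "' must be a single non-negative number")
  }
  if (!(epsilon > 0 && epsilon <= 1))
    stop("signaling_params: 'epsilon' must lie in (0, 1]")
  for (nm in c("Et", "RGt", "N2t")) {
    if (!(p[[nm]] > 0)) stop("signaling_params: '", nm, "' must be > 0")
  }
  structure(p, class = "signaling_params")
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("EGFR-PTPRG-PTPN2 network parameters\n")
  cat(sprintf("  totals: Et = %.4g, RGt = %.4g, N2t = %.4g\n",
              x$Et, x$RGt, x$N2t))
  cat(sprintf("  activation: alpha = (%.4g, %.4g, %.4g)\n",
              x$alpha1, x$alpha2, x$alpha3))
  cat(sprintf("  phosphatases: beta = (%.4g, %.4g), gamma = (%.4g, %.4g), k = (%.4g, %.4g)\n",
              x$beta1, x$beta2, x$gamma1, x$gamma2, x$k1, x$k2))
  cat(sprintf("  ligand: kon = %.4g, koff = %.4g; epsilon = %.4g\n",
              x$kon, x$koff, x$epsilon))
  cat(sprintf("  diffusion (um^2/min): D_Ep = %.4g, D_RGa = %.4g, D_EEp = %.4g; noise sigma = %.4g\n",
              x$D_Ep, x$D_RGa, x$D_EEp, x$sigma_noise))
  invisible(x)
}

#' Discretised circular membrane
#'
#' The cell boundary is a 1-D periodic domain of length \code{2*pi*R} split
#' into \code{n_bins} equal bins; bin 1 is adjacent to bin \code{n_bins}.
#'
#' @param R membrane radius (um).
#' @param n_bins number of bins (>= 3).
#' @return object of class \code{membrane_grid} with bin centre angles and
#'   bin arc length.
#' @export
membrane_grid <- function(R = 2, n_bins = 20) {
  if (!(is.numeric(R) && R > 0)) stop("membrane_grid: R must be > 0")
  n_bins <- as.integer(n_bins)
  if (n_bins < 3L) stop("membrane_grid: n_bins must be >= 3")
  structure(list(R = R, n_bins = n_bins,
                 bin_centers = 2 * pi * (seq_len(n_bins) - 0.5) / n_bins,
                 bin_length = 2 * pi * R / n_bins),
            class = "membrane_grid")
}

#' @export
print.membrane_grid <- function(x, ...) {
  cat(sprintf("circular membrane: R = %.3g um, %d bins (arc %.3g um)\n",
              x$R, x$n_bins, x$bin_length))
  invisible(x)
}
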