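#' Piecewise space-time EGF stimulus protocol
#'
#' A protocol is an ordered list of non-overlapping segments covering the
#' simulated interval. Each segment is one of
#' \itemize{
#'   \item \code{"none"}: no ligand;
#'   \item \code{"uniform"}: spatially uniform EGF of amplitude \code{A};
#'   \item \code{"gaussian_gradient"}: a wrapped (periodic) Gaussian centred
#'     at angle \code{theta0} with amplitude and width schedules. Amplitude
#'     and width may be constants or length-2 vectors \code{c(start, end)}
#'     interpolated linearly in time across the segment ("dynamic" gradient).
#' }
#' Two simultaneous gradients (competing sources) are expressed by giving a
#' segment a second component via \code{theta0_2}, \code{A2}, \code{width2}.
#'
#' @param segments list of segments; each a list with \code{t_start},
#'   \code{t_end}, \code{kind}, and for gradients \code{A}, \code{width}
#'   (angular s.d., radians), \code{theta0}, optionally a second source.
#' @return object of class \code{stimulus_protocol}.
#' @seealso [egf_at()], [make_stimulus_protocol()]
#' @export
stimulus_protocol <- function(segments) {
  if (!length(segments)) stop("stimulus_protocol: need at least one segment")
  t0 <- vapply(segments, function(s) s$t_start, numeric(1))
  t1 <- vapply(segments, function(s) s$t_end, numeric(1))
  o <- order(t0)
  segments <- segments[o]; t0 <- t0[o]; t1 <- t1[o]
  if (any(t1 <= t0)) stop("stimulus_protocol: segment with t_end <= t_start")
  if (length(segments) > 1 && any(t0[-1] < t1[-length(t1)] - 1e-9))
    stop("stimulus_protocol: overlapping segments")
  for (s in segments) {
    if (!s$kind %in% c("none", "uniform", "gaussian_gradient"))
      stop("stimulus_protocol: unknown segment kind '", s$kind, "'")
    if (s$kind != "none") {
      if (any(unlist(s[c("A", if (!is.null(s$A2)) "A2")]) < 0))
        stop("stimulus_protocol: negative amplitude")
    }
  }
  structure(list(segments = segments,
                 t_start = t0[1], t_end = t1[length(t1)]),
            class = "stimulus_protocol")
}

seg_interp <- function(v, frac) {
  if (length(v) == 1L) return(v)
  v[1] + (v[2] - v[1]) * frac
}

wrapped_gaussian <- function(theta, theta0, width, A) {
  # periodic Gaussian on the ring: nearest angular distance
  d <- (theta - theta0 + pi) %% (2 * pi) - pi
  A * exp(-d^2 / (2 * width^2))
}

#' Evaluate the EGF field of a protocol
#'
#' @param protocol a [stimulus_protocol()].
#' @param theta angles (radians) at which to evaluate.
#' @param t single time.
#' @return non-negative EGF concentration at each angle (0 outside all
#'   segments).
#' @export
egf_at <- function(protocol, theta, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  out <- numeric(length(theta))
  for (s in protocol$segments) {
    if (t >= s$t_start && t < s$t_end) {
      if (s$kind == "none") return(out)
      frac <- (t - s$t_start) / (s$t_end - s$t_start)
      if (s$kind == "uniform") {
        out <- out + seg_interp(s$A, frac)
      } else {
        out <- out + wrapped_gaussian(theta, s$theta0,
                                      seg_interp(s$width, frac),
                                      seg_interp(s$A, frac))
        if (!is.null(s$theta0_2)) {
          out <- out + wrapped_gaussian(theta, s$theta0_2,
                                        seg_interp(s$width2, frac),
                                        seg_interp(s$A2, frac))
        }
      }
      return(pmax(out, 0))
    }
  }
  out
}

#' Stimulus-active test
#'
#' @param protocol a [stimulus_protocol()].
#' @param t time.
#' @return TRUE when some non-\code{"none"} segment covers \code{t}.
#' @export
stimulus_on <- function(protocol, t) {
  for (s in protocol$segments)
    if (t >= s$t_start && t < s$t_end) return(s$kind != "none")
  FALSE
}

#' Time the last stimulus segment ends (washout time)
#'
#' @param protocol a [stimulus_protocol()].
#' @return end time of the last non-\code{"none"} segment, or \code{NA} if
#'   the protocol contains none.
#' @export
stimulus_end_time <- function(protocol) {
  ends <- vapply(protocol$segments,
                 function(s) if (s$kind != "none") s$t_end else NA_real_,
                 numeric(1))
  if (all(is.na(ends))) NA_real_ else max(ends, na.rm = TRUE)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus protocol: %d segment(s), t in [%g, %g] min\n",
              length(x$segments), x$t_start, x$t_end))
  for (s in x$segments) {
    extra <- switch(s$kind,
      none = "",
      uniform = sprintf(" A=%s", paste(signif(s$A, 3), collapse = "->")),
      gaussian_gradient = sprintf(" A=%s width=%s theta0=%.2f%s",
        paste(signif(s$A, 3), collapse = "->"),
        paste(signif(s$width, 3), collapse = "->"), s$theta0,
        if (!is.null(s$theta0_2)) " (+second source)" else ""))
    cat(sprintf("  [%6g, %6g) %-17s%s\n", s$t_start, s$t_end, s$kind, extra))
  }
  invisible(x)
}
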