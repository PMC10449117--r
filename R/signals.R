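#' Truncated-Gaussian gradient specification
#'
#' The chemoattractant gradient along the discretized membrane is a truncated
#' Gaussian window of variance `w`: at integer bin offset `n` from the center
#' bin,
#' \deqn{s(n) = s_0 \exp\left(-\tfrac{n^2}{2 w}\right), \qquad
#'       w = (N - 1) / (2\alpha),}
#' so larger `alpha` gives a narrower profile. With the defaults
#' `s0 = 0.02`, `alpha = 2` and `N = 20` the variance is `w = 4.75` bins^2
#' (standard deviation about 2.18 bins), which puts the full width at half
#' maximum at 5.13 bins, i.e. about 25% of the cell perimeter, and leaves a
#' negligible wrap-around discontinuity (about `7e-5 * s0`) at the back of
#' the cell.
#'
#' @param s0 peak amplitude (signal units, nonnegative).
#' @param alpha inverse-width shape constant (> 0, dimensionless).
#' @param center angular position of the maximum (radians); snapped to the
#'   nearest bin, since the profile is defined bin-wise.
#' @param N number of membrane bins (>= 3).
#' @return An object of class `gradient_spec`; field `w` is the variance in
#'   bins^2.
#' @export
gradient_spec <- function(s0 = 0.02, alpha = 2, center = pi, N = 20) {
  if (alpha <= 0) stop("gradient_spec: alpha must be positive")
  if (s0 < 0) stop("gradient_spec: s0 must be nonnegative")
  if (N < 3) stop("gradient_spec: need at least 3 bins")
  structure(list(s0 = s0, alpha = alpha, center = center, N = as.integer(N),
                 w = (N - 1) / (2 * alpha)),
            class = "gradient_spec")
}

#' Full / half width at half maximum of a gradient profile
#'
#' @param spec a [gradient_spec()].
#' @return Named vector with `fwhm` and `hwhm` in bins and `fwhm_frac`, the
#'   FWHM as a fraction of the perimeter.
#' @export
gradient_width <- function(spec) {
  sigma <- sqrt(spec$w)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  c(fwhm = fwhm, hwhm = fwhm / 2, fwhm_frac = fwhm / spec$N)
}

#' Bin-center angles of the discretized membrane
#' @param N number of bins.
#' @return Angles `2*pi*(0:(N-1))/N` (radians); bin 1 sits at `theta = 0`
#'   and, for even `N`, bin `N/2 + 1` at `theta = pi`.
#' @export
membrane_theta <- function(N) 2 * pi * (seq_len(N) - 1) / N

#' Evaluate a Gaussian gradient profile on the membrane bins
#'
#' @param spec a [gradient_spec()].
#' @return Numeric vector of length `N`; maximum `s0` at the bin nearest
#'   `center`, symmetric about the center on the circle.
#' @export
gaussian_profile <- function(spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  N <- spec$N
  ic <- 1 + (round(spec$center / (2 * pi) * N) %% N)  # bin nearest center
  d <- abs(seq_len(N) - ic)
  d <- pmin(d, N - d)                                  # circular bin distance
  spec$s0 * exp(-d^2 / (2 * spec$w))
}

#' Stimulus difference of a profile
#'
#' The percent stimulus difference across the cell,
#' `sd = (s[theta = pi] - s[theta = 0]) * 100`, evaluated at the bins nearest
#' the front (`pi`) and back (`0`) of the membrane.
#'
#' @param x a `gradient_spec` or a numeric profile vector.
#' @return Stimulus difference in percent.
#' @export
stimulus_difference <- function(x) {
  s <- if (inherits(x, "gradient_spec")) gaussian_profile(x) else x
  N <- length(s)
  (s[N %/% 2 + 1] - s[1]) * 100
}

#' Peak amplitude producing a requested stimulus difference
#'
#' Inverts [stimulus_difference()] for a front-centered Gaussian profile:
#' returns the `s0` for which the percent difference between the front and
#' back bins equals `sd`.
#'
#' @param sd stimulus difference (percent).
#' @param alpha,N profile shape parameters as in [gradient_spec()].
#' @return Peak amplitude `s0`.
#' @export
s0_for_sd <- function(sd, alpha = 2, N = 20) {
  unit <- stimulus_difference(gradient_spec(s0 = 1, alpha = alpha, N = N))
  sd / unit
}

#' Stimulation protocol
#'
#' A protocol is a list of gradient epochs (each a [gradient_spec()] with an
#' on/off time) plus an optional uniform additive baseline, or, for the
#' two-bin projection, a table of step amplitudes. Supported kinds:
#' \describe{
#'   \item{single_transient}{one gradient, on then off.}
#'   \item{reversal}{first epoch at `center`, later epoch(s) rotated by pi.}
#'   \item{simultaneous}{two opposed gradients active at the same time; their
#'     profiles are summed.}
#'   \item{consecutive}{repeated transient gradients from the same direction.}
#'   \item{offset}{a gradient plus a uniform baseline (`offset`) applied
#'     while the gradient is on.}
#'   \item{step_two_bin}{piecewise-constant `(sL, sR)` epochs for the
#'     projection model.}
#' }
#'
#' @param kind protocol kind (see above).
#' @param gradients list of epochs, each a list with elements `spec`
#'   (a `gradient_spec`), `on` and `off` (seconds).
#' @param offset uniform additive baseline applied while a gradient is on.
#' @param steps for `step_two_bin`: data frame with columns `sL`, `sR`,
#'   `duration` (seconds). `sR` is conventionally 0.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = "single_transient", gradients = list(),
                          offset = 0, steps = NULL) {
  kind <- match.arg(kind, c("single_transient", "reversal", "simultaneous",
                            "consecutive", "offset", "step_two_bin"))
  if (kind == "step_two_bin") {
    stopifnot(is.data.frame(steps),
              all(c("sL", "sR", "duration") %in% names(steps)),
              all(steps$duration > 0))
  } else {
    for (g in gradients) {
      stopifnot(inherits(g$spec, "gradient_spec"), g$on < g$off)
    }
    if (kind != "simultaneous" && length(gradients) > 1) {
      on <- vapply(gradients, `[[`, 0, "on")
      off <- vapply(gradients, `[[`, 0, "off")
      o <- order(on)
      if (any(off[o][-length(o)] > on[o][-1] + 1e-12))
        stop("protocol_spec: overlapping epochs only allowed for kind 'simultaneous'")
    }
  }
  structure(list(kind = kind, gradients = gradients, offset = offset,
                 steps = steps),
            class = "protocol_spec")
}

#' Convenience constructors for the standard protocols
#'
#' `single_gradient_protocol()` builds one Gaussian epoch;
#' `reversal_protocol()` builds a gradient at `center` followed by one
#' rotated by pi with its own amplitude; `simultaneous_protocol()` builds two
#' opposed gradients with an amplitude ratio active over the same window;
#' `consecutive_protocol()` repeats a transient gradient `n_pulses` times.
#'
#' @param s0,alpha,center,N gradient shape as in [gradient_spec()].
#' @param on,off epoch start/end (s); `off = Inf` gives a sustained gradient.
#' @param offset uniform additive baseline (protocol kind `"offset"` when
#'   nonzero).
#' @param s0_rev amplitude of the reversed gradient.
#' @param t_reverse time of the reversal (s); the reversed epoch runs to
#'   `t_end`.
#' @param t_end end of the reversed/simultaneous epoch (s).
#' @param ratio amplitude ratio of the stronger (front) to the weaker (back)
#'   gradient.
#' @param period,duration,n_pulses pulse train timing (s).
#' @return A [protocol_spec()].
#' @name protocol_constructors
NULL

#' @rdname protocol_constructors
#' @export
single_gradient_protocol <- function(s0 = 0.02, alpha = 2, center = pi,
                                     N = 20, on = 0, off = Inf, offset = 0) {
  protocol_spec(if (offset > 0) "offset" else "single_transient",
                gradients = list(list(
                  spec = gradient_spec(s0, alpha, center, N),
                  on = on, off = off)),
                offset = offset)
}

#' @rdname protocol_constructors
#' @export
reversal_protocol <- function(s0 = 0.02, s0_rev = s0, alpha = 2, center = pi,
                              N = 20, on = 0, t_reverse, t_end = Inf) {
  protocol_spec("reversal", gradients = list(
    list(spec = gradient_spec(s0, alpha, center, N), on = on, off = t_reverse),
    list(spec = gradient_spec(s0_rev, alpha, center + pi, N),
         on = t_reverse, off = t_end)))
}

#' @rdname protocol_constructors
#' @export
simultaneous_protocol <- function(s0 = 0.02, ratio = 2, alpha = 2,
                                  center = pi, N = 20, on = 0, t_end = Inf) {
  protocol_spec("simultaneous", gradients = list(
    list(spec = gradient_spec(s0, alpha, center, N), on = on, off = t_end),
    list(spec = gradient_spec(s0 / ratio, alpha, center + pi, N),
         on = on, off = t_end)))
}

#' @rdname protocol_constructors
#' @export
consecutive_protocol <- function(s0 = 0.02, alpha = 2, center = pi, N = 20,
                                 on = 0, duration, period, n_pulses) {
  stopifnot(duration < period, n_pulses >= 1)
  grads <- lapply(seq_len(n_pulses) - 1, function(k) {
    list(spec = gradient_spec(s0, alpha, center, N),
         on = on + k * period, off = on + k * period + duration)
  })
  protocol_spec("consecutive", gradients = grads)
}

#' Step protocol for the two-bin projection
#' @param sL,sR step amplitudes per epoch (vectors of equal length); `sR`
#'   defaults to 0.
#' @param duration epoch durations (s).
#' @return A [protocol_spec()] of kind `step_two_bin`.
#' @export
step_protocol <- function(sL, duration, sR = 0) {
  protocol_spec("step_two_bin",
                steps = data.frame(sL = sL, sR = rep_len(sR, length(sL)),
                                   duration = rep_len(duration, length(sL))))
}

#' Evaluate the signal of a protocol at one time
#'
#' Assembles all gradients active at time `t` (summing them, as required for
#' simultaneous opposed stimuli) plus the uniform baseline while a gradient
#' is on. Out-of-range times yield a zero signal. For `step_two_bin`
#' protocols the active `(sL, sR)` pair is returned.
#'
#' @param protocol a [protocol_spec()].
#' @param t time (s), `t >= 0`.
#' @param N number of bins (defaults to the protocol's gradient bins).
#' @return Numeric signal vector of length `N`, or `c(sL, sR)`.
#' @export
signal_at <- function(protocol, t, N = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (protocol$kind == "step_two_bin") {
    tb <- cumsum(protocol$steps$duration)
    i <- findInterval(t, c(0, tb), left.open = TRUE, rightmost.closed = FALSE)
    if (i < 1 || i > nrow(protocol$steps)) return(c(sL = 0, sR = 0))
    return(c(sL = protocol$steps$sL[i], sR = protocol$steps$sR[i]))
  }
  if (is.null(N)) {
    if (length(protocol$gradients) == 0)
      stop("signal_at: N required for a protocol without gradients")
    N <- protocol$gradients[[1]]$spec$N
  }
  s <- numeric(N)
  active <- FALSE
  for (g in protocol$gradients) {
    if (t >= g$on && t < g$off) {
      s <- s + gaussian_profile(g$spec)
      active <- TRUE
    }
  }
  if (active && protocol$offset > 0) s <- s + protocol$offset
  s
}

# Epoch boundaries of a protocol (used to split ODE integration at signal
# discontinuities).
protocol_breaks <- function(protocol, t_end) {
  if (protocol$kind == "step_two_bin") {
    tb <- cumsum(protocol$steps$duration)
  } else {
    tb <- unlist(lapply(protocol$gradients, function(g) c(g$on, g$off)))
  }
  tb <- sort(unique(tb[is.finite(tb) & tb > 0 & tb < t_end]))
  c(0, tb, t_end)
}
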