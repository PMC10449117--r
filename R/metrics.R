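# bins nearest the front (theta = pi) and back (theta = 0) of the membrane
front_back_bins <- function(kym) {
  N <- length(kym$theta)
  c(front = N %/% 2 + 1, back = 1L)
}

#' Polarization ratio of a kymograph
#'
#' The ratio `u(theta = pi) / u(theta = 0)`, the standard readout of
#' front/back asymmetry. By default the mean over the last 100 reported
#' samples is returned; pass `t` for an instantaneous ratio.
#'
#' @param kym a `kymograph`.
#' @param t time (s) of an instantaneous ratio, or `NULL` (default) for the
#'   mean over the last 100 samples.
#' @param last number of trailing samples averaged when `t` is `NULL`.
#' @param eps denominator floor; a back concentration below it yields `Inf`.
#' @return Numeric ratio (possibly `Inf`).
#' @export
polarization_ratio <- function(kym, t = NULL, last = 100, eps = 1e-12) {
  fb <- front_back_bins(kym)
  u <- kym$fields$u
  if (!is.null(t)) {
    i <- which.min(abs(kym$times - t))
    num <- u[i, fb["front"]]; den <- u[i, fb["back"]]
  } else {
    n <- nrow(u)
    idx <- max(1, n - last + 1):n
    num <- mean(u[idx, fb["front"]]); den <- mean(u[idx, fb["back"]])
  }
  if (den < eps) return(Inf)
  num / den
}

# First entry time of a min-max normalized trace into the +-band window
# around the mean of its last `last` samples. Returns NA (not reached) when
# the plateau variance check fails or the band is never entered.
plateau_entry_time <- function(trace, times, band = 1e-2, last = 100,
                               check_plateau = TRUE) {
  if (length(trace) < last)
    stop("plateau_entry_time: need at least ", last, " samples")
  rng <- range(trace)
  if (diff(rng) < .Machine$double.eps)
    return(times[1])  # constant trace: the plateau is entered immediately
  un <- (trace - rng[1]) / diff(rng)
  tail_idx <- (length(un) - last + 1):length(un)
  mu <- mean(un[tail_idx])
  if (check_plateau && stats::var(un[tail_idx]) >= band^2) return(NA_real_)
  i <- which(abs(un - mu) <= band)[1]
  if (is.na(i)) NA_real_ else times[i]
}

#' Time to stable polarization
#'
#' The front trace `u(theta = pi, t)` within the stimulation epoch is
#' min-max normalized and the polarization time is the first time point at
#' which it enters a `+-1e-2` window around the mean of the last 100 samples
#' of the epoch; the plateau must itself be stable (variance of the last 100
#' normalized samples below the window squared), otherwise the result is
#' `NA` (not reached).
#'
#' @param kym a `kymograph`.
#' @param epoch `c(on, off)` of the gradient epoch (s); defaults to the
#'   first gradient epoch of the kymograph's protocol, capped at the end of
#'   the simulation.
#' @param band entry window (normalized units).
#' @return Time since epoch start (s), or `NA` if no stable plateau.
#' @export
polarization_time <- function(kym, epoch = NULL, band = 1e-2) {
  if (is.null(epoch)) {
    g <- kym$protocol$gradients[[1]]
    epoch <- c(g$on, min(g$off, max(kym$times)))
  }
  fb <- front_back_bins(kym)
  rows <- which(kym$times >= epoch[1] & kym$times <= epoch[2])
  if (length(rows) < 100)
    stop("polarization_time: epoch shorter than 100 reported samples")
  tr <- kym$fields$u[rows, fb["front"]]
  tt <- kym$times[rows] - epoch[1]
  plateau_entry_time(tr, tt, band = band)
}

#' Activation threshold from a dose-response scan
#'
#' Runs sustained-gradient simulations over a grid of stimulus differences,
#' records the mean plateau polarization ratio per dose, and returns the
#' stimulus difference at which 50% of the maximum ratio is reached (linear
#' interpolation between grid points). For the LEGI and Turing-like
#' mechanisms, which respond smoothly at arbitrarily small doses rather
#' than through a threshold, the published convention fixes the threshold
#' manually at 0.5% and 0.1%; these overrides are applied unless
#' `manual_override = FALSE`.
#'
#' @param model a `model_spec`.
#' @param sd_grid stimulus differences to scan (percent).
#' @param t_end simulated time per dose (s).
#' @param repeats,sigma,seed number of noisy repetitions per dose and their
#'   noise intensity; the default (`repeats = 1`, `sigma = 0`) is the
#'   deterministic scan.
#' @param alpha gradient shape constant.
#' @param domain a [domain_spec()].
#' @param manual_override apply the published manual thresholds for LEGI
#'   (0.5%) and Turing (0.1%).
#' @param rtol,atol integrator tolerances.
#' @return List with `sd_thresh` (percent, `NA` if the curve never reaches
#'   half maximum) and `curve` (data frame `sd`, `ratio`).
#' @export
estimate_sd_thresh <- function(model, sd_grid = c(0.1, 0.3, 0.5, 0.7, 0.9,
                                                  1.1, 1.3, 1.6, 2.0, 3.0),
                               t_end = 600, repeats = 1, sigma = 0, seed = 1,
                               alpha = 2, domain = domain_spec(),
                               manual_override = TRUE,
                               rtol = 1e-7, atol = 1e-9) {
  ratios <- vapply(sd_grid, function(sd) {
    prot <- single_gradient_protocol(s0 = s0_for_sd(sd, alpha = alpha,
                                                    N = domain$N),
                                     alpha = alpha, N = domain$N,
                                     on = 0, off = Inf)
    reps <- vapply(seq_len(repeats), function(r) {
      kym <- if (sigma > 0)
        simulate_rd_sde(model, prot, t_end = t_end, sigma = sigma,
                        seed = seed + r, domain = domain)
      else simulate_rd(model, prot, t_end = t_end, domain = domain,
                       rtol = rtol, atol = atol)
      polarization_ratio(kym)
    }, 0)
    mean(reps)
  }, 0)
  curve <- data.frame(sd = sd_grid, ratio = ratios)
  if (manual_override && model$name %in% c("legi", "turing")) {
    thr <- if (model$name == "legi") 0.5 else 0.1
    return(list(sd_thresh = thr, curve = curve, manual = TRUE))
  }
  list(sd_thresh = halfmax_threshold(curve$sd, curve$ratio), curve = curve,
       manual = FALSE)
}

#' Dose at half-maximal response by linear interpolation
#'
#' The 50%-of-maximum rule applied to a monotone dose-response curve:
#' returns the dose at which the response first reaches half its maximum,
#' interpolating linearly between grid points.
#'
#' @param dose,response equal-length numeric vectors (dose increasing).
#' @return Interpolated dose, or `NA` if the response never reaches half
#'   its maximum.
#' @export
halfmax_threshold <- function(dose, response) {
  half <- max(response) / 2
  i <- which(response >= half)[1]
  if (is.na(i)) NA_real_
  else if (i == 1) dose[1]
  else dose[i - 1] + (half - response[i - 1]) *
    (dose[i] - dose[i - 1]) / (response[i] - response[i - 1])
}

#' Re-polarization time and amplification after gradient reversal
#'
#' For a kymograph produced under a [reversal_protocol()]: the trace at the
#' new front (the reversed gradient's center bin) within the reversal epoch
#' is subjected to the same plateau-entry criterion as
#' [polarization_time()], and the amplification is the plateau ratio
#' `u(new front) / u(old front)`. Re-polarization requires the axis to have
#' actually flipped (amplification > 1); otherwise the time is `NA`
#' (not reached within the epoch).
#'
#' @param kym a `kymograph` whose protocol has kind `"reversal"`.
#' @param band entry window.
#' @return List with `time` (s since reversal, `NA` if not reached),
#'   `amplification`, and `reversed` (logical).
#' @export
repolarization_metrics <- function(kym, band = 1e-2) {
  stopifnot(kym$protocol$kind == "reversal")
  grads <- kym$protocol$gradients
  g_rev <- grads[[length(grads)]]
  N <- length(kym$theta)
  new_front <- 1 + (round(g_rev$spec$center / (2 * pi) * N) %% N)
  old_front <- 1 + ((new_front - 1 + N %/% 2) %% N)
  rows <- which(kym$times >= g_rev$on &
                  kym$times <= min(g_rev$off, max(kym$times)))
  if (length(rows) < 100)
    stop("repolarization_metrics: reversal epoch shorter than 100 samples")
  tr <- kym$fields$u[rows, new_front]
  tt <- kym$times[rows] - g_rev$on
  n <- length(rows)
  idx <- (n - min(100, n) + 1):n
  amp <- mean(kym$fields$u[rows[idx], new_front]) /
    mean(kym$fields$u[rows[idx], old_front])
  t_rev <- plateau_entry_time(tr, tt, band = band)
  if (!is.na(t_rev) && amp <= 1) t_rev <- NA_real_
  list(time = t_rev, amplification = amp, reversed = is.finite(t_rev))
}

#' Resolving time and amplification under simultaneous opposed gradients
#'
#' For a kymograph produced under a [simultaneous_protocol()] (two opposed
#' gradients, the stronger one first in the protocol): time until the
#' membrane establishes a unique polarization axis toward the stronger
#' signal, measured by the plateau-entry criterion on the trace at the
#' stronger gradient's center, plus the plateau amplification toward it.
#'
#' @param kym a `kymograph` whose protocol has kind `"simultaneous"`.
#' @param band entry window.
#' @return List with `time` (s since onset, `NA` if no unique axis),
#'   `amplification`, `resolved`.
#' @export
resolving_metrics <- function(kym, band = 1e-2) {
  stopifnot(kym$protocol$kind == "simultaneous")
  grads <- kym$protocol$gradients
  s0s <- vapply(grads, function(g) g$spec$s0, 0)
  g_strong <- grads[[which.max(s0s)]]
  N <- length(kym$theta)
  strong_bin <- 1 + (round(g_strong$spec$center / (2 * pi) * N) %% N)
  weak_bin <- 1 + ((strong_bin - 1 + N %/% 2) %% N)
  rows <- which(kym$times >= g_strong$on &
                  kym$times <= min(g_strong$off, max(kym$times)))
  if (length(rows) < 100)
    stop("resolving_metrics: epoch shorter than 100 samples")
  tr <- kym$fields$u[rows, strong_bin]
  tt <- kym$times[rows] - g_strong$on
  n <- length(rows)
  idx <- (n - min(100, n) + 1):n
  amp <- mean(kym$fields$u[rows[idx], strong_bin]) /
    mean(kym$fields$u[rows[idx], weak_bin])
  t_res <- plateau_entry_time(tr, tt, band = band)
  if (!is.na(t_res) && amp <= 1) t_res <- NA_real_
  list(time = t_res, amplification = amp, resolved = is.finite(t_res))
}

#' Signal integration index
#'
#' Quantifies how the duration of the polarized state adapts to consecutive
#' transient stimuli:
#' \deqn{\xi = \frac{[u_{\theta=\pi} > 0.5] - [s_{\theta=\pi} > 0]}{t_{max}}}
#' where `[x]` denotes total duration, the front trace is min-max
#' normalized, and `t_max` is the total simulation time. A memoryless model
#' scores near `-[s]/t_max`; a permanently polarized one scores
#' `(t_max - [s])/t_max` regardless of the pulse count; memory that
#' outlives each pulse by `m` seconds scores `m/t_max`-per-pulse.
#'
#' @param kym a `kymograph`, or a numeric front trace.
#' @param signal signal trace at the front bin (required when `kym` is a
#'   trace).
#' @param times sample times (required when `kym` is a trace).
#' @param threshold supra-threshold level on the normalized trace.
#' @return The index (dimensionless, in `[-1, 1]`).
#' @export
signal_integration_index <- function(kym, signal = NULL, times = NULL,
                                     threshold = 0.5) {
  if (inherits(kym, "kymograph")) {
    fb <- front_back_bins(kym)
    trace <- kym$fields$u[, fb["front"]]
    signal <- kym$signal[, fb["front"]]
    times <- kym$times
  } else trace <- kym
  t_max <- max(times) - min(times)
  if (t_max <= 0) stop("signal_integration_index: t_max must be positive")
  dt <- c(diff(times), 0)
  rng <- range(trace)
  un <- if (diff(rng) > 0) (trace - rng[1]) / diff(rng) else trace * 0
  dur_u <- sum(dt[un > threshold])
  dur_s <- sum(dt[signal > 0])
  (dur_u - dur_s) / t_max
}

#' Spurious activation under random perturbations of the resting state
#'
#' Applies mass-shuffling perturbations around the homogeneous steady state
#' — per bin, `(u_s + xi_per * r, v_s - xi_per * r)` with `r ~ U[0, 1]`
#' (and `w_s + xi_per * r'` for LEGI) — and reports the fraction of
#' replicates whose zero-signal simulation ends polarized (plateau
#' `max(u)/min(u)` above `cutoff`). A mechanism with genuine threshold
#' activation scores 0 at small `xi_per`; mechanisms organized past their
#' symmetry-breaking point activate spuriously.
#'
#' @param model a `model_spec`.
#' @param xi_per perturbation amplitude (uM).
#' @param n_reps number of replicates.
#' @param seed integer seed (replicate draws are seeded reproducibly).
#' @param t_end simulated time per replicate (s).
#' @param cutoff plateau ratio above which a run counts as polarized.
#' @param domain a [domain_spec()].
#' @return Fraction of replicates that polarized (in `[0, 1]`).
#' @export
spurious_activation <- function(model, xi_per, n_reps = 10, seed = 1,
                                t_end = 400, cutoff = 1.5,
                                domain = domain_spec()) {
  if (n_reps < 1) stop("spurious_activation: n_reps must be >= 1")
  if (xi_per == 0) return(0)
  N <- domain$N
  hss <- homogeneous_steady_state(model)
  set.seed(as.integer(seed))
  hits <- 0L
  for (rep in seq_len(n_reps)) {
    r <- stats::runif(N)
    u0 <- pmax(hss$u + xi_per * r, 0)
    v0 <- pmax(hss$v - xi_per * r, 0)
    init <- c(u0, v0)
    if (!model$conserved) {
      rw <- stats::runif(N)
      init <- c(init, pmax(hss$w + xi_per * rw, 0))
    }
    kym <- simulate_rd(model, NULL, t_end = t_end, domain = domain,
                       init = init, rtol = 1e-7, atol = 1e-9)
    u_end <- colMeans(kym$fields$u[(nrow(kym$fields$u) - 49):
                                     nrow(kym$fields$u), , drop = FALSE])
    if (max(u_end) / max(min(u_end), 1e-12) > cutoff) hits <- hits + 1L
  }
  hits / n_reps
}
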