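#' Discretized circular-membrane domain
#'
#' The membrane is a ring of `N` uniform bins of physical size
#' `dtheta = L/N`, with `L = 2*pi*R` the cell perimeter. The models carry
#' physical diffusion constants (um^2/s) but the cell size itself is a free
#' scale, and every absolute time in the simulations depends on it. The
#' default perimeter `L = 9.3 um` (`R = 1.48 um`) is the center of the window
#' in which the canonical `c_total` presets of the conserved GTPase model
#' realize their four organization regimes on the N = 20 ring: below
#' `L = 9.0 um` the homogeneous state at `c_total = 2.32 uM` is still
#' linearly stable (no region IV), and above `L = 9.6 um` the pinned
#' polarized state at `c_total = 2.21 uM` becomes a true attractor instead
#' of a transient "ghost" (no region II). Override `R` or `L` to explore
#' other cell sizes; all absolute times scale with this choice.
#'
#' @param N number of bins (>= 3; default 20).
#' @param R cell radius (um).
#' @param L perimeter length (um); defaults to `2*pi*R`.
#' @return An object of class `domain_spec` with fields `N`, `L`, `dtheta`
#'   and `boundary = "periodic"`.
#' @export
domain_spec <- function(N = 20, R = 1.4801, L = 2 * pi * R) {
  stopifnot(N >= 3, L > 0)
  structure(list(N = as.integer(N), R = L / (2 * pi), L = L, dtheta = L / N,
                 boundary = "periodic"),
            class = "domain_spec")
}

# Periodic second-difference (ring Laplacian applied to a bin vector),
# already divided by dtheta^2.
ring_laplacian <- function(x, dtheta) {
  n <- length(x)
  (x[c(2:n, 1)] - 2 * x + x[c(n, 1:(n - 1))]) / dtheta^2
}

# Fast inlined RHS core: returns f(y, s) for a fixed model/domain, with s a
# scalar or length-N signal vector. The kinetics are expanded in place; the
# generic surface stays reaction_rates()/rd_rhs().
rd_core <- function(model, domain) {
  N <- domain$N
  dth2 <- domain$dtheta^2
  D <- model_diffusivities(model)
  ip <- c(2:N, 1)
  im <- c(N, 1:(N - 1))
  p <- model$params
  iu <- 1:N
  iv <- (N + 1):(2 * N)
  if (model$conserved) {
    cu <- D[["u"]] / dth2
    cv <- D[["v"]] / dth2
    if (model$name %in% c("subpb", "wavepinning")) {
      k0 <- p$k0; g <- p$gamma; Kh <- p$K^p$hill; h <- p$hill; del <- p$delta
      function(y, s) {
        u <- y[iu]; v <- y[iv]
        uc <- pmax(u, 0)
        fu <- (k0 + g * uc^h / (Kh + uc^h)) * v - del * u + s * v
        c(fu + cu * (u[ip] - 2 * u + u[im]),
          -fu + cv * (v[ip] - 2 * v + v[im]))
      }
    } else {
      a1 <- p$a1; a2 <- p$a2
      function(y, s) {
        u <- y[iu]; v <- y[iv]
        x <- u + v
        fu <- a1 * (v - x / (1 + a2 * x)^2) + s * v
        c(fu + cu * (u[ip] - 2 * u + u[im]),
          -fu + cv * (v[ip] - 2 * v + v[im]))
      }
    }
  } else {
    iw <- (2 * N + 1):(3 * N)
    cu <- D[["u"]] / dth2; cv <- D[["v"]] / dth2; cw <- D[["w"]] / dth2
    ku <- p$ku; kmu <- p$k_minus_u; kv <- p$kv; kmv <- p$k_minus_v
    kw <- p$kw; kmw <- p$k_minus_w; ut <- p$u_total
    function(y, s) {
      u <- y[iu]; v <- y[iv]; w <- y[iw]
      c(ku * w * (ut - u) - kmu * v * u + cu * (u[ip] - 2 * u + u[im]),
        -kmv * v + kv * s + cv * (v[ip] - 2 * v + v[im]),
        -kmw * w + kw * s + cw * (w[ip] - 2 * w + w[im]))
    }
  }
}

#' Method-of-lines right-hand side of a reaction-diffusion model
#'
#' Builds the time-dependent vector field obtained by discretizing the PDE on
#' the periodic ring: centered second differences for diffusion (bin 1
#' couples to bins N and 2) plus the bin-local reaction terms of the model
#' with the protocol's signal at time `t`; identical, bin for bin, to
#' [reaction_rates()] plus the scaled ring Laplacian.
#'
#' @param model a `model_spec`.
#' @param domain a [domain_spec()].
#' @param protocol a [protocol_spec()] (or `NULL` for no signal).
#' @return A function `f(t, y)` mapping the stacked state vector
#'   (components in [model_components()] order, `N` bins each) to its time
#'   derivative; suitable for [deSolve::ode()].
#' @export
rd_rhs <- function(model, domain, protocol = NULL) {
  N <- domain$N
  if (!is.null(protocol) && protocol$kind != "step_two_bin" &&
      length(protocol$gradients) > 0 &&
      protocol$gradients[[1]]$spec$N != N)
    stop("rd_rhs: protocol and domain bin counts differ")
  core <- rd_core(model, domain)
  function(t, y) {
    s <- if (is.null(protocol)) 0 else signal_at(protocol, t, N = N)
    core(y, s)
  }
}

# Default initial condition: the homogeneous steady state replicated over the
# bins. If that state is linearly unstable for the discretized system (e.g.
# region IV or the Turing preset), a deterministic odd perturbation of
# +-1e-3, transferred between u and v so mass is conserved, selects a
# definite branch.
default_initial_state <- function(model, domain, perturb_if_unstable = TRUE) {
  N <- domain$N
  hss <- homogeneous_steady_state(model)
  comps <- model_components(model)
  y0 <- unlist(lapply(comps, function(nm) rep(hss[[nm]], N)))
  if (perturb_if_unstable && hss_unstable(model, domain)) {
    theta <- membrane_theta(N)
    eps <- 1e-3 * cos(theta - pi)
    y0[1:N] <- pmax(y0[1:N] + eps, 0)
    y0[(N + 1):(2 * N)] <- pmax(y0[(N + 1):(2 * N)] - eps, 0)
  }
  y0
}

# Linear stability of the uniform state of the discretized ring system,
# judged from the numerical Jacobian of the method-of-lines RHS.
hss_unstable <- function(model, domain, tol = 1e-7) {
  f <- rd_rhs(model, domain, NULL)
  hss <- homogeneous_steady_state(model)
  y0 <- unlist(lapply(model_components(model),
                      function(nm) rep(hss[[nm]], domain$N)))
  J <- numeric_jacobian(function(y) f(0, y), y0)
  ev <- Re(eigen(J, only.values = TRUE)$values)
  # conserved models carry an exact zero mode along the mass direction
  ev <- sort(ev, decreasing = TRUE)
  if (model$conserved) ev <- ev[-which.min(abs(ev))]
  max(ev) > tol
}

# Forward-difference numerical Jacobian.
numeric_jacobian <- function(f, x, eps = 1e-7) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

new_kymograph <- function(times, theta, fields, signal, model, domain,
                          protocol) {
  structure(list(times = times, theta = theta, fields = fields,
                 signal = signal, model = model, domain = domain,
                 protocol = protocol),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph> ", x$model$name, ": ", length(x$times), " time points x ",
      length(x$theta), " bins, t in [", min(x$times), ", ", max(x$times),
      "] s\n", sep = "")
  cat("  components:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a kymograph as a space-time image
#' @param x a `kymograph`.
#' @param component which field to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, component = "u", ...) {
  graphics::image(x$times, x$theta, x$fields[[component]],
                  xlab = "time (s)", ylab = expression(theta),
                  main = paste(x$model$name, component), ...)
  invisible(x)
}

#' Simulate a reaction-diffusion polarity model on the membrane ring
#'
#' Integrates the method-of-lines system with an explicit adaptive
#' Runge-Kutta 4(5) scheme, splitting the integration at the protocol's
#' signal on/off times so epoch boundaries are never stepped across, and
#' reports the solution on a uniform grid.
#'
#' @param model a `model_spec`.
#' @param protocol a [protocol_spec()] or `NULL` (no signal).
#' @param t_end end of the simulation (s).
#' @param domain a [domain_spec()].
#' @param init initial stacked state vector; defaults to the homogeneous
#'   steady state (plus a deterministic odd perturbation when that state is
#'   unstable, as in region IV).
#' @param dt_report reporting interval (s; default 1).
#' @param rtol,atol integration tolerances.
#' @return A `kymograph`: list with `times`, `theta` (bin centers), `fields`
#'   (per-component time-by-bin matrices), `signal` (applied signal history),
#'   `model`, `domain`, `protocol`.
#' @export
simulate_rd <- function(model, protocol = NULL, t_end = 1000,
                        domain = domain_spec(), init = NULL, dt_report = 1,
                        rtol = 1e-8, atol = 1e-10) {
  N <- domain$N
  comps <- model_components(model)
  core <- rd_core(model, domain)
  y0 <- if (is.null(init)) default_initial_state(model, domain) else init
  stopifnot(length(y0) == length(comps) * N)
  breaks <- if (is.null(protocol)) c(0, t_end)
            else protocol_breaks(protocol, t_end)
  times_all <- seq(0, t_end, by = dt_report)
  out <- matrix(NA_real_, length(times_all), length(y0))
  out[1, ] <- y0
  cur <- y0
  fn <- function(t, y, parms) list(core(y, parms))
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    # the signal is piecewise constant in time, so one evaluation per epoch
    s_seg <- if (is.null(protocol)) 0
             else signal_at(protocol, (t0 + t1) / 2, N = N)
    idx <- which(times_all > t0 + 1e-12 & times_all <= t1 + 1e-12)
    seg_times <- unique(c(t0, times_all[idx], t1))
    sol <- deSolve::ode(y = cur, times = seg_times, func = fn, parms = s_seg,
                        method = "ode45", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("simulate_rd: integrator failure in [", t0, ", ", t1, "] s")
    sol_t <- sol[, 1]
    for (i in idx) {
      j <- which.min(abs(sol_t - times_all[i]))
      out[i, ] <- sol[j, -1]
    }
    cur <- sol[nrow(sol), -1]
  }
  fields <- stats::setNames(lapply(seq_along(comps), function(i)
    out[, ((i - 1) * N + 1):(i * N), drop = FALSE]), comps)
  signal <- t(vapply(times_all, function(t)
    if (is.null(protocol)) numeric(N) else signal_at(protocol, t, N = N),
    numeric(N)))
  new_kymograph(times_all, membrane_theta(N), fields, signal, model, domain,
                protocol)
}

#' Simulate the model with additive noise (Euler-Maruyama)
#'
#' Integrates the Ito SDE obtained by adding independent Gaussian white noise
#' of intensity `sigma` to every component and bin of the method-of-lines
#' system, with a fixed step `dt`. Negative concentrations produced by the
#' noise are clipped at zero after each step. With `sigma = 0` the scheme
#' reduces to explicit Euler and reproduces [simulate_rd()] up to the global
#' O(dt) error.
#'
#' @inheritParams simulate_rd
#' @param sigma noise intensity (>= 0).
#' @param dt fixed Euler-Maruyama step (s; default 0.01).
#' @param seed integer seed; identical seeds give bit-identical kymographs.
#' @return A `kymograph`.
#' @export
simulate_rd_sde <- function(model, protocol = NULL, t_end = 1000,
                            sigma = 1e-3, dt = 0.01, seed = 1,
                            domain = domain_spec(), init = NULL,
                            dt_report = 1) {
  if (sigma < 0) stop("simulate_rd_sde: sigma must be nonnegative")
  N <- domain$N
  comps <- model_components(model)
  core <- rd_core(model, domain)
  y <- if (is.null(init)) default_initial_state(model, domain) else init
  nvar <- length(y)
  stopifnot(nvar == length(comps) * N)
  n_steps <- round(t_end / dt)
  report_every <- max(1L, round(dt_report / dt))
  times <- seq(0, by = dt * report_every, length.out = n_steps %/% report_every + 1)
  out <- matrix(NA_real_, length(times), nvar)
  out[1, ] <- y
  sqdt <- sqrt(dt)
  set.seed(as.integer(seed))
  breaks <- if (is.null(protocol)) c(0, t_end)
            else protocol_breaks(protocol, t_end)
  s_segs <- lapply(seq_len(length(breaks) - 1), function(k)
    if (is.null(protocol)) 0
    else signal_at(protocol, (breaks[k] + breaks[k + 1]) / 2, N = N))
  row <- 1L
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    seg <- findInterval(t, breaks, rightmost.closed = TRUE)
    y <- y + dt * core(y, s_segs[[seg]])
    if (sigma > 0) y <- y + sigma * sqdt * stats::rnorm(nvar)
    y[y < 0] <- 0
    if (k %% report_every == 0L) {
      row <- row + 1L
      out[row, ] <- y
    }
  }
  fields <- stats::setNames(lapply(seq_along(comps), function(i)
    out[, ((i - 1) * N + 1):(i * N), drop = FALSE]), comps)
  signal <- t(vapply(times, function(t)
    if (is.null(protocol)) numeric(N) else signal_at(protocol, t, N = N),
    numeric(N)))
  new_kymograph(times, membrane_theta(N), fields, signal, model, domain,
                protocol)
}

#' Spatial mean of u + v over time (mass-conservation check)
#' @param kym a `kymograph` of a conserved model.
#' @return Numeric vector of `mean(u + v)` per reported time.
#' @export
total_mass <- function(kym) {
  stopifnot(kym$model$conserved)
  rowMeans(kym$fields$u + kym$fields$v)
}
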