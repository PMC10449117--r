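#' Two-bin (left/right) projection of the membrane
#'
#' The one-dimensional projection collapses the membrane to a left and right
#' bin that exchange material at diffusion-like rates `Du_tilde` (slow,
#' membrane species) and `Dv_tilde` (fast, cytosolic species):
#' \deqn{\dot u_L = G_1 = f_u(u_L, v_L) - \tilde D_u (u_L - u_R) + s_L v_L}
#' \deqn{\dot v_L = G_2 = f_v(u_L, v_L) - \tilde D_v (v_L - v_R) - s_L v_L}
#' and symmetrically for the right bin (\eqn{G_3, G_4}). For conserved
#' kinetics \eqn{u_L + v_L + u_R + v_R = 2 c_{total}} is invariant.
#'
#' @param state numeric vector `c(uL, vL, uR, vR)`.
#' @param model a conserved `model_spec` (wave-pinning/SubPB or Turing).
#' @param sL,sR step signal amplitudes in the left/right bin.
#' @param Du_tilde,Dv_tilde exchange rates (1/s); defaults 0.01 and 10.
#' @return Named derivative vector `c(uL, vL, uR, vR)`.
#' @export
two_bin_rhs <- function(state, model, sL = 0, sR = 0,
                        Du_tilde = 0.01, Dv_tilde = 10) {
  stopifnot(model$conserved, Du_tilde >= 0, Dv_tilde >= 0)
  uL <- state[1]; vL <- state[2]; uR <- state[3]; vR <- state[4]
  fuL <- conserved_fu(model, uL, vL)
  fuR <- conserved_fu(model, uR, vR)
  c(uL = fuL - Du_tilde * (uL - uR) + sL * vL,
    vL = -fuL - Dv_tilde * (vL - vR) - sL * vL,
    uR = fuR - Du_tilde * (uR - uL) + sR * vR,
    vR = -fuR - Dv_tilde * (vR - vL) - sR * vR)
}

#' Two-bin quasi-steady-state reduction of the LEGI model
#'
#' The fast activator and inhibitor are eliminated by their quasi-steady
#' states under step signals `(sL, sR)`:
#' \deqn{v^{qss} = 0.5\, (k_v / k_{-v}) (s_L + s_R)}
#' \deqn{w_L^{qss} = \frac{k_w}{2 \tilde D_w + k_{-w}}
#'       \left(s_L + \frac{\tilde D_w (s_L + s_R)}{k_{-w}}\right), \qquad
#'       w_R^{qss} = \frac{k_w}{k_{-w}} (s_L + s_R) - w_L^{qss},}
#' which leaves a two-variable system for `(uL, uR)`.
#'
#' @param u numeric vector `c(uL, uR)`.
#' @param params a [legi_params()] object.
#' @param sL,sR step signal amplitudes.
#' @param Du_tilde exchange rate of `u` (1/s).
#' @param Dw_tilde exchange rate of `w` (1/s); like `u`, `w` is a slow
#'   membrane species, so it defaults to `Du_tilde`.
#' @return List with derivative vector `du = c(uL, uR)` and the closures
#'   `v_qss`, `wL_qss`, `wR_qss`.
#' @export
legi_two_bin_rhs <- function(u, params, sL = 0, sR = 0,
                             Du_tilde = 0.01, Dw_tilde = Du_tilde) {
  stopifnot(inherits(params, "legi_params"))
  p <- params
  if (p$k_minus_v <= 0 || p$k_minus_w <= 0)
    stop("legi_two_bin_rhs: decay rates must be positive")
  v_qss <- 0.5 * p$kv / p$k_minus_v * (sL + sR)
  wL_qss <- p$kw / (2 * Dw_tilde + p$k_minus_w) *
    (sL + Dw_tilde * (sL + sR) / p$k_minus_w)
  wR_qss <- p$kw / p$k_minus_w * (sL + sR) - wL_qss
  uL <- u[1]; uR <- u[2]
  du <- c(
    uL = p$ku * wL_qss * (p$u_total - uL) - p$k_minus_u * v_qss * uL -
      Du_tilde * (uL - uR),
    uR = p$ku * wR_qss * (p$u_total - uR) - p$k_minus_u * v_qss * uR -
      Du_tilde * (uR - uL))
  list(du = du, v_qss = v_qss, wL_qss = wL_qss, wR_qss = wR_qss)
}

#' Simulate the two-bin projection under a stepped signal protocol
#'
#' Integrates the projection through a sequence of `(sL, sR, duration)`
#' epochs, annotating each sample with its epoch so trajectories can be
#' overlaid on per-epoch phase portraits and landscapes.
#'
#' @param model a conserved `model_spec` or, for LEGI, a `model_spec` with
#'   `name = "legi"` (integrated through its quasi-steady-state reduction).
#' @param protocol a [step_protocol()] (kind `step_two_bin`).
#' @param init initial state `c(uL, vL, uR, vR)` (or `c(uL, uR)` for LEGI);
#'   defaults to the homogeneous steady state at zero signal.
#' @param Du_tilde,Dv_tilde,Dw_tilde exchange rates (1/s).
#' @param dt_report reporting interval (s).
#' @param rtol,atol integration tolerances.
#' @return An object of class `two_bin_trajectory`: data frame with columns
#'   `time`, `uL`, `uR` (plus `vL`, `vR` for conserved models), `sL`, `sR`,
#'   `epoch`, and attributes `model`, `exchange`.
#' @export
simulate_projection <- function(model, protocol, init = NULL,
                                Du_tilde = 0.01, Dv_tilde = 10,
                                Dw_tilde = Du_tilde, dt_report = 0.5,
                                rtol = 1e-10, atol = 1e-12) {
  stopifnot(protocol$kind == "step_two_bin")
  steps <- protocol$steps
  legi <- !model$conserved
  if (is.null(init)) {
    hss <- homogeneous_steady_state(model)
    init <- if (legi) c(hss$u, hss$u) else c(hss$u, hss$v, hss$u, hss$v)
  }
  fn <- if (legi) {
    function(t, y, parms)
      list(legi_two_bin_rhs(y, model$params, parms$sL, parms$sR,
                            Du_tilde, Dw_tilde)$du)
  } else {
    function(t, y, parms)
      list(two_bin_rhs(y, model, parms$sL, parms$sR, Du_tilde, Dv_tilde))
  }
  rows <- list()
  cur <- init
  t0 <- 0
  for (k in seq_len(nrow(steps))) {
    t1 <- t0 + steps$duration[k]
    times <- unique(c(seq(t0, t1, by = dt_report), t1))
    sol <- deSolve::ode(y = cur, times = times, func = fn,
                        parms = list(sL = steps$sL[k], sR = steps$sR[k]),
                        method = "ode45", rtol = rtol, atol = atol)
    df <- as.data.frame(sol)
    names(df) <- if (legi) c("time", "uL", "uR")
                 else c("time", "uL", "vL", "uR", "vR")
    df$sL <- steps$sL[k]; df$sR <- steps$sR[k]; df$epoch <- k
    # drop the duplicated epoch-boundary sample except in the first epoch
    if (k > 1) df <- df[-1, ]
    rows[[k]] <- df
    cur <- unname(sol[nrow(sol), -1])
    t0 <- t1
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("two_bin_trajectory", "data.frame"),
            model = model,
            exchange = c(Du_tilde = Du_tilde, Dv_tilde = Dv_tilde,
                         Dw_tilde = Dw_tilde))
}

#' Steady states of the two-bin projection by multi-start root search
#'
#' Finds the fixed points of the projection at fixed signal by Newton
#' iteration from a deterministic lattice of starting points (symmetric and
#' asymmetric), de-duplicates the converged roots, and reports the stability
#' of each from the Jacobian spectrum. For conserved models the search is
#' performed on the conservation manifold (reduced coordinates
#' `(uL, vL, uR)` with `vR` eliminated), so the spurious zero eigenvalue
#' along the mass direction never enters the stability call.
#'
#' @param model a conserved `model_spec` or LEGI spec.
#' @param sL,sR signal amplitudes.
#' @param Du_tilde,Dv_tilde,Dw_tilde exchange rates.
#' @param c_total override of the conserved total (defaults to the model
#'   parameter).
#' @param n_starts number of lattice starts per coordinate.
#' @return Data frame with columns `uL`, `vL`, `uR`, `vR` (conserved) or
#'   `uL`, `uR` (LEGI), `lambda` (leading eigenvalue real part), `stable`,
#'   `symmetric`.
#' @export
two_bin_fixed_points <- function(model, sL = 0, sR = 0, Du_tilde = 0.01,
                                 Dv_tilde = 10, Dw_tilde = Du_tilde,
                                 c_total = NULL, n_starts = 7) {
  legi <- !model$conserved
  if (legi) {
    f <- function(x) legi_two_bin_rhs(x, model$params, sL, sR,
                                      Du_tilde, Dw_tilde)$du
    ut <- model$params$u_total
    grid <- seq(0, ut, length.out = n_starts)
    starts <- as.matrix(expand.grid(uL = grid, uR = grid))
  } else {
    ct <- if (is.null(c_total)) model$params$c_total else c_total
    f <- function(x) {
      full <- c(x[1], x[2], x[3], 2 * ct - sum(x))
      two_bin_rhs(full, model, sL, sR, Du_tilde, Dv_tilde)[1:3]
    }
    grid <- seq(0.02, ct, length.out = n_starts)
    vfrac <- c(0.25, 0.6, 0.9)
    starts <- as.matrix(expand.grid(uL = grid, vL = 0, uR = grid))
    starts <- do.call(rbind, lapply(vfrac, function(fr) {
      s <- starts
      s[, 2] <- pmax(2 * ct - (s[, 1] + s[, 3]), 0) * fr / 2
      s
    }))
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(f, starts[i, ], tol = 1e-11, maxit = 60)
    if (is.null(r) || any(!is.finite(r)) || any(r < -1e-8)) next
    if (max(abs(f(r))) > 1e-8) next
    dup <- any(vapply(roots, function(x) max(abs(x - r)) < 1e-6, TRUE))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (length(roots) == 0)
    return(data.frame())
  res <- do.call(rbind, lapply(roots, function(r) {
    J <- numeric_jacobian(f, r)
    lam <- max(Re(eigen(J, only.values = TRUE)$values))
    if (legi) {
      data.frame(uL = r[1], uR = r[2], lambda = lam, stable = lam < 0,
                 symmetric = abs(r[1] - r[2]) < 1e-6)
    } else {
      ct <- if (is.null(c_total)) model$params$c_total else c_total
      data.frame(uL = r[1], vL = r[2], uR = r[3], vR = 2 * ct - sum(r),
                 lambda = lam, stable = lam < 0,
                 symmetric = abs(r[1] - r[3]) < 1e-6)
    }
  }))
  res[order(res$uL), , drop = FALSE]
}

# Damped Newton iteration with numerical Jacobian; returns NULL on failure.
newton_root <- function(f, x0, tol = 1e-11, maxit = 60) {
  x <- as.numeric(x0)
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (any(!is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- numeric_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx)) || lam < 1e-4)
        break
      lam <- lam / 2
    }
    x <- xn
  }
  if (max(abs(f(x))) < 1e2 * tol) x else NULL
}
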