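#' Two-dimensional drift field of the projected system
#'
#' The quasi-potential landscape lives in the `(uL, uR)` plane. For the
#' mass-conserved mechanisms the cytosolic component is homogenized by its
#' fast exchange and eliminated by conservation,
#' `v_bar = c_total - (uL + uR)/2`, so the left/right reaction-exchange
#' terms become functions of `(uL, uR)` alone. For LEGI the
#' [legi_two_bin_rhs()] reduction is already two-dimensional.
#'
#' @param model a `model_spec`.
#' @param sL,sR step signal amplitudes.
#' @param Du_tilde,Dw_tilde exchange rates (1/s).
#' @return Function `(uL, uR) -> cbind(duL, duR)`, vectorized.
#' @export
two_bin_drift <- function(model, sL = 0, sR = 0, Du_tilde = 0.01,
                          Dw_tilde = Du_tilde) {
  if (model$conserved) {
    ct <- model$params$c_total
    function(uL, uR) {
      vbar <- ct - (uL + uR) / 2
      cbind(conserved_fu(model, uL, vbar) - Du_tilde * (uL - uR) + sL * vbar,
            conserved_fu(model, uR, vbar) - Du_tilde * (uR - uL) + sR * vbar)
    }
  } else {
    p <- model$params
    v_qss <- 0.5 * p$kv / p$k_minus_v * (sL + sR)
    wL <- p$kw / (2 * Dw_tilde + p$k_minus_w) *
      (sL + Dw_tilde * (sL + sR) / p$k_minus_w)
    wR <- p$kw / p$k_minus_w * (sL + sR) - wL
    function(uL, uR) {
      cbind(p$ku * wL * (p$u_total - uL) - p$k_minus_u * v_qss * uL -
              Du_tilde * (uL - uR),
            p$ku * wR * (p$u_total - uR) - p$k_minus_u * v_qss * uR -
              Du_tilde * (uR - uL))
    }
  }
}

#' Stationary solution of the two-dimensional Fokker-Planck equation
#'
#' Solves \deqn{0 = -\partial_x (G_1 P) - \partial_y (G_3 P) +
#' D (\partial_x^2 + \partial_y^2) P} on a rectangle with reflecting
#' (zero-flux) boundaries. The spatial discretization is a conservative
#' finite-volume scheme with exponential-fitting (Scharfetter-Gummel) face
#' fluxes, which keeps the discrete operator a generator (columns sum to
#' zero, off-diagonal rates nonnegative) and is exact for linear drift; the
#' stationary density is obtained directly from the sparse linear system
#' with a normalization row, i.e. the exact t -> infinity limit of the
#' discrete dynamics rather than a truncated pseudo-time integration.
#'
#' @param drift function `(x, y) -> cbind(dx, dy)` (e.g. [two_bin_drift()]).
#' @param D diffusion constant of the stochastic transitions (default 0.02).
#' @param xlim,ylim grid extent.
#' @param h grid spacing (default 0.02).
#' @param boundary_tol maximal admissible probability mass in the boundary
#'   cells; more mass than this raises a grid-extent error. Set it to `Inf`
#'   when the reflecting walls are the physical boundary of the state space
#'   (e.g. the LEGI box) rather than a numerical truncation.
#' @return List with `x`, `y` (cell centers), `P` (matrix `length(x)` by
#'   `length(y)`, normalized so `sum(P) * h^2 = 1`), `h`, `D`.
#' @export
solve_fokker_planck <- function(drift, D = 0.02, xlim, ylim = xlim, h = 0.02,
                                boundary_tol = 1e-6) {
  x <- seq(xlim[1] + h / 2, xlim[2] - h / 2, by = h)
  y <- seq(ylim[1] + h / 2, ylim[2] - h / 2, by = h)
  nx <- length(x); ny <- length(y)
  if (nx < 5 || ny < 5) stop("solve_fokker_planck: grid too small")
  n <- nx * ny
  idx <- function(i, j) i + (j - 1L) * nx
  gx <- rep(x, ny); gy <- rep(y, each = nx)
  v <- drift(gx, gy)
  # Bernoulli function B(w) = w/(exp(w)-1), stable near 0
  Bfun <- function(w) ifelse(abs(w) < 1e-8, 1 - w / 2, w / expm1(w))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(kL, kR, vface) {
    w <- vface * h / D
    a_LR <- D / h^2 * Bfun(-w)   # rate L -> R
    a_RL <- D / h^2 * Bfun(w)    # rate R -> L
    ii <<- c(ii, kR, kL, kL, kR)
    jj <<- c(jj, kL, kL, kR, kR)
    xx <<- c(xx, a_LR, -a_LR, a_RL, -a_RL)
  }
  # horizontal faces
  iL <- rep(1:(nx - 1), ny); jL <- rep(1:ny, each = nx - 1)
  kL <- idx(iL, jL); kR <- idx(iL + 1L, jL)
  add_faces(kL, kR, (v[kL, 1] + v[kR, 1]) / 2)
  # vertical faces
  iB <- rep(1:nx, ny - 1); jB <- rep(1:(ny - 1), each = nx)
  kB <- idx(iB, jB); kT <- idx(iB, jB + 1L)
  add_faces(kB, kT, (v[kB, 2] + v[kT, 2]) / 2)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # normalization row replaces the equation of the cell with the slowest
  # drift (a point near an attractor, where the density is well supported)
  k0 <- which.min(rowSums(v^2))
  M <- A
  M[k0, ] <- 1
  b <- numeric(n); b[k0] <- 1
  P <- as.numeric(Matrix::solve(M, b))
  P[P < 0] <- 0
  P <- P / (sum(P) * h^2)
  Pm <- matrix(P, nx, ny)
  bmass <- (sum(Pm[c(1, nx), ]) + sum(Pm[, c(1, ny)]) -
              sum(Pm[c(1, nx), c(1, ny)])) * h^2
  if (bmass > boundary_tol)
    stop(sprintf(
      "solve_fokker_planck: boundary probability %.3g exceeds %.3g; enlarge the grid",
      bmass, boundary_tol))
  list(x = x, y = y, P = Pm, h = h, D = D)
}

#' Quasi-potential from a stationary density
#'
#' `Q = -log(pmax(P, floor))`: minima of `Q` are the maxima of `P_ss`; cells
#' below the probability floor all map to the same ceiling value.
#'
#' @param P stationary density matrix (normalized).
#' @param floor probability floor applied before the logarithm.
#' @return Matrix `Q` of the same shape.
#' @export
quasi_potential <- function(P, floor = 1e-12) {
  -log(pmax(P, floor))
}

# centered first/second differences with one-sided stencils at the edges
fd_x <- function(M, h) {
  n <- nrow(M)
  out <- (M[c(2:n, n), ] - M[c(1, 1:(n - 1)), ]) / (2 * h)
  out[1, ] <- (M[2, ] - M[1, ]) / h
  out[n, ] <- (M[n, ] - M[n - 1, ]) / h
  out
}
fd_y <- function(M, h) t(fd_x(t(M), h))
fd_xx <- function(M, h) {
  n <- nrow(M)
  out <- (M[c(2:n, n), ] - 2 * M + M[c(1, 1:(n - 1)), ]) / h^2
  out[1, ] <- out[2, ]
  out[n, ] <- out[n - 1, ]
  out
}
fd_yy <- function(M, h) t(fd_xx(t(M), h))

#' Gaussian curvature of a quasi-potential surface
#'
#' \deqn{K = \frac{Q_{xx} Q_{yy} - Q_{xy}^2}{(1 + Q_x^2 + Q_y^2)^2}}
#' with centered finite differences in the interior and one-sided stencils
#' at the edges.
#'
#' @param Q potential matrix on a uniform grid.
#' @param h grid spacing.
#' @return List with `K`, `Qx`, `Qy`, `Qxx`, `Qyy`, `Qxy`.
#' @export
gaussian_curvature <- function(Q, h) {
  if (nrow(Q) < 5 || ncol(Q) < 5)
    stop("gaussian_curvature: grid must be at least 5x5")
  Qx <- fd_x(Q, h); Qy <- fd_y(Q, h)
  Qxx <- fd_xx(Q, h); Qyy <- fd_yy(Q, h)
  Qxy <- fd_y(Qx, h)
  K <- (Qxx * Qyy - Qxy^2) / (1 + Qx^2 + Qy^2)^2
  list(K = K, Qx = Qx, Qy = Qy, Qxx = Qxx, Qyy = Qyy, Qxy = Qxy)
}

#' Quasi-potential surface of a projected model
#'
#' Convenience wrapper: solves the stationary Fokker-Planck equation for the
#' model's two-bin drift, takes `Q = -ln(P_ss)`, and attaches the curvature
#' and slope fields.
#'
#' @param model a `model_spec`.
#' @param sL,sR step signal amplitudes.
#' @param D,h Fokker-Planck diffusion and grid spacing.
#' @param xlim grid extent. For conserved models the default is
#'   `[-0.4, 2*c_total]`: the lower pad sits outside the physical cone, where
#'   the production term pushes the density back in and it decays within a
#'   few grid cells, so the truncation boundaries carry negligible mass. For
#'   LEGI the default is the physical box `[0, u_total]` (padded above), and
#'   its reflecting walls are real, so the boundary-mass check is disabled.
#' @param floor probability floor for the potential.
#' @param Du_tilde exchange rate.
#' @return Object of class `quasi_potential_surface`: list with the grid,
#'   `P`, `Q`, curvature/slope fields, and the generating context.
#' @export
quasi_potential_surface <- function(model, sL = 0, sR = 0, D = 0.02,
                                    h = 0.02, xlim = NULL, floor = 1e-12,
                                    Du_tilde = 0.01) {
  boundary_tol <- 1e-6
  if (is.null(xlim)) {
    if (model$conserved) {
      # the density below u = 0 is an exponentially decaying tail of the
      # closure (production pushes back in); its residual boundary mass is
      # physically immaterial, so the truncation check is applied loosely
      xlim <- c(-0.5, 2 * model$params$c_total)
      boundary_tol <- 1e-4
    } else {
      xlim <- c(0, 1.25 * model$params$u_total)
      boundary_tol <- Inf
    }
  }
  drift <- two_bin_drift(model, sL = sL, sR = sR, Du_tilde = Du_tilde)
  fp <- solve_fokker_planck(drift, D = D, xlim = xlim, h = h,
                            boundary_tol = boundary_tol)
  Q <- quasi_potential(fp$P, floor = floor)
  cv <- gaussian_curvature(Q, h)
  structure(c(fp, list(Q = Q), cv,
              list(model = model, sL = sL, sR = sR, floor = floor)),
            class = "quasi_potential_surface")
}

#' @export
print.quasi_potential_surface <- function(x, ...) {
  cat("<quasi_potential_surface> ", length(x$x), "x", length(x$y),
      " grid, h = ", x$h, ", D = ", x$D, "\n", sep = "")
  invisible(x)
}

#' Plot a quasi-potential surface as a filled contour map
#' @param x a `quasi_potential_surface`.
#' @param q_cap clip the potential at this value for display.
#' @param ... passed to [graphics::image()].
#' @export
plot.quasi_potential_surface <- function(x, q_cap = NULL, ...) {
  Q <- x$Q
  if (!is.null(q_cap)) Q[Q > q_cap] <- q_cap
  graphics::image(x$x, x$y, Q, xlab = expression(u[L]),
                  ylab = expression(u[R]), col = grDevices::hcl.colors(64),
                  ...)
  graphics::contour(x$x, x$y, Q, add = TRUE, nlevels = 12,
                    col = "grey30", drawlabels = FALSE)
  invisible(x)
}

# 4-neighbour connected components of a logical matrix by iterative minimum-
# label propagation; returns an integer matrix (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  n <- nrow(lab); m <- ncol(lab)
  repeat {
    old <- lab
    shift <- function(M, di, dj) {
      out <- matrix(Inf, n, m)
      ri <- max(1, 1 + di):min(n, n + di)
      rj <- max(1, 1 + dj):min(m, m + dj)
      out[ri, rj] <- M[ri - di, rj - dj]
      out
    }
    Lp <- lab
    Lp[!mask] <- Inf
    cand <- pmin(shift(Lp, 1, 0), shift(Lp, -1, 0),
                 shift(Lp, 0, 1), shift(Lp, 0, -1), Lp)
    upd <- mask & is.finite(cand) & cand < lab
    lab[upd] <- cand[upd]
    if (identical(lab, old)) break
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, c(0L, u)) - 1L
  lab
}

#' Identify asymptotic (well) regions of a quasi-potential surface
#'
#' Thresholds the Gaussian curvature at `K_mean + k_sigma * K_sd` (the
#' statistics taken over the support of the stationary density, not the
#' floored plateau), splits the supra-threshold cells into connected
#' components, and classifies each component as a WELL if its slopes are
#' distributed around zero in both directions. The operational form of that
#' criterion is a sign change of the slope fields around an interior
#' critical point, i.e. the component contains an interior local minimum of
#' `Q`; a positive-curvature component whose slopes are one-sided (no
#' interior minimum — e.g. the shallow "ghost" shoulder left behind by a
#' departed saddle-node) is flagged `well = FALSE`. The mean slopes and
#' their comparison against `slope_tol_factor * sd(slope)` are reported as
#' diagnostics (`slope_ok`): basins truncated by the curvature threshold
#' against a state-space wall can carry a biased mean slope even around a
#' genuine minimum, which is why the sign-change form is the classifier.
#' `Q_bound` of a well is the mean potential on the component's boundary
#' cells; trajectories below it are asymptotically bound to the well.
#'
#' @param surface a [quasi_potential_surface()].
#' @param k_sigma curvature threshold multiplier (default 0.1).
#' @param slope_tol_factor zero-slope tolerance (fraction of the support
#'   slope standard deviation) used for the diagnostic `slope_ok` column.
#' @param min_size components smaller than this many cells are dropped
#'   (isolated cliff debris).
#' @return List with `labels` (component matrix), and `components`: data
#'   frame with `id`, `well`, `slope_ok`, `Q_bound`, `Q_min`, `size`, mean
#'   slopes. Components with `well = FALSE` are positive-curvature
#'   shoulders (e.g. the "ghost" area).
#' @export
asymptotic_regions <- function(surface, k_sigma = 0.1,
                               slope_tol_factor = 0.05, min_size = 5) {
  K <- surface$K
  # statistics on the floored plateau (and its cliff) are meaningless; the
  # curvature criterion applies on the support of the stationary density
  support <- if (!is.null(surface$P) && !is.null(surface$floor))
    surface$P > surface$floor else matrix(TRUE, nrow(K), ncol(K))
  thr <- mean(K[support]) + k_sigma * stats::sd(K[support])
  mask <- support & K > thr
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0) {
    warning("asymptotic_regions: no positive-curvature component found")
    return(list(labels = lab,
                components = data.frame()))
  }
  tol_x <- slope_tol_factor * stats::sd(surface$Qx[support])
  tol_y <- slope_tol_factor * stats::sd(surface$Qy[support])
  n <- nrow(lab); m <- ncol(lab)
  Q <- surface$Q
  keep <- which(tabulate(lab[lab > 0], ncomp) >= min_size)
  comps <- do.call(rbind, lapply(keep, function(id) {
    inside <- lab == id
    mx <- mean(surface$Qx[inside])
    my <- mean(surface$Qy[inside])
    slope_ok <- abs(mx) < tol_x && abs(my) < tol_y
    # interior local minimum of Q => slopes change sign in both directions
    w <- which(inside, arr.ind = TRUE)
    hasmin <- FALSE
    for (r in seq_len(nrow(w))) {
      i <- w[r, 1]; j <- w[r, 2]
      if (i > 1 && i < n && j > 1 && j < m &&
          Q[i, j] <= Q[i - 1, j] && Q[i, j] <= Q[i + 1, j] &&
          Q[i, j] <= Q[i, j - 1] && Q[i, j] <= Q[i, j + 1]) {
        hasmin <- TRUE
        break
      }
    }
    # boundary: component cells adjacent to a non-component cell
    pad <- function(M, di, dj) {
      out <- matrix(FALSE, n, m)
      ri <- max(1, 1 + di):min(n, n + di)
      rj <- max(1, 1 + dj):min(m, m + dj)
      out[ri, rj] <- M[ri - di, rj - dj]
      out
    }
    interior <- inside & pad(inside, 1, 0) & pad(inside, -1, 0) &
      pad(inside, 0, 1) & pad(inside, 0, -1)
    boundary <- inside & !interior
    data.frame(id = id, well = hasmin, slope_ok = slope_ok,
               Q_bound = mean(surface$Q[boundary]),
               Q_min = min(surface$Q[inside]),
               size = sum(inside), mean_slope_x = mx, mean_slope_y = my)
  }))
  if (is.null(comps)) comps <- data.frame()
  # drop labels of discarded debris components
  lab[!(lab %in% keep)] <- 0L
  list(labels = lab, components = comps)
}

#' Classify trajectory samples as asymptotic or transient
#'
#' Each sample of a two-bin trajectory is looked up on the quasi-potential
#' surface of its signal epoch: it is `asymptotic` when it lies inside a
#' well component with potential below that well's `Q_bound`, otherwise
#' `transient`. The ghost dwell is the longest contiguous transient span
#' after the final signal-off during which the phase-space speed stays below
#' `v_slow_frac` times the maximal speed of the post-signal span — the slow
#' passage near the departed attractor. (The maximum, set by the fast
#' transit away from the lost state, is the robust reference: a median or
#' mean over the epoch is dominated by the near-zero speeds of the eventual
#' resting state and would declare nothing slow.)
#'
#' @param traj a [simulate_projection()] trajectory.
#' @param surfaces a single [quasi_potential_surface()] or a list, one per
#'   epoch of the trajectory.
#' @param regions optional precomputed [asymptotic_regions()] per surface.
#' @param v_slow_frac slow-speed fraction for the ghost criterion.
#' @return List with `label` (character per sample), `ghost_dwell` (s),
#'   `dwell` (seconds per label), and `speed`.
#' @export
classify_trajectory <- function(traj, surfaces, regions = NULL,
                                v_slow_frac = 0.1) {
  epochs <- sort(unique(traj$epoch))
  if (inherits(surfaces, "quasi_potential_surface"))
    surfaces <- stats::setNames(rep(list(surfaces), length(epochs)), epochs)
  if (is.null(regions)) regions <- lapply(surfaces, asymptotic_regions)
  label <- character(nrow(traj))
  for (k in seq_along(epochs)) {
    e <- epochs[k]
    srf <- surfaces[[k]]
    reg <- regions[[k]]
    rows <- which(traj$epoch == e)
    ix <- findInterval(traj$uL[rows], srf$x - srf$h / 2,
                       rightmost.closed = TRUE)
    iy <- findInterval(traj$uR[rows], srf$y - srf$h / 2,
                       rightmost.closed = TRUE)
    if (any(ix < 1 | ix > length(srf$x) | iy < 1 | iy > length(srf$y)))
      stop("classify_trajectory: trajectory leaves the surface grid")
    comp_id <- reg$labels[cbind(ix, iy)]
    qval <- srf$Q[cbind(ix, iy)]
    lab_k <- rep("transient", length(rows))
    wells <- reg$components[reg$components$well, , drop = FALSE]
    if (nrow(wells) > 0) {
      inwell <- comp_id %in% wells$id
      qb <- wells$Q_bound[match(comp_id, wells$id)]
      lab_k[inwell & qval <= qb] <- "asymptotic"
    }
    label[rows] <- lab_k
  }
  dt <- c(diff(traj$time), 0)
  speed <- c(sqrt(diff(traj$uL)^2 + diff(traj$uR)^2), 0) /
    pmax(c(diff(traj$time), Inf), 1e-12)
  # ghost dwell: after final signal-off
  off_rows <- which(traj$sL == 0 & traj$sR == 0)
  ghost <- 0
  last_on <- which(traj$sL > 0 | traj$sR > 0)
  if (length(last_on) > 0) {
    post <- off_rows[off_rows > max(last_on)]
    if (length(post) > 1) {
      v_slow <- v_slow_frac * max(speed[post])
      slow_transient <- label[post] == "transient" & speed[post] <= v_slow
      r <- rle(slow_transient)
      if (any(r$values)) {
        runs <- which(r$values)
        ends <- cumsum(r$lengths)
        durs <- vapply(runs, function(j) {
          i1 <- ends[j] - r$lengths[j] + 1
          traj$time[post[ends[j]]] - traj$time[post[i1]]
        }, 0)
        ghost <- max(durs)
      }
    }
  }
  list(label = label,
       ghost_dwell = ghost,
       dwell = tapply(dt, label, sum),
       speed = speed)
}

#' Euler-Maruyama simulation of the projected two-dimensional system
#'
#' Integrates `d(uL,uR) = drift dt + sqrt(2 D) dW` for the `(uL, uR)`
#' closure used by the landscapes; the long-run histogram of this process is
#' the sampling counterpart of the stationary Fokker-Planck density.
#'
#' @param model a `model_spec`.
#' @param sL,sR step signal amplitudes.
#' @param D noise diffusion constant (matches the Fokker-Planck `D`).
#' @param dt step (s).
#' @param n_steps number of steps.
#' @param init initial `c(uL, uR)`; defaults to the homogeneous state.
#' @param seed integer seed.
#' @param Du_tilde exchange rate.
#' @param clip clip negative excursions at zero (physical concentrations).
#'   Disable when comparing against a Fokker-Planck solution on a grid that
#'   extends below zero, so both formulations see the same state space.
#' @return Matrix `n_steps + 1` by 2 of `(uL, uR)` samples.
#' @export
simulate_projection_sde <- function(model, sL = 0, sR = 0, D = 0.02,
                                    dt = 0.01, n_steps = 1e5, init = NULL,
                                    seed = 1, Du_tilde = 0.01, clip = TRUE) {
  drift <- two_bin_drift(model, sL = sL, sR = sR, Du_tilde = Du_tilde)
  if (is.null(init)) {
    h <- homogeneous_steady_state(model)
    init <- c(h$u, h$u)
  }
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- init
  z <- init
  amp <- sqrt(2 * D * dt)
  noise <- matrix(stats::rnorm(2 * n_steps), n_steps, 2)
  for (k in seq_len(n_steps)) {
    z <- z + dt * drift(z[1], z[2])[1, ] + amp * noise[k, ]
    if (clip) z[z < 0] <- 0
    out[k + 1, ] <- z
  }
  colnames(out) <- c("uL", "uR")
  out
}
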