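#' Local perturbation analysis (LPA) reduction
#'
#' Reduces a reaction-diffusion model with a strong slow/fast diffusivity
#' separation (`Dv >= 10 Du` asserted) to a local/global ODE system whose
#' bifurcations diagnose the regimes of the PDE. For the mass-conserved
#' mechanisms the reduction is two equations,
#' \deqn{\dot u_{local} = f_u(u_{local},\, c_{total} - u_{global}), \qquad
#'       \dot u_{global} = f_u(u_{global},\, c_{total} - u_{global}),}
#' where the global equation is exactly the well-mixed model. For LEGI it is
#' the five-equation system in (w_local, w_global, v_global, u_local,
#' u_global), again with the global subsystem equal to the well-mixed model.
#'
#' @param model a `model_spec`.
#' @return List with `vars` (state names), `rhs(y, par, s)` where `par` is
#'   the continued parameter (`c_total` for conserved models, a named kinetic
#'   rate for LEGI, see `par_name`), `par_name`, and `par_default`.
#' @export
lpa_reduce <- function(model) {
  D <- model_diffusivities(model)
  if (D[["v"]] < 10 * D[["u"]])
    stop("lpa_reduce: needs slow/fast separation (Dv >= 10 Du)")
  if (model$conserved) {
    list(
      vars = c("u_local", "u_global"),
      par_name = "c_total",
      par_default = model$params$c_total,
      rhs = function(y, par, s = 0) {
        vg <- par - y[2]
        c(conserved_fu(model, y[1], vg) + s * vg,
          conserved_fu(model, y[2], vg) + s * vg)
      })
  } else {
    p <- model$params
    list(
      vars = c("w_local", "w_global", "v_global", "u_local", "u_global"),
      par_name = "ku",
      par_default = p$ku,
      rhs = function(y, par, s = 0) {
        ku <- par
        c(-p$k_minus_w * y[1] + p$kw * s,
          -p$k_minus_w * y[2] + p$kw * s,
          -p$k_minus_v * y[3] + p$kv * s,
          ku * y[1] * (p$u_total - y[4]) - p$k_minus_u * y[3] * y[4],
          ku * y[2] * (p$u_total - y[5]) - p$k_minus_u * y[3] * y[5])
      })
  }
}

#' Pseudo-arclength continuation of a steady-state branch
#'
#' Traces solutions of `f(x, p) = 0` from a converged starting point with a
#' secant predictor and a Newton corrector on the arclength-augmented system,
#' halving the step on corrector failure and growing it on easy convergence.
#' At every accepted point the leading eigenvalue of the state Jacobian is
#' recorded; special points are flagged in a post-pass:
#' \itemize{
#'   \item a fold (sign change of `dp` along the arc) coinciding with a real
#'     eigenvalue crossing is a saddle-node (`SN`, or `SN_PB` when it folds
#'     an asymmetric branch of a symmetric system);
#'   \item an eigenvalue crossing without a fold on a symmetry-respecting
#'     branch is a pitchfork (`PB`), classified by its symmetry-breaking null
#'     eigenvector;
#'   \item an eigenvalue crossing without a fold on a branch without such a
#'     symmetry is a transcritical point (`TC`).
#' }
#'
#' @param f function `f(x, p)` returning the steady-state residual.
#' @param x0 starting state (will be refined by Newton at `p0`).
#' @param p0 starting parameter value (normally one end of `p_range`).
#' @param p_range numeric length-2; continuation stops outside it.
#' @param direction initial direction of the parameter, `+1` or `-1`.
#' @param ds,ds_min,ds_max initial/minimal/maximal arclength step.
#' @param max_steps cap on accepted points.
#' @param symmetry optional predicate `symmetry(x)` returning `TRUE` on the
#'   symmetric subspace; used to tell PB from TC and SN from SN_PB.
#' @param drop_eigen number of near-zero structural eigenvalues to ignore
#'   (e.g. a conservation mode); default 0.
#' @return A data frame (class `continuation_branch`) with columns `p`, the
#'   state components `x1..xn`, `lambda` (leading eigenvalue real part),
#'   `stable`, `symmetric`; attribute `special_points` is a data frame with
#'   columns `type`, `p`, and the state at the flagged point.
#' @export
continue_branch <- function(f, x0, p0, p_range, direction = 1, ds = 2e-3,
                            ds_min = 1e-6, ds_max = 2e-2, max_steps = 4000,
                            symmetry = NULL, drop_eigen = 0) {
  x <- newton_root(function(z) f(z, p0), x0)
  if (is.null(x)) stop("continue_branch: no converged steady state at range start")
  n <- length(x)
  lead_eig <- function(x, p) {
    J <- numeric_jacobian(function(z) f(z, p), x)
    ev <- sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
    if (drop_eigen > 0) {
      o <- order(abs(ev))
      ev <- ev[-o[seq_len(drop_eigen)]]
    }
    max(ev)
  }
  pts_p <- numeric(0); pts_x <- NULL; pts_l <- numeric(0)
  push <- function(x, p) {
    pts_p[length(pts_p) + 1] <<- p
    pts_x <<- rbind(pts_x, x)
    pts_l[length(pts_l) + 1] <<- lead_eig(x, p)
  }
  push(x, p0)
  # initial tangent from the natural parameterization
  Jx <- numeric_jacobian(function(z) f(z, p0), x)
  fp <- (f(x, p0 + 1e-7) - f(x, p0)) / 1e-7
  dxdp <- tryCatch(solve(Jx, -fp), error = function(e) rep(0, n))
  tan <- c(dxdp, 1) * direction
  tan <- tan / sqrt(sum(tan^2))
  z <- c(x, p0)
  for (step in seq_len(max_steps)) {
    repeat {
      z_pred <- z + ds * tan
      zc <- z_pred
      ok <- FALSE
      for (it in 1:25) {
        fx <- f(zc[1:n], zc[n + 1])
        res <- c(fx, sum(tan * (zc - z_pred)))
        if (max(abs(res)) < 1e-10) { ok <- TRUE; break }
        Jx <- numeric_jacobian(function(w) f(w, zc[n + 1]), zc[1:n])
        fp <- (f(zc[1:n], zc[n + 1] + 1e-7) - fx) / 1e-7
        A <- rbind(cbind(Jx, fp), tan)
        dz <- tryCatch(solve(A, -res), error = function(e) NULL)
        if (is.null(dz) || any(!is.finite(dz))) break
        zc <- zc + dz
      }
      if (ok || ds <= ds_min) break
      ds <- max(ds / 2, ds_min)
    }
    if (!ok) break
    new_tan <- (zc - z) / sqrt(sum((zc - z)^2))
    if (sum(new_tan * tan) < 0) new_tan <- -new_tan
    tan <- new_tan
    z <- zc
    push(z[1:n], z[n + 1])
    ds <- min(ds * 1.3, ds_max)
    if (z[n + 1] < min(p_range) - 1e-9 || z[n + 1] > max(p_range) + 1e-9) break
    if (any(abs(z[1:n]) > 1e3)) break
  }
  colnames(pts_x) <- paste0("x", seq_len(n))
  out <- data.frame(p = pts_p, pts_x, lambda = pts_l,
                    stable = pts_l < 0)
  out$symmetric <- if (is.null(symmetry)) NA
                   else apply(pts_x, 1, symmetry)
  sp <- detect_special_points(out, n, symmetry)
  if (nrow(sp) > 0) {
    # Newton refinement of each flagged point on the extended system
    # {f(x, p) = 0, lambda_min(J_x) = 0}: the eigenvalue closest to zero is
    # real and simple at these codimension-one points, so the system is
    # smooth and the refined location carries |Re lambda| ~ 0.
    lead0 <- function(x, p) {
      J <- numeric_jacobian(function(w) f(w, p), x)
      ev <- Re(eigen(J, only.values = TRUE)$values)
      ev[which.min(abs(ev))]
    }
    g <- function(z) c(f(z[1:n], z[n + 1]), lead0(z[1:n], z[n + 1]))
    # At folds the extended system is regular and Newton drives the
    # eigenvalue residual to ~1e-11. At a pitchfork/transcritical crossing
    # the branch Jacobian is singular along the crossing direction, so the
    # extended Newton can fail there; the linearly interpolated crossing
    # location is kept in that case (its accuracy is set by the local step
    # size, and the analytic symmetry-breaking determinant provides the
    # sharp pitchfork location independently).
    for (i in seq_len(nrow(sp))) {
      x0 <- as.numeric(sp[i, 3:(n + 2)])
      p0 <- sp$p[i]
      z <- newton_root(g, c(x0, p0), tol = 1e-11, maxit = 40)
      if (!is.null(z) && abs(z[n + 1] - p0) < 0.05) {
        sp[i, 3:(n + 2)] <- z[1:n]
        sp$p[i] <- z[n + 1]
      }
    }
  }
  structure(out, class = c("continuation_branch", "data.frame"),
            special_points = sp)
}

# Post-pass classification of folds and eigenvalue crossings on one branch.
detect_special_points <- function(br, n, symmetry) {
  sp <- list()
  m <- nrow(br)
  if (m < 3) return(data.frame())
  dp <- diff(br$p)
  folds <- which(dp[-1] * dp[-length(dp)] < 0) + 1
  crossings <- which(br$lambda[-1] * br$lambda[-m] < 0)
  used <- logical(m)
  for (i in folds) {
    sym_here <- if (is.null(symmetry)) NA else isTRUE(br$symmetric[i])
    type <- if (isTRUE(sym_here)) "SN" else "SN_PB"
    sp[[length(sp) + 1]] <- data.frame(type = type, p = br$p[i],
                                       br[i, 2:(n + 1)])
    used[max(1, i - 2):min(m, i + 2)] <- TRUE
  }
  for (i in crossings) {
    if (used[i]) next   # crossing belongs to an already-flagged fold
    p_c <- br$p[i] + (br$p[i + 1] - br$p[i]) *
      abs(br$lambda[i]) / (abs(br$lambda[i]) + abs(br$lambda[i + 1]))
    sym_here <- if (is.null(symmetry)) NA else isTRUE(br$symmetric[i])
    type <- if (isTRUE(sym_here)) "PB" else "TC"
    sp[[length(sp) + 1]] <- data.frame(type = type, p = p_c,
                                       br[i, 2:(n + 1)])
  }
  if (length(sp) == 0) data.frame() else do.call(rbind, sp)
}

# Reduced two-bin steady-state residual on the conservation manifold:
# x = (uL, vL, uR), vR = 2*c_total - sum(x).
two_bin_reduced_f <- function(model, sL = 0, sR = 0, Du_tilde = 0.01,
                              Dv_tilde = 10) {
  function(x, ct) {
    full <- c(x[1], x[2], x[3], 2 * ct - sum(x))
    two_bin_rhs(full, model, sL, sR, Du_tilde, Dv_tilde)[1:3]
  }
}

#' Bifurcation diagram of the two-bin projection versus total concentration
#'
#' Traces the homogeneous branch (from the uniform steady state at the lower
#' end of the range) and the inhomogeneous branches (seeded by a multi-start
#' fixed-point search at the upper end, then continued down through the fold
#' and back), and collects pitchfork (`PB`) and saddle-node (`SN_PB`)
#' points. Branches come in mirror pairs under the left/right exchange
#' symmetry; the mirror of each asymmetric branch is included.
#'
#' @param model a conserved `model_spec`.
#' @param c_range range of `c_total` (uM).
#' @param sL,sR step signal amplitudes (both 0 for the unsignaled diagram).
#' @param Du_tilde,Dv_tilde exchange rates (1/s).
#' @return An object of class `bifurcation_diagram`: list with `parameter`,
#'   `branches` (list of `continuation_branch` data frames with columns
#'   `p, uL, vL, uR, vR, lambda, stable, symmetric`), `special_points`, and
#'   `model`.
#' @export
two_bin_bifurcation <- function(model, c_range = c(2.0, 2.4), sL = 0, sR = 0,
                                Du_tilde = 0.01, Dv_tilde = 10) {
  f <- two_bin_reduced_f(model, sL, sR, Du_tilde, Dv_tilde)
  sym <- function(x) abs(x[1] - x[3]) < 1e-6
  m_lo <- model
  m_lo$params$c_total <- min(c_range)
  h <- homogeneous_steady_state(m_lo)
  branches <- list()
  hss_br <- continue_branch(f, c(h$u, h$v, h$u), min(c_range), c_range,
                            direction = 1, symmetry = sym)
  branches$hss <- hss_br
  m_hi <- model
  m_hi$params$c_total <- max(c_range)
  fp_hi <- two_bin_fixed_points(m_hi, sL = sL, sR = sR,
                                Du_tilde = Du_tilde, Dv_tilde = Dv_tilde)
  asym <- fp_hi[!fp_hi$symmetric & fp_hi$uL > fp_hi$uR, , drop = FALSE]
  if (nrow(asym) > 0) {
    seed <- asym[which.max(asym$uL), ]
    ihss_br <- continue_branch(f, c(seed$uL, seed$vL, seed$uR), max(c_range),
                               c_range, direction = -1, symmetry = sym)
    branches$ihss_upper <- ihss_br
    mirror <- ihss_br
    mirror[, c("x1", "x3")] <- mirror[, c("x3", "x1")]
    attr(mirror, "special_points") <- NULL  # avoid duplicating the fold
    branches$ihss_lower <- mirror
  }
  branches <- lapply(branches, function(b) {
    names(b)[2:4] <- c("uL", "vL", "uR")
    b$vR <- 2 * b$p - (b$uL + b$vL + b$uR)
    b
  })
  sp <- do.call(rbind, lapply(branches, function(b) {
    s <- attr(b, "special_points")
    if (is.null(s) || nrow(s) == 0) return(NULL)
    names(s)[3:5] <- c("uL", "vL", "uR")
    s
  }))
  if (is.null(sp)) sp <- data.frame()
  rownames(sp) <- NULL
  structure(list(parameter = "c_total", branches = branches,
                 special_points = sp, model = model,
                 signal = c(sL = sL, sR = sR)),
            class = "bifurcation_diagram")
}

#' Plot a bifurcation diagram
#' @param x a `bifurcation_diagram`.
#' @param component which state component to plot against the parameter.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bifurcation_diagram <- function(x, component = "uL", ...) {
  all_p <- unlist(lapply(x$branches, `[[`, "p"))
  all_v <- unlist(lapply(x$branches, `[[`, component))
  graphics::plot(range(all_p), range(all_v), type = "n",
                 xlab = x$parameter, ylab = component, ...)
  for (b in x$branches) {
    st <- b$stable
    graphics::lines(b$p[st], b[[component]][st], lwd = 2)
    graphics::lines(b$p[!st], b[[component]][!st], lty = 2)
  }
  sp <- x$special_points
  if (nrow(sp) > 0) {
    graphics::points(sp$p, sp[[component]], pch = 19, col = "red")
    graphics::text(sp$p, sp[[component]], sp$type, pos = 3, col = "red",
                   cex = 0.8)
  }
  invisible(x)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> vs", x$parameter, "-",
      length(x$branches), "branch(es)\n")
  if (nrow(x$special_points) > 0) {
    cat("special points:\n")
    print(x$special_points, digits = 5)
  } else cat("no special points detected\n")
  invisible(x)
}

#' Pitchfork condition of the two-bin projection
#'
#' Determinant of the reduced linearization restricted to the odd
#' (symmetry-breaking) perturbation mode, evaluated at a symmetric steady
#' state; its zero crossing along a parameter sweep locates the pitchfork.
#' With the derivatives of the reaction term at the symmetric state
#' (\eqn{f_{u,u}, f_{u,v}}) and uniform signal `s`, the doubled entries are
#' \deqn{F = 2\begin{pmatrix} f_{u,u} - 2\tilde D_u & f_{u,v} + s \\
#'  -f_{u,u} & -(f_{u,v} + s) - 2\tilde D_v \end{pmatrix}}
#' and the value returned is `det(F)` (positive at a stable symmetric state
#' below the pitchfork; it crosses zero from positive to negative as the
#' branch destabilizes).
#'
#' @param model a conserved `model_spec`.
#' @param state symmetric state: list/vector with `u`, `v` of one bin, or
#'   `NULL` to use [homogeneous_steady_state()].
#' @param s uniform signal amplitude.
#' @param Du_tilde,Dv_tilde exchange rates (1/s).
#' @return Scalar determinant value.
#' @export
pb_condition <- function(model, state = NULL, s = 0, Du_tilde = 0.01,
                         Dv_tilde = 10) {
  stopifnot(model$conserved)
  if (is.null(state)) state <- homogeneous_steady_state(model, s = s)
  if (is.numeric(state)) {
    if (length(state) >= 4 && abs(state[1] - state[3]) > 1e-8)
      stop("pb_condition: state must be symmetric")
    u <- state[1]; v <- state[2]
  } else if (!is.null(state$uL)) {
    if (abs(state$uL - state$uR) > 1e-8)
      stop("pb_condition: state must be symmetric")
    u <- state$uL; v <- state$vL
  } else {
    u <- state$u; v <- state$v
  }
  d <- conserved_fu_derivs(model, u, v)
  F11 <- 2 * (d$fu_u - 2 * Du_tilde)
  F12 <- 2 * (d$fu_v + s)
  F21 <- 2 * (-d$fu_u)
  F22 <- 2 * (-(d$fu_v + s) - 2 * Dv_tilde)
  F11 * F22 - F12 * F21
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the pitchfork along a c_total sweep from the analytic condition
#'
#' @param model a conserved `model_spec` (its `c_total` is swept).
#' @param c_range sweep interval.
#' @param Du_tilde,Dv_tilde exchange rates.
#' @return `c_total` at which [pb_condition()] crosses zero.
#' @export
locate_pb <- function(model, c_range = c(2.0, 2.4), Du_tilde = 0.01,
                      Dv_tilde = 10) {
  g <- function(ct) {
    m <- model
    m$params$c_total <- ct
    pb_condition(m, Du_tilde = Du_tilde, Dv_tilde = Dv_tilde)
  }
  cs <- seq(min(c_range), max(c_range), length.out = 200)
  vals <- vapply(cs, g, 0)
  i <- which(vals[-1] * vals[-length(vals)] < 0)[1]
  if (is.na(i)) stop("locate_pb: no sign change of the pitchfork condition in range")
  stats::uniroot(g, lower = cs[i], upper = cs[i + 1], tol = 1e-10)$root
}

#' Unfolding of the pitchfork under a step signal
#'
#' Recomputes the two-bin diagram versus `c_total` for each signal amplitude
#' `sL` (with `sR = 0`). At `sL = 0` the symmetric branch and its pitchfork
#' exist; any `sL > 0` breaks the symmetry, leaving a marginally asymmetric
#' branch in place of the homogeneous one plus a detached strongly
#' asymmetric (polarized) branch found by multi-seed continuation.
#'
#' @param model a conserved `model_spec` (normally the region II preset,
#'   where the unfolding is the mechanism of interest).
#' @param amplitudes nonnegative `sL` values.
#' @param c_range range of `c_total`.
#' @param Du_tilde,Dv_tilde exchange rates.
#' @return Named list of [two_bin_bifurcation()] diagrams, one per
#'   amplitude.
#' @export
unfolding_diagram <- function(model, amplitudes, c_range = c(2.0, 2.4),
                              Du_tilde = 0.01, Dv_tilde = 10) {
  stopifnot(all(amplitudes >= 0))
  out <- lapply(amplitudes, function(a)
    two_bin_bifurcation(model, c_range, sL = a, sR = 0,
                        Du_tilde = Du_tilde, Dv_tilde = Dv_tilde))
  names(out) <- paste0("sL=", amplitudes)
  out
}

#' Continuation of the LPA reduction
#'
#' Continues the steady state of the local/global system of [lpa_reduce()]
#' versus its natural parameter (`c_total` for the conserved mechanisms,
#' `ku` for LEGI). The trivial branch has `u_local = u_global`; for the
#' Turing-like model the local equation destabilizes at a transcritical
#' point `c_total = 1/a2` where a nontrivial local branch exchanges
#' stability with it.
#'
#' @param model a `model_spec`.
#' @param p_range parameter range.
#' @param s uniform signal (default 0).
#' @return A `continuation_branch` (see [continue_branch()]).
#' @export
lpa_continuation <- function(model, p_range, s = 0) {
  sys <- lpa_reduce(model)
  f <- function(x, p) sys$rhs(x, p, s)
  p0 <- min(p_range)
  if (model$conserved) {
    m0 <- model
    m0$params$c_total <- p0
    h <- homogeneous_steady_state(m0, s = s)
    x0 <- c(h$u, h$u)
  } else {
    x0 <- rep(0, 5)
    if (s > 0) {
      p <- model$params
      w <- p$kw * s / p$k_minus_w; v <- p$kv * s / p$k_minus_v
      u <- p0 * w * p$u_total / (p0 * w + p$k_minus_u * v)
      x0 <- c(w, w, v, u, u)
    }
  }
  # the local/global system carries no exchange symmetry, so eigenvalue
  # crossings without folds are transcritical by the geometry rule
  continue_branch(f, x0, p0, p_range, direction = 1, symmetry = NULL)
}

#' Classify the organization regime of a total concentration
#'
#' Looks `c_total` up against the special points of the unsignaled two-bin
#' diagram: below the saddle-node (`SN_PB`) the homogeneous state is the
#' only attractor (region I, or region II — "criticality" — within `margin`
#' of the saddle-node); between `SN_PB` and the pitchfork both homogeneous
#' and polarized states coexist (region III); beyond the pitchfork only the
#' polarized state is stable (region IV).
#'
#' @param c_total value to classify (uM).
#' @param diagram a [two_bin_bifurcation()] result at `sL = sR = 0`; when
#'   omitted it is computed for the wave-pinning kinetics.
#' @param margin width of the criticality band below the saddle-node (uM).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_region <- function(c_total, diagram = NULL, margin = 0.05) {
  if (is.null(diagram))
    diagram <- two_bin_bifurcation(model_preset("region_III"))
  sp <- diagram$special_points
  sn <- sp$p[sp$type %in% c("SN", "SN_PB")]
  pb <- sp$p[sp$type == "PB"]
  if (length(sn) == 0 || length(pb) == 0)
    stop("classify_region: diagram lacks SN_PB or PB points")
  sn <- min(sn); pb <- min(pb)
  if (c_total >= pb) "IV"
  else if (c_total >= sn) "III"
  else if (c_total >= sn - margin) "II"
  else "I"
}
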