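#' Parameter set for the wave-pinning / SubPB reaction kinetics
#'
#' The kinetics describe a Rho-GTPase-like cycle between a membrane-bound
#' active form \eqn{u} and a cytosolic inactive form \eqn{v}:
#' \deqn{f_u(u, v) = (k_0 + \gamma u^2 / (K^2 + u^2))\, v - \delta u,}
#' with \eqn{f_v = -f_u} (mass conservation). The positive feedback is a Hill
#' function of order 2 (exponent exposed via `hill` for exploration). The same
#' kinetics power both the wave-pinning regime (bistable, region III) and the
#' critically organized SubPB regime (region II); the two presets differ only
#' in the conserved total concentration `c_total`.
#'
#' @param k0 basal activation rate (1/s).
#' @param gamma maximal feedback conversion rate (1/s).
#' @param K feedback saturation concentration (uM).
#' @param delta inactivation rate (1/s).
#' @param c_total conserved mean total concentration u + v (uM).
#' @param Du,Dv membrane/cytosol diffusion constants (um^2/s); `Dv > Du`.
#' @param hill Hill exponent of the positive feedback (default 2).
#' @return An object of class `wave_pinning_params`.
#' @export
wave_pinning_params <- function(k0 = 0.067, gamma = 1, K = 1, delta = 1,
                                c_total = 2.26, Du = 0.1, Dv = 10, hill = 2) {
  p <- list(k0 = k0, gamma = gamma, K = K, delta = delta,
            c_total = c_total, Du = Du, Dv = Dv, hill = hill)
  stopifnot(all(unlist(p) > 0))
  if (Dv <= Du) stop("wave_pinning_params: Dv must exceed Du")
  structure(p, class = "wave_pinning_params")
}

#' Parameter set for the LEGI (local excitation, global inhibition) model
#'
#' Incoherent feed-forward motif: a membrane-bound activator \eqn{w} and a
#' fast cytosolic inhibitor \eqn{v} are both produced by the signal and
#' jointly set a membrane response component \eqn{u}:
#' \deqn{f_w = -k_{-w} w, \quad f_v = -k_{-v} v, \quad
#'       f_u = k_u w (u_{total} - u) - k_{-u} v u,}
#' with the signal entering as \eqn{+k_w s} on \eqn{w} and \eqn{+k_v s} on
#' \eqn{v}. Not mass-conserved.
#'
#' `u_total` is not pinned down by the published parameter tables; the default
#' of 1 uM makes `u` a fractional occupancy in `[0, 1]`, the usual convention
#' in the LEGI literature.
#'
#' @param ku,k_minus_u,kv,k_minus_v first-order rates (1/s).
#' @param kw,k_minus_w bimolecular production / first-order decay rates
#'   (1/(uM s) and 1/s).
#' @param u_total total response component (uM).
#' @param Du,Dv,Dw diffusivities (um^2/s).
#' @return An object of class `legi_params`.
#' @export
legi_params <- function(ku = 2, k_minus_u = 2, kv = 1, k_minus_v = 1,
                        kw = 1, k_minus_w = 1, u_total = 1,
                        Du = 0.5, Dv = 10, Dw = 0.5) {
  p <- list(ku = ku, k_minus_u = k_minus_u, kv = kv, k_minus_v = k_minus_v,
            kw = kw, k_minus_w = k_minus_w, u_total = u_total,
            Du = Du, Dv = Dv, Dw = Dw)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "legi_params")
}

#' Parameter set for the Turing-like mass-conserved activator model
#'
#' Reaction term of the activator:
#' \deqn{f_u(u, v) = a_1 \left(v - \frac{u + v}{(1 + a_2 (u + v))^2}\right),}
#' with \eqn{f_v = -f_u}. In the regime used for polarity modeling the total
#' concentration is past the transcritical point of its local-perturbation
#' reduction (at \eqn{c_{total} = 1/a_2}), so the homogeneous state is
#' unstable and the membrane is polarized even without signal.
#'
#' @param a1 kinetic rate scale (1/s).
#' @param a2 saturation coefficient (1/uM).
#' @param c_total conserved mean total concentration (uM).
#' @param Du,Dv diffusion constants (um^2/s).
#' @return An object of class `turing_params`.
#' @export
turing_params <- function(a1 = 2.5, a2 = 0.7, c_total = 2.5,
                          Du = 0.1, Dv = 10) {
  p <- list(a1 = a1, a2 = a2, c_total = c_total, Du = Du, Dv = Dv)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "turing_params")
}

#' Assemble a model specification
#'
#' Bundles a named mechanism with its parameters into the object consumed by
#' the integrators, the two-bin projection and the bifurcation tools.
#'
#' @param name one of `"subpb"`, `"wavepinning"`, `"turing"`, `"legi"`.
#'   `subpb` and `wavepinning` share the same kinetics and differ only through
#'   the `c_total` preset they are normally paired with.
#' @param params a `wave_pinning_params`, `turing_params` or `legi_params`
#'   object matching `name`; defaults to the canonical preset parameters.
#' @return An object of class `model_spec` with fields `name`, `params`,
#'   `n_components` (2 or 3) and `conserved`.
#' @seealso [model_preset()] for the published parameter presets.
#' @export
model_spec <- function(name, params = NULL) {
  name <- match.arg(name, c("subpb", "wavepinning", "turing", "legi"))
  if (is.null(params)) {
    params <- switch(name,
      subpb       = wave_pinning_params(c_total = 2.21),
      wavepinning = wave_pinning_params(c_total = 2.26),
      turing      = turing_params(),
      legi        = legi_params())
  }
  ok <- switch(name,
    subpb       = inherits(params, "wave_pinning_params"),
    wavepinning = inherits(params, "wave_pinning_params"),
    turing      = inherits(params, "turing_params"),
    legi        = inherits(params, "legi_params"))
  if (!ok) stop("model_spec: params class does not match model name ", name)
  structure(list(
    name = name,
    params = params,
    n_components = if (name == "legi") 3L else 2L,
    conserved = name != "legi"
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name,
      if (x$conserved) " (mass-conserved, " else " (open, ",
      x$n_components, " components)\n", sep = "")
  p <- unlist(x$params)
  cat(paste0("  ", names(p), " = ", signif(p, 6)), sep = "\n")
  invisible(x)
}

#' Published parameter presets
#'
#' Returns a [model_spec()] carrying the canonical parameter set of each
#' mechanism or organization regime: the shared GTPase-cycle parameters
#' k0 = 0.067/s, gamma = 1/s, K = 1 uM, delta = 1/s with total concentrations
#' c_total = 2.1, 2.21, 2.26, 2.32 uM for regions I-IV (region II is the SubPB
#' preset, region III the wave-pinning preset); the LEGI rates
#' ku = k-u = 2/s, kv = k-v = 1/s, kw = k-w = 1/(uM s); and the Turing-like
#' kinetics a1 = 2.5/s, a2 = 0.7/uM.
#'
#' @param name one of `"region_I"`, `"region_II"`, `"subpb"`, `"region_III"`,
#'   `"wavepinning"`, `"region_IV"`, `"legi"`, `"turing"`.
#' @return A `model_spec`.
#' @export
model_preset <- function(name) {
  name <- match.arg(name, c("region_I", "region_II", "subpb", "region_III",
                            "wavepinning", "region_IV", "legi", "turing"))
  spec <- switch(name,
    region_I    = model_spec("wavepinning", wave_pinning_params(c_total = 2.1)),
    region_II   = ,
    subpb       = model_spec("subpb", wave_pinning_params(c_total = 2.21)),
    region_III  = ,
    wavepinning = model_spec("wavepinning", wave_pinning_params(c_total = 2.26)),
    region_IV   = model_spec("wavepinning", wave_pinning_params(c_total = 2.32)),
    legi        = model_spec("legi"),
    turing      = model_spec("turing"))
  spec$label <- name
  spec
}

#' Component names of a model
#' @param model a `model_spec`.
#' @return Character vector of field names (`c("u","v")` or `c("u","v","w")`).
#' @export
model_components <- function(model) {
  if (model$n_components == 3L) c("u", "v", "w") else c("u", "v")
}

#' Diffusivities of a model in component order
#' @param model a `model_spec`.
#' @return Named numeric vector (um^2/s).
#' @export
model_diffusivities <- function(model) {
  p <- model$params
  if (model$name == "legi") c(u = p$Du, v = p$Dv, w = p$Dw)
  else c(u = p$Du, v = p$Dv)
}

# Reaction term f_u(u, v) of the conserved two-component mechanisms,
# vectorized over bins.
conserved_fu <- function(model, u, v) {
  p <- model$params
  switch(model$name,
    subpb = ,
    wavepinning = (p$k0 + p$gamma * u^p$hill / (p$K^p$hill + u^p$hill)) * v -
      p$delta * u,
    turing = {
      x <- u + v
      p$a1 * (v - x / (1 + p$a2 * x)^2)
    },
    stop("conserved_fu: not a conserved model: ", model$name))
}

# Analytic partial derivatives of f_u for the conserved mechanisms.
conserved_fu_derivs <- function(model, u, v) {
  p <- model$params
  switch(model$name,
    subpb = ,
    wavepinning = {
      h <- p$hill
      hillterm <- u^h / (p$K^h + u^h)
      dhill <- h * u^(h - 1) * p$K^h / (p$K^h + u^h)^2
      list(fu_u = p$gamma * dhill * v - p$delta,
           fu_v = p$k0 + p$gamma * hillterm)
    },
    turing = {
      x <- u + v
      g <- (1 - p$a2 * x) / (1 + p$a2 * x)^3  # d/dx [x/(1+a2 x)^2]
      list(fu_u = -p$a1 * g, fu_v = p$a1 * (1 - g))
    },
    stop("conserved_fu_derivs: not a conserved model: ", model$name))
}

#' Reaction part of the time derivatives
#'
#' Evaluates the reaction terms (no diffusion) of a model at the given
#' concentrations, with the local signal coupled as `+s*v` on `u` and `-s*v`
#' on `v` for the mass-conserved mechanisms, and as `+kw*s` on `w`, `+kv*s`
#' on `v` for LEGI. For conserved models `du/dt + dv/dt == 0` exactly,
#' including the signal terms.
#'
#' @param model a `model_spec`.
#' @param state named list of nonnegative concentration vectors (`u`, `v`,
#'   and `w` for LEGI), all the same length.
#' @param s local signal amplitude; scalar or a vector matching the state
#'   length. Must be nonnegative.
#' @return Named list of per-component time derivatives (same shape as
#'   `state`).
#' @export
reaction_rates <- function(model, state, s = 0) {
  if (!inherits(model, "model_spec")) stop("reaction_rates: need a model_spec")
  comps <- model_components(model)
  if (!all(comps %in% names(state)))
    stop("reaction_rates: state must contain ", paste(comps, collapse = ", "))
  for (nm in comps)
    if (any(state[[nm]] < 0))
      stop("reaction_rates: negative concentration in component ", nm)
  if (any(s < 0)) stop("reaction_rates: signal must be nonnegative")
  p <- model$params
  if (model$conserved) {
    fu <- conserved_fu(model, state$u, state$v) + s * state$v
    list(u = fu, v = -fu)
  } else {
    list(
      u = p$ku * state$w * (p$u_total - state$u) -
        p$k_minus_u * state$v * state$u,
      v = -p$k_minus_v * state$v + p$kv * s,
      w = -p$k_minus_w * state$w + p$kw * s)
  }
}

#' Homogeneous steady state of a model under a uniform signal
#'
#' For the mass-conserved mechanisms the spatially uniform steady states
#' solve \eqn{f_u(u, c_{total} - u) + s (c_{total} - u) = 0} on
#' \eqn{[0, c_{total}]}; all real nonnegative roots are returned (found by a
#' dense sign scan plus bracketed root refinement) and the smallest-`u` root
#' is flagged as the homogeneous-steady-state candidate. For LEGI the steady
#' state is available in closed form.
#'
#' @param model a `model_spec`.
#' @param s uniform signal amplitude (default 0).
#' @param n_scan scan resolution for root bracketing.
#' @return List with elements `u`, `v` (and `w` for LEGI) of the HSS
#'   candidate, and `roots`: a data frame of all uniform steady states.
#' @export
homogeneous_steady_state <- function(model, s = 0, n_scan = 4000) {
  p <- model$params
  if (!model$conserved) {
    w <- p$kw * s / p$k_minus_w
    v <- p$kv * s / p$k_minus_v
    den <- p$ku * w + p$k_minus_u * v
    u <- if (den > 0) p$ku * w * p$u_total / den else 0
    return(list(u = u, v = v, w = w,
                roots = data.frame(u = u, v = v, w = w)))
  }
  ct <- p$c_total
  g <- function(u) conserved_fu(model, u, ct - u) + s * (ct - u)
  us <- seq(0, ct, length.out = n_scan)
  gs <- g(us)
  roots <- numeric(0)
  zero_hits <- us[gs == 0]
  roots <- c(roots, zero_hits)
  sgn <- sign(gs)
  idx <- which(sgn[-1] * sgn[-n_scan] < 0)
  for (i in idx) {
    r <- stats::uniroot(g, lower = us[i], upper = us[i + 1],
                        tol = 1e-14)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0)
    stop("homogeneous_steady_state: no real root in [0, c_total]")
  # collapse near-duplicates from scan endpoints
  keep <- c(TRUE, diff(roots) > 1e-9 * max(ct, 1))
  roots <- roots[keep]
  list(u = roots[1], v = ct - roots[1],
       roots = data.frame(u = roots, v = ct - roots))
}
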