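---
title: "Polarity mechanisms, transients, and quasi-potential landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarity mechanisms, transients, and quasi-potential landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(polaritylab)
```

## The scientific problem

Migrating cells polarize: a chemoattractant gradient across the membrane is
read out into a stable front/back asymmetry of signaling activity. The
classical model families explain pieces of the phenomenology — fast
polarization, gradient amplification, threshold activation (noise
rejection), transient *memory* of a removed stimulus, re-polarization when
the gradient flips, and resolution of competing simultaneous cues — but no
fixed-point ("autonomous") account explains all of them at once. This
package implements four mechanisms on a common footing so that their
responses to spatial-temporal signals can be compared quantitatively, and it
implements the *non-autonomous* analysis machinery (time-indexed bifurcation
diagrams, quasi-potential landscapes, curvature-based classification of
transients) needed to see **why** they differ:

* **Wave-pinning** (`model_preset("wavepinning")`, region III): a
  mass-conserved GTPase cycle with Hill-2 positive feedback,
  $f_u(u,v) = (k_0 + \gamma u^2/(K^2+u^2))\,v - \delta u$, $f_v = -f_u$.
  Homogeneous (HSS) and polarized (IHSS) states coexist; stimuli trigger
  hard, persistent transitions.
* **SubPB** (`model_preset("subpb")`, region II): the same kinetics with the
  total concentration just *below* the saddle-node (SN~PB~) that stabilizes
  the subcritical pitchfork. Only the HSS exists at rest, but the "ghost" of
  the polarized state transiently traps trajectories — memory without
  permanence.
* **LEGI** (`model_preset("legi")`): local excitation, global inhibition —
  an incoherent feed-forward motif with a single steady state; graded,
  adaptive, reversible responses.
* **Turing-like** (`model_preset("turing")`): a mass-conserved
  activator–substrate model organized past its transcritical point, so the
  non-polar state is unstable and the membrane polarizes spontaneously.

## Model equations and discretization

The membrane is a 1-D periodic domain (angle $\theta$), discretized into
$N = 20$ bins; diffusion uses centered second differences with periodic
wrap (bin 1 couples to bins 2 and $N$), and the signal couples as $+s v$
on the active form and $-s v$ on the inactive pool (for LEGI, as
$+k_w s$ and $+k_v s$ on activator and inhibitor). Deterministic
integration uses an explicit adaptive Runge–Kutta 4(5) scheme
(`deSolve::ode(method = "ode45")`), split at the protocol's signal on/off
times; stochastic runs use fixed-step Euler–Maruyama with additive Gaussian
noise on every bin and component, clipping negative excursions at zero.

### The domain scale

The kinetic parameters and diffusivities are in physical units
(µM, 1/s, µm²/s), but the cell size is a free scale that every absolute
time depends on. The default perimeter, $L = 9.3\ \mu m$, is the center of
the window in which the four canonical total concentrations
($c_{total} = 2.1, 2.21, 2.26, 2.32\ \mu M$) realize their four regimes on
the $N = 20$ ring:

* below $L \approx 9.0\ \mu m$ the homogeneous state at
  $c_{total} = 2.32$ is still linearly stable — no region IV;
* above $L \approx 9.6\ \mu m$ the polarized state at $c_{total} = 2.21$
  becomes a true attractor rather than a ghost — no region II memory.

This calibration uses only the qualitative regime structure, not any
measured threshold or time. One published contrast cannot be accommodated
at the same scale: wave-pinning's *failure* to re-polarize under a
2×-threshold reversed gradient requires the sharp-front (lattice-pinned)
regime, which on a 20-bin ring only appears for $L \gtrsim 11\ \mu m$ —
where the region II ghost no longer exists. Model-comparison work in this
literature typically rescales each mechanism separately to physiological
response times, which resolves the tension at the price of per-model
scales; this package deliberately keeps one common scale and reports the
reversal quantities as they come out (see *Known limitations*).

### The gradient

Stimuli are truncated Gaussian windows over the bins,
$s(n) = s_0 \exp(-n^2 / 2w)$ with *variance* $w = (N-1)/2\alpha$
($w = 4.75$ bins² at the defaults $\alpha = 2$, $N = 20$), giving a full
width at half maximum of 5.13 bins ≈ 25% of the perimeter and a negligible
wrap-around jump (≈ $7\times10^{-5} s_0$). Reading $w$ as a standard
deviation instead would contradict both the 25%-FWHM statement and the
negligible-discontinuity property, which is why the variance reading is
used. Stimulus strength is quoted as the percent difference across the
cell, $sd = (s_{\theta=\pi} - s_{\theta=0})\times 100$; the default
$s_0 = 0.02$ corresponds to $sd \approx 2\%$.

## The two-bin projection and bifurcation structure

For phase-plane work the membrane is collapsed to two exchanging bins
(`two_bin_rhs()`), with exchange rates $\tilde D_u = 0.01$/s,
$\tilde D_v = 10$/s. The steady-state structure versus $c_{total}$ is
traced by a native pseudo-arclength continuation (secant predictor, Newton
corrector on the arclength-augmented system, adaptive step) on the
conservation-reduced coordinates $(u_L, v_L, u_R)$, so the structural zero
eigenvalue of mass conservation never pollutes the stability call.
Detected special points are refined by Newton iteration on the extended
system $\{f = 0, \lambda_{\min} = 0\}$, which pins folds to an eigenvalue
zero crossing to $\sim 10^{-10}$; at pitchfork/transcritical crossings the
branch Jacobian is singular along the crossing direction, so those keep
their step-size-limited interpolated location (the analytic determinant
below provides the sharp pitchfork independently). Classification is
geometric: a fold on an
asymmetric branch is SN~PB~; an eigenvalue crossing without a fold on a
symmetry-respecting branch is the pitchfork; such a crossing on a system
without the exchange symmetry (the local-perturbation reductions) is
transcritical. With the published parameters this places SN~PB~ at
$c_{total} \approx 2.215$ and the pitchfork at $\approx 2.3087$; the
analytic symmetry-breaking determinant (`pb_condition()`, the odd-mode
$2\times2$ reduction of the 4-D Jacobian) locates the same pitchfork to
better than $10^{-3}$, and the Turing-like local-perturbation reduction
shows its transcritical point at exactly $1/a_2$.

`classify_region()` reports I/II/III/IV relative to the located SN~PB~ and
PB; the criticality band defining region II extends 0.05 µM below SN~PB~
(covers the published region II representative 2.21 while excluding the
region I representative 2.1; exposed as `margin`).

## Quasi-potential landscapes

The projected dynamics in the $(u_L, u_R)$ plane (cytosol homogenized by
its fast exchange and eliminated through conservation,
$\bar v = c_{total} - (u_L + u_R)/2$ — the equation is written in two
variables and this closure is the documented choice) is made stochastic
with diffusion $D = 0.02$ and its stationary Fokker–Planck density solved
on a grid of spacing $h = 0.02$. The discretization is a conservative
finite volume with exponential-fitting (Scharfetter–Gummel) face fluxes —
a generator matrix with nonnegative off-diagonal rates that is exact for
linear drift — and the stationary density is obtained directly from the
sparse linear system with a normalization row: the exact $t\to\infty$
limit, with no pseudo-time truncation error. On the quadratic
(Ornstein–Uhlenbeck) oracle the solution is exact to rounding; on
gradient-flow drifts the recovered potential matches $U/D$ to well under
3% RMS on the density support.

Boundaries are reflecting. For the conserved models the grid is
$[-0.5, 2c_{total}]^2$: the pad below zero lies outside the physical cone,
where production pushes the density back in and it decays within a few
cells, so truncation-boundary mass is negligible; for LEGI the box
$[0, u_{total}]$ *is* the physical state space and its walls are real.
The potential is $Q = -\ln\max(P_{ss}, 10^{-12})$.

### Asymptotic regions and transients

Gaussian curvature $K = (Q_{xx}Q_{yy} - Q_{xy}^2)/(1 + Q_x^2 + Q_y^2)^2$
is computed by centered differences (one-sided at edges; empirically
second-order). Candidate asymptotic regions are connected components of
$\{K > \bar K + 0.1\,\mathrm{sd}(K)\}$, with statistics restricted to the
support of the density — the floored plateau and its cliff would otherwise
dominate both moments. A component is a **well** when its slopes are
distributed around zero in both directions; operationally, when it
contains an interior local minimum of $Q$ (slopes change sign around an
interior critical point). The naive alternative — thresholding the mean
slope at a fraction of the slope standard deviation — is reported as a
diagnostic but not used for classification: basins truncated by the
curvature threshold against the $u = 0$ wall carry biased mean slopes even
around genuine minima, making that test a coin flip exactly where it
matters. With these definitions the region III landscape at rest has three
wells (HSS + two IHSS) and the region II landscape has one well plus a
positive-curvature shoulder pair with one-sided slopes — the ghost area.

A trajectory sample is *asymptotic* when it lies in a well with potential
below that well's boundary value `Q_bound` (mean of $Q$ on the component
boundary), else *transient*. The ghost dwell is the longest contiguous
transient span after signal removal with phase-space speed below 10% of
the post-signal maximum; the maximum (set by the fast transit away from the
lost attractor) is the robust speed reference, since the epoch's median or
mean is dominated by the near-zero speeds of the eventual resting state.
Under a 300 s step stimulus of amplitude 0.02, region II shows a ghost
dwell of roughly a minute before resetting; region III shows none — it is
trapped in the polarized well itself.

## The metric suite

All quantifications operate on kymographs with a 1 s reporting grid:

* `polarization_ratio()`: $u_{\theta=\pi}/u_{\theta=0}$, by default the
  mean over the last 100 samples.
* `polarization_time()`: min–max normalize the front trace over the
  stimulation epoch; first entry into $\pm 10^{-2}$ of the mean of the
  last 100 samples, which must themselves be a stable plateau (variance
  below the window squared) or the result is "not reached".
* `estimate_sd_thresh()`: sustained-gradient dose–response scan over a
  $sd$ grid; threshold at 50% of the maximal plateau ratio by linear
  interpolation. For LEGI and Turing (graded responders) the published
  manual conventions 0.5% and 0.1% apply.
* `repolarization_metrics()` / `resolving_metrics()`: plateau-entry time
  at the new front after a gradient reversal (amplitude $2\times$
  threshold) or under simultaneous opposed gradients (amplitude ratio 2,
  each scaled to the model's own threshold — the same per-model
  normalization the reversal protocol uses), plus the plateau
  amplification; re-polarization additionally requires the axis to have
  flipped.
* `signal_integration_index()`: (duration of supra-threshold normalized
  front activity − signal duration)/total time.
* `spurious_activation()`: fraction of replicates polarizing from randomly
  perturbed rest states $(u_s + \xi r, v_s - \xi r)$ at zero signal
  (plateau max/min ratio above 1.5).

## Parameter choices that are this package's own

| choice | value | why |
|---|---|---|
| perimeter $L$ | 9.3 µm | center of the regime-structure window (above) |
| Turing $c_{total}$ | 2.5 µM | not printed; past the transcritical point (1/0.7 ≈ 1.43 µM) with mode-1 growth ≈ 0.013/s so spontaneous polarization happens on simulation time scales (at 2.0 µM growth is ~9×10⁻⁴/s — regime not expressed) |
| LEGI $u_{total}$ | 1 µM | not printed; makes $u$ a fractional occupancy |
| LEGI $\tilde D_w$ | $=\tilde D_u$ | $w$ is the slow membrane species |
| region IV initial state | HSS ± 10⁻³ odd perturbation | deterministic branch selection where the HSS is unstable |
| two-bin step amplitudes | ramp 0 → 0.02 in 3 steps | published increments not printed |
| activation cutoff (spurious runs) | plateau ratio 1.5 | separates the bimodal outcome cleanly |
| SDE step | 0.01 s | stability of the stiffest (cytosol-diffusion) mode with ample margin |

Problem sizes used by the shipped experiments: $N = 20$ bins (refinement
to $N = 40$ changes plateau ratios by <1%), simulations of 500–2500 s,
dose–response scans of 10 amplitudes, Fokker–Planck grids of about
240×240 cells.

## What the synthetic experiments do and do not show

The simulated stimulation protocols emulate idealized chemoattractant
fields: piecewise-constant-in-time Gaussian windows, reversals,
simultaneous opposed pairs, pulse trains — with noise entering only
through the integrator, never the signal. Passing the suite shows that the
four mechanisms, at their published parameters, separate qualitatively as
claimed (threshold vs graded activation; memory vs persistence vs
immediate reset; fast vs slow resolving) and that the landscape machinery
attributes those separations to the correct phase-space structures. It
does not show anything about receptor-level biology, 2-D cell geometry,
moving boundaries, or fluctuating natural gradients.

## Known limitations

* Absolute times inherit the domain-scale choice; only orderings and
  bounds are meaningful across mechanisms.
* At the single documented scale, wave-pinning re-polarizes under the
  2×-threshold reversed gradient (its pinned state at $c_{total} = 2.26$
  sits close to the fold), unlike in the sharp-front regime; the minimal
  re-polarizing amplitude multiple is correspondingly 1 rather than ≈ 7.
* The printed LEGI equations have no basal turnover: at zero signal the
  response component is frozen (only diffusion acts). Polarization ratios
  reset quickly after stimulus removal, but the absolute level does not,
  which inflates LEGI's signal-integration index relative to a formulation
  with basal turnover.
* The spurious-activation noise amplitude grid and the dose–response
  repeat noise are not printed; the deterministic scan is the default and
  noisy repeats are exposed via `repeats`/`sigma`.
```
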