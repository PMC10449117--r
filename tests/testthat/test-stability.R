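test_that("LPA reduction: degeneracy, global subsystem, local bistability", {
  m <- model_preset("wavepinning")
  sys <- lpa_reduce(m)
  # a local variable initialized on the global one stays there forever:
  # the local equation degenerates to the global one
  y <- c(0.7, 0.7)
  d <- sys$rhs(y, 2.26)
  expect_equal(d[1], d[2])
  # the global subsystem is exactly the well-mixed model
  h <- homogeneous_steady_state(m)
  expect_lt(abs(sys$rhs(c(h$u, h$u), 2.26)[2]), 1e-10)
  # local equation at frozen global state: dense scan oracle for root count.
  # The local bistability window opens near c_total ~ 2.0 (the reduction
  # over-covers the patterning regimes, as local perturbation analyses do):
  # far below it the local equation is monostable, at the coexistence
  # representative 2.26 it is bistable.
  local_roots <- function(ct) {
    mm <- m; mm$params$c_total <- ct
    hh <- homogeneous_steady_state(mm)
    g <- function(ul) polaritylab:::conserved_fu(mm, ul, ct - hh$u)
    us <- seq(0, ct, length.out = 3000)
    gs <- g(us)
    sum(gs[-1] * gs[-length(gs)] < 0)
  }
  expect_equal(local_roots(1.5), 1L)
  expect_equal(local_roots(2.26), 3L)
  # no slow/fast separation -> unsupported
  bad <- model_spec("wavepinning", wave_pinning_params(Du = 2, Dv = 10))
  expect_error(lpa_reduce(bad), "separation")
})

test_that("pitchfork condition: determinant identities", {
  m <- model_preset("region_III")
  h <- homogeneous_steady_state(m)
  d <- polaritylab:::conserved_fu_derivs(m, h$u, h$v)
  # decoupled bins: |F| equals 4 * det of the single-bin Jacobian
  J1 <- matrix(c(d$fu_u, -d$fu_u, d$fu_v, -d$fu_v), 2, 2)
  expect_equal(pb_condition(m, Du_tilde = 0, Dv_tilde = 0), 4 * det(J1),
               tolerance = 1e-12)
  # scaling all reaction terms by c scales the determinant by c^2
  ms <- m
  ms$params$k0 <- m$params$k0 * 2
  ms$params$gamma <- m$params$gamma * 2
  ms$params$delta <- m$params$delta * 2
  # same steady state (the root condition is homogeneous in the rates),
  # doubled rates double both derivative entries
  expect_equal(pb_condition(ms, state = h, Du_tilde = 0, Dv_tilde = 0),
               4 * pb_condition(m, state = h, Du_tilde = 0, Dv_tilde = 0))
  expect_error(pb_condition(m, state = c(0.3, 1.9, 0.5, 1.7)), "symmetric")
})

test_that("two-bin continuation reproduces the published region structure", {
  bd <- cached("bifdiag", two_bin_bifurcation(model_preset("region_III")))
  sp <- bd$special_points
  expect_gt(nrow(sp), 0)
  pb <- min(sp$p[sp$type == "PB"])
  sn <- min(sp$p[sp$type %in% c("SN", "SN_PB")])
  # ordering of the printed representative concentrations:
  # 2.1, 2.21 (HSS only) < SN_PB < 2.26 (coexistence) < PB < 2.32 (IHSS only)
  expect_gt(sn, 2.21)
  expect_lt(sn, 2.26)
  expect_gt(pb, 2.26)
  expect_lt(pb, 2.32)
  expect_equal(classify_region(2.10, bd), "I")
  expect_equal(classify_region(2.21, bd), "II")
  expect_equal(classify_region(2.26, bd), "III")
  expect_equal(classify_region(2.32, bd), "IV")
  # the analytic symmetry-breaking determinant locates the same pitchfork
  pb_det <- locate_pb(model_preset("region_III"))
  expect_lt(abs(pb_det - pb), 1e-3)
  # flagged folds sit on an eigenvalue zero crossing after refinement
  f <- polaritylab:::two_bin_reduced_f(model_preset("region_III"))
  for (i in which(sp$type %in% c("SN", "SN_PB"))) {
    x <- as.numeric(sp[i, c("uL", "vL", "uR")])
    J <- polaritylab:::numeric_jacobian(function(w) f(w, sp$p[i]), x)
    ev <- Re(eigen(J, only.values = TRUE)$values)
    expect_lt(min(abs(ev)), 1e-6)
  }
  # mirror symmetry of the asymmetric branches
  up <- bd$branches$ihss_upper
  lo <- bd$branches$ihss_lower
  expect_equal(up$uL, lo$uR)
  expect_equal(up$uR, lo$uL)
})

test_that("Turing LPA shows a transcritical point at c_total = 1/a2", {
  lt <- cached("lpa_turing",
               lpa_continuation(model_preset("turing"), c(1.0, 2.0)))
  sp <- attr(lt, "special_points")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$type, "TC")
  expect_equal(sp$p, 1 / model_preset("turing")$params$a2, tolerance = 1e-3)
})

test_that("LEGI continuation is a single branch without special points", {
  # at rest and under a uniform baseline alike
  for (s in c(0, 0.2)) {
    ll <- lpa_continuation(model_preset("legi"), c(0.5, 4), s = s)
    sp <- attr(ll, "special_points")
    expect_equal(nrow(sp), 0L)
    expect_true(all(ll$lambda <= 1e-10))
  }
})

test_that("a step signal unfolds the pitchfork", {
  m <- model_preset("region_II")
  ud <- cached("unfolding",
               unfolding_diagram(m, amplitudes = c(0, 0.005),
                                 c_range = c(2.1, 2.35)))
  # without signal the symmetric pitchfork exists
  sp0 <- ud[[1]]$special_points
  expect_true("PB" %in% sp0$type)
  hss0 <- ud[[1]]$branches$hss
  expect_lt(max(abs(hss0$uL - hss0$uR)), 1e-8)
  # any positive amplitude leaves no symmetric branch and no pitchfork
  br1 <- ud[[2]]$branches$hss
  expect_gt(min(abs(br1$uL - br1$uR)), 1e-6)
  sp1 <- ud[[2]]$special_points
  expect_false("PB" %in% sp1$type)
  # at the maximal step amplitude the strongly asymmetric state is the only
  # stable solution at the region II concentration
  fp <- two_bin_fixed_points(m, sL = 0.02, sR = 0)
  stable <- fp[fp$stable, ]
  expect_gt(nrow(stable), 0)
  expect_true(all(stable$uL - stable$uR > 0.3))
})
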