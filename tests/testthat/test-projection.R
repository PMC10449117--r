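test_that("two-bin derivatives: symmetry, conservation, rest state", {
  m <- model_preset("region_III")
  h <- homogeneous_steady_state(m)
  sym <- c(h$u, h$v, h$u, h$v)
  # symmetric state under equal signals: exchange terms vanish
  d <- two_bin_rhs(c(0.4, 1.8, 0.4, 1.8), m, sL = 0.01, sR = 0.01)
  expect_equal(d[["uL"]], d[["uR"]])
  expect_equal(d[["vL"]], d[["vR"]])
  # total mass is conserved exactly without signal
  set.seed(1)
  for (i in 1:50) {
    st <- stats::runif(4, 0, 2)
    expect_lt(abs(sum(two_bin_rhs(st, m))), 1e-14)
  }
  # the homogeneous steady state replicated to both bins is a fixed point
  expect_lt(max(abs(two_bin_rhs(sym, m))), 1e-9)
})

test_that("LEGI quasi-steady-state closures hold identically", {
  p <- model_preset("legi")$params
  r <- legi_two_bin_rhs(c(0, 0), p, sL = 0, sR = 0)
  expect_equal(r$v_qss, 0)
  expect_equal(unname(r$du), c(0, 0))
  # wL + wR equals the printed total for random signals and exchange rates
  set.seed(2)
  for (i in 1:50) {
    sL <- stats::runif(1, 0, 0.1); sR <- stats::runif(1, 0, 0.1)
    dw <- stats::runif(1, 0, 1)
    r <- legi_two_bin_rhs(c(0.2, 0.3), p, sL, sR, Dw_tilde = dw)
    expect_equal(r$wL_qss + r$wR_qss, p$kw / p$k_minus_w * (sL + sR))
  }
  # symmetric closure under equal signals
  r <- legi_two_bin_rhs(c(0.2, 0.2), p, sL = 0.05, sR = 0.05)
  expect_equal(r$wL_qss, r$wR_qss)
  # with no w exchange the left closure reduces to kw/k-w * sL
  r <- legi_two_bin_rhs(c(0.2, 0.3), p, sL = 0.07, sR = 0.01, Dw_tilde = 0)
  expect_equal(r$wL_qss, p$kw / p$k_minus_w * 0.07)
})

test_that("left/right exchange symmetry swaps trajectories exactly", {
  m <- model_preset("region_II")
  pr1 <- step_protocol(sL = c(0.02, 0), duration = c(100, 100))
  pr2 <- protocol_spec("step_two_bin",
                       steps = data.frame(sL = c(0, 0), sR = c(0.02, 0),
                                          duration = c(100, 100)))
  init <- c(0.3, 1.9, 0.2, 1.9)
  t1 <- simulate_projection(m, pr1, init = init)
  t2 <- simulate_projection(m, pr2, init = init[c(3, 4, 1, 2)])
  expect_equal(t1$uL, t2$uR, tolerance = 1e-12)
  expect_equal(t1$uR, t2$uL, tolerance = 1e-12)
})

test_that("zero-signal epochs from the rest state stay constant", {
  m <- model_preset("region_II")
  traj <- simulate_projection(m, step_protocol(sL = 0, duration = 50))
  expect_lt(max(abs(traj$uL - traj$uL[1])), 1e-8)
  expect_lt(max(abs(traj$uL - traj$uR)), 1e-10)
})

test_that("region II responds with transient memory, region III persists", {
  prot <- step_protocol(sL = c(0.02, 0), duration = c(300, 700))
  t2 <- simulate_projection(model_preset("region_II"), prot)
  du2 <- t2$uL - t2$uR
  # polarized during the signal, a transient plateau after removal,
  # and finally a return to the symmetric state
  expect_gt(du2[t2$time == 300], 0.3)
  expect_gt(du2[t2$time == 350], 0.3)    # memory outlives the signal
  expect_lt(abs(du2[nrow(t2)]), 1e-3)    # but decays eventually
  t3 <- simulate_projection(model_preset("region_III"), prot)
  du3 <- t3$uL - t3$uR
  expect_gt(du3[nrow(t3)], 0.3)          # sustained polarization
})

test_that("fixed-point structure: bistability appears only past criticality", {
  fp2 <- two_bin_fixed_points(model_preset("region_II"))
  expect_true(all(fp2$symmetric))
  expect_equal(sum(fp2$stable), 1L)
  fp3 <- two_bin_fixed_points(model_preset("region_III"))
  expect_equal(sum(fp3$symmetric & fp3$stable), 1L)
  expect_equal(sum(!fp3$symmetric & fp3$stable), 2L)
  expect_equal(sum(!fp3$symmetric & !fp3$stable), 2L)
  # the symmetric fixed point coincides with the well-mixed steady state
  h <- homogeneous_steady_state(model_preset("region_III"))
  sym_root <- fp3[fp3$symmetric, ]
  expect_equal(sym_root$uL, h$u, tolerance = 1e-8)
  expect_equal(sym_root$vL, h$v, tolerance = 1e-8)
  # mirror pairing of the asymmetric states
  asym <- fp3[!fp3$symmetric & fp3$stable, ]
  expect_equal(sort(asym$uL), sort(asym$uR), tolerance = 1e-8)
})
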