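test_that("stationary solver reproduces Ornstein-Uhlenbeck closed forms", {
  D <- 0.02
  fp <- solve_fokker_planck(function(x, y) cbind(-x, -y), D = D,
                            xlim = c(-1, 1), h = 0.02)
  analytic <- outer(fp$x, fp$y,
                    function(x, y) exp(-(x^2 + y^2) / (2 * D)))
  analytic <- analytic / (sum(analytic) * fp$h^2)
  bulk <- fp$P > max(fp$P) * 1e-4
  expect_lt(max(abs(fp$P[bulk] - analytic[bulk]) / analytic[bulk]), 0.02)
  # probability is normalized
  expect_equal(sum(fp$P) * fp$h^2, 1, tolerance = 1e-9)
  # zero drift on a reflecting box: uniform density
  fp0 <- solve_fokker_planck(function(x, y) cbind(0 * x, 0 * y), D = D,
                             xlim = c(0, 1), h = 0.05, boundary_tol = Inf)
  expect_lt(diff(range(fp0$P)) / mean(fp0$P), 1e-8)
  # outward drift piles mass on the truncation boundary: grid-extent error
  expect_error(solve_fokker_planck(function(x, y) cbind(x, y), D = D,
                                   xlim = c(-1, 1), h = 0.05),
               "boundary")
})

test_that("quasi-potential: log transform, floor, quadratic recovery", {
  D <- 0.02
  fp <- solve_fokker_planck(function(x, y) cbind(-x, -y), D = D,
                            xlim = c(-1, 1), h = 0.02)
  Q <- quasi_potential(fp$P)
  # uniform density maps to a constant potential
  expect_equal(quasi_potential(matrix(0.25, 4, 4)),
               matrix(-log(0.25), 4, 4))
  # cells under the floor share the ceiling value
  Pf <- matrix(c(1, 1e-15, 1e-20, 1), 2, 2)
  Qf <- quasi_potential(Pf, floor = 1e-12)
  expect_equal(Qf[1, 2], -log(1e-12))
  expect_equal(Qf[2, 1], -log(1e-12))
  # the Gaussian's potential is quadratic: (x^2+y^2)/(2D) up to a constant
  bulk <- fp$P > max(fp$P) * 1e-3
  theo <- outer(fp$x, fp$y, function(x, y) (x^2 + y^2) / (2 * D))
  resid <- (Q - theo)[bulk]
  expect_lt(stats::sd(resid) / mean(theo[bulk]), 0.01)
})

test_that("Gaussian curvature: closed forms and O(h^2) convergence", {
  h <- 0.05
  x <- seq(-1, 1, by = h)
  bowl <- outer(x, x, function(a, b) (a^2 + b^2) / 2)
  saddle <- outer(x, x, function(a, b) (a^2 - b^2) / 2)
  plane <- outer(x, x, function(a, b) 0.3 + 0.2 * a + 0.7 * b)
  i0 <- which(x == 0)
  expect_equal(gaussian_curvature(bowl, h)$K[i0, i0], 1, tolerance = 1e-10)
  expect_equal(gaussian_curvature(saddle, h)$K[i0, i0], -1,
               tolerance = 1e-10)
  expect_lt(max(abs(gaussian_curvature(plane, h)$K)), 1e-10)
  expect_error(gaussian_curvature(matrix(0, 3, 3), h), "5x5")
  # halving h quarters the interior error on an analytic surface
  kerr <- function(h) {
    x <- seq(-1, 1, by = h)
    Q <- outer(x, x, function(a, b) sin(a) * cos(b))
    K <- gaussian_curvature(Q, h)$K
    Qx <- outer(x, x, function(a, b) cos(a) * cos(b))
    Qy <- outer(x, x, function(a, b) -sin(a) * sin(b))
    Qxx <- outer(x, x, function(a, b) -sin(a) * cos(b))
    Qyy <- Qxx
    Qxy <- outer(x, x, function(a, b) -cos(a) * sin(b))
    Kex <- (Qxx * Qyy - Qxy^2) / (1 + Qx^2 + Qy^2)^2
    n <- length(x)
    inner <- 3:(n - 2)
    max(abs((K - Kex)[inner, inner]))
  }
  e1 <- kerr(0.04)
  e2 <- kerr(0.02)
  expect_lt(e2, e1 / 3.2)  # ~4x reduction expected at second order
})

test_that("gradient-flow drift recovers its potential up to a constant", {
  # drift = -grad U with a double-well U: Q from the Fokker-Planck solve
  # must equal U/D on the density support (detailed balance)
  D <- 0.02
  U <- function(x, y) 0.1 * (x^2 - 1)^2 + 0.15 * y^2
  drift <- function(x, y) cbind(-0.4 * x * (x^2 - 1), -0.3 * y)
  fp <- solve_fokker_planck(drift, D = D, xlim = c(-2, 2), h = 0.02)
  Q <- quasi_potential(fp$P)
  theo <- outer(fp$x, fp$y, U) / D
  sup <- fp$P > 1e-12
  resid <- (Q - theo)[sup]
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)) / diff(range(theo[sup])), 0.03)
})

test_that("landscapes of the projected model: well counts per regime", {
  reg3 <- cached_regions("region_III")
  wells3 <- reg3$components[reg3$components$well, ]
  expect_equal(nrow(wells3), 3L)
  # one symmetric well and a mirror pair of polarized wells
  srf3 <- cached_surface("region_III")
  # Q_bound exceeds the well minimum in every well
  expect_true(all(wells3$Q_bound > wells3$Q_min))
  # region II: a single well (the non-polar state) plus a positive-curvature
  # shoulder pair with one-sided slopes (the ghost area)
  reg2 <- cached_regions("region_II")
  comp2 <- reg2$components
  expect_equal(sum(comp2$well), 1L)
  expect_gte(sum(!comp2$well), 1L)
})

test_that("trajectory classification separates ghost memory from attractors", {
  g2 <- cached_ghost("region_II")
  g3 <- cached_ghost("region_III")
  # region II: after signal removal the trajectory is transiently trapped
  # outside any well (the ghost) before re-entering the non-polar well
  expect_gt(g2$cls$ghost_dwell, 0)
  expect_true("transient" %in% g2$cls$label)
  # region III: the trajectory lands in the polarized well immediately
  expect_equal(g3$cls$ghost_dwell, 0)
  # a trajectory resting at a well minimum is asymptotic throughout
  m <- model_preset("region_III")
  rest <- simulate_projection(m, step_protocol(sL = 0, duration = 60))
  cls_rest <- classify_trajectory(rest, cached_surface("region_III"),
                                  regions = list(cached_regions("region_III")))
  expect_true(all(cls_rest$label == "asymptotic"))
})

test_that("long-run projected SDE histogram matches the stationary density", {
  m <- model_preset("region_I")
  srf <- cached_surface("region_I")
  path <- simulate_projection_sde(m, D = 0.02, dt = 0.01, n_steps = 1e6,
                                  seed = 11, clip = FALSE)
  burn <- 2e4
  ix <- findInterval(path[-(1:burn), 1], srf$x - srf$h / 2)
  iy <- findInterval(path[-(1:burn), 2], srf$y - srf$h / 2)
  ok <- ix >= 1 & ix <= length(srf$x) & iy >= 1 & iy <= length(srf$y)
  H <- matrix(0, length(srf$x), length(srf$y))
  tab <- table(factor(ix[ok], levels = seq_along(srf$x)),
               factor(iy[ok], levels = seq_along(srf$y)))
  H[] <- as.numeric(tab) / sum(tab)
  Pn <- srf$P / sum(srf$P)
  expect_lt(0.5 * sum(abs(H - Pn)), 0.05)
})
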