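# minimal synthetic kymograph for metric arithmetic
fake_kymograph <- function(u, times = seq_len(nrow(u)) - 1,
                           signal = matrix(0, nrow(u), ncol(u))) {
  structure(list(times = times,
                 theta = 2 * pi * (seq_len(ncol(u)) - 1) / ncol(u),
                 fields = list(u = u), signal = signal,
                 model = model_preset("region_II"),
                 domain = domain_spec(N = ncol(u)), protocol = NULL),
            class = "kymograph")
}

test_that("polarization ratio arithmetic", {
  N <- 20
  u <- matrix(1.3, 150, N)
  expect_equal(polarization_ratio(fake_kymograph(u)), 1)
  # front/back-mirrored field gives the reciprocal ratio
  pat <- 1 + 0.5 * cos(2 * pi * (seq_len(N) - 1) / N - pi)
  mir <- pat[1 + ((seq_len(N) - 1 + N / 2) %% N)]
  k1 <- fake_kymograph(matrix(pat, 150, N, byrow = TRUE))
  k2 <- fake_kymograph(matrix(mir, 150, N, byrow = TRUE))
  expect_equal(polarization_ratio(k1), 1 / polarization_ratio(k2))
  # zero back concentration is flagged as infinite
  u0 <- matrix(1, 150, N); u0[, 1] <- 0
  expect_identical(polarization_ratio(fake_kymograph(u0)), Inf)
  # instantaneous ratio at a requested time
  ut <- matrix(1, 150, N); ut[100, 11] <- 3
  expect_equal(polarization_ratio(fake_kymograph(ut), t = 99), 3)
})

test_that("plateau-entry polarization time on constructed traces", {
  N <- 20
  # step-constant trace: entered at the first sample
  u <- matrix(1, 200, N); u[, 11] <- 2
  kym <- fake_kymograph(u)
  kym$protocol <- single_gradient_protocol(on = 0, off = Inf)
  expect_equal(polarization_time(kym, epoch = c(0, 199)), 0)
  # linear ramp to a plateau: band entry computable by hand
  tr <- c(seq(0, 1, length.out = 201), rep(1, 200))  # ramp over 200 s
  u <- matrix(1, 401, N); u[, 11] <- 1 + tr
  kym <- fake_kymograph(u)
  # normalized trace = t/200 during the ramp; plateau mean = 1;
  # |t/200 - 1| <= 0.01 first holds at t = 198 (allow one sample of
  # floating-point slack exactly on the band edge)
  expect_lte(abs(polarization_time(kym, epoch = c(0, 400)) - 198), 1)
  # epochs shorter than the plateau window are a domain error
  expect_error(polarization_time(kym, epoch = c(0, 50)), "100")
})

test_that("half-maximum threshold interpolation recovers known midpoints", {
  doses <- seq(0, 4, by = 0.25)
  logistic <- 6 / (1 + exp(-(doses - 1.7) / 0.08))
  thr <- halfmax_threshold(doses, logistic)
  expect_equal(thr, 1.7, tolerance = 0.25 / 2)
  # invariance under grid refinement within one grid step
  fine <- seq(0, 4, by = 0.05)
  thr_fine <- halfmax_threshold(fine, 6 / (1 + exp(-(fine - 1.7) / 0.08)))
  expect_lt(abs(thr - thr_fine), 0.25)
  # hand-checked interpolation: half-max 2.5 is crossed between the
  # responses 1 (dose 1) and 3 (dose 2): 1 + 1.5/2 = 1.75
  expect_equal(halfmax_threshold(c(1, 2, 3), c(1, 3, 5)), 1.75)
})

test_that("manual threshold conventions for the graded mechanisms", {
  # LEGI and Turing respond smoothly at any dose; the published convention
  # pins their thresholds rather than the 50%-of-max interpolation
  thr_l <- estimate_sd_thresh(model_preset("legi"), sd_grid = c(0.1, 0.5),
                              t_end = 150)
  expect_true(thr_l$manual)
  expect_equal(thr_l$sd_thresh, 0.5)
  thr_t <- estimate_sd_thresh(model_preset("turing"), sd_grid = c(0.1, 0.5),
                              t_end = 150)
  expect_equal(thr_t$sd_thresh, 0.1)
})

test_that("signal integration index follows its defining arithmetic", {
  times <- 0:999
  sig <- as.numeric(times >= 100 & times < 300)  # 200 s of stimulation
  # (traces below anchor 0 and 1 so the internal min-max normalization is
  # the identity and the arithmetic can be checked by hand)
  # essentially never supra-threshold: index = (1 - signal duration)/t_max
  low <- rep(0.3, 1000); low[1] <- 0; low[2] <- 1
  expect_equal(signal_integration_index(low, sig, times), (1 - 200) / 999,
               tolerance = 2 / 999)
  # supra-threshold during the signal plus m seconds of memory: index = m/t_max
  m_mem <- 150
  tr <- as.numeric(times >= 100 & times < 300 + m_mem)
  expect_equal(signal_integration_index(tr, sig, times), m_mem / 999,
               tolerance = 2 / 999)
  # supra-threshold throughout: (t_max - signal)/t_max, pulse count invariant
  hi <- rep(1, 1000); hi[1] <- 0   # normalization anchor
  sig2 <- as.numeric((times >= 100 & times < 200) |
                       (times >= 400 & times < 500))
  expect_equal(signal_integration_index(hi, sig, times),
               (999 - 200) / 999, tolerance = 2 / 999)
  expect_equal(signal_integration_index(hi, sig2, times),
               (999 - 200) / 999, tolerance = 2 / 999)
  # additivity over disjoint supra-threshold intervals
  tr2 <- as.numeric((times >= 100 & times < 350) |
                      (times >= 400 & times < 550))
  idx_joint <- signal_integration_index(tr2, sig2, times)
  expect_equal(idx_joint, (250 + 150 - 200) / 999, tolerance = 2 / 999)
})

test_that("spurious activation: null case, determinism, purity", {
  m <- model_preset("subpb")
  expect_equal(spurious_activation(m, xi_per = 0), 0)
  expect_error(spurious_activation(m, xi_per = 0.1, n_reps = 0), "n_reps")
  # metrics are pure functions of the kymograph
  kym <- region_kymograph("region_II")
  expect_identical(polarization_ratio(kym), polarization_ratio(kym))
  expect_identical(signal_integration_index(kym),
                   signal_integration_index(kym))
})
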