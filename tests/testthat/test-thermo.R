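# PMF construction, minima, standard-state Kd / binding free energy.

RT300 <- dimerscope::GAS_CONSTANT_KCAL * 300

test_that("zero force integrates to a flat PMF with quadrature-accumulated error", {
  r <- seq(2, 6, 0.1)
  prof <- mean_force_profile(r, rep(0, length(r)), rep(0.5, length(r)))
  pmf <- integrate_mean_force(prof, reference_from = 4.6)
  expect_equal(pmf$W, rep(0, length(r)), tolerance = 1e-12)
  # error grows moving inward from the reference edge
  expect_true(all(diff(pmf$error) <= 1e-12))
  expect_equal(pmf$error[length(r)], 0)
  # explicit quadrature formula at the first grid point
  segvar <- (0.1 / 2)^2 * (0.5^2 + 0.5^2)
  expect_equal(pmf$error[1], sqrt(segvar * (length(r) - 1)), tolerance = 1e-9)
})

test_that("a harmonic force integrates to the analytic quadratic well", {
  r <- seq(2, 6, 0.01)
  k <- 3; r0 <- 3.6
  # F = -dW/dr with W = k/2 (r - r0)^2 - const
  prof <- mean_force_profile(r, -k * (r - r0))
  pmf <- integrate_mean_force(prof, reference_from = 5.5)
  Wexp <- k / 2 * (r - r0)^2
  Wexp <- Wexp - mean(Wexp[r >= 5.5])
  expect_equal(pmf$W, Wexp, tolerance = 1e-4)
  expect_error(integrate_mean_force(prof, reference_from = 10), "inside")
  expect_error(mean_force_profile(c(1, 1, 2), c(0, 0, 0)), "increasing")
})

test_that("find_minima reports wells by depth and location", {
  r <- seq(2.6, 6, 0.02)
  single <- synth_mean_force(pmf_plan(depth = 2, center = 3.6))
  pmf <- integrate_mean_force(single$profile)
  m <- find_minima(pmf, depth_min = 0.2)
  expect_equal(nrow(m), 1)
  expect_equal(m$r, 3.6, tolerance = 0.03)
  expect_equal(m$depth, 2, tolerance = 0.05)

  # double well mirroring two shallow minima at 3.2 and 3.6 nm
  W2 <- function(x) -1.2 * exp(-(x - 3.6)^2 / (2 * 0.12^2)) -
    0.8 * exp(-(x - 3.2)^2 / (2 * 0.12^2))
  F2 <- -(W2(r + 1e-6) - W2(r - 1e-6)) / 2e-6
  pmf2 <- integrate_mean_force(mean_force_profile(r, F2))
  m2 <- find_minima(pmf2, depth_min = 0.2)
  expect_equal(m2$r, c(3.2, 3.6), tolerance = 0.03)

  flat <- integrate_mean_force(mean_force_profile(r, rep(0, length(r))))
  expect_equal(nrow(find_minima(flat, depth_min = 0.1)), 0)
})

test_that("square-well Kd matches the closed-form configurational integral", {
  r <- seq(2.6, 6, 0.001)
  eps <- 2.5; lo <- 3.3; hi <- 3.9
  W <- ifelse(r >= lo & r <= hi, -eps, 0)
  pmf <- structure(list(r = r, W = W, error = rep(0, length(r)),
                        reference_window = c(4.6, 6)), class = "PMFProfile")
  est <- kd_from_pmf(pmf, bound_window = c(lo, hi), temperature = 300)
  # analytic: Ka = (4 pi / 3)(hi^3 - lo^3) e^{eps/RT} / V0
  ka <- 4 * pi / 3 * (hi^3 - lo^3) * exp(eps / RT300) /
    dimerscope::STANDARD_STATE_VOLUME_NM3
  expect_equal(est$kd, 1 / ka, tolerance = 1e-3)

  # W == 0 limit: the pure volume-entropy value from the same formula
  pmf0 <- structure(list(r = r, W = rep(0, length(r)),
                         error = rep(0, length(r)),
                         reference_window = c(4.6, 6)), class = "PMFProfile")
  est0 <- kd_from_pmf(pmf0, bound_window = c(lo, hi))
  ka0 <- 4 * pi / 3 * (hi^3 - lo^3) / dimerscope::STANDARD_STATE_VOLUME_NM3
  expect_equal(est0$kd, 1 / ka0, tolerance = 1e-3)
})

test_that("an unflat reference window is rejected with advice", {
  r <- seq(2.6, 6, 0.05)
  prof <- mean_force_profile(r, rep(-0.5, length(r)))  # constant pull
  pmf <- integrate_mean_force(prof)
  expect_error(kd_from_pmf(pmf), "not flat")
})

test_that("Kd is invariant to adding a constant to W before re-referencing", {
  fx <- synth_mean_force(pmf_plan(depth = 2))
  pmf <- integrate_mean_force(fx$profile)
  est1 <- kd_from_pmf(pmf)
  shifted <- pmf
  shifted$W <- shifted$W + 7.5
  shifted$W <- shifted$W - mean(shifted$W[shifted$r >= 4.6])
  expect_equal(kd_from_pmf(shifted)$kd, est1$kd, tolerance = 1e-12)
})

test_that("deepening the well strictly decreases Kd; grid refinement is converged", {
  kds <- vapply(c(0.5, 1, 2, 3, 4), function(d) {
    fx <- synth_mean_force(pmf_plan(depth = d))
    kd_from_pmf(integrate_mean_force(fx$profile),
                bound_window = c(3.0, 4.2))$kd
  }, numeric(1))
  expect_true(all(diff(kds) < 0))

  k1 <- kd_from_pmf(integrate_mean_force(
    synth_mean_force(pmf_plan(depth = 2, dr = 0.02))$profile),
    bound_window = c(3.0, 4.2))$kd
  k2 <- kd_from_pmf(integrate_mean_force(
    synth_mean_force(pmf_plan(depth = 2, dr = 0.01))$profile),
    bound_window = c(3.0, 4.2))$kd
  expect_lt(abs(k1 - k2) / k2, 0.005)
})

test_that("Kd <-> deltaG conversions reproduce the canonical weak-dimer pairs", {
  expect_equal(dg_from_kd(1), 0)
  expect_equal(dg_from_kd(5e-3, 300), -3.1, tolerance = 0.1)
  expect_equal(dg_from_kd(0.107, 300), -1.3, tolerance = 0.05)
  # round trip at machine precision
  for (kd in c(1e-9, 5e-3, 0.107, 2)) {
    expect_equal(kd_from_dg(dg_from_kd(kd)), kd, tolerance = 1e-12)
  }
  expect_error(dg_from_kd(-1), "positive")
})

test_that("fold ratio: 107 mM vs 5 mM is ~20-fold and survives round trips", {
  e1 <- list(kd = 5e-3, temperature = 300)
  e2 <- list(kd = 0.107, temperature = 300)
  expect_equal(fold_ratio(e1, e1), 1)
  expect_equal(fold_ratio(e1, e2), 21.4)
  expect_equal(round(fold_ratio(e1, e2) / 10) * 10, 20)
  rt1 <- list(kd = kd_from_dg(dg_from_kd(5e-3)), temperature = 300)
  expect_equal(fold_ratio(rt1, e2), fold_ratio(e1, e2), tolerance = 1e-12)
  expect_error(fold_ratio(e1, list(kd = 1, temperature = 310)),
               "temperature")
})

test_that("profiles round-trip through TSV", {
  fx <- synth_mean_force(pmf_plan(depth = 1.5, noise_sd = 0.3, seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(fx$profile, path)
  back <- read_mean_force(path)
  expect_equal(back$r, fx$profile$r)
  expect_equal(back$force, fx$profile$force, tolerance = 1e-9)
  expect_equal(back$stderr, fx$profile$stderr)
})
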