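test_that("anisotropy map implements the pump-probe ratio with masking", {
  o <- seq(100, 500, 100)
  base <- matrix(10, 5, 5)
  sp <- make_spectrum2d(o, o, 3 * base, scheme = "parallel")
  ss <- make_spectrum2d(o, o, base, scheme = "perpendicular")
  m <- anisotropy_map(sp, ss)
  expect_true(all(m$r == 0.4))
  ## equal intensities -> 0; inverted ratio -> -0.2
  expect_true(all(anisotropy_map(make_spectrum2d(o, o, base),
                                 make_spectrum2d(o, o, base))$r == 0))
  expect_true(all(anisotropy_map(make_spectrum2d(o, o, base),
                                 make_spectrum2d(o, o, 2 * base))$r == -0.2))
  ## near-zero denominators are masked, not divided
  par <- base; perp <- base
  par[3, 3] <- 0.04; perp[3, 3] <- -0.015   # |par + 2 perp| = 1% of max
  m <- anisotropy_map(make_spectrum2d(o, o, par), make_spectrum2d(o, o, perp))
  expect_true(is.na(m$r[3, 3]))
  expect_equal(sum(is.na(m$r)), 1L)
  ## mismatched axes and waiting times are errors
  expect_error(anisotropy_map(make_spectrum2d(o + 1, o, base),
                              make_spectrum2d(o, o, base)), "axes")
  expect_error(anisotropy_map(make_spectrum2d(o, o, base, t2 = 0),
                              make_spectrum2d(o, o, base, t2 = 24)),
               "waiting")
})

test_that("anisotropy is scale invariant and consistent under channel swap", {
  o <- seq(1, 4)
  set.seed(2)
  par <- matrix(abs(rnorm(16)) + 0.5, 4)
  perp <- matrix(abs(rnorm(16)) + 0.5, 4)
  m1 <- anisotropy_map(make_spectrum2d(o, o, par), make_spectrum2d(o, o, perp),
                       mask_threshold = 0)
  m2 <- anisotropy_map(make_spectrum2d(o, o, par * 137.2),
                       make_spectrum2d(o, o, perp * 137.2), mask_threshold = 0)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  ## swapping the schemes maps r -> -r / (1 + ... ) per the defining algebra
  ms <- anisotropy_map(make_spectrum2d(o, o, perp), make_spectrum2d(o, o, par),
                       mask_threshold = 0)
  expect_equal(ms$r, (perp - par) / (perp + 2 * par), tolerance = 1e-12)
  ## r stays within the mathematical bounds for positive intensities
  expect_true(all(m1$r > -0.5 & m1$r < 1))
})

test_that("diagonal anisotropy spectrum drops masked points", {
  o <- seq(10, 50, 10)
  par <- matrix(3, 5, 5); perp <- matrix(1, 5, 5)
  par[2, 2] <- 1e-4; perp[2, 2] <- -5e-5
  m <- anisotropy_map(make_spectrum2d(o, o, par), make_spectrum2d(o, o, perp))
  d <- anisotropy_spectrum_diagonal(m)
  expect_equal(d$omega, o[-2])
  expect_true(all(d$r == 0.4))
  ## fully masked diagonal errors
  m$r[] <- NA_real_
  expect_error(anisotropy_spectrum_diagonal(m), "masked")
})

test_that("traces pick the nearest grid point and report masked times", {
  o <- seq(100, 300, 100)
  mk <- function(t2, v) {
    par <- matrix(3 * v, 3, 3); perp <- matrix(v, 3, 3)
    anisotropy_map(make_spectrum2d(o, o, par, t2 = t2),
                   make_spectrum2d(o, o, perp, t2 = t2))
  }
  maps <- list(mk(0, 1), mk(24, 1), mk(48, 1))
  tr <- anisotropy_trace(maps, c(140, 310))
  expect_equal(unname(tr$point), c(100, 300))
  expect_equal(tr$r_values, rep(0.4, 3))
  maps[[2]]$r[1, 3] <- NA_real_
  expect_error(anisotropy_trace(maps, c(140, 310)), "t2 = 24")
})

test_that("exponential fits recover synthetic decay constants", {
  t2 <- seq(0, 336, 24)
  ## noise-free tau = 500 fs, fixed zero offset: recovered within 1 fs
  tr <- fit_exponential(make_trace(t2, 0.4 * exp(-t2 / 500)),
                        fixed_r_inf = 0)
  expect_true(tr$fit$fit_ok)
  expect_equal(tr$fit$tau, 500, tolerance = 1e-3)
  expect_equal(tr$fit$r0, 0.4, tolerance = 1e-6)
  ## floating offset
  tr <- fit_exponential(make_trace(t2, 0.1 + 0.3 * exp(-t2 / 500)))
  expect_true(tr$fit$fit_ok)
  expect_equal(tr$fit$tau, 500, tolerance = 1e-3)
  expect_equal(tr$fit$r_inf, 0.1, tolerance = 1e-6)
  ## noisy parameter recovery: mean of 20 replicates within 10%
  set.seed(99)
  taus <- replicate(20, {
    r <- 0.4 * exp(-t2 / 500) + rnorm(length(t2), 0, 0.01)
    fit_exponential(make_trace(t2, r), fixed_r_inf = 0, t2_min = 0)$fit$tau
  })
  expect_lt(abs(mean(taus) - 500) / 500, 0.1)
})

test_that("flat and degenerate traces are flagged, never thrown", {
  t2 <- seq(0, 336, 24)
  tr <- fit_exponential(make_trace(t2, rep(0.4, length(t2))))
  expect_false(tr$fit$fit_ok)
  expect_match(tr$fit$reason, "no decay")
  ## decay below the amplitude threshold
  tr <- fit_exponential(make_trace(t2, 0.39 + 0.015 * exp(-t2 / 200)))
  expect_false(tr$fit$fit_ok)
  ## pathological trace: no exception, fit_ok FALSE or finite tau
  tr <- fit_exponential(make_trace(t2, c(0.4, rep(0.1, 7), rep(0.35, 7))))
  expect_type(tr$fit$fit_ok, "logical")
  expect_error(fit_exponential(make_trace(t2[1:3], c(0.4, 0.3, 0.2))),
               "4 waiting")
})

test_that("cross-peak anisotropy follows (3 cos^2 theta - 1)/5", {
  ## two uncoupled transitions at angle theta; the transfer-free (GSB)
  ## cross peak carries the textbook photoselection anisotropy.  A pure
  ## Gaussian window over a long coherence grid keeps the diagonal peaks
  ## from leaking onto the cross peak (no Lorentzian tails, no
  ## truncation ringing).
  for (theta in c(0, 30, 54.7356, 90)) {
    th <- theta * pi / 180
    pos <- rbind(c(0, 0, 0), c(600, 0, 0))
    dip <- rbind(c(0, 0, 1), c(sin(th), 0, cos(th)))
    agg <- make_aggregate(pos, dip)
    ht <- frozen_ht(agg, n_steps = 260)
    ht$dE[1, ] <- -400; ht$dE[2, ] <- 400
    ht$J[] <- 0
    grid <- grid_spec(t1_max = 512, t3_max = 512, t2_values = 0)
    resp <- apodize(twod_response(ht, grid, pathways = "GSB", n_samples = 1),
                    apodization_spec(tau_homo = 1e9, tau_inhomo = 60))
    sp <- spectrum_2d(resp, 0, "parallel")
    ss <- spectrum_2d(resp, 0, "perpendicular")
    i1 <- which.min(abs(sp$omega1 - (15390 - 400)))
    i2 <- which.min(abs(sp$omega3 - (15390 + 400)))
    r_cross <- (sp$map[i1, i2] - ss$map[i1, i2]) /
      (sp$map[i1, i2] + 2 * ss$map[i1, i2])
    expect_equal(r_cross, (3 * cos(th)^2 - 1) / 5, tolerance = 1e-6)
  }
})

test_that("pipeline-generated diagonal anisotropies stay in the physical band", {
  agg <- build_cylinder(preset_cylinder("system1-like", 24, seed = 9))
  grid <- grid_spec(t1_max = 96, t3_max = 96, t2_values = c(0, 24))
  resp <- averaged_response(agg, grid, seed = 21, n_samples = 2,
                            n_realizations = 2)
  for (m in maps_of(resp)) {
    d <- anisotropy_spectrum_diagonal(m)
    expect_true(all(d$r >= -0.22 & d$r <= 0.42))
  }
})
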