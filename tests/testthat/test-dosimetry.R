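test_that("buildup-tail shape evaluates the quadratic-times-exponential form", {
  expect_equal(buildup_tail_raw(0, 2, 0.05), 0)
  expect_equal(buildup_tail_raw(1, 1, 1e-300), 0.5)
  d <- c(0.5, 2, 10, 30); n <- 4; mu <- 0.05
  expect_equal(buildup_tail_raw(d, n, mu), d / (d^2 + n) * exp(-mu * d),
               tolerance = 1e-15)
  expect_error(buildup_tail_raw(-1, 2, 0.05), ">= 0")
})

test_that("the dose peak is located to high precision", {
  # vanishing attenuation: the peak of d/(d^2+n) sits at sqrt(n)
  expect_equal(find_dmax(4, 1e-9), 2, tolerance = 1e-4)
  # grid-scan oracle
  grid <- seq(0.001, 10, by = 1e-4)
  d_scan <- grid[which.max(buildup_tail_raw(grid, 2.25, 0.04))]
  expect_equal(find_dmax(2.25, 0.04), d_scan, tolerance = 1e-4)
  # harder attenuation pulls the peak toward the surface
  dm <- vapply(c(0.01, 0.03, 0.1, 0.3), function(mu) find_dmax(4, mu),
               numeric(1))
  expect_true(all(diff(dm) <= 1e-9))
})

test_that("PDD is normalised at its own peak and decays beyond it", {
  m <- pdd_model(n = 2.25, mu = 0.0465)
  expect_equal(pdd(m$dmax, m), 100)
  expect_equal(pdd(0, m), 0)
  d <- seq(m$dmax, 40, length.out = 200)
  p <- pdd(d, m)
  expect_true(all(p <= 100 + 1e-9))
  expect_true(all(diff(p) < 0))
  expect_equal(pdd(2 * m$dmax, m),
               100 * buildup_tail_raw(2 * m$dmax, m$n, m$mu) /
                 buildup_tail_raw(m$dmax, m$n, m$mu))
})

test_that("SSD-explicit PDD and the Mayneord factor are mutually consistent", {
  m <- pdd_model(n = 2.25, mu = 0.046)
  cal <- machine_calibration(Ks = 1)
  expect_equal(pdd_at_ssd(m$dmax, 100, m, cal), 100)
  # arithmetic instance
  expect_equal(pdd_at_ssd(11.5, 100, m, cal),
               100 * ((100 + m$dmax) / (100 + 11.5))^2 *
                 exp(-0.046 * (11.5 - m$dmax)))
  # the SSD2/SSD1 ratio IS the Mayneord factor, to machine precision
  set.seed(12)
  for (i in 1:25) {
    s1 <- runif(1, 60, 120); s2 <- runif(1, 60, 120); d <- runif(1, 0.1, 35)
    expect_equal(pdd_at_ssd(d, s2, m, cal) / pdd_at_ssd(d, s1, m, cal),
                 mayneord_factor(s1, s2, d, m$dmax), tolerance = 1e-12)
  }
  expect_equal(mayneord_factor(90, 90, 10, 1.5), 1)
  expect_equal(mayneord_factor(80, 100, 1.5, 1.5), 1)
  expect_equal(mayneord_factor(80, 100, 10, 1.5),
               ((100 + 1.5) / (80 + 1.5))^2 * ((80 + 10) / (100 + 10))^2,
               tolerance = 1e-12)
  # reciprocity and the beyond-peak direction of the correction
  expect_equal(mayneord_factor(80, 100, 10, 1.5) *
                 mayneord_factor(100, 80, 10, 1.5), 1, tolerance = 1e-12)
  expect_gt(mayneord_factor(80, 100, 10, 1.5), 1)
})

test_that("effective depth scales each segment by its eta", {
  seg <- data.frame(label = c(1L, 2L), t_in = c(0, 30), t_out = c(30, 70),
                    z = c(30, 40), eta = c(1, 0.275), zeff = c(30, 11))
  # 3 cm soft tissue + 4 cm lung -> 3 + 4 * 0.275 = 4.1 cm
  expect_equal(effective_depth(seg, 70), 4.1)
  # water-equivalent everywhere: effective equals geometric
  seg1 <- transform(seg, eta = 1)
  expect_equal(effective_depth(seg1, 70), 7)
  # monotone in the target position; gaps count as water
  gap <- data.frame(label = c(1L, 1L), t_in = c(0, 50), t_out = c(20, 80),
                    eta = c(1, 1))
  expect_equal(effective_depth(gap, 80), 8)
  ds <- vapply(seq(5, 70, by = 5), function(u) effective_depth(seg, u),
               numeric(1))
  expect_true(all(diff(ds) >= 0))
  expect_error(effective_depth(seg, -5), "before the body entry")
  # nested-sphere lateral beam against closed-form chords
  tum <- make_ellipsoid_mesh(c(0, 0, 0), c(15, 15, 15), 4)
  lung <- make_ellipsoid_mesh(c(0, 0, 0), c(60, 60, 60), 4)
  body <- make_ellipsoid_mesh(c(0, 0, 0), c(150, 150, 150), 4)
  organs <- list(list(label = 1L, mesh = body, eta = 1),
                 list(label = 2L, mesh = lung, eta = 0.275),
                 list(label = 3L, mesh = tum, eta = 1))
  segs <- trace_beam(ray(c(-400, 0, 0), c(1, 0, 0)), organs)
  # to the common centre: 90 mm water + 45 mm lung + 15 mm tumour
  expect_equal(effective_depth(segs, 400), (90 + 45 * 0.275 + 15) / 10,
               tolerance = 1e-3)
})

test_that("monitor units convert linearly to dose with the SSD correction", {
  cal <- machine_calibration(Dref = 1, dref = 10, SSD0 = 100)
  expect_equal(ssd_factor(100, cal), 1)
  expect_equal(ssd_factor(110, cal), (110 / 120)^2)
  expect_equal(ssd_factor(1e9, cal), 0, tolerance = 1e-12)
  expect_equal(ssd_factor(110, cal, exponent = 1), 110 / 120)
  expect_equal(dose_at_point(100, cal, 100, 100), 100)
  expect_equal(dose_at_point(100, cal, 50, 100), 50)
  expect_equal(dose_at_point(200, cal, 73, 95),
               2 * dose_at_point(100, cal, 73, 95))
  cal2 <- machine_calibration(Dref = 0.8, Scrc = 0.97, Spr = 1.02)
  expect_equal(dose_at_point(150, cal2, 64.2, 92),
               150 * 0.8 * 0.642 * 0.97 * 1.02 * ssd_factor(92, cal2),
               tolerance = 1e-12)
})

test_that("buildup-tail parameters are recoverable from sampled curves", {
  truth <- pdd_model(n = 2.25, mu = 0.0465)
  d <- seq(0.2, 25, length.out = 50)
  clean <- sample_pdd_curve(truth, d, noise_sd = 0)
  f0 <- fit_pdd(clean, init = c(n = 2, mu = 0.05))
  expect_lt(abs(f0$n - 2.25) / 2.25, 1e-4)
  expect_lt(abs(f0$mu - 0.0465) / 0.0465, 1e-4)
  noisy <- sample_pdd_curve(truth, d, noise_sd = 0.01, seed = 7)
  f1 <- fit_pdd(noisy, init = c(n = 2, mu = 0.05))
  expect_lt(abs(f1$n - 2.25) / 2.25, 0.05)
  expect_lt(abs(f1$mu - 0.0465) / 0.0465, 0.05)
  expect_gt(attr(f1, "rms"), 0)
  # unidentifiable: all samples at one depth
  flat <- data.frame(depth_cm = rep(5, 6), pdd_pct = rep(80, 6))
  expect_error(fit_pdd(flat), "fit-failure")
})

test_that("material maps default unlisted labels to water", {
  eta <- material_map(c(`2` = 0.275, `4` = 1.05))
  expect_equal(eta(c(1, 2, 4, 9)), c(1, 0.275, 1.05, 1))
  expect_error(material_map(c(`1` = -2)), "positive")
})
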