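test_that("straight-line limit: no scattering means no deflection", {
  g <- scanner_geometry()
  ev <- transport_beam(g, NULL, E0 = 200, n = 5, mcs = FALSE,
                       straggling = FALSE, seed = 1)
  expect_true(all(ev$flag == "ok"))
  expect_equal(ev$u4, ev$u1)
  expect_equal(ev$v4, ev$v1)
  expect_equal(ev$x4, rep(0, 5))
  # E_out = E_in minus the tracker/air losses only, identical for all
  expect_true(all(ev$E_out < ev$E_in))
  expect_equal(length(unique(ev$E_out)), 1L)
  expect_equal(ev$wepl_true[1], wepl_calibration(g, 200), tolerance = 1e-9)
})

test_that("energy bookkeeping matches the summed water-equivalent slabs", {
  g <- scanner_geometry()
  ev <- transport_beam(g, phantom(), E0 = 200, n = 200, beam = "flat",
                       mcs = TRUE, straggling = FALSE, seed = 3)
  ok <- ev$flag == "ok"
  expect_gt(sum(ok), 150)
  lhs <- csda_range("water", ev$E_in[ok]) - csda_range("water", ev$E_out[ok])
  expect_lt(max(abs(lhs - ev$wepl_true[ok]) / pmax(ev$wepl_true[ok], 0.1)),
            0.005)
})

test_that("Monte-Carlo WEPL agrees with the analytic chord integral", {
  g <- scanner_geometry()
  ph <- water_phantom(R = 30)
  ev <- transport_beam(g, ph, E0 = 200, n = 2000, beam = "pencil", offset = 0,
                       mcs = TRUE, straggling = FALSE, seed = 4)
  w_mc <- mean(wepl_from_energies(ev$E_in, ev$E_out) - wepl_calibration(g, 200),
               na.rm = TRUE)
  w_an <- analytic_wepl(ph, 0, 0)
  expect_lt(abs(w_mc - w_an) / w_an, 0.005)
})

test_that("higher beam energy scatters less", {
  g <- scanner_geometry()
  e200 <- transport_beam(g, NULL, 200, 5000, mcs = TRUE, straggling = FALSE,
                         seed = 5)
  e250 <- transport_beam(g, NULL, 250, 5000, mcs = TRUE, straggling = FALSE,
                         seed = 5)
  expect_lt(sd(e250$x4), sd(e200$x4))
  expect_gt(count_unscattered(e250), count_unscattered(e200))
})

test_that("unscattered-count estimator is binomial and beam is symmetric", {
  g <- scanner_geometry()
  n <- 2e4
  f <- vapply(c(11, 23), function(s) {
    ev <- transport_beam(g, NULL, 200, n, mcs = TRUE, straggling = FALSE,
                         seed = s)
    count_unscattered(ev) / n
  }, numeric(1))
  p <- mean(f)
  expect_lt(abs(f[1] - f[2]), 3 * sqrt(2 * p * (1 - p) / n))
  # lateral exit distribution centred on the axis within 3 standard errors
  ev <- transport_beam(g, NULL, 200, n, mcs = TRUE, straggling = FALSE,
                       seed = 31)
  expect_lt(abs(mean(ev$x4)), 3 * sd(ev$x4) / sqrt(n))
})

test_that("all-MCS-off run counts every proton as unscattered", {
  g <- scanner_geometry()
  ev <- transport_beam(g, NULL, 200, 500, mcs = FALSE, straggling = FALSE)
  expect_equal(count_unscattered(ev), 500L)
})

test_that("sweeps have the right shape and trends", {
  # single-point grids
  s1 <- sweep_thickness(0.2, E = 200, n = 2000, seed = 2)
  expect_equal(nrow(s1), 1L)
  s2 <- sweep_interval(50, E = 200, n = 2000, seed = 2)
  expect_equal(nrow(s2), 1L)
  expect_true(all(s1$fraction >= 0 & s1$fraction <= 1))
  # thinner strips scatter less (endpoints of the sweep)
  st <- sweep_thickness(c(0.01, 0.2, 1.0), E = 200, n = 5000, seed = 7)
  expect_gt(st$count[1], st$count[3])
  expect_true(all(diff(st$spread_mm) > 0))
  # counts fall and spread grows as the lever arm grows
  si <- sweep_interval(c(10, 70, 200), E = 200, n = 5000, seed = 8)
  expect_true(all(diff(si$count) < 0))
  expect_true(all(diff(si$spread_mm) > 0))
  # higher energy keeps more protons at every interval
  si250 <- sweep_interval(c(10, 70, 200), E = 250, n = 5000, seed = 8)
  expect_true(all(si250$count > si$count))
})

test_that("scan acquisition is reproducible and spans the circle", {
  g <- scanner_geometry()
  ph <- toy_phantom()
  ev1 <- acquire_scan(g, ph, E = 200, n_angles = 4, step_deg = 90,
                      protons_per_angle = 300, seed = 11)
  ev2 <- acquire_scan(g, ph, E = 200, n_angles = 4, step_deg = 90,
                      protons_per_angle = 300, seed = 11)
  expect_identical(ev1, ev2)
  expect_equal(sort(unique(ev1$angle)), c(0, 90, 180, 270))
  expect_equal(nrow(ev1), 1200L)
  # 180 projections at 2 degrees span 360 degrees
  a <- (seq_len(180) - 1) * 2
  expect_equal(max(a) + 2, 360)
  # empty request
  expect_equal(nrow(acquire_scan(g, ph, n_angles = 0)), 0L)
  expect_equal(nrow(acquire_scan(g, ph, n_angles = 2, protons_per_angle = 0)), 0L)
})

test_that("protons that exhaust their range are flagged stopped", {
  g <- scanner_geometry(phantom_gap = 600)
  # 600 mm of water far exceeds the ~26 cm range of a 200 MeV proton
  big <- phantom(body_radius = 290,
                 inserts = data.frame(material = character(0), x = numeric(0),
                                      y = numeric(0), radius = numeric(0),
                                      label = character(0)))
  ev <- transport_beam(g, big, E0 = 200, n = 20, beam = "pencil",
                       mcs = FALSE, straggling = FALSE, seed = 1)
  expect_true(all(ev$flag == "stopped"))
  expect_true(all(is.na(ev$E_out)))
})
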