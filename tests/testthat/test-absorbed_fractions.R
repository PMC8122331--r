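test_that("csda_range reproduces tabulated values and is monotone", {
  # spot checks against the embedded reference rows
  expect_equal(csda_range(100, "electron"), 1.431e-2)
  expect_equal(csda_range(1000, "electron"), 4.367e-1)
  expect_equal(csda_range(5000, "alpha"), 3.55e-3)
  E <- c(0.1, 1, 5, 20, 100, 500, 2000)
  expect_true(all(diff(csda_range(E, "electron")) > 0))
  # range vanishes with energy
  expect_lt(csda_range(1e-3, "electron"), 1e-9)
  expect_error(csda_range(0, "electron"), "positive")
  expect_error(csda_range(-5, "alpha"), "positive")
})

test_that("energy_from_range inverts csda_range", {
  E <- c(0.5, 2, 15, 80, 350, 1500)
  expect_equal(energy_from_range(csda_range(E, "electron"), "electron"), E,
               tolerance = 1e-6)
  Ea <- c(600, 3000, 8377)
  expect_equal(energy_from_range(csda_range(Ea, "alpha"), "alpha"), Ea,
               tolerance = 1e-6)
  expect_identical(energy_from_range(0, "electron"), 0)
})

test_that("simulate_phi obeys the containment limits and is reproducible", {
  # 100 keV electron, range 0.0143 cm: a 2 cm sphere contains nearly all
  big <- simulate_phi(100, "electron", 2, histories = 5000, seed = 7)
  expect_gt(big$phi, 1 - 3 * max(big$se, 1e-4) - 0.02)
  expect_lte(big$phi, 1)
  # a sphere far smaller than the range absorbs almost nothing
  small <- simulate_phi(1000, "electron", 1e-4, histories = 5000, seed = 7)
  expect_lt(small$phi, 0.02)
  again <- simulate_phi(100, "electron", 2, histories = 5000, seed = 7)
  expect_identical(big$phi, again$phi)
  expect_error(simulate_phi(100, "electron", -1, seed = 1), "positive")
  expect_error(simulate_phi(100, "electron", 1, histories = 10), "1000")
})

test_that("energy is conserved history by history", {
  res <- simulate_phi(447, "electron", 0.05, histories = 2000, seed = 3,
                      keep_histories = TRUE)
  dep <- attr(res, "deposited_keV")
  esc <- attr(res, "escaped_keV")
  expect_equal(dep + esc, rep(447, 2000), tolerance = 1e-9)
  expect_true(all(dep >= 0), all(esc >= 0))
})

test_that("Monte Carlo phi agrees with the chord-length oracle", {
  energies <- c(10, 50, 150, 447, 1640)
  for (E in energies) {
    R <- csda_range(E, "electron")
    for (r in R * c(0.3, 1, 3)) {
      mc <- simulate_phi(E, "electron", r, histories = 20000, seed = 11)
      oracle <- chord_oracle_phi(E, "electron", r)
      expect_lt(abs(mc$phi - oracle), 3 * mc$se + 1e-3,
                label = sprintf("E=%g r=%g", E, r))
    }
  }
})

test_that("the chord oracle has the right asymptotics", {
  # short range: loss is O(range/radius)
  E <- 20; R <- csda_range(E, "electron")
  expect_gt(chord_oracle_phi(E, "electron", 100 * R), 0.99)
  phis <- vapply(R * c(0.5, 1, 2, 5, 20), function(r)
    chord_oracle_phi(E, "electron", r), numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_true(all(phis >= 0 & phis <= 1))
})

test_that("phi grids are bounded, monotone in radius, and reproducible", {
  g <- fixture_grid()
  expect_true(all(g$phi >= 0 & g$phi <= 1))
  # non-decreasing in radius per line, allowing Monte Carlo jitter
  for (j in seq_len(nrow(g$lines))) {
    expect_true(all(diff(g$phi[, j]) > -4 * max(g$se[, j])),
                label = paste("line", j))
  }
  g2 <- build_phi_grid(fixture_records("177Lu"), histories = 1500, seed = 5)
  g3 <- build_phi_grid(fixture_records("177Lu"), histories = 1500, seed = 5)
  expect_identical(g2$phi, g3$phi)
})

test_that("aggregated electron phi at small radii orders 161Tb > 177Lu > 131I > 90Y", {
  g <- fixture_grid()
  for (r in c(0.01, 0.05)) {
    agg <- vapply(c("161Tb", "177Lu", "131I", "90Y"), function(nm) {
      rec <- load_radionuclide(nm)
      mean_absorbed_energy(rec, r, g) / total_charged_energy(rec)
    }, numeric(1))
    expect_true(all(diff(agg) < 0), label = paste("r =", r))
  }
})

test_that("mean absorbed energy is bounded and behaves with radius and weight", {
  g <- fixture_grid()
  tb <- load_radionuclide("161Tb")
  expect_lte(mean_absorbed_energy(tb, 2.5, g), total_charged_energy(tb))
  expect_gt(mean_absorbed_energy(tb, 2.5, g), mean_absorbed_energy(tb, 0.1, g))
  y <- load_radionuclide("90Y")
  expect_lt(mean_absorbed_energy(y, 0.01, g), 0.2 * mean_absorbed_energy(y, 2.5, g))
  ac <- load_radionuclide("225Ac")
  e1 <- mean_absorbed_energy(ac, 0.2, g, weight_alpha = 1)
  e5 <- mean_absorbed_energy(ac, 0.2, g, weight_alpha = 5)
  el <- load_radionuclide("225Ac")
  el$lines <- el$lines[el$lines$particle_class != "alpha", ]
  e_el <- mean_absorbed_energy(el, 0.2, g)
  expect_equal(e5 - e_el, 5 * (e1 - e_el), tolerance = 1e-9)
  expect_error(mean_absorbed_energy(tb, 10, g), "hull")
  expect_error(mean_absorbed_energy(tb, 1e-6, g), "hull")
})

test_that("phi grids round-trip through CSV with their metadata", {
  g <- build_phi_grid(fixture_records("161Tb"), histories = 1500, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_phi_grid(g, f)
  g2 <- read_phi_grid(f)
  expect_equal(g2$phi, g$phi, tolerance = 1e-12)
  expect_equal(g2$radii_cm, g$radii_cm, tolerance = 1e-12)
  expect_identical(g2$histories, g$histories)
  expect_identical(g2$seed, g$seed)
})
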