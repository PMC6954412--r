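# Dipolar frequencies, time-trace calculation against the analytic
# Fredholm kernel, offset sums, depth fitting, and symmetry properties.

test_that("dipolar frequency has the magic-angle zero, r^-3 scaling and the constants value", {
  th_magic <- acos(1 / sqrt(3))
  expect_equal(dipolar_frequency(3.7, th_magic), 0, tolerance = 1e-10)
  expect_equal(dipolar_frequency(4, 0.3) / dipolar_frequency(2, 0.3), 1 / 8,
               tolerance = 1e-12)
  # independent constants oracle: mu0 muB^2 g^2 / (4 pi h r^3) at theta = 90
  muB <- 9.2740100783e-24; h <- 6.62607015e-34
  D_oracle <- 1e-7 * muB^2 * 2.0023^2 / h * 1e21     # MHz nm^3
  expect_equal(dipolar_frequency(2, pi / 2, D = dipolar_constant(2.0023)),
               D_oracle / 8, tolerance = 1e-6)
  expect_equal(dipolar_constant(2.0023), 52.04, tolerance = 0.01)
  expect_error(dipolar_frequency(-1, 0), "positive")
})

test_that("ideal-excitation single-distance trace equals the analytic dipolar kernel", {
  ens <- as_ensemble(axis_pair(3.7))
  st <- peldor_settings("X", n_orient = 4000, t_us = seq(0, 1.8, by = 0.03))
  tr <- calc_time_trace(ens, st, excitation = "ideal")
  expect_equal(tr$V[1], 1)
  # independent oracle: adaptive quadrature of the Fredholm kernel
  kern <- vapply(st$t_us, function(t)
    stats::integrate(function(x) cos(2 * pi * st$D / 3.7^3 * (1 - 3 * x^2) * t),
                     0, 1, rel.tol = 1e-10)$value, numeric(1))
  expect_lt(sqrt(mean((tr$V - kern)^2)), 1e-3)
})

test_that("suppressed pump or magic-angle geometry leaves the trace flat", {
  ens <- as_ensemble(axis_pair(3.7))
  st <- peldor_settings("X", n_orient = 500, t_us = seq(0, 1, by = 0.05))
  # pump far outside the spectrum: no pumped partners, no modulation
  tr <- calc_time_trace(ens, st, pump_MHz = 1e5, probe_MHz = 40)
  expect_equal(tr$V, rep(1, length(st$t_us)), tolerance = 1e-6)
  # single field orientation at the magic angle from u: zero dipolar
  # frequency, so even ideal excitation gives a flat trace
  th <- acos(1 / sqrt(3))
  st1 <- peldor_settings("X", n_orient = 1, t_us = seq(0, 1, by = 0.05))
  b1 <- as.numeric(sphere_grid(1))
  perp <- pracma::cross(b1, c(0, 0, 1))
  if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
  u_m <- as.numeric(rotation_about_axis(perp, th * 180 / pi) %*% b1)
  frA <- nitroxide_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  frB <- nitroxide_frame(37 * u_m, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  trm <- calc_time_trace(as_ensemble(spin_pair(frA, frB)), st1,
                         excitation = "ideal")
  expect_equal(trm$V, rep(1, length(st1$t_us)), tolerance = 1e-9)
})

test_that("trace values stay within the modulation-depth bounds", {
  base <- place_labels_on_helix(helix_spec())
  ens <- generate_ensemble(base, n = 40, seed = 2)
  st <- peldor_settings("X", n_orient = 600)
  tr <- calc_time_trace(ens, st, pump_MHz = 0, probe_MHz = 55)
  expect_true(all(tr$V <= 1 + 0.05))
  expect_true(all(tr$V >= 1 - 2 * tr$lambda - 0.05))
})

test_that("offset sums renormalize and single-trace sums are identities", {
  ens <- as_ensemble(axis_pair(3.6))
  st <- peldor_settings("X", n_orient = 400, t_us = seq(0, 1, by = 0.05))
  tr <- calc_time_trace(ens, st, pump_MHz = 0, probe_MHz = 40)
  expect_equal(sum_offsets(list(tr))$V, tr$V, tolerance = 1e-12)
  expect_equal(sum_offsets(list(tr, tr, tr))$V, tr$V, tolerance = 1e-12)
  tr2 <- calc_time_trace(ens, peldor_settings("X", n_orient = 400,
                                              t_us = seq(0, 1, by = 0.04)),
                         pump_MHz = 0, probe_MHz = 40)
  expect_error(sum_offsets(list(tr, tr2)), "grid")
})

test_that("the four-offset X-band sum approximates the ideal powder trace", {
  base <- place_labels_on_helix(helix_spec())
  ens <- generate_ensemble(base, n = 120, seed = 6)
  st <- peldor_settings("X", n_orient = 1000)
  trs <- simulate_peldor(ens, st, nu_n = c(40, 55, 70, 85))
  s <- sum_offsets(trs)
  powder <- calc_time_trace(ens, st, excitation = "ideal")
  matched <- fit_modulation_depth(s, powder, band = "G")
  expect_lt(sqrt(mean((matched$V - powder$V)^2)), 0.02)
})

test_that("modulation-depth fitting recovers exact and noisy scalings and bypasses X band", {
  ens <- as_ensemble(axis_pair(3.7))
  st <- peldor_settings("X", n_orient = 800)
  tr <- calc_time_trace(ens, st, pump_MHz = 0, probe_MHz = 55)
  same <- fit_modulation_depth(tr, tr, band = "G")
  expect_equal(same$meta$depth_scale, 1, tolerance = 1e-12)
  expect_equal(same$V, tr$V, tolerance = 1e-12)
  doubled <- peldor_trace(tr$t_us, 1 - 2 * (1 - tr$V))
  fit2 <- fit_modulation_depth(tr, doubled, band = "G")
  expect_equal(fit2$meta$depth_scale, 2, tolerance = 1e-12)
  # noisy reference: recover the scale within 5 percent
  set.seed(14)
  noisy <- peldor_trace(tr$t_us, 1 - 1.5 * (1 - tr$V) + stats::rnorm(length(tr$V), 0, 0.01))
  fit3 <- fit_modulation_depth(tr, noisy, band = "G")
  expect_lt(abs(fit3$meta$depth_scale - 1.5) / 1.5, 0.05)
  # X-band mode is the identity
  passthrough <- fit_modulation_depth(tr, doubled, band = "X")
  expect_identical(passthrough, tr)
  flat <- peldor_trace(tr$t_us, rep(1, length(tr$t_us)))
  expect_error(fit_modulation_depth(flat, tr, band = "G"), "flat")
})

test_that("a 180-degree flip of either label about its spin center leaves the trace unchanged", {
  base <- place_labels_on_helix(helix_spec())
  ens <- generate_ensemble(base, n = 10, seed = 3)
  for (band in c("X", "G")) {
    st <- peldor_settings(band, n_orient = 400, t_us = seq(0, 1.2, by = 0.04))
    co <- carrier_offsets(st$sp, st$fs, n_orient = 800)
    tr0 <- calc_time_trace(ens, st, pump_MHz = co$pump_MHz[1], probe_MHz = co$probe_MHz[1])
    flipped <- structure(lapply(ens, flip_conformer, which = "A"),
                         class = "spin_pair_ensemble")
    tr1 <- calc_time_trace(flipped, st, pump_MHz = co$pump_MHz[1],
                           probe_MHz = co$probe_MHz[1])
    expect_lt(sqrt(mean((tr0$V - tr1$V)^2)), 1e-6)
  }
})

test_that("doubling the powder grid changes the trace by well under half a percent", {
  base <- place_labels_on_helix(helix_spec())
  ens <- generate_ensemble(base, n = 60, seed = 8)
  st1 <- peldor_settings("X", n_orient = 3000)
  st2 <- peldor_settings("X", n_orient = 6000)
  tr1 <- calc_time_trace(ens, st1, pump_MHz = 0, probe_MHz = 55)
  tr2 <- calc_time_trace(ens, st2, pump_MHz = 0, probe_MHz = 55)
  expect_lt(sqrt(mean((tr1$V - tr2$V)^2)), 0.005)
})

test_that("trace files round-trip through the two-column ASCII format", {
  ens <- as_ensemble(axis_pair(3.8))
  st <- peldor_settings("X", n_orient = 300, t_us = seq(0, 1, by = 0.05))
  tr <- calc_time_trace(ens, st, pump_MHz = 0, probe_MHz = 70)
  path <- withr::local_tempfile(fileext = ".dat")
  write_trace(tr, path, extra = c(seed = "11"))
  back <- read_trace(path)
  expect_equal(back$t_us, tr$t_us, tolerance = 1e-6)
  expect_equal(back$V, tr$V, tolerance = 1e-8)
  expect_identical(back$meta$seed, "11")
  expect_identical(back$meta$band, "X")
})
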