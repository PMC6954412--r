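# Background correction, kernel quadrature, Tikhonov inversion and
# distribution statistics.

test_that("background fitting recovers pure exponentials and the k = 0 case", {
  t <- seq(0, 1.8, by = 0.01)
  raw <- peldor_trace(t, exp(-0.3 * t))
  bg <- fit_background(raw, 0.5)
  expect_equal(bg$k, 0.3, tolerance = 1e-9)
  expect_equal(bg$form_factor$V, rep(1, length(t)), tolerance = 1e-9)
  # k = 0 input: form factor equals the (renormalized) input
  flatbg <- fit_background(peldor_trace(t, rep(0.8, length(t))), 0.5)
  expect_equal(flatbg$k, 0)
  expect_error(fit_background(peldor_trace(t, exp(-0.3 * t) - 0.9), 0.5),
               "non-positive")
  expect_error(fit_background(raw, 0.999), "fewer than 10")
})

test_that("background fitting separates a synthetic form factor from a 3D background", {
  t <- seq(0, 1.8, by = 0.01)
  # broadened form factor whose dipolar modulation has decayed to its
  # plateau inside the fit window (the log-linear tail fit presumes this;
  # at 3.7 nm a 1.8 us window is too short for the premise to hold)
  r <- seq(1.5, 8, by = 0.02)
  K <- build_kernel(t, r)
  P <- stats::dnorm(r, 2.8, 0.40); P <- P / pracma::trapz(r, P)
  F_true <- 0.7 + 0.3 * drop(K$K %*% P) * 0.02
  raw <- peldor_trace(t, F_true * exp(-0.25 * t))
  bg <- fit_background(raw, fit_window_start = 0.5)
  expect_equal(bg$k, 0.25, tolerance = 0.005)
  expect_lt(sqrt(mean((bg$form_factor$V - F_true)^2)), 0.01)
})

test_that("kernel entries match adaptive quadrature and the limiting rows/columns", {
  t <- seq(0, 1.8, by = 0.1)
  r <- c(1.8, 2.5, 3.7, 5.0, 7.9)
  K <- build_kernel(t, r)
  expect_equal(K$K[1, ], rep(1, length(r)), tolerance = 1e-12)
  expect_true(all(abs(K$K) <= 1 + 1e-12))
  # spot-check five (t, r) pairs against stats::integrate
  set.seed(19)
  for (q in 1:5) {
    it <- sample(2:length(t), 1); ir <- sample(seq_along(r), 1)
    oracle <- stats::integrate(function(x)
      cos(2 * pi * K$D / r[ir]^3 * (1 - 3 * x^2) * t[it]), 0, 1,
      rel.tol = 1e-12)$value
    expect_equal(K$K[it, ir], oracle, tolerance = 1e-6)
  }
  # distant spins: kernel column ~ 1 for all times in the window
  Kfar <- build_kernel(seq(0, 1.8, by = 0.1), r_nm = 1000)
  expect_equal(drop(Kfar$K), rep(1, length(t)), tolerance = 1e-6)
  expect_error(build_kernel(t, r_nm = c(2, -1)), "positive")
})

test_that("noiseless delta and Gaussian distributions are recovered by the inversion", {
  t <- seq(0, 1.8, by = 0.02)
  r <- seq(1.5, 8, by = 0.02)
  K <- build_kernel(t, r)
  lam <- 0.35
  # delta at 3.70 nm: mode recovered within one grid step
  Pd <- rep(0, length(r)); Pd[which.min(abs(r - 3.7))] <- 1 / 0.02
  Fd <- (1 - lam) + lam * drop(K$K %*% Pd) * 0.02
  fit_d <- tikhonov_invert(peldor_trace(t, Fd), kernel = K)
  expect_lt(abs(fit_d$stats$mode_A - 37.0), 0.2)
  # Gaussian (mean 3.70 nm, sd 0.287 nm): mode within 0.05 nm, FWHM within
  # 15 percent of 0.675 nm
  Pg <- stats::dnorm(r, 3.70, 0.287); Pg <- Pg / pracma::trapz(r, Pg)
  Fg <- (1 - lam) + lam * drop(K$K %*% Pg) * 0.02
  fit_g <- tikhonov_invert(peldor_trace(t, Fg), kernel = K)
  expect_lt(abs(fit_g$stats$mode_A / 10 - 3.70), 0.05)
  expect_lt(abs(fit_g$stats$fwhm_nm - 0.675) / 0.675, 0.15)
  expect_equal(fit_g$lambda, lam, tolerance = 0.02)
  # output contract: non-negative, unit integral
  expect_true(all(fit_g$P >= 0))
  expect_equal(pracma::trapz(r, fit_g$P), 1, tolerance = 1e-9)
  # alpha selection is deterministic
  fit_g2 <- tikhonov_invert(peldor_trace(t, Fg), kernel = K)
  expect_identical(fit_g2$alpha, fit_g$alpha)
  expect_identical(fit_g2$P, fit_g$P)
  # the L-curve corner option also recovers the noiseless Gaussian
  fit_lc <- tikhonov_invert(peldor_trace(t, Fg), kernel = K, alpha = "lcurve")
  expect_lt(abs(fit_lc$stats$mode_A / 10 - 3.70), 0.05)
})

test_that("a modulation-free trace is flagged instead of producing a spurious peak", {
  t <- seq(0, 1.8, by = 0.02)
  K <- build_kernel(t, seq(1.5, 8, by = 0.05))
  fit <- tikhonov_invert(peldor_trace(t, rep(1, length(t))), kernel = K)
  expect_true("no modulation detected" %in% fit$flags)
  expect_true(all(fit$P == 0))
  # pure background in, flat flagged distribution out
  bg <- fit_background(peldor_trace(t, exp(-0.4 * t)), 0.5)
  fit2 <- tikhonov_invert(bg$form_factor, kernel = K)
  expect_true("no modulation detected" %in% fit2$flags)
})

test_that("ensemble round trip recovers the generated distance distribution", {
  base <- place_labels_on_helix(helix_spec())
  ens <- generate_ensemble(base, fluctuation_spec(0.287, 15), n = 1500, seed = 21)
  st <- peldor_settings("X", n_orient = 1500)
  powder <- calc_time_trace(ens, st, excitation = "ideal")
  fit <- tikhonov_invert(powder, r_nm = seq(1.5, 8, by = 0.02), D = st$D)
  r_emp <- ensemble_distances(ens)
  expect_lt(abs(fit$stats$mean_nm - mean(r_emp)), 0.05)
  expect_lt(abs(fit$stats$mode_A / 10 - base$r), 0.1)
  expect_lt(abs(fit$stats$fwhm_nm - 2.3548 * stats::sd(r_emp)) /
              (2.3548 * stats::sd(r_emp)), 0.15)
})

test_that("distribution statistics match closed forms and tie-break rules", {
  r <- seq(1.5, 8, by = 0.01)
  P <- stats::dnorm(r, 3.7, 0.25)
  st <- distribution_stats(r, P)
  expect_equal(st$fwhm_nm, 2.3548 * 0.25, tolerance = 0.01)
  expect_equal(st$mode_A, 37.0, tolerance = 0.05)
  expect_equal(st$mean_nm, 3.7, tolerance = 1e-3)
  expect_equal(st$sd_nm, 0.25, tolerance = 1e-2)
  expect_false(st$ambiguous)
  # single populated bin at 3.72 nm reports 37.2 A
  P1 <- rep(0, length(r)); P1[which.min(abs(r - 3.72))] <- 5
  expect_equal(distribution_stats(r, P1)$mode_A, 37.2, tolerance = 1e-6)
  # equal twin peaks: lower-r mode and the ambiguity flag
  P2 <- stats::dnorm(r, 3.0, 0.1) + stats::dnorm(r, 5.0, 0.1)
  st2 <- distribution_stats(r, P2)
  expect_true(st2$ambiguous)
  expect_equal(st2$mode_A, 30.0, tolerance = 0.05)
  expect_error(distribution_stats(r, rep(0, length(r))), "all-zero")
})

test_that("deer_fit methods expose coefficients, residuals and predictions consistently", {
  t <- seq(0, 1.8, by = 0.03)
  r <- seq(1.5, 8, by = 0.05)
  K <- build_kernel(t, r)
  P <- stats::dnorm(r, 3.6, 0.3); P <- P / pracma::trapz(r, P)
  Fv <- 0.65 + 0.35 * drop(K$K %*% P) * 0.05
  fit <- tikhonov_invert(peldor_trace(t, Fv), kernel = K)
  expect_equal(unname(coef(fit)), fit$P)
  expect_equal(fitted(fit) + residuals(fit), Fv, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, t_us = t), fitted(fit), tolerance = 1e-9)
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("mode", out)))
})
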