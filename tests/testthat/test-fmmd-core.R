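# Nonlinear magnetization and frequency-mixing demodulation.

test_that("Langevin function: origin, saturation, oddness, series branch", {
  expect_identical(langevin(0), 0)
  # frozen high-precision value of coth(1) - 1
  expect_equal(langevin(1), 0.31303528549933130, tolerance = 1e-14)
  expect_equal(langevin(50), 1 - 1 / 50, tolerance = 1e-12)
  expect_gt(langevin(700), 0.998)
  expect_lt(langevin(-700), -0.998)
  xs <- c(1e-8, 1e-4, 0.01, 0.0199, 0.02, 0.5, 2, 10)
  expect_equal(langevin(-xs), -langevin(xs), tolerance = 1e-14)
  # monotone increasing across the series/closed-form switch
  grid <- seq(-5, 5, by = 1e-3)
  expect_true(all(diff(langevin(grid)) > 0))
  expect_true(all(abs(langevin(seq(-100, 100, by = 0.37))) <= 1))
})

test_that("response series: zero amount, single-tone parity, linear scaling", {
  e <- default_excitation()
  s0 <- response_series(particle_xi(0.3, amount = 0), e)
  expect_true(all(s0$m == 0))

  # H2 = 0: odd nonlinearity of a single tone has only odd harmonics
  e1 <- excitation_config(H2 = 0)
  s1 <- response_series(particle_xi(0.5), e1)
  sp1 <- mixing_spectrum(s1, orders = 8)
  h <- sp1[sp1$n == 0, ]
  even_pow <- sum(h$amplitude[h$m %% 2 == 0]^2)
  expect_lt(even_pow / sum(h$amplitude^2), 1e-10)

  sa <- response_series(particle_xi(0.3, amount = 1), e)
  sb <- response_series(particle_xi(0.3, amount = 2), e)
  expect_equal(sb$m, 2 * sa$m, tolerance = 1e-14)
})

test_that("excitation config invariants are enforced", {
  expect_error(excitation_config(f1 = 50, f2 = 1000), "f1 > f2")
  expect_error(excitation_config(sample_rate = 2000), "sample_rate")
  expect_error(excitation_config(f1 = 1000, f2 = 1000 / pi), "denominator|integer")
})

test_that("mixing spectrum matches Fourier orthogonality and the DFT bin oracle", {
  e <- default_excitation()
  n <- e$samples_per_period
  t <- (seq_len(n) - 1) / e$sample_rate
  pure <- sin(2 * pi * e$f1 * t)
  sp <- mixing_spectrum(pure, e)
  expect_equal(mixing_amplitude(sp, 1, 0), 1, tolerance = 1e-10)
  expect_lt(max(sp$amplitude[!(sp$m == 1 & sp$n == 0)]), 1e-10)

  # lock-in projection equals the windowless DFT bin on integer periods
  s <- response_series(particle_xi(0.3), e)
  sp <- mixing_spectrum(s)
  for (i in sample.int(nrow(sp), 10)) {
    expect_equal(sp$amplitude[i],
                 dft_bin_amplitude(s$m, sp$frequency_hz[i], e$sample_rate),
                 tolerance = 1e-9)
  }

  expect_error(mixing_spectrum(s$m[-1], e), "integer number of common periods")
})

test_that("f1+2f2 amplitude approaches the cubic small-signal law", {
  e <- default_excitation()
  for (xi in c(0.3, 0.1, 0.05)) {
    a12 <- mixing_amplitude(mixing_spectrum(response_series(particle_xi(xi), e)))
    ratio <- a12 / a12_small_signal(xi, xi)
    tol <- if (xi > 0.1) 0.05 else 0.01
    expect_lt(abs(ratio - 1), tol)
  }
})

test_that("mixing amplitudes are invariant under time-origin shift", {
  e <- excitation_config(n_periods = 2L)
  s <- response_series(particle_xi(0.3), e)
  quarter <- e$samples_per_period / 4
  shifted <- c(s$m[-seq_len(quarter)], s$m[seq_len(quarter)])
  a <- mixing_spectrum(s$m, e)
  b <- mixing_spectrum(shifted, e)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
})

test_that("odd-order selection rule for symmetric two-tone excitation", {
  e <- default_excitation()
  sp <- mixing_spectrum(response_series(particle_xi(0.4), e), orders = 6)
  even <- (sp$m + sp$n) %% 2 == 0
  expect_lt(sum(sp$amplitude[even]^2) / sum(sp$amplitude^2), 1e-10)
})

test_that("every component scales exactly with particle amount", {
  e <- default_excitation()
  a <- mixing_spectrum(response_series(particle_xi(0.3, amount = 1), e))
  b <- mixing_spectrum(response_series(particle_xi(0.3, amount = 3.7), e))
  nz <- a$amplitude > 1e-12
  expect_equal(b$amplitude[nz] / a$amplitude[nz],
               rep(3.7, sum(nz)), tolerance = 1e-10)
})

test_that("amount quantification: round trip, linearity, saturation flag", {
  e <- default_excitation()
  cal <- calibrate_quantification(particle_xi(0.3, amount = 1), e)
  expect_equal(unclass(quantify_amount(0, cal)), 0, ignore_attr = TRUE)

  amounts <- c(1, 2, 4)
  rec <- vapply(amounts, function(a) {
    a12 <- mixing_amplitude(mixing_spectrum(response_series(particle_xi(0.3, amount = a), e)))
    as.numeric(quantify_amount(a12, cal))
  }, numeric(1))
  expect_equal(rec / rec[1], amounts / amounts[1], tolerance = 0.01)

  # decade sweep: R^2 of amplitude vs amount
  sweep <- seq(0.5, 5, length.out = 10)
  a12s <- vapply(sweep, function(a)
    mixing_amplitude(mixing_spectrum(response_series(particle_xi(0.3, amount = a), e))),
    numeric(1))
  fit <- stats::lm(a12s ~ sweep)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)

  expect_warning(quantify_amount(cal$a12_max * 2, cal), "linear regime")
  expect_error(quantify_amount(-1, cal), "non-negative")
})

test_that("spectrum CSV export has the documented columns", {
  e <- default_excitation()
  sp <- mixing_spectrum(response_series(particle_xi(0.2), e))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f)
  df <- read.csv(f)
  expect_named(df, c("m", "n", "frequency_hz", "amplitude", "phase_rad"))
  expect_equal(df$amplitude, sp$amplitude, tolerance = 1e-12)
})
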