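#' Langevin function
#'
#' Equilibrium magnetization of a superparamagnetic moment ensemble as a
#' function of the dimensionless field argument \eqn{\xi}:
#' \eqn{L(\xi) = \coth\xi - 1/\xi}. This static nonlinearity is the sole
#' source of harmonic and frequency-mixing content in the simulated
#' detector signal; superparamagnetic iron oxide nanoparticles (SPIONs)
#' show no hysteresis, so magnetization follows the applied field
#' instantaneously.
#'
#' Near the origin the closed form suffers catastrophic cancellation, so a
#' Taylor branch \eqn{\xi/3 - \xi^3/45 + 2\xi^5/945} is used for
#' \eqn{|\xi| < 0.02} (next omitted term is below 1e-18 there).
#'
#' @param xi Numeric vector, any finite values (dimensionless field).
#' @return Numeric vector in \[-1, 1\]; odd and monotone increasing.
#' @examples
#' langevin(0)        # 0
#' langevin(1)        # coth(1) - 1 = 0.31303...
#' @export
langevin <- function(xi) {
  stopifnot(is.numeric(xi))
  out <- numeric(length(xi))
  small <- is.finite(xi) & abs(xi) < 0.02
  xs <- xi[small]
  out[small] <- xs / 3 - xs^3 / 45 + 2 * xs^5 / 945
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out[!is.finite(xi)] <- NaN
  out
}

#' SPION particle parameters for the Langevin response model
#'
#' @param moment_scale Field-to-\eqn{\xi} conversion factor (per field
#'   unit); \eqn{\xi = moment\_scale \cdot H}. Must be > 0.
#' @param saturation Saturation magnetization per unit amount (signal
#'   units). Must be > 0.
#' @param amount Particle quantity (dimensionless or grams). Must be >= 0;
#'   an amount of 0 produces an identically zero response.
#' @param particles_per_gram Reference particle density stored as
#'   metadata; defaults to 1.8e15 (100 nm SPIONs).
#' @return An object of class `langevin_particle`.
#' @export
langevin_particle <- function(moment_scale, saturation = 1, amount = 1,
                              particles_per_gram = 1.8e15) {
  if (!is_scalar_num(moment_scale) || moment_scale <= 0)
    stopf("moment_scale must be a positive scalar")
  if (!is_scalar_num(saturation) || saturation <= 0)
    stopf("saturation must be a positive scalar")
  if (!is_scalar_num(amount) || amount < 0)
    stopf("amount must be a non-negative scalar")
  structure(list(moment_scale = moment_scale, saturation = saturation,
                 amount = amount, particles_per_gram = particles_per_gram),
            class = "langevin_particle")
}

#' Two-tone excitation configuration
#'
#' The sample is exposed to a field with a high-frequency tone `f1` and a
#' low-frequency tone `f2`; the nonlinear magnetization then carries
#' intermodulation products at `m*f1 + n*f2`. `f1/f2` must be rational
#' with a small denominator so that a common fundamental period exists and
#' demodulation can be leakage-free.
#'
#' @param f1,f2 Tone frequencies in Hz, `f1 > f2 > 0`.
#' @param H1,H2 Tone amplitudes (field units; \eqn{\xi_i} =
#'   `moment_scale * Hi`).
#' @param sample_rate Sampling rate in Hz. Must exceed `2*(f1 + 4*f2)` so
#'   that all mixing terms up to order 5 are resolved, and must divide
#'   into an integer number of samples per common period.
#' @param n_periods Integer number of common fundamental periods to
#'   simulate.
#' @return An object of class `excitation_config` with derived fields
#'   `f0` (common fundamental, Hz) and `samples_per_period`.
#' @export
excitation_config <- function(f1 = 1000, f2 = 50, H1 = 1, H2 = 1,
                              sample_rate = 20000, n_periods = 1L) {
  if (!is_scalar_num(f1) || !is_scalar_num(f2) || f1 <= f2 || f2 <= 0)
    stopf("require f1 > f2 > 0")
  scale <- 1e6
  g <- function(a, b) { while (b > 0) { t <- b; b <- a %% b; a <- t }; a }
  f0 <- g(round(f1 * scale), round(f2 * scale)) / scale
  if (f1 / f0 > 1e4 || f2 / f0 > 1e4)
    stopf("f1/f2 must be rational with a small denominator (common fundamental too low)")
  if (!is_scalar_num(sample_rate) || sample_rate <= 2 * (f1 + 4 * f2))
    stopf("sample_rate must exceed 2*(f1 + 4*f2) = %g Hz", 2 * (f1 + 4 * f2))
  spp <- sample_rate / f0
  if (abs(spp - round(spp)) > 1e-9)
    stopf("sample_rate must give an integer number of samples per common period (f0 = %g Hz)", f0)
  n_periods <- as.integer(n_periods)
  if (n_periods < 1L) stopf("n_periods must be >= 1")
  structure(list(f1 = f1, f2 = f2, H1 = H1, H2 = H2,
                 sample_rate = sample_rate, n_periods = n_periods,
                 f0 = f0, samples_per_period = as.integer(round(spp))),
            class = "excitation_config")
}

#' Simulate the time-domain magnetization response to two-tone excitation
#'
#' \eqn{M(t) = amount \cdot saturation \cdot
#' L(moment\_scale (H_1 \sin 2\pi f_1 t + H_2 \sin 2\pi f_2 t))},
#' sampled at `sample_rate` over exactly `n_periods` common periods.
#'
#' @param p A [langevin_particle()].
#' @param e An [excitation_config()].
#' @param noise_sd Standard deviation of optional additive white Gaussian
#'   noise (signal units); default 0 (deterministic).
#' @param seed RNG seed for the noise; ignored when `noise_sd = 0`.
#' @return An object of class `fmmd_series`: list with `t` (s), `m`
#'   (signal units) and the `excitation` used.
#' @export
response_series <- function(p, e, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(p, "langevin_particle"), inherits(e, "excitation_config"))
  n <- e$samples_per_period * e$n_periods
  t <- (seq_len(n) - 1) / e$sample_rate
  h <- e$H1 * sin(2 * pi * e$f1 * t) + e$H2 * sin(2 * pi * e$f2 * t)
  m <- p$amount * p$saturation * langevin(p$moment_scale * h)
  if (noise_sd > 0)
    m <- m + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  structure(list(t = t, m = m, excitation = e), class = "fmmd_series")
}

#' Extract frequency-mixing components from a response series
#'
#' For every integer pair (m, n) with `|m| + |n| <= orders` and
#' `m*f1 + n*f2 > 0`, the amplitude and phase at that exact frequency are
#' obtained by projection onto sine/cosine over the full (integer number
#' of common periods) series. On such series the projection equals the
#' corresponding windowless DFT bin, so there is no spectral leakage.
#'
#' @param series An `fmmd_series` (or a plain numeric vector, in which
#'   case `e` must be supplied and the series length must be an integer
#'   multiple of `e$samples_per_period`).
#' @param e The [excitation_config()]; defaults to the one stored in
#'   `series`.
#' @param orders Maximum mixing order `|m| + |n|` (default 5).
#' @return A data.frame of class `mixing_spectrum` with columns `m`, `n`,
#'   `frequency_hz`, `amplitude`, `phase_rad`. Amplitudes are invariant
#'   under a time-origin shift of the input; phases are not.
#' @export
mixing_spectrum <- function(series, e = NULL, orders = 5L) {
  if (inherits(series, "fmmd_series")) {
    if (is.null(e)) e <- series$excitation
    x <- series$m
  } else {
    if (is.null(e)) stopf("e must be supplied for a plain numeric series")
    x <- as.numeric(series)
  }
  n <- length(x)
  if (n %% e$samples_per_period != 0)
    stopf("series must span an integer number of common periods (%d samples each)",
          e$samples_per_period)
  t <- (seq_len(n) - 1) / e$sample_rate
  comb <- expand.grid(m = 0:orders, n = -orders:orders)
  comb <- comb[abs(comb$m) + abs(comb$n) <= orders, ]
  comb$frequency_hz <- comb$m * e$f1 + comb$n * e$f2
  comb <- comb[comb$frequency_hz > 0, ]
  comb <- comb[order(comb$frequency_hz, comb$m), ]
  amp <- numeric(nrow(comb)); ph <- numeric(nrow(comb))
  for (i in seq_len(nrow(comb))) {
    w <- 2 * pi * comb$frequency_hz[i] * t
    a <- 2 * sum(x * cos(w)) / n
    b <- 2 * sum(x * sin(w)) / n
    amp[i] <- sqrt(a^2 + b^2)
    ph[i] <- atan2(a, b)
  }
  out <- data.frame(m = comb$m, n = comb$n, frequency_hz = comb$frequency_hz,
                    amplitude = amp, phase_rad = ph, row.names = NULL)
  attr(out, "excitation") <- e
  class(out) <- c("mixing_spectrum", "data.frame")
  out
}

#' Look up one mixing component's amplitude
#'
#' @param spec A `mixing_spectrum`.
#' @param m,n Integer mixing indices; the default (1, 2) selects the
#'   `f1 + 2 f2` term used for particle quantification.
#' @return Amplitude (signal units).
#' @export
mixing_amplitude <- function(spec, m = 1L, n = 2L) {
  i <- which(spec$m == m & spec$n == n)
  if (length(i) != 1L) stopf("component (%d, %d) not in spectrum", m, n)
  spec$amplitude[i]
}

#' Build a particle-quantification calibration from a known-amount reference
#'
#' Simulates the full nonlinear response of a reference particle in the
#' small-signal regime and records the slope amplitude-per-amount of the
#' `f1 + 2 f2` mixing term, which is proportional to particle amount
#' there. Signals above `a12_max` are outside the recorded linear regime
#' and get flagged on inversion.
#'
#' @param p Reference [langevin_particle()] with known `amount > 0`.
#' @param e [excitation_config()].
#' @param a12_max Upper bound of the linear regime in signal units;
#'   default 5x the reference amplitude.
#' @return List of class `fmmd_calibration` with `slope` and `a12_max`.
#' @export
calibrate_quantification <- function(p, e, a12_max = NULL) {
  stopifnot(p$amount > 0)
  a12 <- mixing_amplitude(mixing_spectrum(response_series(p, e)))
  slope <- a12 / p$amount
  if (is.null(a12_max)) a12_max <- 5 * a12
  structure(list(slope = slope, a12_max = a12_max),
            class = "fmmd_calibration")
}

#' Convert a measured `f1 + 2 f2` amplitude to particle amount
#'
#' @param a12 Measured mixing amplitude(s), signal units.
#' @param cal An `fmmd_calibration` (or any list with positive `slope`
#'   and `a12_max`).
#' @return Amount(s) = `a12 / slope`. A warning is raised and the
#'   attribute `saturated` set where `a12 > a12_max` (outside the
#'   calibrated linear regime).
#' @export
quantify_amount <- function(a12, cal) {
  if (!is.numeric(a12) || any(a12 < 0)) stopf("a12 must be non-negative")
  if (is.null(cal$slope) || cal$slope <= 0) stopf("calibration slope must be > 0")
  sat <- a12 > cal$a12_max
  if (any(sat)) warning("amplitude exceeds calibrated linear regime; amount underestimated")
  out <- a12 / cal$slope
  attr(out, "saturated") <- sat
  out
}

#' Small-signal analytic amplitude of the `f1 + 2 f2` mixing term
#'
#' Leading-order Taylor prediction \eqn{\xi_1 \xi_2^2 |3 a_3 / 4|} with
#' \eqn{a_3 = -1/45} (the cubic coefficient of the Langevin function),
#' i.e. \eqn{\xi_1 \xi_2^2 / 60} per unit `amount * saturation`.
#'
#' @param xi1,xi2 Dimensionless tone amplitudes.
#' @return Predicted amplitude (per unit amount and saturation).
#' @export
a12_small_signal <- function(xi1, xi2) xi1 * xi2^2 / 60

#' Write a mixing spectrum to CSV
#'
#' Columns: m, n, frequency_hz, amplitude, phase_rad.
#' @param spec A `mixing_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}
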