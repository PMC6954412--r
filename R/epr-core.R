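# Nitroxide spin physics: first-order orientation-dependent resonance
# offsets from g and 14N hyperfine tensors, rectangular-pulse excitation
# profiles, and powder spectra used to position pump and probe pulses.

#' Nitroxide spin parameters
#'
#' Principal g values and 14N hyperfine principal values (MHz) of the
#' label, assumed collinear (shared principal axes: x along N-O, z normal
#' to the ring plane). Defaults are the CW-EPR validated values of the
#' guanine-derived isoindoline nitroxide label used for nucleic acid
#' duplexes: g = (2.0088, 2.0065, 2.0027), A = (15, 15, 98) MHz. The 14N
#' nucleus has I = 1, with the three m_I levels equally populated.
#'
#' @param g length-3 numeric, principal g values (x, y, z).
#' @param A_MHz length-3 numeric, hyperfine principal values in MHz.
#' @return object of class `spin_parameters`.
#' @export
spin_parameters <- function(g = c(2.0088, 2.0065, 2.0027),
                            A_MHz = c(15, 15, 98)) {
  stopifnot(length(g) == 3L, length(A_MHz) == 3L,
            all(g > 1.9), all(g < 2.1), all(A_MHz >= 0))
  structure(list(g = as.numeric(g), A_MHz = as.numeric(A_MHz),
                 g_iso = mean(g)), class = "spin_parameters")
}

#' @export
print.spin_parameters <- function(x, ...) {
  cat(sprintf("Nitroxide spin parameters: g = (%.4f, %.4f, %.4f), A = (%g, %g, %g) MHz\n",
              x$g[1], x$g[2], x$g[3], x$A_MHz[1], x$A_MHz[2], x$A_MHz[3]))
  invisible(x)
}

#' Magnetic field / microwave band setup
#'
#' @param band `"X"` (~9 GHz / 0.3 T, spectrum dominated by the 14N
#'   hyperfine anisotropy) or `"G"` (180 GHz / 6.4 T, dominated by the
#'   g anisotropy).
#' @param frequency_GHz reference microwave frequency.
#' @param B0_T static field in Tesla.
#' @return object of class `field_setup`.
#' @export
field_setup <- function(band = c("X", "G"),
                        frequency_GHz = NULL, B0_T = NULL) {
  band <- match.arg(band)
  if (is.null(frequency_GHz)) frequency_GHz <- if (band == "X") 9.0 else 180
  if (is.null(B0_T)) B0_T <- if (band == "X") 0.3 else 6.4
  stopifnot(B0_T > 0, frequency_GHz > 0)
  structure(list(band = band, frequency_GHz = frequency_GHz, B0_T = B0_T),
            class = "field_setup")
}

#' Rectangular microwave pulse
#'
#' @param duration_ns pulse length in ns.
#' @param flip_angle nominal on-resonance flip angle in radians (pi or
#'   pi/2); the nutation frequency is `flip_angle / duration`.
#' @return object of class `mw_pulse`.
#' @export
mw_pulse <- function(duration_ns, flip_angle = pi) {
  stopifnot(duration_ns > 0, flip_angle > 0)
  structure(list(duration_ns = duration_ns, flip_angle = flip_angle),
            class = "mw_pulse")
}

#' Orientation-dependent resonance offset
#'
#' First-order (high-field) resonance offset of a nitroxide whose frame
#' sees the static field along unit vector `n` (components in the label
#' frame):
#' `nu(n, m_I) = (muB B0 / h) (g(n) - g_iso) + m_I A(n)`, with
#' `g(n) = sqrt(sum g_ii^2 n_i^2)` and `A(n) = sqrt(sum A_ii^2 n_i^2)`.
#' Offsets are reported in MHz relative to the isotropic electron Zeeman
#' frequency. Invariant under n -> -n.
#'
#' @param n unit 3-vector or n x 3 matrix of unit rows (field direction in
#'   the nitroxide frame).
#' @param sp [spin_parameters].
#' @param m_I 14N magnetic quantum number, -1, 0 or +1.
#' @param fs [field_setup] (supplies B0).
#' @return offset(s) in MHz.
#' @export
resonance_offset <- function(n, sp, m_I, fs) {
  n <- rbind(n)
  norms <- rowSums(n^2)
  if (any(abs(norms - 1) > 1e-6))
    stop("field direction must be a unit vector", call. = FALSE)
  stopifnot(m_I %in% c(-1, 0, 1))
  g_eff <- sqrt(n^2 %*% sp$g^2)
  A_eff <- sqrt(n^2 %*% sp$A_MHz^2)
  unname(drop(MU_B_OVER_H_MHZ_PER_T * fs$B0_T * (g_eff - sp$g_iso) + m_I * A_eff))
}

#' Excitation probability of a rectangular pulse
#'
#' Transition probability of a two-level spin at offset `offset_MHz` from
#' the pulse carrier, from the exact rotating-frame solution for a
#' rectangular pulse (Rabi formula):
#' `p = w1^2/(w1^2 + dw^2) * sin^2( t/2 * sqrt(w1^2 + dw^2) )`
#' with nutation rate `w1 = flip_angle / duration` and `dw = 2 pi offset`.
#' On resonance this is `sin^2(flip_angle / 2)`; it decays to zero far off
#' resonance.
#'
#' @param p a [mw_pulse].
#' @param offset_MHz numeric vector of offsets from the carrier.
#' @return probabilities in `[0, 1]` (vectorized).
#' @export
excitation_probability <- function(p, offset_MHz) {
  w1 <- p$flip_angle / p$duration_ns          # rad/ns
  dw <- 2 * pi * offset_MHz * 1e-3            # MHz -> rad/ns
  weff2 <- w1^2 + dw^2
  (w1^2 / weff2) * sin(sqrt(weff2) * p$duration_ns / 2)^2
}

#' Deterministic Fibonacci sphere grid
#'
#' Near-uniform deterministic orientation grid: point i of n has
#' z = 1 - (2i-1)/n and azimuth i * golden angle. Used for reproducible
#' powder averaging; a seeded Monte Carlo alternative is available via
#' `random = TRUE` for convergence testing.
#'
#' @param n number of orientations.
#' @param random if `TRUE`, draw uniformly on the sphere instead
#'   (respects the current RNG state).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_grid <- function(n, random = FALSE) {
  stopifnot(n >= 1)
  if (random) {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
  } else {
    i <- seq_len(n)
    z <- 1 - (2 * i - 1) / n
    phi <- i * pi * (3 - sqrt(5))
  }
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Absorption powder spectrum of the nitroxide
#'
#' Histogram of first-order resonance offsets over a uniform orientation
#' grid and the three equally populated 14N m_I levels, normalized to unit
#' area. The bin of maximum intensity defines the X-band pump position
#' ("intensity maximum of the nitroxide powder spectrum").
#'
#' @param sp [spin_parameters].
#' @param fs [field_setup].
#' @param n_orient orientation grid size (Fibonacci sphere).
#' @param bin_MHz histogram bin width.
#' @return object of class `powder_spectrum`: list with `mids` (bin
#'   centers, MHz), `density` (1/MHz, integrates to 1), `max_offset`
#'   (center of the argmax bin), `bin_MHz`.
#' @export
powder_spectrum <- function(sp, fs, n_orient = 3000, bin_MHz = 1) {
  if (n_orient < 1) stop("empty orientation grid", call. = FALSE)
  n <- sphere_grid(n_orient)
  off <- c(resonance_offset(n, sp, -1, fs),
           resonance_offset(n, sp, 0, fs),
           resonance_offset(n, sp, +1, fs))
  lo <- floor(min(off) / bin_MHz) * bin_MHz - bin_MHz
  hi <- ceiling(max(off) / bin_MHz) * bin_MHz + bin_MHz
  breaks <- seq(lo, hi, by = bin_MHz)
  h <- graphics::hist(off, breaks = breaks, plot = FALSE)
  dens <- h$counts / (length(off) * bin_MHz)
  structure(list(mids = h$mids, density = dens,
                 max_offset = h$mids[which.max(h$counts)], bin_MHz = bin_MHz,
                 band = fs$band),
            class = "powder_spectrum")
}

#' @export
print.powder_spectrum <- function(x, ...) {
  cat(sprintf("%s-band nitroxide powder spectrum: %d bins of %g MHz, max at %+.1f MHz\n",
              x$band, length(x$mids), x$bin_MHz, x$max_offset))
  invisible(x)
}

#' @export
plot.powder_spectrum <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "l",
                 xlab = "offset from isotropic center (MHz)",
                 ylab = "intensity (1/MHz)",
                 main = sprintf("%s-band powder spectrum", x$band), ...)
  graphics::abline(v = x$max_offset, lty = 3)
  invisible(x)
}

#' Pump and probe carrier offsets for a band
#'
#' X-band: the pump is set at the maximum of the powder spectrum and the
#' probe `nu_n` MHz above it. G-band: field positions correspond to the
#' canonical orientations B || g_xx, g_yy, g_zz; each maps to the pump
#' carrier sitting at the m_I = 0 resonance offset of that orientation,
#' with the probe at a fixed offset (60 MHz) from the pump.
#'
#' @param sp [spin_parameters].
#' @param fs [field_setup].
#' @param nu_n X-band probe offsets above the pump (MHz), or G-band
#'   probe-pump offset (scalar, default 60).
#' @param positions G-band field positions, subset of `c("gxx","gyy","gzz")`.
#' @param n_orient grid size for locating the X-band spectral maximum.
#' @return data frame with columns `label`, `pump_MHz`, `probe_MHz`.
#' @export
carrier_offsets <- function(sp, fs, nu_n = c(40, 55, 70, 85),
                            positions = c("gxx", "gyy", "gzz"),
                            n_orient = 3000) {
  if (fs$band == "X") {
    ps <- powder_spectrum(sp, fs, n_orient = n_orient)
    pump <- ps$max_offset
    data.frame(label = sprintf("%gMHz", nu_n),
               pump_MHz = pump, probe_MHz = pump + nu_n)
  } else {
    axes <- list(gxx = c(1, 0, 0), gyy = c(0, 1, 0), gzz = c(0, 0, 1))
    positions <- match.arg(positions, names(axes), several.ok = TRUE)
    pump <- vapply(positions, function(p) resonance_offset(axes[[p]], sp, 0, fs),
                   numeric(1))
    if (length(nu_n) != 1L) nu_n <- 60
    data.frame(label = positions, pump_MHz = pump, probe_MHz = pump + nu_n)
  }
}
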