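#' Gaussian source spectrum
#'
#' Spectrometer-convention source: samples are uniform in wavelength over a
#' span of +/- 2 FWHM about the center, which makes the wavenumber grid
#' k = 2 pi / lambda non-uniform — reconstruction must k-linearize. The
#' envelope is a peak-normalized Gaussian whose full width at half maximum
#' equals `fwhm_nm` within one grid step.
#'
#' @param center_nm center wavelength in nm (default 1300).
#' @param fwhm_nm spectral bandwidth FWHM in nm (default 170).
#' @param n_samples samples per A-scan (default 1024, minimum 64).
#' @return object of class `source_spectrum` with fields `wavelength_nm`
#'   (ascending), `k` (rad/um, descending), `envelope`, `k0` (rad/um at the
#'   center wavelength).
#' @export
make_source_spectrum <- function(center_nm = 1300, fwhm_nm = 170,
                                 n_samples = 1024) {
  if (n_samples < 64) stop("n_samples must be at least 64")
  if (!(center_nm > fwhm_nm / 2 && fwhm_nm > 0))
    stop("require center_nm > fwhm_nm/2 > 0")
  wl <- seq(center_nm - 2 * fwhm_nm, center_nm + 2 * fwhm_nm,
            length.out = n_samples)
  env <- exp(-4 * log(2) * ((wl - center_nm) / fwhm_nm)^2)
  env <- env / max(env)
  structure(list(center_nm = center_nm, fwhm_nm = fwhm_nm,
                 n_samples = as.integer(n_samples),
                 wavelength_nm = wl,
                 k = 2000 * pi / wl,      # rad/um
                 k0 = 2000 * pi / center_nm,
                 envelope = env),
            class = "source_spectrum")
}

#' Scan geometry
#'
#' @param n_ascans A-scans per B-scan.
#' @param n_bscans number of B-scans (default 1).
#' @param lateral_pitch_um A-scan spacing in microns (6 for volumes, 4 for
#'   high-density B-scans).
#' @param bscan_pitch_um B-scan spacing (defaults to `lateral_pitch_um`).
#' @param lateral_psf_fwhm_um lateral intensity PSF FWHM (default 9).
#' @param medium_group_index group index; depths are optical path lengths and
#'   the default 1 makes them physical depths in the tests.
#' @export
scan_geometry <- function(n_ascans, n_bscans = 1, lateral_pitch_um = 6,
                          bscan_pitch_um = lateral_pitch_um,
                          lateral_psf_fwhm_um = 9, medium_group_index = 1) {
  stopifnot(n_ascans >= 1, n_bscans >= 1, lateral_pitch_um > 0,
            bscan_pitch_um > 0, lateral_psf_fwhm_um > 0,
            medium_group_index > 0)
  structure(list(n_ascans = as.integer(n_ascans),
                 n_bscans = as.integer(n_bscans),
                 lateral_pitch_um = lateral_pitch_um,
                 bscan_pitch_um = bscan_pitch_um,
                 lateral_psf_fwhm_um = lateral_psf_fwhm_um,
                 medium_group_index = medium_group_index),
            class = "scan_geometry")
}

ascan_positions <- function(geometry) {
  (seq_len(geometry$n_ascans) - 0.5) * geometry$lateral_pitch_um
}

bscan_positions <- function(geometry) {
  (seq_len(geometry$n_bscans) - 0.5) * geometry$bscan_pitch_um
}

#' Diffuser state sequence
#'
#' Models the rotating ground-glass diffuser as a per-scatterer phase
#' perturbation with controllable frame-to-frame correlation. Frame 1 draws
#' i.i.d. uniform(-pi, pi) phases; each later frame keeps every scatterer's
#' phase with probability `rho` and redraws it otherwise (circular mixing),
#' so the complex-phasor correlation between consecutive frames is exactly
#' `rho` in expectation: `rho = 1` reproduces conventional OCT (diffuser
#' removed, all frames identical), `rho = 0` gives fresh uncorrelated speckle
#' every frame.
#'
#' @param M number of frames (>= 1).
#' @param rho frame-to-frame phasor correlation in [0, 1].
#' @param n_scatterers number of scatterers the phases apply to.
#' @param seed RNG seed.
#' @return object of class `diffuser_sequence` with `phases` (n x M matrix),
#'   `rho` and `M`.
#' @export
diffuser_sequence <- function(M, rho, n_scatterers, seed = 1L) {
  if (M < 1) stop("M must be at least 1")
  if (!is.finite(rho) || rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  set.seed(seed)
  n <- as.integer(n_scatterers)
  ph <- matrix(0, n, M)
  if (n > 0) {
    ph[, 1] <- stats::runif(n, -pi, pi)
    if (M > 1) for (m in 2:M) {
      redraw <- stats::runif(n) >= rho
      ph[, m] <- ph[, m - 1]
      ph[redraw, m] <- stats::runif(sum(redraw), -pi, pi)
    }
  }
  structure(list(phases = ph, rho = rho, M = as.integer(M), seed = seed),
            class = "diffuser_sequence")
}

#' Extract one diffuser state
#' @param seq a [diffuser_sequence()].
#' @param m frame index.
#' @export
diffuser_state <- function(seq, m) {
  stopifnot(inherits(seq, "diffuser_sequence"), m >= 1, m <= seq$M)
  list(frame_index = as.integer(m), correlation = seq$rho,
       phases = seq$phases[, m])
}

# amplitude transmission through vessel attenuators for each scatterer:
# chord length of the vertical ray from the surface to the scatterer through
# each (infinite-axis) vessel cylinder
vessel_transmission <- function(spec, positions) {
  trans <- rep(1, nrow(positions))
  for (r in spec$regions) {
    if (r$type != "vessel") next
    ax <- r$to - r$from
    u <- ax / sqrt(sum(ax^2))
    rad2 <- (r$diameter_um / 2)^2
    w <- cbind(positions[, 1] - r$from[1],
               positions[, 2] - r$from[2],
               -r$from[3])
    c0 <- w %*% u
    A <- 1 - u[3]^2
    Bq <- 2 * (w[, 3] - c0 * u[3])
    Cq <- rowSums(w^2) - c0^2 - rad2
    L <- numeric(nrow(positions))
    if (A < 1e-12) {
      # vessel parallel to the beam: inside the column -> full path
      L[Cq <= 0] <- positions[Cq <= 0, 3]
    } else {
      disc <- Bq^2 - 4 * A * Cq
      hit <- disc > 0
      if (any(hit)) {
        sq <- sqrt(disc[hit])
        t1 <- (-Bq[hit] - sq) / (2 * A)
        t2 <- (-Bq[hit] + sq) / (2 * A)
        L[hit] <- pmax(0, pmin(t2, positions[hit, 3]) - pmax(t1, 0))
      }
    }
    trans <- trans * exp(-r$attenuation_per_um * L)
  }
  trans
}

#' Simulate raw spectral-domain interferogram frames
#'
#' For the A-scan at lateral position x_j, frame m, spectral sample k_i:
#' \deqn{I_m(k_i) = E(k_i)\,\bigl|1 + \sum_s a_s T_s w_s
#'   e^{i[2 k_i n z_s + \phi_s + \phi_{s,m} + a_2 (k_i-k_0)^2 +
#'   a_3 (k_i-k_0)^3]}\bigr|^2 + \epsilon}
#' with `w_s` a Gaussian lateral weight of the geometry's PSF FWHM, `T_s` the
#' cumulative vessel attenuation above scatterer s, `phi_s` a fixed i.i.d.
#' uniform scatterer phase, `phi_{s,m}` the diffuser perturbation and
#' `epsilon` zero-mean Gaussian noise on the spectral intensity (clamped at
#' zero). The reference-arm amplitude is fixed at 1; keep scatterer
#' amplitudes well below 1 so autocorrelation terms stay negligible (they are
#' still simulated). Deterministic under a fixed seed.
#'
#' @param field a [build_scatterer_field()] result.
#' @param source a [make_source_spectrum()].
#' @param geometry a [scan_geometry()].
#' @param dispersion numeric `c(a2, a3)` spectral-phase coefficients
#'   (rad um^2, rad um^3) used to corrupt the spectra.
#' @param diffuser a [diffuser_sequence()] whose row count matches the field.
#' @param noise_sd standard deviation of additive spectral noise.
#' @param seed RNG seed for scatterer phases and noise.
#' @return object of class `spectral_frame_set`; `data` has dim
#'   (n_samples, n_ascans, n_bscans, M), values >= 0.
#' @export
simulate_frames <- function(field, source, geometry, dispersion = c(0, 0),
                            diffuser, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(field, "scatterer_field"),
            inherits(source, "source_spectrum"),
            inherits(geometry, "scan_geometry"),
            inherits(diffuser, "diffuser_sequence"))
  dispersion <- as.numeric(dispersion)
  stopifnot(length(dispersion) == 2, all(is.finite(dispersion)))
  n_s <- nrow(field$positions)
  if (nrow(diffuser$phases) != n_s)
    stop("diffuser sequence was built for a different scatterer count")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")

  # warn when the dispersion group delay exceeds the Nyquist depth
  dk_max <- max(abs(source$k - source$k0))
  delay <- abs(dispersion[1]) * dk_max + 1.5 * abs(dispersion[2]) * dk_max^2
  k_span <- diff(range(source$k))
  z_max <- (source$n_samples / 2) * pi * (source$n_samples - 1) /
    (source$n_samples * k_span)
  if (delay > z_max)
    warning("dispersion phase aliases beyond the Nyquist depth")

  set.seed(seed)
  phi0 <- stats::runif(n_s, -pi, pi)
  ord <- order(field$positions[, 1])
  amps <- field$amplitudes * vessel_transmission(field$spec, field$positions)
  z_opt <- field$positions[, 3] * geometry$medium_group_index

  data <- simulate_frames_cpp(field$positions[ord, 1], field$positions[ord, 2],
                              z_opt[ord], amps[ord], phi0[ord],
                              diffuser$phases[ord, , drop = FALSE],
                              source$k, source$envelope,
                              ascan_positions(geometry),
                              bscan_positions(geometry),
                              geometry$lateral_psf_fwhm_um,
                              2.5 * geometry$lateral_psf_fwhm_um,
                              dispersion[1], dispersion[2], source$k0)
  if (noise_sd > 0)
    data <- pmax(data + stats::rnorm(length(data), 0, noise_sd), 0)
  structure(list(data = data, source = source, geometry = geometry,
                 dispersion = dispersion, noise_sd = noise_sd,
                 rho = diffuser$rho, M = diffuser$M, seed = seed),
            class = "spectral_frame_set")
}

#' @export
print.spectral_frame_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("spectral_frame_set: %d frame(s) x %d B-scan(s) x %d A-scan(s) x %d samples (rho = %g)\n",
              d[4], d[3], d[2], d[1], x$rho))
  invisible(x)
}

#' Linear-interpolated full width at half maximum
#'
#' @param x abscissa (monotone increasing).
#' @param y nonnegative profile with a single dominant peak.
#' @return FWHM in the units of `x`.
#' @export
interp_fwhm <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  i0 <- which.max(y)
  half <- y[i0] / 2
  # left crossing
  il <- i0
  while (il > 1 && y[il - 1] > half) il <- il - 1
  if (il == 1) stop("peak truncated on the left")
  xl <- x[il - 1] + (x[il] - x[il - 1]) * (half - y[il - 1]) /
    (y[il] - y[il - 1])
  ir <- i0
  while (ir < length(y) && y[ir + 1] > half) ir <- ir + 1
  if (ir == length(y)) stop("peak truncated on the right")
  xr <- x[ir] + (x[ir + 1] - x[ir]) * (half - y[ir]) / (y[ir + 1] - y[ir])
  xr - xl
}
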