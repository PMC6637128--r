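#' Enhancement configuration
#'
#' Defaults for the display-oriented post-processing chain; the chain order
#' is fixed (vessel-shadow gain, then 3-D anisotropic diffusion, then
#' histogram equalization), but every stage is independently callable.
#' Quantitative metrics (speckle contrast, margin errors) are always computed
#' before equalization.
#'
#' @param gain_clip_max maximum shadow-compensation gain (default 10).
#' @param diffusion_n_iter,diffusion_kappa,diffusion_dt Perona-Malik
#'   parameters; `kappa = NULL` auto-sets to the 90th percentile of the
#'   gradient magnitude, `dt` must respect the 6-neighbour explicit
#'   stability bound dt <= 1/6 (default 1/7).
#' @param eq_n_bins,eq_on_log_scale histogram-equalization bin count and
#'   whether to equalize dB-scaled data (default TRUE).
#' @param target_voxel_um isotropic resampling pitch (default 4).
#' @param flatten_threshold_fraction,flatten_median_px surface-detection
#'   threshold (fraction of each column's max) and surface median-filter
#'   width in pixels.
#' @export
enhance_config <- function(gain_clip_max = 10, diffusion_n_iter = 10,
                           diffusion_kappa = NULL, diffusion_dt = 1 / 7,
                           eq_n_bins = 256, eq_on_log_scale = TRUE,
                           target_voxel_um = 4,
                           flatten_threshold_fraction = 0.5,
                           flatten_median_px = 5) {
  stopifnot(gain_clip_max >= 1, diffusion_n_iter >= 0,
            diffusion_dt > 0, diffusion_dt <= 1 / 6,
            eq_n_bins >= 2, target_voxel_um > 0,
            flatten_threshold_fraction > 0, flatten_threshold_fraction <= 1,
            flatten_median_px >= 1)
  structure(list(gain_clip_max = gain_clip_max,
                 diffusion_n_iter = as.integer(diffusion_n_iter),
                 diffusion_kappa = diffusion_kappa,
                 diffusion_dt = diffusion_dt,
                 eq_n_bins = as.integer(eq_n_bins),
                 eq_on_log_scale = eq_on_log_scale,
                 target_voxel_um = target_voxel_um,
                 flatten_threshold_fraction = flatten_threshold_fraction,
                 flatten_median_px = as.integer(flatten_median_px)),
            class = "enhance_config")
}

#' Vessel-shadow gain compensation
#'
#' Vessels attenuate everything beneath them, darkening whole columns. The
#' compensating gain makes the average signal along depth uniform across the
#' field of view: with m(x, y) the depth-mean of each lateral position and T
#' the field-of-view mean of m, each column is multiplied by
#' g(x, y) = min(T / m(x, y), gain_clip_max). Wherever the clip is not hit the
#' post-gain depth-means are exactly equal.
#'
#' @param volume linear-scale [intensity_volume()].
#' @param gain_clip_max gain ceiling protecting empty/deep columns.
#' @return gain-compensated [intensity_volume()]; the gain map and the
#'   clipped-column count are attached as attributes `gain` and `n_clipped`.
#' @export
remove_vessel_shadows <- function(volume, gain_clip_max = 10) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (volume$log_scaled) stop("shadow gain requires linear scale")
  v <- volume$values
  m <- colMeans(v)                       # (x, y) depth-means
  Tbar <- mean(m)
  g <- matrix(gain_clip_max, nrow(m), ncol(m))
  ok <- m > 0
  g[ok] <- pmin(Tbar / m[ok], gain_clip_max)
  n_clip <- sum(!ok) + sum(ok & Tbar / m >= gain_clip_max)
  if (any(!ok))
    message(sum(!ok), " zero-mean column(s) set to the clip gain")
  out <- v * rep(g, each = dim(v)[1])
  res <- intensity_volume(out, volume$axial_pitch_um, volume$lateral_pitch_um,
                          provenance = "enhanced", n_frames = volume$n_frames)
  attr(res, "gain") <- g
  attr(res, "n_clipped") <- n_clip
  res
}

#' Three-dimensional anisotropic diffusion (Perona-Malik)
#'
#' Explicit 6-neighbour scheme with exponential conductance
#' c(g) = exp(-(g/kappa)^2) and zero-flux (reflecting) boundaries. Fluxes are
#' antisymmetric across voxel faces, so the global mean is conserved and, for
#' dt <= 1/6, no value leaves the input extrema. Edges with gradients well
#' above kappa conduct almost nothing and are preserved while low-contrast
#' speckle remnants are smoothed.
#'
#' @param volume an [intensity_volume()].
#' @param n_iter number of iterations (default 10).
#' @param kappa conductance scale; `NULL` auto-sets it to the 90th percentile
#'   of the input's neighbour-difference magnitudes.
#' @param dt time step, must satisfy dt <= 1/6 (default 1/7).
#' @export
anisotropic_diffusion_3d <- function(volume, n_iter = 10, kappa = NULL,
                                     dt = 1 / 7) {
  stopifnot(inherits(volume, "intensity_volume"))
  v <- volume$values
  if (any(!is.finite(v))) stop("non-finite input")
  if (dt <= 0 || dt > 1 / 6) stop("dt must be in (0, 1/6]")
  d <- dim(v)
  if (is.null(kappa)) {
    g <- c(if (d[1] > 1) abs(v[-1, , , drop = FALSE] - v[-d[1], , , drop = FALSE]),
           if (d[2] > 1) abs(v[, -1, , drop = FALSE] - v[, -d[2], , drop = FALSE]),
           if (d[3] > 1) abs(v[, , -1, drop = FALSE] - v[, , -d[3], drop = FALSE]))
    kappa <- stats::quantile(g, 0.9, names = FALSE)
    if (!is.finite(kappa) || kappa <= 0) kappa <- 1
  }
  if (kappa <= 0) stop("kappa must be positive")
  out <- anisodiff3_cpp(as.numeric(v), d[1], d[2], d[3],
                        as.integer(n_iter), kappa, dt)
  res <- volume
  res$values <- array(out, d)
  res$provenance <- "enhanced"
  res
}

#' Global histogram equalization
#'
#' Display-only contrast stretch: optionally map to dB, then apply the
#' cumulative-histogram mapping (piecewise-linear between bin edges, hence
#' monotone non-decreasing and nearly exactly uniformizing) onto [0, 1]. The
#' output is flagged `log_scaled` so downstream quantitative code refuses it.
#'
#' @param volume nonnegative [intensity_volume()].
#' @param n_bins histogram bins (default 256).
#' @param on_log_scale equalize dB-scaled values (default TRUE); an -80 dB
#'   floor relative to the maximum avoids log(0).
#' @export
equalize_histogram <- function(volume, n_bins = 256, on_log_scale = TRUE) {
  stopifnot(inherits(volume, "intensity_volume"), n_bins >= 2)
  v <- volume$values
  if (any(v < 0)) stop("volume must be nonnegative")
  x <- if (on_log_scale) {
    floor_val <- max(v) * 1e-8
    10 * log10(pmax(v, floor_val))
  } else v
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant volume: identity mapping")
    out <- array(0.5, dim(v))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
    cdf <- c(0, cumsum(h)) / length(x)
    # piecewise-linear interpolation of the CDF between bin edges
    out <- array(stats::approx(edges, cdf, xout = x, rule = 2)$y, dim(v))
  }
  res <- volume
  res$values <- out
  res$log_scaled <- TRUE
  res$provenance <- "enhanced"
  res
}

# linear interpolation along the first margin of a 3-D array
interp_first_axis <- function(v, old_pitch, target) {
  d <- dim(v)
  n_out <- max(1L, as.integer(round(d[1] * old_pitch / target)))
  centers_in <- (seq_len(d[1]) - 0.5) * old_pitch
  centers_out <- (seq_len(n_out) - 0.5) * target
  pos <- (centers_out - centers_in[1]) / old_pitch + 1
  lo <- pmin(pmax(floor(pos), 1), d[1])
  hi <- pmin(lo + 1, d[1])
  f <- pmin(pmax(pos - lo, 0), 1)
  m <- matrix(v, d[1])
  out <- m[lo, , drop = FALSE] * (1 - f) + m[hi, , drop = FALSE] * f
  array(out, c(n_out, d[2], d[3]))
}

#' Resample to cube-shaped voxels
#'
#' Trilinear interpolation (separable, one axis at a time) onto an isotropic
#' grid, default 4 um sides; output physical extents match the input within
#' one voxel and the pitch metadata is updated.
#'
#' @param volume an [intensity_volume()].
#' @param target_voxel_um isotropic voxel pitch (default 4).
#' @export
resample_isotropic <- function(volume, target_voxel_um = 4) {
  stopifnot(inherits(volume, "intensity_volume"), target_voxel_um > 0)
  d <- dim(volume$values)
  pitches <- c(volume$axial_pitch_um, volume$lateral_pitch_um)
  if (any(target_voxel_um >= pitches * d))
    stop("target voxel exceeds the physical extent of an axis")
  v <- interp_first_axis(volume$values, pitches[1], target_voxel_um)
  v <- aperm(interp_first_axis(aperm(v, c(2, 1, 3)), pitches[2],
                               target_voxel_um), c(2, 1, 3))
  v <- aperm(interp_first_axis(aperm(v, c(3, 2, 1)), pitches[3],
                               target_voxel_um), c(3, 2, 1))
  intensity_volume(v, target_voxel_um, c(target_voxel_um, target_voxel_um),
                   provenance = volume$provenance,
                   log_scaled = volume$log_scaled,
                   n_frames = volume$n_frames)
}

median_filter_2d <- function(m, k) {
  if (k <= 1) return(m)
  r <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(NA_real_, c(nr, nc, (2 * r + 1)^2))
  s <- 1
  for (di in -r:r) for (dj in -r:r) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)   # replicate borders
    cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    stack[, , s] <- m[ri, cj]
    s <- s + 1
  }
  apply(stack, c(1, 2), stats::median)
}

#' Flatten a volume to its tissue surface
#'
#' Per lateral position the surface depth is the first sample where the
#' axially smoothed intensity exceeds `surface_threshold_fraction` times that
#' column's maximum; the surface map is median-filtered, and every column is
#' shifted (integer voxels) so the surface lies in one constant plane, with
#' zero padding for out-of-range voxels. En-face views of the flattened
#' volume then sample a constant depth below the surface.
#'
#' @param volume an [intensity_volume()].
#' @param surface_threshold_fraction threshold as a fraction of each column's
#'   maximum (default 0.5).
#' @param median_filter_px width of the square median filter applied to the
#'   surface map (default 5).
#' @return list with `volume` (flattened [intensity_volume()]),
#'   `surface_index` (x by y matrix of detected surface z indices) and
#'   `surface_um`.
#' @export
flatten_volume <- function(volume, surface_threshold_fraction = 0.5,
                           median_filter_px = 5) {
  stopifnot(inherits(volume, "intensity_volume"))
  v <- volume$values
  d <- dim(v)
  sm <- v
  if (d[1] >= 3) {   # light axial smoothing against speckle spikes
    sm <- (v[c(1, seq_len(d[1] - 1)), , , drop = FALSE] + v +
           v[c(seq_len(d[1] - 1) + 1, d[1]), , , drop = FALSE]) / 3
  }
  zsurf <- matrix(NA_real_, d[2], d[3])
  for (y in seq_len(d[3])) for (x in seq_len(d[2])) {
    col <- sm[, x, y]
    thr <- surface_threshold_fraction * max(col)
    idx <- which(col >= thr)
    if (length(idx)) zsurf[x, y] <- idx[1]
  }
  if (anyNA(zsurf)) {
    message(sum(is.na(zsurf)), " column(s) below threshold; surface ",
            "interpolated from neighbours")
    zsurf[is.na(zsurf)] <- stats::median(zsurf, na.rm = TRUE)
  }
  zsurf <- round(median_filter_2d(zsurf, median_filter_px))
  target <- min(zsurf)
  out <- array(0, d)
  for (y in seq_len(d[3])) for (x in seq_len(d[2])) {
    s <- zsurf[x, y] - target
    if (s == 0) out[, x, y] <- v[, x, y]
    else if (s > 0) out[seq_len(d[1] - s), x, y] <- v[(s + 1):d[1], x, y]
    else out[(1 - s):d[1], x, y] <- v[seq_len(d[1] + s), x, y]
  }
  res <- volume
  res$values <- out
  list(volume = res, surface_index = zsurf,
       surface_um = (zsurf - 1) * volume$axial_pitch_um)
}

#' Run the full enhancement chain
#'
#' Shadow-gain compensation, anisotropic diffusion, then histogram
#' equalization, in the fixed chain order.
#'
#' @param volume linear-scale [intensity_volume()].
#' @param config an [enhance_config()].
#' @export
enhance_chain <- function(volume, config = enhance_config()) {
  v <- remove_vessel_shadows(volume, config$gain_clip_max)
  v <- anisotropic_diffusion_3d(v, config$diffusion_n_iter,
                                config$diffusion_kappa, config$diffusion_dt)
  equalize_histogram(v, config$eq_n_bins, config$eq_on_log_scale)
}
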