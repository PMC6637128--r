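#' Linear-scale frame compounding
#'
#' Voxelwise arithmetic mean of per-frame intensity volumes. Compounding must
#' happen on linear intensity: the fully-developed-speckle laws (contrast
#' sigma/mu = 1 for one frame, 1/sqrt(M) for M uncorrelated frames) do not
#' hold on log-compressed data.
#'
#' @param volumes list of [intensity_volume()] objects with identical shapes
#'   and pitches, all linear-scale.
#' @return an [intensity_volume()] with provenance "compounded SM-OCT".
#' @export
compound_frames <- function(volumes) {
  stopifnot(is.list(volumes), length(volumes) >= 1)
  v1 <- volumes[[1]]
  for (v in volumes) {
    stopifnot(inherits(v, "intensity_volume"))
    if (v$log_scaled) stop("compounding requires linear-scale volumes")
    if (!identical(dim(v$values), dim(v1$values)) ||
        !isTRUE(all.equal(v$axial_pitch_um, v1$axial_pitch_um)) ||
        !isTRUE(all.equal(v$lateral_pitch_um, v1$lateral_pitch_um)))
      stop("mixed volume shapes or pitches")
  }
  acc <- Reduce(`+`, lapply(volumes, `[[`, "values"))
  intensity_volume(acc / length(volumes), v1$axial_pitch_um,
                   v1$lateral_pitch_um, provenance = "compounded SM-OCT",
                   n_frames = length(volumes))
}

roi_values <- function(volume, roi = NULL) {
  v <- volume$values
  if (is.null(roi)) return(as.numeric(v))
  if (is.array(roi) || is.logical(roi)) return(v[roi])
  stopifnot(is.list(roi))
  z <- if (is.null(roi$z)) seq_len(dim(v)[1]) else roi$z
  x <- if (is.null(roi$x)) seq_len(dim(v)[2]) else roi$x
  y <- if (is.null(roi$y)) seq_len(dim(v)[3]) else roi$y
  if (min(z) < 1 || max(z) > dim(v)[1] || min(x) < 1 || max(x) > dim(v)[2] ||
      min(y) < 1 || max(y) > dim(v)[3]) stop("ROI out of bounds")
  as.numeric(v[z, x, y])
}

#' Speckle contrast of a region of interest
#'
#' Contrast C = sigma/mu on linear intensity is the standard speckle-noise
#' measure: C = 1 for fully developed speckle, C = 1/sqrt(M) after averaging
#' M uncorrelated frames. `effective_n = 1/C^2` converts a measured contrast
#' back into an equivalent number of independent looks.
#'
#' @param volume linear-scale [intensity_volume()].
#' @param roi `NULL` (whole volume), a logical array, or a list with integer
#'   index vectors `z`, `x`, `y`; at least 100 voxels.
#' @return object of class `speckle_stats`.
#' @export
speckle_contrast <- function(volume, roi = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (volume$log_scaled) stop("speckle statistics require linear scale")
  vals <- roi_values(volume, roi)
  if (length(vals) < 100) stop("ROI must contain at least 100 voxels")
  mu <- mean(vals)
  if (mu == 0) stop("ROI mean is zero")
  s <- stats::sd(vals)
  structure(list(n_frames = volume$n_frames, roi = roi, mean = mu, sd = s,
                 contrast = s / mu, effective_n = (mu / s)^2),
            class = "speckle_stats")
}

#' @export
print.speckle_stats <- function(x, ...) {
  cat(sprintf("speckle_stats: M = %d, mu = %.4g, sd = %.4g, C = %.4g, effective N = %.3g\n",
              x$n_frames, x$mean, x$sd, x$contrast, x$effective_n))
  invisible(x)
}

#' Speckle contrast as a function of the number of averaged frames
#'
#' Compounds the first M per-frame volumes for each requested M, measures the
#' ROI contrast, and fits the slope of log C versus log M; for uncorrelated
#' speckle (diffuser correlation rho = 0) the slope is -1/2 — speckle noise
#' falls with the square root of the number of averaged frames.
#'
#' @param volumes list of per-frame linear [intensity_volume()] objects.
#' @param M_list frame counts to evaluate, e.g. `c(1, 4, 16, 64)`.
#' @param roi passed to [speckle_contrast()]; should cover a homogeneous
#'   region.
#' @return list with `table` (data.frame M, mean, sd, contrast, effective_n)
#'   and `slope` (least-squares log-log slope).
#' @export
contrast_vs_frames <- function(volumes, M_list = c(1, 4, 16, 64), roi = NULL) {
  stopifnot(is.list(volumes))
  M_list <- sort(unique(as.integer(M_list)))
  if (length(volumes) < max(M_list))
    stop("fewer frames than max(M_list)")
  rows <- lapply(M_list, function(M) {
    st <- speckle_contrast(compound_frames(volumes[seq_len(M)]), roi)
    data.frame(M = M, mean = st$mean, sd = st$sd, contrast = st$contrast,
               effective_n = st$effective_n)
  })
  tab <- do.call(rbind, rows)
  slope <- if (nrow(tab) >= 2)
    unname(stats::coef(stats::lm(log(contrast) ~ log(M), data = tab))[2])
  else NA_real_
  list(table = tab, slope = slope)
}
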