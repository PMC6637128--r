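#' Acquisition protocol specification
#'
#' Bundles a phantom with an acquisition configuration emulating the two
#' protocols the instrument was run with: volumes at 6 um lateral spacing
#' with 18-40 averages, and dense B-scans at 4 um spacing with 100 averages.
#' The diffuser correlation selects the branch: `rho = 0` is SM-OCT
#' (uncorrelated speckle every frame), `rho = 1` is the conventional-OCT
#' control with the diffuser removed.
#'
#' @param name protocol label.
#' @param phantom a [phantom_spec()].
#' @param n_ascans,n_bscans scan grid.
#' @param lateral_pitch_um,bscan_pitch_um lateral sampling (microns).
#' @param M number of repeated frames.
#' @param rho diffuser frame correlation in [0, 1].
#' @param dispersion true `c(a2, a3)` used to corrupt the spectra.
#' @param compensate logical: estimate and apply dispersion compensation
#'   (FALSE reconstructs with the known truth negated, the usual case when
#'   the corruption is zero).
#' @param noise_sd additive spectral noise standard deviation.
#' @param n_samples,center_nm,fwhm_nm source configuration.
#' @param lateral_psf_fwhm_um beam intensity FWHM.
#' @param enhance an [enhance_config()].
#' @param slab_window_um depth window below the flattened surface averaged
#'   into the en-face slab for margin work (default c(50, 150)).
#' @param contrast_roi optional ROI (see [speckle_contrast()]) in a
#'   homogeneous region, enabling the per-M contrast table.
#' @param M_list frame counts for the contrast table.
#' @param seed master seed; field, diffuser and noise seeds derive from it.
#' @export
protocol_spec <- function(name, phantom, n_ascans, n_bscans = 1,
                          lateral_pitch_um = 6,
                          bscan_pitch_um = lateral_pitch_um,
                          M = 40, rho = 0, dispersion = c(0, 0),
                          compensate = FALSE, noise_sd = 1e-3,
                          n_samples = 1024, center_nm = 1300, fwhm_nm = 170,
                          lateral_psf_fwhm_um = 9,
                          enhance = enhance_config(),
                          slab_window_um = c(50, 150),
                          contrast_roi = NULL,
                          M_list = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"), M >= 1,
            rho >= 0, rho <= 1)
  structure(list(name = name, phantom = phantom,
                 n_ascans = as.integer(n_ascans),
                 n_bscans = as.integer(n_bscans),
                 lateral_pitch_um = lateral_pitch_um,
                 bscan_pitch_um = bscan_pitch_um,
                 M = as.integer(M), rho = rho,
                 dispersion = as.numeric(dispersion),
                 compensate = compensate, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples),
                 center_nm = center_nm, fwhm_nm = fwhm_nm,
                 lateral_psf_fwhm_um = lateral_psf_fwhm_um,
                 enhance = enhance, slab_window_um = slab_window_um,
                 contrast_roi = contrast_roi, M_list = M_list,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Volume protocol defaults (6 um pitch, 18-40 averages)
#' @param ... passed to [protocol_spec()].
#' @inheritParams protocol_spec
#' @export
volume_protocol <- function(name, phantom, n_ascans, n_bscans, M = 40, ...) {
  if (M < 18 || M > 40)
    warning("volume protocol conventionally uses 18 to 40 averages")
  protocol_spec(name, phantom, n_ascans, n_bscans, lateral_pitch_um = 6,
                M = M, ...)
}

#' B-scan protocol defaults (4 um pitch, 100 averages)
#' @param ... passed to [protocol_spec()].
#' @inheritParams protocol_spec
#' @export
bscan_protocol <- function(name, phantom, n_ascans, M = 100, ...) {
  protocol_spec(name, phantom, n_ascans, n_bscans = 1, lateral_pitch_um = 4,
                M = M, ...)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

enface_slab <- function(volume, window_um) {
  nz <- dim(volume$values)[1]
  z_lo <- max(1L, 1L + floor(window_um[1] / volume$axial_pitch_um))
  z_hi <- min(nz, 1L + ceiling(window_um[2] / volume$axial_pitch_um))
  if (z_hi <= z_lo) stop("slab window outside the depth range")
  apply(volume$values[z_lo:z_hi, , , drop = FALSE], c(2, 3), mean)
}

#' Run an end-to-end acquisition protocol on a phantom
#'
#' Phantom to scatterer field to raw frames (with diffuser states) to
#' reconstruction to compounding to enhancement to margin/layer metrics,
#' fully deterministic under the protocol seed. The M-frame compound is the
#' SM-OCT (or, at rho = 1, OCT-control) product; the first single frame is
#' always kept as the conventional speckled reference.
#'
#' @param ps a [protocol_spec()].
#' @param out_dir optional directory; when given, volumes (TIFF), the
#'   contrast table (CSV), the frame set and a JSON metrics report are
#'   written there.
#' @return a report list with the compounded and single-frame volumes, the
#'   flattened volume, speckle statistics, the contrast table (when a
#'   `contrast_roi` was configured), margin and layer metrics (when the
#'   phantom defines tumors/layers), and provenance metadata.
#' @export
run_protocol <- function(ps, out_dir = NULL) {
  stopifnot(inherits(ps, "protocol_spec"))
  field <- with_stage("phantom", build_scatterer_field(ps$phantom))
  source <- with_stage("forward",
                       make_source_spectrum(ps$center_nm, ps$fwhm_nm,
                                            ps$n_samples))
  geometry <- scan_geometry(ps$n_ascans, ps$n_bscans, ps$lateral_pitch_um,
                            ps$bscan_pitch_um, ps$lateral_psf_fwhm_um)
  diffuser <- with_stage("forward",
                         diffuser_sequence(ps$M, ps$rho,
                                           nrow(field$positions),
                                           seed = ps$seed + 1L))
  frames <- with_stage("forward",
                       simulate_frames(field, source, geometry,
                                       ps$dispersion, diffuser,
                                       noise_sd = ps$noise_sd,
                                       seed = ps$seed + 2L))
  model <- if (ps$compensate)
    with_stage("reconstruct", estimate_dispersion(frames))
  else dispersion_model(ps$dispersion[1], ps$dispersion[2])
  vols <- with_stage("reconstruct", reconstruct_volume(frames, model))
  compound <- with_stage("compound", compound_frames(vols))
  single <- vols[[1]]

  contrast <- NULL
  if (!is.null(ps$contrast_roi)) {
    Ms <- ps$M_list %||% unique(pmin(c(1, 4, 16, 64), ps$M))
    contrast <- with_stage("compound",
                           contrast_vs_frames(vols, Ms, ps$contrast_roi))
  }

  shadowed <- with_stage("enhance",
                         remove_vessel_shadows(compound,
                                               ps$enhance$gain_clip_max))
  smooth <- with_stage("enhance",
                       anisotropic_diffusion_3d(shadowed,
                                                ps$enhance$diffusion_n_iter,
                                                ps$enhance$diffusion_kappa,
                                                ps$enhance$diffusion_dt))
  display <- with_stage("enhance",
                        equalize_histogram(smooth, ps$enhance$eq_n_bins,
                                           ps$enhance$eq_on_log_scale))
  flat <- with_stage("enhance",
                     flatten_volume(compound,
                                    ps$enhance$flatten_threshold_fraction,
                                    ps$enhance$flatten_median_px))

  region_types <- vapply(ps$phantom$regions, `[[`, "", "type")
  margin <- NULL
  if (any(region_types == "tumor")) {
    margin <- with_stage("margin", {
      slab <- enface_slab(flat$volume, ps$slab_window_um)
      flat1 <- flatten_volume(single, ps$enhance$flatten_threshold_fraction,
                              ps$enhance$flatten_median_px)
      slab1 <- enface_slab(flat1$volume, ps$slab_window_um)
      pitch <- c(ps$lateral_pitch_um, ps$bscan_pitch_um)
      mask <- segment_tumor(slab, pitch)
      mask1 <- segment_tumor(slab1, pitch)
      truth <- ground_truth_masks(ps$phantom, c(pitch, ps$phantom$extent_um[3]))
      tumor_ids <- which(region_types == "tumor")
      tmask <- matrix(truth$labels[, , 1] %in% tumor_ids,
                      dim(truth$labels)[1], dim(truth$labels)[2])
      out <- list(threshold = attr(mask, "threshold"),
                  mask = mask, mask_single = mask1, truth_mask = tmask)
      if (any(mask) && any(tmask)) {
        curve <- extract_margin_curve(mask, pitch)
        truth_curve <- extract_margin_curve(tmask, pitch)
        out$curve <- curve
        out$error <- margin_error(curve, truth_curve)
        if (any(mask1))
          out$error_single <- margin_error(
            extract_margin_curve(mask1, pitch), truth_curve)
      }
      out
    })
  }

  layers <- NULL
  if (sum(region_types == "layer") >= 2) {
    layers <- with_stage("margin", {
      ls <- ps$phantom$regions[region_types == "layer"]
      edges <- sort(unique(c(vapply(ls, `[[`, 0, "z_min"),
                             vapply(ls, `[[`, 0, "z_max"))))
      flat1 <- flatten_volume(single, ps$enhance$flatten_threshold_fraction,
                              ps$enhance$flatten_median_px)
      list(compound = layer_profile(flat$volume, edges),
           single = layer_profile(flat1$volume, edges))
    })
  }

  report <- list(name = ps$name, spec = ps, dispersion_model = model,
                 frames = frames, volumes = vols,
                 compound = compound, single = single,
                 enhanced = display, flattened = flat,
                 contrast = contrast, margin = margin, layers = layers,
                 speckle = speckle_contrast(compound))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    with_stage("io", {
      write_volume_tiff(compound, file.path(out_dir, "compound.tiff"))
      write_volume_tiff(single, file.path(out_dir, "single_frame.tiff"))
      write_volume_tiff(display, file.path(out_dir, "enhanced.tiff"))
      write_frameset(frames, file.path(out_dir, "frames.rds"))
      if (!is.null(contrast))
        write_contrast_csv(contrast, file.path(out_dir, "contrast.csv"))
      metrics <- list(name = ps$name, M = ps$M, rho = ps$rho,
                      speckle_contrast = report$speckle$contrast,
                      contrast_table = if (!is.null(contrast)) contrast$table,
                      contrast_slope = if (!is.null(contrast)) contrast$slope,
                      margin_mean_abs_error_um =
                        if (!is.null(margin$error)) margin$error$mean_abs_error_um,
                      margin_p95_error_um =
                        if (!is.null(margin$error)) margin$error$p95_error_um,
                      layer_cnr_compound =
                        if (!is.null(layers)) layers$compound$cnr,
                      layer_cnr_single =
                        if (!is.null(layers)) layers$single$cnr)
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }
  report
}
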