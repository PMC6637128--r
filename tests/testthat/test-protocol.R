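tiny_margin_phantom <- function(seed = 71) {
  phantom_spec(c(144, 144, 50),
               regions = list(
                 region_layer(8, 40, 0.06, 0.004),
                 region_tumor(c(72 + 900, 72, 24), c(900, 2000, 2000),
                              0.06, 0.0016)),
               seed = seed)
}

tiny_protocol <- function(rho = 0, M = 6, seed = 81) {
  protocol_spec("tiny", tiny_margin_phantom(), n_ascans = 24, n_bscans = 24,
                lateral_pitch_um = 6, M = M, rho = rho, noise_sd = 1e-4,
                n_samples = 96, slab_window_um = c(10, 32), seed = seed,
                enhance = enhance_config(diffusion_n_iter = 3,
                                         flatten_median_px = 3))
}

test_that("protocol reports are complete and bit-reproducible", {
  rep1 <- run_protocol(tiny_protocol())
  # report contract: compound + single volumes, speckle stats, margin block
  expect_s3_class(rep1$compound, "intensity_volume")
  expect_equal(rep1$compound$provenance, "compounded SM-OCT")
  expect_equal(rep1$compound$n_frames, 6L)
  expect_s3_class(rep1$single, "intensity_volume")
  expect_s3_class(rep1$speckle, "speckle_stats")
  expect_true(rep1$enhanced$log_scaled)
  expect_false(is.null(rep1$margin))
  expect_true(is.numeric(rep1$margin$error$mean_abs_error_um))

  rep2 <- run_protocol(tiny_protocol())
  expect_identical(rep1$compound$values, rep2$compound$values)
  expect_identical(rep1$margin$error, rep2$margin$error)
})

test_that("tumor discrimination: tumor side is darker and margin found", {
  rep <- run_protocol(tiny_protocol())
  cp <- rep$flattened$volume$values
  zz <- seq_len(dim(cp)[1])
  slab <- apply(cp[zz > 8 & zz < 28, , , drop = FALSE], c(2, 3), mean)
  brain <- mean(slab[1:10, ])
  tumor <- mean(slab[15:24, ])
  expect_lt(tumor, brain)
  # segmented margin sits near the true x = 72 boundary
  expect_lt(rep$margin$error$mean_abs_error_um, 12)
})

test_that("diffuser-off control leaves contrast unchanged; SM-OCT reduces it", {
  ph <- phantom_spec(c(48 * 6, 10, 60),
                     regions = list(region_layer(10, 50, 0.06, 0.002)),
                     seed = 91)
  zmid <- function(v) {
    zz <- (seq_len(dim(v$values)[1]) - 1) * v$axial_pitch_um
    list(z = which(zz > 14 & zz < 46), x = 4:45)
  }
  run_branch <- function(rho) {
    ps <- protocol_spec("branch", ph, n_ascans = 48, n_bscans = 1,
                        lateral_pitch_um = 6, M = 8, rho = rho,
                        noise_sd = 1e-4, n_samples = 128, seed = 93)
    run_protocol(ps)
  }
  sm <- run_branch(0)
  oct <- run_branch(1)
  roi <- zmid(sm$single)
  c_sm1 <- speckle_contrast(sm$single, roi)$contrast
  c_sm <- speckle_contrast(sm$compound, roi)$contrast
  c_oct1 <- speckle_contrast(oct$single, roi)$contrast
  c_oct <- speckle_contrast(oct$compound, roi)$contrast
  # rho = 1, M > 1: within 5% of the single-frame contrast
  expect_gt(c_oct, 0.95 * c_oct1)
  expect_lt(abs(c_oct - c_oct1) / c_oct1, 0.05)
  # paired-branch property: SM-OCT compound contrast < OCT control's
  expect_lt(c_sm, c_oct)
  expect_lt(c_sm, 0.6 * c_sm1)  # M = 8 should give a large reduction
})

test_that("protocol artifacts are persisted when out_dir is given", {
  out <- file.path(tempdir(), "smoct-proto")
  on.exit(unlink(out, recursive = TRUE))
  ps <- tiny_protocol()
  ps$contrast_roi <- list(z = 10:25, x = 2:23, y = 2:23)
  ps$M_list <- c(1, 4)
  rep <- run_protocol(ps, out_dir = out)
  expect_true(file.exists(file.path(out, "compound.tiff")))
  expect_true(file.exists(file.path(out, "single_frame.tiff")))
  expect_true(file.exists(file.path(out, "contrast.csv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  metrics <- jsonlite::fromJSON(file.path(out, "metrics.json"))
  expect_equal(metrics$M, 6)
  back <- read_volume_tiff(file.path(out, "compound.tiff"))
  expect_equal(dim(back$values), dim(rep$compound$values))
})

test_that("stage errors carry stage tags", {
  ps <- tiny_protocol()
  ps$slab_window_um <- c(500, 600)   # outside the depth range
  expect_error(run_protocol(ps), "\\[margin\\]")
})

test_that("phantom and protocol configs round-trip through JSON", {
  ph <- tiny_margin_phantom()
  cfg <- phantom_to_config(ph)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  back <- phantom_from_config(jsonlite::fromJSON(json, simplifyVector = TRUE,
                                                 simplifyDataFrame = FALSE,
                                                 simplifyMatrix = FALSE))
  expect_equal(back$extent_um, ph$extent_um)
  expect_equal(length(back$regions), 2)
  expect_equal(back$regions[[2]]$radii, ph$regions[[2]]$radii)
  expect_identical(build_scatterer_field(back)$positions,
                   build_scatterer_field(ph)$positions)
})

test_that("the CLI runs a protocol end to end", {
  out <- file.path(tempdir(), "smoct-cli")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  cfg <- list(
    phantom = phantom_to_config(
      phantom_spec(c(96, 12, 50),
                   regions = list(region_layer(8, 40, 0.06, 0.003)),
                   seed = 7)),
    protocol = list(name = "cli-test", n_ascans = 16, n_bscans = 1, M = 2,
                    rho = 0, n_samples = 96, noise_sd = 1e-4,
                    slab_window_um = c(8, 30)))
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path), add = TRUE)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)

  status <- suppressMessages(
    smoct_cli(c("protocol", "run", "--config", cfg_path,
                "--out-dir", out, "--seed", "5")))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "metrics.json")))

  frames_path <- tempfile(fileext = ".rds")
  on.exit(unlink(frames_path), add = TRUE)
  status2 <- suppressMessages(
    smoct_cli(c("simulate", "--config", cfg_path, "--out", frames_path)))
  expect_equal(status2, 0L)
  fr <- read_frameset(frames_path)
  expect_s3_class(fr, "spectral_frame_set")

  # bad input: nonzero status, no exception
  expect_equal(suppressMessages(smoct_cli(c("reconstruct"))), 1L)
  expect_equal(suppressMessages(smoct_cli(c("bogus"))), 2L)
})
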