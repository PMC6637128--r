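test_that("shadow gain equalizes depth-means exactly where unclipped", {
  # depth-uniform volume: all gains 1, output = input
  set.seed(1)
  flat <- intensity_volume(array(rep(1:10, 64), c(10, 8, 8)), 4, c(6, 6))
  out <- remove_vessel_shadows(flat)
  expect_equal(out$values, flat$values)
  expect_true(all(attr(out, "gain") == 1))

  # one dark column: gain = T / m by definition
  v <- array(1, c(10, 4, 1))
  v[, 2, 1] <- 0.5
  vol <- intensity_volume(v, 4, c(6, 6))
  out2 <- remove_vessel_shadows(vol)
  Tbar <- mean(c(1, 0.5, 1, 1))
  expect_equal(attr(out2, "gain")[2, 1], Tbar / 0.5)

  # random shadowed volume: post-gain depth-mean CV < 1e-6, pre-gain > 0.1
  set.seed(2)
  r <- array(rexp(10 * 12 * 6), c(10, 12, 6))
  r[, 3:5, 2:4] <- r[, 3:5, 2:4] * 0.2
  rv <- intensity_volume(r, 4, c(6, 6))
  pre <- colMeans(rv$values)
  expect_gt(sd(pre) / mean(pre), 0.1)
  post <- colMeans(remove_vessel_shadows(rv)$values)
  expect_lt(sd(post) / mean(post), 1e-6)

  # zero column hits the clip and is reported
  z <- array(1, c(5, 4, 1)); z[, 1, 1] <- 0
  expect_message(remove_vessel_shadows(intensity_volume(z, 4, c(6, 6))),
                 "clip")
})

test_that("anisotropic diffusion conserves mean, extrema and constants", {
  const <- intensity_volume(array(3.7, c(12, 10, 8)), 4, c(4, 4))
  expect_equal(anisotropic_diffusion_3d(const, n_iter = 5)$values,
               const$values)

  set.seed(3)
  noisy <- intensity_volume(array(rexp(16 * 14 * 10), c(16, 14, 10)),
                            4, c(4, 4))
  out <- anisotropic_diffusion_3d(noisy, n_iter = 10)
  expect_lt(abs(mean(out$values) - mean(noisy$values)) / mean(noisy$values),
            1e-6)
  expect_gte(min(out$values), min(noisy$values) - 1e-12)
  expect_lte(max(out$values), max(noisy$values) + 1e-12)

  expect_error(anisotropic_diffusion_3d(noisy, dt = 0.2), "dt")
  bad <- noisy; bad$values[1] <- NaN
  expect_error(anisotropic_diffusion_3d(bad), "finite")
})

test_that("diffusion retains step edges better than a matched Gaussian blur", {
  # 3-D step edge with additive noise; oracle: Gaussian blur matched to the
  # same noise-variance reduction on the same realization
  set.seed(4)
  dims <- c(8, 40, 8)
  clean <- array(1, dims)
  clean[, 21:40, ] <- 3
  noisy <- clean + array(rnorm(prod(dims), 0, 0.25), dims)
  vol <- intensity_volume(pmax(noisy, 0), 4, c(4, 4))
  pm <- anisotropic_diffusion_3d(vol, n_iter = 10, kappa = 0.5)$values

  edge_grad <- function(a) mean(abs(a[, 21, ] - a[, 20, ]))
  noise_var <- function(a) var(as.numeric(a[, 5:16, ]))
  target_var <- noise_var(pm)

  gauss_blur_x <- function(a, sigma) {
    half <- max(1, ceiling(3 * sigma))
    kern <- dnorm(-half:half, sd = sigma); kern <- kern / sum(kern)
    out <- array(0, dim(a))
    for (t in seq_along(kern)) {
      sh <- t - half - 1
      idx <- pmin(pmax(seq_len(dim(a)[2]) + sh, 1), dim(a)[2])
      out <- out + kern[t] * a[, idx, , drop = FALSE]
    }
    out
  }
  # find the blur width with equal variance reduction
  sigmas <- seq(0.3, 4, by = 0.1)
  vars <- vapply(sigmas, function(s) noise_var(gauss_blur_x(vol$values, s)),
                 numeric(1))
  s_match <- sigmas[which.min(abs(vars - target_var))]
  gb <- gauss_blur_x(vol$values, s_match)

  g0 <- edge_grad(vol$values)
  expect_gt(edge_grad(pm) / g0, edge_grad(gb) / g0)
})

test_that("histogram equalization is monotone and uniformizing", {
  set.seed(5)
  v <- intensity_volume(array(rexp(40 * 30 * 10), c(40, 30, 10)), 4, c(4, 4))
  eq <- equalize_histogram(v, n_bins = 256, on_log_scale = TRUE)
  expect_true(eq$log_scaled)
  # monotone non-decreasing mapping
  o <- order(v$values)
  expect_true(all(diff(eq$values[o]) >= -1e-12))
  # post-equalization histogram near-uniform: max bin <= 2x mean bin
  h <- tabulate(pmin(floor(eq$values * 256) + 1, 256), nbins = 256)
  expect_lte(max(h), 2 * mean(h))
  # already-uniform input is (nearly) a fixed point up to bin quantization
  u <- intensity_volume(array(seq(0, 1, length.out = 4000), c(40, 10, 10)),
                        4, c(4, 4))
  eu <- equalize_histogram(u, n_bins = 256, on_log_scale = FALSE)
  expect_lt(max(abs(eu$values - u$values)), 1 / 256 + 1e-9)
  expect_warning(equalize_histogram(
    intensity_volume(array(1, c(10, 10, 1)), 4, c(4, 4))), "constant")
})

test_that("isotropic resampling follows extent arithmetic exactly", {
  # pitches (2, 6, 6), extent 512 x 600 x 600 -> 128 x 150 x 150 at 4 um
  set.seed(6)
  smooth <- function(n) (sin(seq(0, 3, length.out = n)) + 2)
  v <- array(outer(smooth(256), outer(smooth(100), smooth(100))),
             c(256, 100, 100))
  vol <- intensity_volume(v, 2, c(6, 6))
  out <- resample_isotropic(vol, 4)
  expect_equal(dim(out$values), c(128L, 150L, 150L))
  expect_equal(out$axial_pitch_um, 4)
  expect_equal(out$lateral_pitch_um, c(4, 4))
  # volume integral of the smooth phantom preserved within 1%
  int_in <- mean(v)
  int_out <- mean(out$values)
  expect_rel_equal(int_out, int_in, 0.01)

  # constant volume: constant output, exactly
  cv <- resample_isotropic(intensity_volume(array(2.5, c(20, 30, 30)),
                                            2, c(6, 6)), 4)
  expect_true(all(cv$values == 2.5))

  # already isotropic at the target: identity up to round-off
  iso <- intensity_volume(array(rexp(10 * 12 * 14), c(10, 12, 14)), 4, c(4, 4))
  out2 <- resample_isotropic(iso, 4)
  expect_equal(dim(out2$values), dim(iso$values))
  expect_lt(max(abs(out2$values - iso$values)), 1e-9)

  expect_error(resample_isotropic(iso, 100), "extent")
})

test_that("flattening recovers planar surfaces and aligns tissue", {
  # surface already at z = 0: zero shift
  set.seed(7)
  v0 <- array(0, c(30, 16, 16))
  v0[1:20, , ] <- 1
  f0 <- flatten_volume(intensity_volume(v0, 4, c(6, 6)))
  expect_true(all(f0$surface_index == 1))
  expect_equal(f0$volume$values, v0)

  # tilted plane of known slope: recovered within one voxel across the field
  nz <- 60; nx <- 24; ny <- 10
  v <- array(0, c(nz, nx, ny))
  z0 <- function(x) 4 + round(0.5 * x)   # slope 0.5 voxel per column
  for (x in seq_len(nx)) v[z0(x):nz, x, ] <- 1
  fl <- flatten_volume(intensity_volume(v, 4, c(6, 6)), median_filter_px = 3)
  truth <- vapply(seq_len(nx), z0, numeric(1))
  expect_lte(max(abs(fl$surface_index - truth)), 1)
  # post-flattening the surface sits at one constant index +/- 1
  first_tissue <- apply(fl$volume$values, c(2, 3),
                        function(col) which(col > 0.5)[1])
  expect_lte(diff(range(first_tissue)), 1)
})

test_that("the chain runs in order and flags display output", {
  fx <- fix_speckle()
  cp <- compound_frames(fx$vols)
  out <- enhance_chain(cp, enhance_config(diffusion_n_iter = 3))
  expect_true(out$log_scaled)
  expect_equal(out$provenance, "enhanced")
  expect_error(remove_vessel_shadows(out), "linear")
})
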