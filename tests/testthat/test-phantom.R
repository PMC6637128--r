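test_that("empty and invalid specs behave per contract", {
  spec <- phantom_spec(c(100, 100, 100), regions = list(),
                       background_density = 0, seed = 1)
  field <- build_scatterer_field(spec)
  expect_equal(nrow(field$positions), 0)

  expect_error(phantom_spec(c(0, 100, 100)), "positive")
  expect_error(phantom_spec(c(100, 100, 100), background_density = -1),
               "negative density")
  expect_error(region_layer(0, 50, -0.1, 1), "density")
  expect_error(region_fascicle(c(0, 0, 0), c(1, 0, 0), 0, 0.1, 1))
})

test_that("amplitudes are Rayleigh with the region mean; tumor 0.3x layer", {
  layer <- region_layer(0, 60, 0.05, 1.0)
  tumor <- region_tumor(c(100, 100, 30), c(60, 60, 25), 0.05, 0.3)
  spec <- phantom_spec(c(200, 200, 60), regions = list(layer, tumor),
                       seed = 5)
  field <- build_scatterer_field(spec)
  a_layer <- field$amplitudes[field$region_labels == 1]
  a_tumor <- field$amplitudes[field$region_labels == 2]
  expect_gt(length(a_layer), 1e4)
  expect_gt(length(a_tumor), 1e4)
  # sample-mean oracle over the drawn amplitudes, 5% tolerance
  expect_rel_equal(mean(a_tumor) / mean(a_layer), 0.3, 0.05)
  expect_rel_equal(mean(a_layer), 1.0, 0.05)
  # Rayleigh shape: sd/mean = sqrt(4/pi - 1)
  expect_rel_equal(sd(a_layer) / mean(a_layer), sqrt(4 / pi - 1), 0.05)
})

test_that("identical seeds give bit-identical fields and masks", {
  mk <- function() {
    spec <- phantom_spec(c(150, 120, 80),
                         regions = list(
                           region_layer(0, 40, 0.03, 0.8),
                           region_fascicle(c(10, 60, 20), c(140, 60, 20),
                                           50, 0.08, 1.5),
                           region_vessel(c(75, 0, 15), c(75, 120, 15), 20,
                                         0.05)),
                         background_density = 0.005, seed = 99)
    list(f = build_scatterer_field(spec),
         m = ground_truth_masks(spec, c(4, 4, 4)))
  }
  a <- mk(); b <- mk()
  expect_identical(a$f$positions, b$f$positions)
  expect_identical(a$f$amplitudes, b$f$amplitudes)
  expect_identical(a$m$labels, b$m$labels)
  # a different seed changes the realization
  spec2 <- phantom_spec(c(150, 120, 80),
                        regions = list(region_layer(0, 40, 0.03, 0.8)),
                        seed = 100)
  expect_false(identical(build_scatterer_field(spec2)$positions,
                         a$f$positions))
})

test_that("Poisson counts match density x volume over many seeds", {
  # small layer so 200 seeds stay fast; lambda = 0.02 * 50*50*20 = 1000
  lambda <- 0.02 * 50 * 50 * 20
  counts <- vapply(1:200, function(s) {
    spec <- phantom_spec(c(50, 50, 20),
                         regions = list(region_layer(0, 20, 0.02, 1)),
                         seed = s)
    nrow(build_scatterer_field(spec)$positions)
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("ground-truth masks label voxel centers with last-region-wins", {
  # empty spec: all background
  empty <- ground_truth_masks(phantom_spec(c(40, 40, 40)), 4)
  expect_true(all(empty$labels == 0))

  # single full-extent layer: everything labeled
  one <- ground_truth_masks(
    phantom_spec(c(40, 40, 40), regions = list(region_layer(0, 41, 0.1, 1))),
    4)
  expect_true(all(one$labels == 1))

  # overlap: later region wins
  spec <- phantom_spec(c(40, 40, 40),
                       regions = list(region_layer(0, 41, 0.1, 1),
                                      region_layer(20, 41, 0.1, 0.5)))
  m <- ground_truth_masks(spec, 4)
  expect_true(all(m$labels[, , 1:5] == 1))
  expect_true(all(m$labels[, , 6:10] == 2))
  expect_named(m$legend, c("background", "layer1", "layer2"))

  expect_error(ground_truth_masks(spec, c(4, 4, 50)), "extent")
  expect_error(ground_truth_masks(spec, -1), "positive")
})

test_that("half-space tumor voxel fraction matches analytic geometry", {
  # huge ellipsoid emulating the half-space x > 120 in a 240-wide block
  tumor <- region_tumor(c(120 + 1e5, 120, 30), c(1e5, 4e5, 4e5), 0.05, 0.3)
  spec <- phantom_spec(c(240, 240, 60), regions = list(tumor), seed = 3)
  m <- ground_truth_masks(spec, 4)
  frac <- mean(m$labels == 1)
  # analytic volume fraction 0.5, +/- one voxel shell (4/240)
  expect_lt(abs(frac - 0.5), 4 / 240)
})

test_that("scatterer labels agree with mask labels for >= 99% of points", {
  spec <- phantom_spec(c(150, 120, 80),
                       regions = list(
                         region_layer(0, 40, 0.05, 0.8),
                         region_fascicle(c(10, 60, 20), c(140, 60, 20),
                                         50, 0.08, 1.5)),
                       background_density = 0.01, seed = 7)
  field <- build_scatterer_field(spec)
  m <- ground_truth_masks(spec, c(2, 2, 2))
  idx <- cbind(pmin(pmax(ceiling(field$positions[, 1] / 2), 1), dim(m$labels)[1]),
               pmin(pmax(ceiling(field$positions[, 2] / 2), 1), dim(m$labels)[2]),
               pmin(pmax(ceiling(field$positions[, 3] / 2), 1), dim(m$labels)[3]))
  agree <- m$labels[idx] == field$region_labels
  expect_gt(mean(agree), 0.99)
})

test_that("fascicle diameters in the 40-80 um anatomical range are honored", {
  d <- 60
  fas <- region_fascicle(c(0, 50, 30), c(150, 50, 30), d, 0.1, 1.5)
  spec <- phantom_spec(c(150, 100, 60), regions = list(fas), seed = 11)
  field <- build_scatterer_field(spec)
  r <- sqrt((field$positions[, 2] - 50)^2 + (field$positions[, 3] - 30)^2)
  expect_lte(max(r), d / 2 + 1e-9)
  # points fill the tube: radial extent close to the nominal radius
  expect_gt(max(r), 0.9 * d / 2)
})

test_that("tumor fingers project along +x from the ellipsoid surface", {
  tum <- region_tumor(c(60, 100, 40), c(40, 50, 30), 0.05, 0.3,
                      n_fingers = 3, finger_length_um = 60,
                      finger_width_um = 16)
  spec <- phantom_spec(c(250, 200, 80), regions = list(tum), seed = 13)
  field <- build_scatterer_field(spec)
  # some scatterers beyond the ellipsoid +x surface, inside fingers
  beyond <- field$positions[, 1] > 60 + 40 + 1
  expect_gt(sum(beyond), 0)
  expect_lte(max(field$positions[, 1]), 60 + 40 + 60 + 1e-6)
  # mask has finger voxels labeled tumor beyond the ellipsoid
  m <- ground_truth_masks(spec, 4)
  expect_gt(sum(m$labels[seq(ceiling(104 / 4), 40), , ] == 1), 0)
})
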