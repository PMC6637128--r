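# Shared fixtures, built once per test run and cached (helpers are loaded a
# single time for the whole suite, so expensive simulations are reused
# across test files).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a single reflector at 200 um optical depth, 1024-sample source
fix_reflector_frames <- function(dispersion = c(0, 0), n_samples = 1024) {
  key <- sprintf("refl_%g_%g_%d", dispersion[1], dispersion[2], n_samples)
  fixture(key, function() {
    spec <- phantom_spec(c(48, 48, 400), seed = 1)
    field <- build_scatterer_field(spec)
    field$positions <- matrix(c(21, 24, 200), 1)
    field$amplitudes <- 0.01
    field$region_labels <- 0L
    src <- make_source_spectrum(1300, 170, n_samples)
    geom <- scan_geometry(n_ascans = 8, lateral_pitch_um = 6)
    dif <- diffuser_sequence(1, 1, 1, seed = 2)
    suppressWarnings(simulate_frames(field, src, geom, dispersion, dif,
                                     noise_sd = 0, seed = 3))
  })
}

# small homogeneous speckle acquisition: thin-y slab, M = 16 uncorrelated
# frames; reused by forward/compound/protocol tests
fix_speckle <- function() {
  fixture("speckle16", function() {
    ph <- phantom_spec(c(64 * 6, 10, 70),
                       regions = list(region_layer(10, 60, 0.06, 0.002)),
                       seed = 41)
    field <- build_scatterer_field(ph)
    src <- make_source_spectrum(1300, 170, 128)
    geom <- scan_geometry(n_ascans = 64, lateral_pitch_um = 6)
    dif <- diffuser_sequence(16, 0, nrow(field$positions), seed = 42)
    frames <- simulate_frames(field, src, geom, c(0, 0), dif,
                              noise_sd = 1e-4, seed = 43)
    vols <- reconstruct_volume(frames)
    zz <- (seq_len(dim(vols[[1]]$values)[1]) - 1) * vols[[1]]$axial_pitch_um
    list(phantom = ph, field = field, source = src, geometry = geom,
         diffuser = dif, frames = frames, vols = vols,
         roi = list(z = which(zz > 15 & zz < 55), x = 4:61))
  })
}

# synthetic per-frame volumes with i.i.d. unit-mean exponential intensities
# (the fully developed speckle law without the OCT forward model)
make_exp_vols <- function(M, dims = c(25, 20, 20), seed = 7) {
  set.seed(seed)
  lapply(seq_len(M), function(m)
    intensity_volume(array(stats::rexp(prod(dims)), dims), 4, c(4, 4)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
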