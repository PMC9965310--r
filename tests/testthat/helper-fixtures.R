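# Shared fixtures.  Phantom generation and pipeline runs are deterministic,
# so expensive objects are built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the canonical small pit used by fill/metric tests: 1 x 1 x 0.5 mm pit at
# 0.1 mm spacing (500 truth voxels), sealed, noiseless
pit_phantom <- function() cached("pit_sealed", generate_phantom(
  phantom_spec(spacing = 0.1, niche_dims = c(1, 1, 0.5), noise_sigma = 0,
               mouth = "sealed")))

pit_phantom_flush <- function() cached("pit_flush", generate_phantom(
  phantom_spec(spacing = 0.1, niche_dims = c(1, 1, 0.5), noise_sigma = 0,
               mouth = "flush")))

default_phantom <- function() cached("default_phantom",
                                     generate_phantom(phantom_spec()))

pit_frame <- function() fit_ccs(pit_phantom()$fiducials)

# default-configuration pipeline run on a given phantom
pipeline_run <- function(ph, key, ...) cached(key, {
  suppressWarnings(run_semiauto_segmentation(
    pipeline_config(volume = ph$volume, fiducials = ph$fiducials, ...)))
})

# a random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# tiny volume helper
make_vol <- function(data, spacing = 0.1, origin = c(0, 0, 0)) {
  volume_image(data, rep(spacing, 3), origin)
}

expect_world_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
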