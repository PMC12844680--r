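# Synthetic-scene generator: determinism, geometry bounds, and the
# modality-complementarity structure the fusion experiments rely on.

test_that("spec validation names the offending field", {
  expect_error(scene_spec(height_px = 0), "height_px")
  expect_error(scene_spec(crown_radius_range = c(30, 20)),
               "crown_radius_range")
  expect_error(scene_spec(64, 64, crown_radius_range = c(5, 40)),
               "crown_radius_range")
  expect_error(scene_spec(frac_ms_cued = 1.2), "frac_ms_cued")
  expect_error(scene_spec(noise_sigma = -1), "noise_sigma")
})

test_that("no crowns means an empty mask; same seed means identical output", {
  s0 <- generate_sample(scene_spec(64, 64, n_crowns = 0), seed = 5)
  expect_equal(sum(s0$mask), 0)
  sp <- tiny_spec()
  a <- generate_sample(sp, seed = 11)
  b <- generate_sample(sp, seed = 11)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$ms, b$ms)
  expect_identical(a$mask, b$mask)
  c <- generate_sample(sp, seed = 12)
  expect_false(identical(a$mask, c$mask))
})

test_that("sample arrays share size, stay in [0,1], mask is binary", {
  s <- generate_sample(tiny_spec(), seed = 2)
  expect_equal(dim(s$rgb), c(64, 64, 3))
  expect_equal(dim(s$ms), c(64, 64, 4))
  expect_equal(dim(s$mask), c(64, 64))
  expect_true(all(s$rgb >= 0 & s$rgb <= 1))
  expect_true(all(s$ms >= 0 & s$ms <= 1))
  expect_true(all(s$mask %in% c(0, 1)))
})

test_that("mask coverage lies within the analytic superellipse bound", {
  # 5 crowns with semi-major axis in [20, 30] on 256x256: the rendered
  # union must lie in [0.5, 1] x sum(pi r^2) / area, overlap allowed
  sp <- scene_spec(256, 256, n_crowns = 5, crown_radius_range = c(20, 30),
                   n_distractors = 0)
  for (seed in c(1, 2, 3)) {
    s <- generate_sample(sp, seed = seed)
    frac <- mean(s$mask)
    expect_gte(frac, 5 * pi * 20^2 * 0.5 / 256^2)
    expect_lte(frac, 5 * pi * 30^2 / 256^2)
  }
})

test_that("expected coverage is non-decreasing in crown count", {
  cov_at <- function(k) {
    mean(vapply(1:20, function(s) {
      sp <- scene_spec(96, 96, n_crowns = k, crown_radius_range = c(6, 10),
                       n_distractors = 0)
      mean(generate_sample(sp, seed = s)$mask)
    }, 1))
  }
  cv <- vapply(c(0, 2, 4, 8), cov_at, 1)
  expect_true(all(diff(cv) >= 0))
})

test_that("ms-cued crowns are spectrally separable but color-matched to distractors", {
  # shadowing is a separate confound (tested via frac_shadowed above);
  # the separability margins are defined on unshadowed scenes. The RGB
  # distance bound (0.08) is an order of magnitude below the contrast
  # of rgb-cued crowns to canopy (~0.5); the NIR margin (0.15) is well
  # above the noise scale (0.02).
  sp <- scene_spec(128, 128, n_crowns = 6, crown_radius_range = c(8, 16),
                   frac_ms_cued = 1, frac_shadowed = 0, n_distractors = 6)
  for (seed in 1:5) {
    ct <- modality_contrast(generate_sample(sp, seed = seed))
    expect_gt(ct$nir_margin, 0.15)
    expect_lt(ct$rgb_distance, 0.08)
  }
})

test_that("dataset generation composes generate_sample with derived seeds", {
  sp <- tiny_spec()
  ds <- generate_dataset(sp, 4, seed = 9)
  expect_length(ds$samples, 4)
  expect_equal(nrow(ds$manifest), 4)
  for (i in 1:4) {
    ref <- generate_sample(sp, ds$manifest$seed[i], ds$manifest$id[i])
    expect_identical(ds$samples[[i]]$mask, ref$mask)
    expect_identical(ds$samples[[i]]$ms, ref$ms)
  }
  expect_identical(ds$manifest, generate_dataset(sp, 4, seed = 9)$manifest)
  e <- generate_dataset(sp, 0, seed = 1)
  expect_length(e$samples, 0)
  expect_equal(nrow(e$manifest), 0)
})

test_that("samples round-trip through PNG/TIFF files", {
  s <- generate_sample(tiny_spec(), seed = 4)
  dir <- tempfile("io")
  write_sample(s, dir, "t1")
  r <- read_sample(dir, "t1")
  expect_equal(r$mask, s$mask)
  expect_lt(max(abs(r$rgb - s$rgb)), 1 / 255)  # 8-bit quantization
  expect_lt(max(abs(r$ms - s$ms)), 1e-6)       # float TIFF
  unlink(dir, recursive = TRUE)
})
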