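test_that("a spikeless noiseless particle is a perfect circle", {
  ct <- generate_contour(shape_params(25, 0, 0), seed = 1)
  r <- signature_of(ct)
  expect_lt(max(abs(r - 25)), 1e-12 * 25)
})

test_that("a regular 12-spike star is dominated by harmonic 12", {
  ct <- generate_contour(shape_params(30, 12, 0.3, 0.2, angular_jitter = 0,
                                      roughness = 0), seed = 3)
  d <- compute_descriptor(ct)
  expect_equal(dominant_harmonic(d), 12L)
  # cross-check the peak against the direct DFT oracle
  sig <- signature_of(ct)
  expect_equal(Mod(d$coeffs[13]), Mod(direct_dft(sig, 12)), tolerance = 1e-9)
})

test_that("generation is deterministic in params and seed", {
  p <- shape_params(30, 7, 0.4, 0.25, angular_jitter = 0.05, roughness = 0.03)
  expect_identical(generate_contour(p, seed = 42), generate_contour(p, seed = 42))
  expect_false(identical(generate_contour(p, seed = 42),
                         generate_contour(p, seed = 43)))
  ep <- ensemble_params(p, cv = 0.1, n_particles = 5, seed = 9)
  expect_identical(generate_ensemble(ep), generate_ensemble(ep))
})

test_that("invalid shape parameters are rejected", {
  expect_error(shape_params(-1), "positive")
  expect_error(shape_params(30, 2.5), "integer")
  expect_error(shape_params(30, 5, 0.95), "0.9")
  expect_error(shape_params(30, 5, 0.5, -0.1), "positive")
  # roughness large enough to drive the radius negative
  expect_error(generate_contour(shape_params(30, 0, 0, roughness = 3), seed = 1),
               "non-positive")
})

test_that("zero variability yields identical feature vectors", {
  p <- shape_params(30, 6, 0.35, 0.3, angular_jitter = 0, roughness = 0)
  cts <- generate_ensemble(ensemble_params(p, cv = 0, n_particles = 4, seed = 5))
  feats <- describe_contours(cts, n = 256, k = 64)
  m <- nanoshape:::feature_matrix(feats)
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-9)
})

test_that("per-particle parameter draws honour the requested CV", {
  # spikeless particles: the signature's mean radius equals the drawn base
  # radius exactly
  ep <- ensemble_params(shape_params(40, 0, 0),
                        cv = c(base_radius_nm = 0.2), n_particles = 400,
                        seed = 31)
  cts <- generate_ensemble(ep)
  radii <- describe_contours(cts, n = 256, k = 8)$mean_radius_nm
  expect_lt(abs(mean(radii) / 40 - 1), 0.05)
  expect_lt(abs(stats::sd(radii) / mean(radii) - 0.2), 0.05)
})

test_that("replicate ensembles overlap; distinct families do not", {
  feats <- dplyr::bind_rows(
    describe_contours(generate_ensemble(preset_ensemble("star", 200, seed = 1)),
                      n = 256, k = 64, label = "star_a"),
    describe_contours(generate_ensemble(preset_ensemble("star", 200, seed = 2)),
                      n = 256, k = 64, label = "star_b"),
    describe_contours(generate_ensemble(preset_ensemble("urchin", 200, seed = 3)),
                      n = 256, k = 64, label = "urchin")
  )
  sp <- fit_shape_space(feats)
  pr <- project_ensemble(feats, sp, 3)
  expect_gte(overlap_coefficient(pr, "star_a", "star_b")$ovl, 0.8)
  expect_lte(overlap_coefficient(pr, "star_a", "urchin")$ovl, 0.05)
})

test_that("rendering produces a clean two-level image with one component each", {
  ct <- generate_contour(shape_params(30, 5, 0.4, 0.3), seed = 2)
  img <- render_image(ct, canvas_px = 128, noise_sd = 0, seed = 7)
  expect_length(unique(as.vector(img$pixels)), 2)
  expect_length(segment_particles(img), 1)
})

test_that("placement is non-overlapping and fails loudly when impossible", {
  cts <- generate_ensemble(
    ensemble_params(preset_params("flower"), cv = 0.05, n_particles = 5, seed = 3))
  img <- render_image(cts, canvas_px = 400, noise_sd = 0, seed = 8)
  pl <- attr(img, "placements")
  dmat <- as.matrix(stats::dist(pl[, c("x_px", "y_px")]))
  need <- outer(pl$bound_radius_px, pl$bound_radius_px, "+") + 5
  diag(need) <- 0
  expect_true(all(dmat >= need))

  big <- generate_ensemble(
    ensemble_params(preset_params("star"), cv = 0, n_particles = 8, seed = 4))
  expect_error(render_image(big, canvas_px = 150, seed = 9, max_tries = 20),
               "place|too large")
})

test_that("the rendered image round-trips the dominant harmonic", {
  ct <- generate_contour(shape_params(40, 12, 0.35, 0.12,
                                      angular_jitter = 0, roughness = 0),
                         seed = 6)
  img <- render_image(ct, canvas_px = 160, noise_sd = 0.03, seed = 10)
  rec <- extract_contours(img)
  d <- compute_descriptor(resample_contours(rec, 1024))
  expect_equal(dominant_harmonic(d), 12L)
})
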