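test_that("a circle has zero harmonic content and exact mean radius", {
  d <- compute_descriptor(circle_contour(7.5, 1024))
  expect_equal(d$mean_radius_nm, 7.5, tolerance = 1e-9)
  expect_true(all(Mod(d$coeffs[-1]) / Re(d$coeffs[1]) < 1e-10))
  expect_true(all(feature_vector(d) < 1e-10))
})

test_that("a single-cosine contour recovers its analytic amplitude", {
  n <- 1024
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1 + 0.2 * cos(5 * th)
  ct <- contour_tbl(cbind(r * cos(th), r * sin(th)), "cos5")
  d <- compute_descriptor(ct)

  # one-sided normalized amplitude at k = 5 is exactly the cosine amplitude
  amp5 <- 2 * Mod(d$coeffs[6]) / Re(d$coeffs[1])
  expect_equal(amp5, 0.2, tolerance = 1e-6)
  others <- Mod(d$coeffs[-c(1, 6)]) / Re(d$coeffs[1])
  expect_true(all(others < 1e-9))

  # against the direct O(N^2) DFT oracle on the same signature
  sig <- signature_of(ct)
  for (k in c(0, 1, 5, 17)) {
    expect_equal(d$coeffs[k + 1], direct_dft(sig, k), tolerance = 1e-9)
  }
  expect_equal(dominant_harmonic(d), 5L)
})

test_that("descriptors are translation-invariant", {
  st <- generate_contour(shape_params(30, 5, 0.4, 0.3), seed = 4)
  moved <- dplyr::mutate(st, x_nm = x_nm + 123.4, y_nm = y_nm - 56.7)
  d0 <- compute_descriptor(st)
  d1 <- compute_descriptor(moved)
  expect_lt(max(Mod(d0$coeffs - d1$coeffs)), 1e-9)
})

test_that("feature vectors are invariant to rotation, scale and start index", {
  withr::local_seed(4242)
  for (seed in 1:20) {
    p <- shape_params(
      base_radius_nm = stats::runif(1, 20, 50),
      n_spikes = sample(0:12, 1),
      spike_amplitude = stats::runif(1, 0, 0.5),
      spike_sharpness = stats::runif(1, 0.15, 0.6),
      angular_jitter = 0.03, roughness = 0.02
    )
    ct <- generate_contour(p, seed = seed)
    rc <- resample_contours(ct, 256)
    f0 <- feature_vector(compute_descriptor(rc), 64)

    xy <- as.matrix(rc[, c("x_nm", "y_nm")])
    a <- stats::runif(1, 0, 2 * pi)
    rot <- xy %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
    f_rot <- feature_vector(compute_descriptor(
      resample_contours(contour_tbl(rot, "r"), 256)), 64)
    expect_lt(max(abs(f_rot - f0)), 1e-9)

    scl <- contour_tbl(xy * 3, "s")
    f_scl <- feature_vector(compute_descriptor(
      resample_contours(scl, 256)), 64)
    expect_lt(max(abs(f_scl - f0)), 1e-9)

    shift <- sample(nrow(xy), 1)
    cyc <- contour_tbl(xy[c(shift:nrow(xy), seq_len(shift - 1)), ], "c")
    f_cyc <- feature_vector(compute_descriptor(
      resample_contours(cyc, 256)), 64)
    expect_lt(max(abs(f_cyc - f0)), 1e-9)
  }
})

test_that("the transform satisfies Parseval's identity", {
  ct <- generate_contour(shape_params(30, 9, 0.3, 0.2, roughness = 0.05),
                         seed = 11)
  rc <- resample_contours(ct, 512)
  d <- compute_descriptor(rc)
  sig <- signature_of(rc)
  energy <- sum(sig^2) / d$n
  cmod2 <- Mod(d$coeffs)^2
  spectral <- cmod2[1] + 2 * sum(cmod2[2:(d$n / 2)]) + cmod2[d$n / 2 + 1]
  expect_equal(spectral, energy, tolerance = 1e-9)
})

test_that("reconstruction inverts the transform and truncates gracefully", {
  ct <- generate_contour(shape_params(30, 5, 0.45, 0.35), seed = 7)
  rc <- resample_contours(ct, 1024)
  d <- compute_descriptor(rc)
  sig <- signature_of(rc)

  # full spectrum: identity (relative to the signature scale)
  full <- signature_of(reconstruct_contour(d, d$n / 2))
  expect_lt(max(abs(full - sig)) / mean(sig), 1e-9)

  # no harmonics: a circle of the mean radius
  circ <- signature_of(reconstruct_contour(d, 0))
  expect_true(all(abs(circ - d$mean_radius_nm) < 1e-9))

  # 8 harmonics capture a 5-spiked star
  rec8 <- signature_of(reconstruct_contour(d, 8))
  expect_gte(stats::cor(sig, rec8), 0.99)

  # truncation error is monotone non-increasing in the harmonic cut
  errs <- vapply(c(1, 2, 4, 8, 16, 32, 64), function(kk) {
    sqrt(mean((signature_of(reconstruct_contour(d, kk)) - sig)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("degenerate and non-star contours are handled", {
  # flat (zero-area) polygon
  x <- c(seq(0, 1, length.out = 17), seq(1, 0, length.out = 17)[-c(1, 17)])
  flat <- contour_tbl(cbind(x, 0), "flat")
  expect_error(compute_descriptor(flat), "degenerate")

  # crescent: not star-shaped about its centroid -> warning, not error
  th1 <- seq(-2.4, 2.4, length.out = 60)
  th2 <- rev(seq(-2.2, 2.2, length.out = 40))
  cres <- contour_tbl(rbind(cbind(10 * cos(th1), 10 * sin(th1)),
                            cbind(6 * cos(th2), 6 * sin(th2))), "cres")
  expect_warning(compute_descriptor(resample_contours(cres, 64)),
                 "star-shaped")
})

test_that("describe_contours matches per-particle descriptors", {
  cts <- generate_ensemble(
    ensemble_params(preset_params("star"), cv = 0.1, n_particles = 5, seed = 2))
  feats <- describe_contours(cts, n = 256, k = 64, label = "star")
  expect_equal(nrow(feats), 5)
  expect_equal(feats$label, rep("star", 5))
  one <- resample_contours(cts[cts$particle_id == "p0003", ], 256)
  fv <- feature_vector(compute_descriptor(one), 64)
  expect_equal(unlist(feats[feats$particle_id == "p0003",
                            paste0("h", sprintf("%04d", 1:64))]),
               fv, tolerance = 1e-12)
  expect_error(describe_contours(cts, n = 256, k = 200), "between 1 and")
})
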