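# Small synthetic feature tibbles with controlled structure.
feature_tbl <- function(m, label = "e") {
  colnames(m) <- sprintf("h%04d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(label = label,
                   particle_id = sprintf("%s%03d", label, seq_len(nrow(m))),
                   mean_radius_nm = 1),
    tibble::as_tibble(m)
  )
}

test_that("explained variance ratios are a ranked partition of unity", {
  withr::local_seed(1)
  f <- feature_tbl(matrix(rnorm(200), 20, 10))
  sp <- fit_shape_space(f)
  expect_equal(sum(sp$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(sp$explained_variance_ratio) <= 1e-12))
  # components orthonormal
  g <- crossprod(sp$components)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(sp$components))) {
    v <- sp$components[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("rank-1 data concentrates all variance in PC1", {
  withr::local_seed(2)
  dirv <- rnorm(8); dirv <- dirv / sqrt(sum(dirv^2))
  f <- feature_tbl(outer(seq(-1, 1, length.out = 25), dirv))
  sp <- fit_shape_space(f)
  expect_equal(sp$explained_variance_ratio[1], 1, tolerance = 1e-9)
})

test_that("two displaced clusters align PC1 with the displacement", {
  withr::local_seed(3)
  dirv <- rnorm(12); dirv <- dirv / sqrt(sum(dirv^2))
  a <- matrix(rnorm(40 * 12, sd = 0.01), 40, 12)
  b <- sweep(matrix(rnorm(40 * 12, sd = 0.01), 40, 12), 2, 5 * dirv, "+")
  f <- dplyr::bind_rows(feature_tbl(a, "a"), feature_tbl(b, "b"))
  sp <- fit_shape_space(f)
  expect_gte(abs(sum(sp$components[, 1] * dirv)), 0.99)
})

test_that("degenerate fits are rejected", {
  f <- feature_tbl(matrix(1, 1, 4))
  expect_error(fit_shape_space(f), "at least 2")
})

test_that("projection is centred and invertible with the full basis", {
  withr::local_seed(4)
  f <- feature_tbl(matrix(rnorm(30 * 8), 30, 8))
  sp <- fit_shape_space(f)
  m <- length(sp$sdev)
  pr <- project_ensemble(f, sp, m = m)
  coords <- as.matrix(pr[, paste0("pc", 1:m)])
  expect_lt(max(abs(colMeans(coords))), 1e-9)
  # orthonormal basis: inverse projection restores the features
  back <- coords %*% t(sp$components[, 1:m]) +
    matrix(sp$mean_vector, 30, 8, byrow = TRUE)
  expect_lt(max(abs(back - nanoshape:::feature_matrix(f))), 1e-9)
  expect_error(project_ensemble(feature_tbl(matrix(rnorm(20), 5, 4)), sp),
               "does not match")
})

test_that("identical particles project to a single point", {
  f <- feature_tbl(matrix(rep(c(1, 2, 3, 4), each = 25), 25, 4))
  f2 <- dplyr::bind_rows(
    f, feature_tbl(matrix(rnorm(100, sd = 2), 25, 4), "b"))
  sp <- fit_shape_space(f2)
  pr <- project_ensemble(f2, sp, 2)
  a <- pr[pr$label == "e", ]
  expect_lt(max(abs(a$pc1 - a$pc1[1])), 1e-9)
  cen <- ensemble_centroids(pr)
  expect_equal(cen$pc1[cen$label == "e"], a$pc1[1], tolerance = 1e-9)
})

test_that("representative particle minimises distance with first-index ties", {
  pr <- tibble::tibble(
    label = "e",
    particle_id = c("far1", "hit", "far2"),
    pc1 = c(3, 1, -1), pc2 = c(0, 0, 0)
  )
  # centroid at pc1 = 1: 'hit' sits exactly on it
  expect_equal(representative_particle(pr)$particle_id, "hit")

  tie <- tibble::tibble(label = "e",
                        particle_id = c("left", "right"),
                        pc1 = c(-1, 1), pc2 = 0)
  expect_equal(representative_particle(tie)$particle_id, "left")

  single <- tibble::tibble(label = "e", particle_id = "only", pc1 = 2, pc2 = 2)
  expect_equal(representative_particle(single)$particle_id, "only")
  expect_error(representative_particle(single[0, ]), "empty")
})

test_that("confidence ellipse matches the chi-square construction", {
  pr <- gauss_projection(10000, 0, "g", m = 2, seed = 10)
  ell <- confidence_ellipse(pr, 0.95)
  want <- sqrt(stats::qchisq(0.95, 2))
  expect_lt(abs(ell$semi_major - want) / want, 0.02)
  expect_lt(abs(ell$semi_minor - want) / want, 0.02)
  expect_true(ell$semi_major >= ell$semi_minor)
})

test_that("ellipse coverage is calibrated across levels", {
  pr <- gauss_projection(10000, 0, "g", m = 2, seed = 11)
  for (lvl in c(0.5, 0.9, 0.95)) {
    ell <- confidence_ellipse(pr, lvl)
    cover <- mean(points_in_ellipse(pr, ell))
    expect_lt(abs(cover - lvl), 0.02)
  }
})

test_that("degenerate point clouds cannot form an ellipse", {
  same <- tibble::tibble(label = "e", particle_id = as.character(1:5),
                         pc1 = 1, pc2 = 2)
  expect_error(confidence_ellipse(same), "degenerate")
  line <- tibble::tibble(label = "e", particle_id = as.character(1:10),
                         pc1 = 1:10, pc2 = 2 * (1:10))
  expect_error(confidence_ellipse(line), "degenerate")
  expect_error(confidence_ellipse(same[1:2, ]), "at least 3")
  expect_error(confidence_ellipse(same, level = 1.2), "level")
})

test_that("distances from an isotropic Gaussian follow a Rayleigh law", {
  pr <- gauss_projection(2000, 0, "g", m = 2, seed = 12)
  dp <- distance_pdf(pr, m = 2)
  d <- sort(dp$distances$distance)
  ks <- max(abs(seq_along(d) / length(d) - (1 - exp(-d^2 / 2))))
  expect_lte(ks, 0.05)
  # KDE integrates to 1 on its grid
  dens <- dp$density
  expect_equal(nanoshape:::trapz(dens$distance, dens$density), 1,
               tolerance = 1e-3)
  expect_equal(nrow(dens), 512)
})

test_that("degenerate distance distributions are rejected", {
  same <- tibble::tibble(label = "e", particle_id = as.character(1:25),
                         pc1 = 1, pc2 = 2, pc3 = 0)
  expect_error(distance_pdf(same), "degenerate|identical")
  few <- gauss_projection(10, 0, "g", m = 3, seed = 1)
  expect_error(distance_pdf(few), "at least 20")
})

test_that("replicate ensembles sit closer than their own spread", {
  f1 <- describe_contours(generate_ensemble(
    preset_ensemble("flower", 60, seed = 21)), n = 256, k = 64, label = "r1")
  f2 <- describe_contours(generate_ensemble(
    preset_ensemble("flower", 60, seed = 22)), n = 256, k = 64, label = "r2")
  sp <- fit_shape_space(dplyr::bind_rows(f1, f2))
  pr <- project_ensemble(dplyr::bind_rows(f1, f2), sp, 3)
  cen <- ensemble_centroids(pr)
  sep <- sqrt(sum((cen[1, c("pc1", "pc2", "pc3")] -
                   cen[2, c("pc1", "pc2", "pc3")])^2))
  dp <- distance_pdf(pr, m = 3)
  spread <- glance(dp)$mean_distance
  expect_lt(sep, min(spread))
})
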