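test_that("the projection axis joins the centers of gravity", {
  pr <- dplyr::bind_rows(
    tibble::tibble(label = "a", particle_id = paste0("a", 1:3),
                   pc1 = c(-0.1, 0, 0.1), pc2 = 0, pc3 = 0),
    tibble::tibble(label = "b", particle_id = paste0("b", 1:3),
                   pc1 = 1 + c(-0.1, 0, 0.1), pc2 = 0, pc3 = 0)
  )
  ax <- projection_axis(pr, "a", "b")
  expect_equal(unname(ax$axis), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ax$centroid_distance, 1, tolerance = 1e-12)
  expect_false(ax$degenerate)

  rev <- projection_axis(pr, "b", "a")
  expect_equal(unname(rev$axis), c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(rev$centroid_distance, 1, tolerance = 1e-12)

  expect_error(projection_axis(pr, "a", "zz"), "present")
})

test_that("coincident centroids fall back to PC1 with a flag", {
  pr <- dplyr::bind_rows(
    tibble::tibble(label = "a", particle_id = paste0("a", 1:4),
                   pc1 = c(-1, 1, -1, 1), pc2 = c(-1, -1, 1, 1), pc3 = 0),
    tibble::tibble(label = "b", particle_id = paste0("b", 1:4),
                   pc1 = c(-2, 2, -2, 2), pc2 = c(-2, -2, 2, 2), pc3 = 0)
  )
  ax <- projection_axis(pr, "a", "b")
  expect_true(ax$degenerate)
  expect_equal(unname(ax$axis), c(1, 0, 0))
})

test_that("halves of one ensemble overlap almost completely", {
  pr <- gauss_projection(1000, 0, "all", m = 3, seed = 5) |>
    dplyr::mutate(label = rep(c("h1", "h2"), each = 500))
  r <- overlap_coefficient(pr, "h1", "h2")
  expect_gte(r$ovl, 0.9)
})

test_that("overlap tracks the Gaussian closed form and decreases with separation", {
  ovls <- vapply(c(0, 1, 2, 4), function(delta) {
    pr <- dplyr::bind_rows(gauss_projection(5000, 0, "a", m = 1, seed = 31),
                           gauss_projection(5000, delta, "b", m = 1, seed = 32))
    overlap_coefficient(pr, "a", "b")$ovl
  }, numeric(1))
  expect_true(all(abs(ovls - 2 * stats::pnorm(-c(0, 1, 2, 4) / 2)) < 0.03))
  expect_true(all(diff(ovls) < 0))
})

test_that("overlap is symmetric, bounded, and rotation-invariant", {
  pr <- dplyr::bind_rows(gauss_projection(200, c(0, 0, 0), "a", seed = 6),
                         gauss_projection(200, c(1.5, -1, 0.5), "b", seed = 7))
  r_ab <- overlap_coefficient(pr, "a", "b")
  r_ba <- overlap_coefficient(pr, "b", "a")
  expect_lt(abs(r_ab$ovl - r_ba$ovl), 1e-9)
  expect_gte(r_ab$ovl, 0)
  expect_lte(r_ab$ovl, 1)
  expect_gte(r_ab$bhattacharyya, r_ab$ovl)

  # rigid rotation of the shape-space coordinates
  withr::local_seed(8)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  m <- as.matrix(pr[, c("pc1", "pc2", "pc3")]) %*% q
  pr_rot <- dplyr::mutate(pr, pc1 = m[, 1], pc2 = m[, 2], pc3 = m[, 3])
  r_rot <- overlap_coefficient(pr_rot, "a", "b")
  expect_lt(abs(r_rot$ovl - r_ab$ovl), 1e-9)
})

test_that("well-separated clusters have essentially zero overlap", {
  pr <- dplyr::bind_rows(gauss_projection(500, 0, "a", m = 2, sd = 0.01, seed = 9),
                         gauss_projection(500, 1, "b", m = 2, sd = 0.01, seed = 10))
  expect_lte(overlap_coefficient(pr, "a", "b")$ovl, 1e-3)
})

test_that("degenerate or undersized ensembles are rejected", {
  pr <- dplyr::bind_rows(
    tibble::tibble(label = "a", particle_id = paste0("a", 1:30),
                   pc1 = 0, pc2 = 0, pc3 = 0),
    gauss_projection(30, 1, "b", seed = 11)
  )
  expect_error(overlap_coefficient(pr, "a", "b"), "zero variance")
  small <- dplyr::bind_rows(gauss_projection(10, 0, "a", seed = 1),
                            gauss_projection(10, 1, "b", seed = 2))
  expect_error(overlap_coefficient(small, "a", "b"), "at least 20")
  expect_s3_class(overlap_coefficient(small, "a", "b", min_n = 5),
                  "overlap_result")
})

test_that("independence uses an inclusive threshold", {
  pr <- dplyr::bind_rows(gauss_projection(100, 0, "a", seed = 12),
                         gauss_projection(100, 8, "b", seed = 13))
  r <- overlap_coefficient(pr, "a", "b")

  r0 <- r; r0$ovl <- 0
  expect_true(independence_test(r0)$independent)
  r_at <- r; r_at$ovl <- 0.05
  expect_true(independence_test(r_at, threshold = 0.05)$independent)
  r1 <- r; r1$ovl <- 1
  expect_false(independence_test(r1)$independent)
  rep <- independence_test(r, threshold = 0.1)
  expect_named(rep, c("independent", "ovl", "threshold", "centroid_distance",
                      "label_a", "label_b"))
})

test_that("overlap_matrix covers every unordered pair", {
  pr <- dplyr::bind_rows(gauss_projection(50, 0, "a", seed = 14),
                         gauss_projection(50, 2, "b", seed = 15),
                         gauss_projection(50, 4, "c", seed = 16))
  om <- overlap_matrix(pr)
  expect_equal(nrow(om), 3)
  expect_true(all(om$ovl >= 0 & om$ovl <= 1))
})
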