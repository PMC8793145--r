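# Programmatic fixtures shared across the suite.

# Equal-angle circle contour of radius r (counterclockwise).
circle_contour <- function(r = 10, n = 256, id = "circ") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour_tbl(cbind(r * cos(th), r * sin(th)), id)
}

# Axis-aligned square of side s with subdivided edges (>= 16 vertices, CCW).
square_contour <- function(s = 10, per_edge = 8, id = "sq") {
  t <- seq(0, s, length.out = per_edge + 1)[-(per_edge + 1)]
  xy <- rbind(
    cbind(t, 0), cbind(s, t), cbind(s - t, s), cbind(0, s - t)
  )
  contour_tbl(xy, id)
}

# Binary disk mask: TRUE where distance from (cy, cx) <= r (pixel centres).
disk_mask <- function(nr, nc, cy, cx, r) {
  d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  d2 <= r^2
}

# Synthetic projection cloud: n points from an isotropic Gaussian in m PCs.
gauss_projection <- function(n, mu, label, m = 3, sd = 1, seed = NULL) {
  draw <- function() {
    coords <- matrix(stats::rnorm(n * m, sd = sd), n, m)
    coords <- sweep(coords, 2, rep_len(mu, m), "+")
    colnames(coords) <- paste0("pc", seq_len(m))
    dplyr::bind_cols(
      tibble::tibble(label = label,
                     particle_id = paste0(label, seq_len(n))),
      tibble::as_tibble(coords)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Direct O(N^2) DFT of a real signal, forward 1/N convention; oracle for the
# FFT-based descriptor.
direct_dft <- function(x, k) {
  n <- length(x)
  t <- seq_len(n) - 1
  sum(x * exp(-2i * pi * k * t / n)) / n
}

# Radial signature (centroid distances) of a one-particle contour table.
signature_of <- function(ct) {
  xy <- as.matrix(ct[, c("x_nm", "y_nm")])
  ctr <- colMeans(xy)
  sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
}
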