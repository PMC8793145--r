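#' Fourier shape descriptors of the radial signature
#'
#' Each resampled contour is reduced to its radial signature: the
#' centroid-to-boundary distance `r(t)` at the `n` equally-arc-spaced points.
#' The signature is Fourier analysed with the forward-`1/n` convention,
#' `c_k = (1/n) * sum_t r(t) exp(-2*pi*i*k*t/n)`, and the one-sided
#' coefficients `c_0 .. c_{n/2}` are kept. `c_0` is then the mean radius
#' (real and positive for any non-degenerate contour), and the descriptor is
#' translation-invariant by construction because the signature is
#' centroid-relative.
#'
#' Contours that are not star-shaped about their centroid (the radial
#' signature is then a multivalued function of angle) are flagged with a
#' warning but still encoded: the arc-length parameterisation remains
#' well-defined.
#'
#' @param rc a resampled contour table for one particle (see
#'   [resample_contours()]); the point count must be a power of two.
#' @return A `shape_descriptor` object with fields `coeffs` (complex,
#'   length n/2 + 1), `n`, `mean_radius_nm`, and `source_id`.
#' @export
compute_descriptor <- function(rc) {
  ids <- unique(rc$particle_id)
  if (length(ids) != 1) {
    abort("compute_descriptor() takes a single particle; see describe_contours()")
  }
  xy <- contour_matrices(rc)[[1]]
  n <- nrow(xy)
  if (!is_power_of_two(n)) abort("signature length must be a power of two")
  ctr <- colMeans(xy)
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  if (any(r == 0) || abs(poly_signed_area(xy)) == 0) {
    abort(paste0("particle '", ids, "': degenerate (zero-area) contour"))
  }
  ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  dang <- diff(ang) %% (2 * pi)
  dang[dang > pi] <- dang[dang > pi] - 2 * pi
  if (any(dang < 0) && any(dang > 0) && min(dang) < -1e-12) {
    warn(paste0("particle '", ids, "' is not star-shaped about its centroid; ",
                "radial signature is multivalued in angle"))
  }
  coeffs <- stats::fft(r) / n
  structure(
    list(
      coeffs = coeffs[seq_len(n / 2 + 1)],
      n = n,
      mean_radius_nm = Re(coeffs[1]),
      centroid = ctr,
      source_id = ids
    ),
    class = "shape_descriptor"
  )
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf("<shape_descriptor '%s': n = %d, mean radius = %.3g nm>\n",
              x$source_id, x$n, x$mean_radius_nm))
  invisible(x)
}

#' Invariant harmonic feature vector
#'
#' The feature vector is the scale-normalised magnitude spectrum
#' `|c_1|/c_0 .. |c_K|/c_0`. Dropping phase makes it invariant to in-plane
#' rotation and to the cyclic start index of the signature; dividing by `c_0`
#' makes it invariant to uniform scaling; centroid-relative radii make it
#' invariant to translation. A perfect circle maps to the zero vector.
#'
#' @param d a `shape_descriptor`.
#' @param k number of harmonics retained (default n/2, the full one-sided
#'   spectrum).
#' @return Numeric vector of length `k`, named `h0001..`.
#' @export
feature_vector <- function(d, k = d$n / 2) {
  stopifnot(inherits(d, "shape_descriptor"))
  if (k < 1 || k > d$n / 2) {
    abort("`k` must be between 1 and n/2")
  }
  v <- Mod(d$coeffs[1 + seq_len(k)]) / Re(d$coeffs[1])
  names(v) <- sprintf("h%04d", seq_len(k))
  v
}

#' Reconstruct a contour from truncated harmonics
#'
#' Validation utility: inverts the descriptor after zeroing all harmonics
#' above `k_keep` and re-embeds the reconstructed radial signature as a
#' closed curve around the original centroid at equal angular spacing.
#' `k_keep = 0` yields a circle of the mean radius; `k_keep = n/2` reproduces
#' the input signature exactly (up to floating point).
#'
#' @param d a `shape_descriptor`.
#' @param k_keep number of harmonics kept, `0 <= k_keep <= n/2`.
#' @return A contour table with `n` vertices.
#' @export
reconstruct_contour <- function(d, k_keep = d$n / 2) {
  stopifnot(inherits(d, "shape_descriptor"))
  if (k_keep < 0 || k_keep > d$n / 2) abort("`k_keep` must be in [0, n/2]")
  r <- reconstruct_signature(d, k_keep)
  theta <- 2 * pi * (seq_len(d$n) - 1) / d$n
  xy <- cbind(d$centroid[1] + r * cos(theta), d$centroid[2] + r * sin(theta))
  contour_tbl(xy, d$source_id)
}

# Inverse transform of the truncated one-sided spectrum (Hermitian extension).
reconstruct_signature <- function(d, k_keep) {
  n <- d$n
  half <- d$coeffs
  if (k_keep < n / 2) half[(k_keep + 2):length(half)] <- 0 + 0i
  full <- complex(length.out = n)
  full[1] <- half[1]
  full[2:(n / 2 + 1)] <- half[2:(n / 2 + 1)]
  full[n:(n / 2 + 2)] <- Conj(half[2:(n / 2)])
  Re(stats::fft(full, inverse = TRUE))
}

#' Dominant harmonic of a shape descriptor
#'
#' Index `k >= 1` of the largest-magnitude harmonic: the number of angular
#' protrusions for a regularly spiked particle.
#'
#' @param d a `shape_descriptor`.
#' @return Integer harmonic index.
#' @export
dominant_harmonic <- function(d) {
  stopifnot(inherits(d, "shape_descriptor"))
  which.max(Mod(d$coeffs[-1]))
}

# Radial signature of one resampled particle (exported via describe path).
radial_signature <- function(rc) {
  xy <- contour_matrices(rc)[[1]]
  ctr <- colMeans(xy)
  sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
}

#' Describe an ensemble of contours as harmonic feature vectors
#'
#' Pipeline verb: resamples every contour to `n` points (skipped when the
#' table already has exactly `n` vertices per particle), computes the radial
#' Fourier descriptor, and returns one row per particle with the mean radius
#' and the `k` scale/rotation/start-invariant harmonic magnitudes in columns
#' `h0001..`.
#'
#' @inheritParams contour_tbl
#' @param n signature length (power of two, >= 64).
#' @param k harmonics retained (default n/2).
#' @param label optional ensemble label attached as a `label` column.
#' @return A feature tibble: `label`, `particle_id`, `mean_radius_nm`,
#'   `h0001 .. h<k>`.
#' @export
describe_contours <- function(contours, n = 1024, k = n / 2, label = NULL) {
  if (k < 1 || k > n / 2) abort("`k` must be between 1 and n/2")
  counts <- table(contours$particle_id)
  if (!all(counts == n)) contours <- resample_contours(contours, n)
  mats <- contour_matrices(contours)
  rows <- purrr::imap(mats, function(xy, id) {
    d <- compute_descriptor(contour_tbl(xy, id))
    c(mean_radius_nm = d$mean_radius_nm, feature_vector(d, k))
  })
  m <- do.call(rbind, rows)
  out <- dplyr::bind_cols(
    tibble::tibble(particle_id = names(mats), mean_radius_nm = m[, 1]),
    tibble::as_tibble(m[, -1, drop = FALSE])
  )
  if (!is.null(label)) out <- dplyr::mutate(out, label = label, .before = 1)
  attr(out, "n_signature") <- n
  attr(out, "k_harmonics") <- k
  out
}

# Extract the numeric particles-x-k matrix from a feature tibble.
feature_matrix <- function(features) {
  cols <- grep("^h\\d+$", names(features), value = TRUE)
  if (!length(cols)) abort("no harmonic feature columns (h0001..) found")
  m <- as.matrix(features[, cols])
  rownames(m) <- features$particle_id
  m
}
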