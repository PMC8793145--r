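#' Axis joining two ensemble centers of gravity
#'
#' The "coordinate X" onto which both ensembles are projected: the unit
#' vector from the center of gravity of `a` to that of `b`, with origin at
#' `a`'s center. When the centroids coincide (within 1e-12) the axis falls
#' back to the PC1 direction and is flagged degenerate.
#'
#' @param projection a projection tibble holding both ensembles (same shape
#'   space, same PCs).
#' @param a,b labels of the two ensembles.
#' @return A list: `axis` (unit vector), `origin`, `centroid_distance`,
#'   `degenerate`.
#' @export
projection_axis <- function(projection, a, b) {
  pcs <- grep("^pc\\d+$", names(projection), value = TRUE)
  if (!all(c(a, b) %in% projection$label)) {
    abort("labels `a` and `b` must both be present in the projection")
  }
  ca <- colMeans(as.matrix(projection[projection$label == a, pcs]))
  cb <- colMeans(as.matrix(projection[projection$label == b, pcs]))
  delta <- cb - ca
  d <- sqrt(sum(delta^2))
  if (d < 1e-12) {
    axis <- c(1, rep(0, length(pcs) - 1))
    names(axis) <- pcs
    return(list(axis = axis, origin = ca, centroid_distance = d,
                degenerate = TRUE))
  }
  list(axis = delta / d, origin = ca, centroid_distance = d, degenerate = FALSE)
}

#' Overlap coefficient between two shape distributions
#'
#' Both ensembles' points are projected onto the line joining their centers
#' of gravity; each projected sample gets a Gaussian kernel density (its own
#' Silverman bandwidth) evaluated on one shared 512-point grid spanning the
#' joint range plus three maximal bandwidths on each side. The overlap
#' coefficient is the trapezoidal integral of the pointwise minimum of the
#' two densities — the estimated fraction of particles common to both
#' distributions, in `[0, 1]` and symmetric in its arguments. The
#' Bhattacharyya coefficient (integral of the pointwise geometric mean) is
#' reported alongside as a secondary statistic.
#'
#' @inheritParams projection_axis
#' @param bw optional fixed bandwidth used for both ensembles (default:
#'   Silverman's rule, separately per ensemble).
#' @param min_n minimum particles per ensemble for a meaningful density
#'   (default 20).
#' @return An `overlap_result`: `ovl`, `bhattacharyya`, `labels`, `axis`,
#'   `centroid_distance`, `grid`, `pdf_a`, `pdf_b`, `bandwidths`,
#'   `degenerate_axis`.
#' @export
overlap_coefficient <- function(projection, a, b, bw = NULL, min_n = 20) {
  ax <- projection_axis(projection, a, b)
  pcs <- grep("^pc\\d+$", names(projection), value = TRUE)
  xa <- as.matrix(projection[projection$label == a, pcs])
  xb <- as.matrix(projection[projection$label == b, pcs])
  if (nrow(xa) < min_n || nrow(xb) < min_n) {
    abort(sprintf("each ensemble needs at least %d particles", min_n))
  }
  ta <- as.vector(sweep(xa, 2, ax$origin) %*% ax$axis)
  tb <- as.vector(sweep(xb, 2, ax$origin) %*% ax$axis)
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) {
    abort("degenerate projection: an ensemble has zero variance along the axis")
  }
  bwa <- bw %||% silverman_bw(ta)
  bwb <- bw %||% silverman_bw(tb)
  pad <- 3 * max(bwa, bwb)
  grid <- seq(min(ta, tb) - pad, max(ta, tb) + pad, length.out = 512)
  fa <- gauss_kde(ta, grid, bwa)
  fb <- gauss_kde(tb, grid, bwb)
  structure(
    list(
      ovl = min(1, trapz(grid, pmin(fa, fb))),
      bhattacharyya = min(1, trapz(grid, sqrt(fa * fb))),
      labels = c(a = a, b = b),
      axis = ax$axis,
      centroid_distance = ax$centroid_distance,
      grid = grid,
      pdf_a = fa,
      pdf_b = fb,
      bandwidths = c(a = bwa, b = bwb),
      degenerate_axis = ax$degenerate
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap '%s' vs '%s': OVL = %.4f, centroid distance = %.4g>\n",
              x$labels["a"], x$labels["b"], x$ovl, x$centroid_distance))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(
    x = rep(x$grid, 2),
    density = c(x$pdf_a, x$pdf_b),
    label = rep(unname(x$labels), each = length(x$grid))
  )
}

#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(
    label_a = unname(x$labels["a"]),
    label_b = unname(x$labels["b"]),
    ovl = x$ovl,
    bhattacharyya = x$bhattacharyya,
    centroid_distance = x$centroid_distance,
    degenerate_axis = x$degenerate_axis
  )
}

#' Decide statistical shape independence
#'
#' Two ensembles are deemed independent shapes when their overlap coefficient
#' does not exceed the threshold (boundary inclusive). The default threshold
#' of 0.05 — at most 5% of particles shared — is a declared convention,
#' configurable and surfaced in every report.
#'
#' @param result an `overlap_result`.
#' @param threshold OVL at or below which the ensembles count as independent.
#' @return A one-row tibble: `independent`, `ovl`, `threshold`,
#'   `centroid_distance`, `label_a`, `label_b`.
#' @export
independence_test <- function(result, threshold = 0.05) {
  stopifnot(inherits(result, "overlap_result"))
  tibble::tibble(
    independent = result$ovl <= threshold,
    ovl = result$ovl,
    threshold = threshold,
    centroid_distance = result$centroid_distance,
    label_a = unname(result$labels["a"]),
    label_b = unname(result$labels["b"])
  )
}

#' Pairwise overlap matrix across all ensembles in a projection
#'
#' @inheritParams overlap_coefficient
#' @return A tibble with one row per unordered label pair: `label_a`,
#'   `label_b`, `ovl`, `centroid_distance`.
#' @export
overlap_matrix <- function(projection, bw = NULL, min_n = 20) {
  labs <- unique(projection$label)
  if (length(labs) < 2) abort("need at least two ensembles")
  pairs <- utils::combn(labs, 2)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    r <- overlap_coefficient(projection, pairs[1, i], pairs[2, i],
                             bw = bw, min_n = min_n)
    tibble::tibble(label_a = pairs[1, i], label_b = pairs[2, i],
                   ovl = r$ovl, centroid_distance = r$centroid_distance)
  }) |>
    dplyr::bind_rows()
}
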