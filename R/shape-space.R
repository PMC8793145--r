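#' Fit a PCA shape space over pooled ensembles
#'
#' Principal component analysis of the pooled harmonic feature matrix of all
#' ensembles under comparison (centred, never rescaled per feature: harmonic
#' magnitudes share units, and standardising would inflate high-frequency
#' noise). The space is refit per comparison on whatever ensembles are
#' pooled, so coordinates are comparison-specific. Component signs follow a
#' fixed convention — each component's largest-magnitude loading is positive —
#' so runs are reproducible across platforms.
#'
#' @param features a feature tibble from [describe_contours()], typically
#'   several ensembles row-bound together (a `label` column distinguishes
#'   them).
#' @return A `shape_space` object: `mean_vector`, `components` (columns,
#'   orthonormal, ranked by variance), `sdev`, `explained_variance_ratio`,
#'   `k`, `n_particles`.
#' @export
fit_shape_space <- function(features) {
  x <- feature_matrix(features)
  if (nrow(x) < 2) abort("at least 2 particles are required to fit a shape space")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- fit$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  var <- fit$sdev^2
  structure(
    list(
      mean_vector = fit$center,
      components = rot,
      sdev = fit$sdev,
      explained_variance_ratio = var / sum(var),
      k = ncol(x),
      n_particles = nrow(x)
    ),
    class = "shape_space"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf(
    "<shape_space: %d particles, %d harmonics, %d components; PC1-3 variance %.1f%% / %.1f%% / %.1f%%>\n",
    x$n_particles, x$k, length(x$sdev),
    100 * evr[1], 100 * (evr[2] %||% NA), 100 * (evr[3] %||% NA)))
  invisible(x)
}

#' @export
tidy.shape_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$sdev),
    std_dev = x$sdev,
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @export
glance.shape_space <- function(x, ...) {
  tibble::tibble(
    n_particles = x$n_particles,
    k_harmonics = x$k,
    n_components = length(x$sdev),
    evr_pc1 = x$explained_variance_ratio[1],
    evr_pc123 = sum(x$explained_variance_ratio[seq_len(min(3, length(x$sdev)))])
  )
}

#' Project ensembles into a shape space
#'
#' Centres each particle's feature vector on the space's mean and projects it
#' onto the first `m` components. Each particle becomes one point; an
#' ensemble becomes a cloud whose mean coordinate is its center of gravity
#' (its "typical shape").
#'
#' @param features feature tibble (must have the same harmonic count as the
#'   space; a `label` column, if absent, is filled with `"ensemble"`).
#' @param space a `shape_space` from [fit_shape_space()].
#' @param m number of leading components (default 3).
#' @return A projection tibble: `label`, `particle_id`, `pc1 .. pc<m>`.
#' @export
project_ensemble <- function(features, space, m = 3) {
  stopifnot(inherits(space, "shape_space"))
  x <- feature_matrix(features)
  if (ncol(x) != space$k) {
    abort(sprintf("feature dimension (%d) does not match the shape space (%d)",
                  ncol(x), space$k))
  }
  if (m < 1 || m > ncol(space$components)) {
    abort("`m` must be between 1 and the number of components")
  }
  coords <- sweep(x, 2, space$mean_vector) %*% space$components[, seq_len(m), drop = FALSE]
  colnames(coords) <- paste0("pc", seq_len(m))
  lab <- if ("label" %in% names(features)) features$label else "ensemble"
  dplyr::bind_cols(
    tibble::tibble(label = lab, particle_id = features$particle_id),
    tibble::as_tibble(coords)
  )
}

# pc-coordinate columns of a projection tibble, as a matrix.
projection_matrix <- function(projection) {
  cols <- grep("^pc\\d+$", names(projection), value = TRUE)
  as.matrix(projection[, cols])
}

#' Ensemble centers of gravity
#'
#' @param projection a projection tibble from [project_ensemble()].
#' @return One row per label with the mean coordinate in each PC.
#' @export
ensemble_centroids <- function(projection) {
  projection |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::matches("^pc\\d+$"), mean),
                     n = dplyr::n(), .groups = "drop")
}

#' Most representative particle of each ensemble
#'
#' The particle closest (Euclidean, in the projected coordinates) to its
#' ensemble's center of gravity; ties go to the particle appearing first in
#' the table. This is the "typical shape" one would display for the ensemble.
#'
#' @inheritParams ensemble_centroids
#' @return A tibble: `label`, `particle_id`, `distance`.
#' @export
representative_particle <- function(projection) {
  if (nrow(projection) == 0) abort("empty projection")
  projection |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(df, key) {
      xy <- as.matrix(df[, grep("^pc\\d+$", names(df), value = TRUE)])
      ctr <- colMeans(xy)
      d <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
      i <- which.min(d)                      # first index wins ties
      tibble::tibble(particle_id = df$particle_id[i], distance = d[i])
    }) |>
    dplyr::ungroup()
}

#' Confidence ellipse of an ensemble in the PC1-PC2 plane
#'
#' Gaussian confidence ellipse from the sample mean and covariance of the
#' first two PCs: semi-axes are `sqrt(eigenvalue * q)` with `q` the
#' chi-square quantile at `level` with 2 degrees of freedom, and the
#' orientation follows the leading eigenvector. For a Gaussian cloud the
#' ellipse contains `level` of the points in expectation (the conventional
#' "region containing 95% of the points" at the default level).
#'
#' @inheritParams ensemble_centroids
#' @param level coverage probability in (0, 1).
#' @return A tibble, one row per label: `center_pc1`, `center_pc2`,
#'   `semi_major`, `semi_minor`, `angle_rad`, `level`, `n`.
#' @export
confidence_ellipse <- function(projection, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  projection |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        abort(paste0("ensemble '", key$label,
                     "': at least 3 particles are needed for an ellipse"))
      }
      xy <- cbind(df$pc1, df$pc2)
      s <- stats::cov(xy)
      ev <- eigen(s, symmetric = TRUE)
      if (min(ev$values) <= max(ev$values) * 1e-12 || max(ev$values) == 0) {
        abort(paste0("ensemble '", key$label,
                     "': degenerate (collinear or identical) points"))
      }
      q <- stats::qchisq(level, df = 2)
      tibble::tibble(
        center_pc1 = mean(xy[, 1]),
        center_pc2 = mean(xy[, 2]),
        semi_major = sqrt(ev$values[1] * q),
        semi_minor = sqrt(ev$values[2] * q),
        angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
        level = level,
        n = nrow(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Which points fall inside a confidence ellipse
#'
#' @param projection projection tibble with `pc1`, `pc2` columns.
#' @param ellipse a single-row ellipse tibble from [confidence_ellipse()].
#' @return Logical vector, one entry per projection row.
#' @export
points_in_ellipse <- function(projection, ellipse) {
  stopifnot(nrow(ellipse) == 1)
  dx <- projection$pc1 - ellipse$center_pc1
  dy <- projection$pc2 - ellipse$center_pc2
  ca <- cos(ellipse$angle_rad); sa <- sin(ellipse$angle_rad)
  u <- ca * dx + sa * dy
  v <- -sa * dx + ca * dy
  (u / ellipse$semi_major)^2 + (v / ellipse$semi_minor)^2 <= 1
}

#' Dispersity of an ensemble as a distance PDF
#'
#' Per-particle Euclidean distance to the ensemble's own center of gravity in
#' the first `m` PCs, summarised as a Gaussian kernel density (Silverman
#' bandwidth, reflected at zero so the density of the non-negative distances
#' integrates to one) on a 512-point grid from 0 to the maximum distance plus
#' three bandwidths. This is the ensemble's shape-variance profile: narrow
#' means monodisperse, broad or multimodal means heterogeneous.
#'
#' @inheritParams ensemble_centroids
#' @param m number of PCs used for the distances (default 3).
#' @param bw kernel bandwidth; default Silverman's rule per ensemble.
#' @return A `distance_pdf` object with `$distances` (label, particle_id,
#'   distance) and `$density` (label, distance, density) tibbles.
#' @export
distance_pdf <- function(projection, m = 3, bw = NULL) {
  pcs <- grep("^pc\\d+$", names(projection), value = TRUE)
  if (length(pcs) < m) abort(sprintf("projection has fewer than m = %d PCs", m))
  labs <- unique(projection$label)
  dist_tbl <- list(); dens_tbl <- list(); bws <- numeric(0)
  for (lb in labs) {
    df <- projection[projection$label == lb, ]
    if (nrow(df) < 20) {
      abort(paste0("ensemble '", lb, "': at least 20 particles are required"))
    }
    xy <- as.matrix(df[, pcs[seq_len(m)]])
    ctr <- colMeans(xy)
    d <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
    if (all(d == 0)) {
      abort(paste0("ensemble '", lb,
                   "': all particles identical; distance distribution degenerate"))
    }
    h <- bw %||% silverman_bw(d)
    grid <- seq(0, max(d) + 3 * h, length.out = 512)
    dens <- gauss_kde(d, grid, h, reflect = TRUE)
    dist_tbl[[lb]] <- tibble::tibble(label = lb, particle_id = df$particle_id,
                                     distance = d)
    dens_tbl[[lb]] <- tibble::tibble(label = lb, distance = grid, density = dens)
    bws[lb] <- h
  }
  structure(
    list(
      distances = dplyr::bind_rows(dist_tbl),
      density = dplyr::bind_rows(dens_tbl),
      bandwidth = bws,
      m = m
    ),
    class = "distance_pdf"
  )
}

#' @export
print.distance_pdf <- function(x, ...) {
  s <- x$distances |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$distance),
                     sd = stats::sd(.data$distance), .groups = "drop")
  cat(sprintf("<distance_pdf over first %d PCs>\n", x$m))
  print(s)
  invisible(x)
}

#' @export
tidy.distance_pdf <- function(x, ...) x$density

#' @export
glance.distance_pdf <- function(x, ...) {
  x$distances |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_distance = mean(.data$distance),
                     sd_distance = stats::sd(.data$distance),
                     .groups = "drop") |>
    dplyr::mutate(bandwidth = x$bandwidth[.data$label])
}
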