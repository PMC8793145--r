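#' Parametric branched-particle shapes
#'
#' The generator emulates the 2D projected outlines of branched gold
#' nanoparticles (spheres, stars, flowers, urchins): a smooth base disk of
#' radius `base_radius_nm` decorated with `n_spikes` angular protrusions.
#' The radial profile is
#'
#' `r(theta) = R * (1 + A * sum_j g((theta - theta_j) / s) + rough * eta(theta))`
#'
#' with `g` a periodic von-Mises-style unit bump `exp((cos(x) - 1) / s^2)`
#' (smooth, band-limited, and sharpness-tunable between broad "flower" lobes
#' and needle-like "urchin" spikes), spike centres equally spaced plus
#' Gaussian placement jitter, and `eta` a smooth zero-mean broadband radial
#' noise (random low-order Fourier series, unit variance). Any parameter
#' combination driving the radius non-positive anywhere is an error.
#'
#' @param base_radius_nm base disk radius in nm (> 0).
#' @param n_spikes number of protrusions (integer >= 0).
#' @param spike_amplitude fractional radial amplitude of protrusions,
#'   in `[0, 0.9]`.
#' @param spike_sharpness angular width parameter (> 0; smaller = sharper).
#' @param angular_jitter SD (radians) of spike placement noise.
#' @param roughness amplitude of the broadband radial noise, as a fraction of
#'   the base radius.
#' @return A `shape_params` list.
#' @export
shape_params <- function(base_radius_nm = 30, n_spikes = 0,
                         spike_amplitude = 0, spike_sharpness = 0.3,
                         angular_jitter = 0, roughness = 0) {
  if (base_radius_nm <= 0) abort("`base_radius_nm` must be positive")
  if (n_spikes < 0 || n_spikes != round(n_spikes)) {
    abort("`n_spikes` must be a non-negative integer")
  }
  if (spike_amplitude < 0 || spike_amplitude > 0.9) {
    abort("`spike_amplitude` must be in [0, 0.9]")
  }
  if (spike_sharpness <= 0) abort("`spike_sharpness` must be positive")
  if (angular_jitter < 0 || roughness < 0) {
    abort("`angular_jitter` and `roughness` must be non-negative")
  }
  structure(
    list(base_radius_nm = base_radius_nm, n_spikes = as.integer(n_spikes),
         spike_amplitude = spike_amplitude, spike_sharpness = spike_sharpness,
         angular_jitter = angular_jitter, roughness = roughness),
    class = "shape_params"
  )
}

#' Generate one particle contour
#'
#' Samples the radial profile at 1024 equally spaced angles and returns a
#' closed counterclockwise contour. Identical `params` and `seed` give a
#' bitwise-identical contour.
#'
#' @param params a [shape_params()].
#' @param seed integer seed for the jitter/roughness draws.
#' @param particle_id id for the output table.
#' @param n_theta number of angular samples.
#' @return A contour table.
#' @export
generate_contour <- function(params, seed = 1, particle_id = "p001",
                             n_theta = 1024) {
  stopifnot(inherits(params, "shape_params"))
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  withr::with_seed(as.integer(seed), {
    bump <- numeric(n_theta)
    if (params$n_spikes > 0 && params$spike_amplitude > 0) {
      centers <- 2 * pi * (seq_len(params$n_spikes) - 1) / params$n_spikes
      if (params$angular_jitter > 0) {
        centers <- centers + stats::rnorm(params$n_spikes,
                                          sd = params$angular_jitter)
      }
      kappa <- 1 / params$spike_sharpness^2
      for (cth in centers) bump <- bump + exp(kappa * (cos(theta - cth) - 1))
    }
    eta <- numeric(n_theta)
    if (params$roughness > 0) {
      for (k in 1:10) {
        eta <- eta + (stats::rnorm(1) * cos(k * theta) +
                      stats::rnorm(1) * sin(k * theta)) / k
      }
      eta <- (eta - mean(eta)) / stats::sd(eta)
    }
    r <- params$base_radius_nm *
      (1 + params$spike_amplitude * bump + params$roughness * eta)
    if (any(r <= 0)) {
      abort("parameter combination produces a non-positive radius")
    }
    contour_tbl(cbind(r * cos(theta), r * sin(theta)), particle_id)
  })
}

#' Ensemble-level generator parameters
#'
#' Particle-to-particle variability is modelled by drawing each particle's
#' parameters around `mean`: lognormal draws (exact mean, given coefficient
#' of variation) for the positive continuous parameters, and a rounded
#' truncated-normal draw for the spike count when a `n_spikes` CV is given.
#' Child seeds are derived deterministically from `seed`, so any single
#' particle is reproducible in isolation.
#'
#' @param mean a [shape_params()] giving the ensemble's mean shape.
#' @param cv coefficient of variation: a single number applied to
#'   `base_radius_nm`, `spike_amplitude` and `spike_sharpness`, or a named
#'   vector choosing per-parameter CVs (names among those three plus
#'   `n_spikes`).
#' @param n_particles number of particles (>= 1).
#' @param seed ensemble seed.
#' @return An `ensemble_params` list.
#' @export
ensemble_params <- function(mean, cv = 0.1, n_particles = 200, seed = 1) {
  stopifnot(inherits(mean, "shape_params"))
  if (any(cv < 0)) abort("`cv` must be non-negative")
  if (n_particles < 1) abort("`n_particles` must be at least 1")
  if (is.null(names(cv))) {
    if (length(cv) != 1) abort("unnamed `cv` must be a single number")
    cv <- c(base_radius_nm = cv, spike_amplitude = cv, spike_sharpness = cv)
  }
  ok <- c("base_radius_nm", "spike_amplitude", "spike_sharpness", "n_spikes")
  if (!all(names(cv) %in% ok)) {
    abort(paste0("`cv` names must be among: ", paste(ok, collapse = ", ")))
  }
  structure(
    list(mean = mean, cv = cv, n_particles = as.integer(n_particles),
         seed = as.integer(seed)),
    class = "ensemble_params"
  )
}

# Lognormal with exact mean m and coefficient of variation cv.
rlnorm_cv <- function(n, m, cv) {
  if (m == 0 || cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a contour ensemble
#'
#' @param ep an [ensemble_params()].
#' @param id_prefix prefix for particle ids.
#' @return A contour table with `n_particles` closed polygons.
#' @export
generate_ensemble <- function(ep, id_prefix = "p") {
  stopifnot(inherits(ep, "ensemble_params"))
  n <- ep$n_particles
  m <- ep$mean
  cv <- ep$cv
  cv_of <- function(p) if (p %in% names(cv)) unname(cv[p]) else 0
  draws <- withr::with_seed(ep$seed, {
    list(
      radius = rlnorm_cv(n, m$base_radius_nm, cv_of("base_radius_nm")),
      amp = pmin(rlnorm_cv(n, m$spike_amplitude, cv_of("spike_amplitude")), 0.9),
      sharp = rlnorm_cv(n, m$spike_sharpness, cv_of("spike_sharpness")),
      spikes = if (cv_of("n_spikes") > 0) {
        pmax(0L, as.integer(round(stats::rnorm(
          n, m$n_spikes, sd = cv_of("n_spikes") * m$n_spikes))))
      } else rep(m$n_spikes, n)
    )
  })
  seeds <- derive_seeds(ep$seed, n)
  purrr::map(seq_len(n), function(i) {
    p <- shape_params(
      base_radius_nm = draws$radius[i],
      n_spikes = draws$spikes[i],
      spike_amplitude = draws$amp[i],
      spike_sharpness = draws$sharp[i],
      angular_jitter = m$angular_jitter,
      roughness = m$roughness
    )
    generate_contour(p, seed = seeds[i],
                     particle_id = sprintf("%s%04d", id_prefix, i))
  }) |>
    dplyr::bind_rows()
}

#' Shape family presets
#'
#' Mean-shape presets for the four classic branched-particle families. The
#' spike count is the family's identity and is held fixed within an ensemble;
#' particle-to-particle variability (default CV 0.10 on radius, amplitude and
#' sharpness) models batch heterogeneity.
#'
#' @param family one of `"sphere"`, `"star"`, `"flower"`, `"urchin"`.
#' @return A [shape_params()].
#' @export
preset_params <- function(family = c("sphere", "star", "flower", "urchin")) {
  family <- match.arg(family)
  switch(family,
    sphere = shape_params(base_radius_nm = 30, n_spikes = 0,
                          spike_amplitude = 0, spike_sharpness = 0.3,
                          angular_jitter = 0, roughness = 0.03),
    star = shape_params(base_radius_nm = 35, n_spikes = 5,
                        spike_amplitude = 0.55, spike_sharpness = 0.35,
                        angular_jitter = 0.06, roughness = 0.02),
    flower = shape_params(base_radius_nm = 35, n_spikes = 9,
                          spike_amplitude = 0.28, spike_sharpness = 0.5,
                          angular_jitter = 0.06, roughness = 0.02),
    urchin = shape_params(base_radius_nm = 35, n_spikes = 40,
                          spike_amplitude = 0.22, spike_sharpness = 0.12,
                          angular_jitter = 0.04, roughness = 0.02)
  )
}

#' @rdname preset_params
#' @inheritParams ensemble_params
#' @export
preset_ensemble <- function(family, n_particles = 200, seed = 1, cv = 0.1) {
  ensemble_params(preset_params(family), cv = cv,
                  n_particles = n_particles, seed = seed)
}

#' Render contours into a noisy micrograph-like image
#'
#' Places the particles on a bright background at non-overlapping positions
#' (rejection sampling on bounding discs, >= `margin_px` apart and away from
#' the border), fills each polygon dark, and adds Gaussian pixel noise. The
#' placement record is attached for ground-truth checks.
#'
#' @inheritParams contour_tbl
#' @param canvas_px square canvas side in pixels.
#' @param pixel_size_nm nm per pixel.
#' @param noise_sd Gaussian intensity noise SD (0 gives an exactly two-valued
#'   image).
#' @param seed placement/noise seed.
#' @param margin_px minimum clearance between particles and to the border.
#' @param max_tries placement attempts per particle before failing.
#' @param fg,bg foreground (particle) and background intensities.
#' @return A [particle_image()] with a `placements` attribute (tibble:
#'   `particle_id`, `x_px`, `y_px`, `bound_radius_px`).
#' @export
render_image <- function(contours, canvas_px = 512, pixel_size_nm = 1,
                         noise_sd = 0.02, seed = 1, margin_px = 5,
                         max_tries = 500, fg = 0.2, bg = 0.8) {
  mats <- contour_matrices(contours)
  rel <- purrr::map(mats, function(xy) {
    ctr <- curve_centroid(xy)
    sweep(xy, 2, ctr) / pixel_size_nm
  })
  rad <- purrr::map_dbl(rel, ~ max(sqrt(rowSums(.x^2))))
  if (any(2 * rad + 2 * margin_px >= canvas_px)) {
    abort("a particle is too large for the canvas at this pixel size")
  }
  img <- matrix(bg, canvas_px, canvas_px)
  placements <- withr::with_seed(as.integer(seed), {
    centers <- matrix(NA_real_, length(rel), 2)
    for (i in seq_along(rel)) {
      lo <- rad[i] + margin_px
      hi <- canvas_px - 1 - rad[i] - margin_px
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(2, lo, hi)
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        if (i == 1 || all(sqrt(rowSums(sweep(prev, 2, cand)^2)) >=
                          rad[seq_len(i - 1)] + rad[i] + margin_px)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("could not place particle %d without overlap after %d tries",
                      i, max_tries))
      }
    }
    for (i in seq_along(rel)) {
      img <- fill_polygon(img, rel[[i]][, 1] + centers[i, 1],
                           rel[[i]][, 2] + centers[i, 2], fg)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(canvas_px^2, sd = noise_sd),
                           canvas_px, canvas_px)
    }
    tibble::tibble(particle_id = names(rel), x_px = centers[, 1],
                   y_px = centers[, 2], bound_radius_px = rad)
  })
  out <- particle_image(img, pixel_size_nm, id = "render")
  attr(out, "placements") <- placements
  out
}

# Even-odd scanline polygon fill; coordinates are 0-based pixel centres
# (x = column - 1, y = row - 1).
fill_polygon <- function(img, px, py, value) {
  nr <- nrow(img); nc <- ncol(img)
  x1 <- px; y1 <- py
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  ys <- seq(max(0, floor(min(py))), min(nr - 1, ceiling(max(py))))
  for (yc in ys) {
    cross <- ((y1 <= yc) & (y2 > yc)) | ((y2 <= yc) & (y1 > yc))
    if (!any(cross)) next
    xs <- sort(x1[cross] + (yc - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      lo <- max(0, ceiling(xs[i]))
      hi <- min(nc - 1, floor(xs[i + 1]))
      if (hi >= lo) img[yc + 1, (lo:hi) + 1] <- value
    }
  }
  img
}
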