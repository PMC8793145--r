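#' Surrogate readout landscapes over shape space
#'
#' A stand-in for an expensive biological readout (e.g., a transcriptome- or
#' ELISA-derived score): a deterministic sum of isotropic Gaussian bumps over
#' shape-space coordinates, with hidden targets at the bump centres. Higher
#' values mean "more biologically interesting"; the readout strictly
#' decreases with distance from an isotropic target. The abstraction is a
#' plain function of a coordinate, so a table of real assay results could
#' replace it without touching the search loop.
#'
#' @param centers matrix (one row per bump) or vector (single bump) of bump
#'   centres in shape-space coordinates.
#' @param amplitudes peak heights (recycled).
#' @param widths Gaussian widths (SD, recycled).
#' @return A `readout_landscape` object.
#' @export
readout_landscape <- function(centers, amplitudes = 1, widths = 1) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  k <- nrow(centers)
  structure(
    list(centers = centers,
         amplitudes = rep_len(amplitudes, k),
         widths = rep_len(widths, k)),
    class = "readout_landscape"
  )
}

#' @rdname readout_landscape
#' @param coord shape-space coordinate (numeric vector, same dimension as the
#'   bump centres).
#' @param landscape a `readout_landscape`.
#' @export
surrogate_readout <- function(coord, landscape) {
  stopifnot(inherits(landscape, "readout_landscape"))
  d2 <- rowSums(sweep(landscape$centers, 2, coord)^2)
  sum(landscape$amplitudes * exp(-d2 / (2 * landscape$widths^2)))
}

#' Configuration of a shape learning trajectory
#'
#' @param start an [ensemble_params()]: the first synthesis condition.
#' @param step_scales named numeric vector of initial step sizes for the
#'   generator parameters being searched (names among `base_radius_nm`,
#'   `spike_amplitude`, `spike_sharpness`).
#' @param ovl_gate overlap at or below which two ensembles are independent
#'   enough that a readout is informative (default 0.05).
#' @param backtrack_ovl overlap below which a step was an overlarge,
#'   discontinuous jump and must be retried at half scale (default 0.01).
#'   Must satisfy `0 <= backtrack_ovl < ovl_gate < 1`.
#' @param max_steps maximum number of proposals.
#' @param seed master seed; every ensemble and placement draw derives from it.
#' @param n_signature,k_harmonics,m signature length, harmonic count and
#'   working PC dimension used for the trajectory's shape space (smaller than
#'   the analysis defaults, since the loop synthesises an ensemble per step).
#' @param step_floor stop when every step scale falls below this fraction of
#'   its initial value.
#' @return A `trajectory_config`.
#' @export
trajectory_config <- function(start, step_scales, ovl_gate = 0.05,
                              backtrack_ovl = 0.01, max_steps = 50, seed = 1,
                              n_signature = 256, k_harmonics = 64, m = 3,
                              step_floor = 0.02) {
  stopifnot(inherits(start, "ensemble_params"))
  if (!(backtrack_ovl >= 0 && backtrack_ovl < ovl_gate && ovl_gate < 1)) {
    abort("need 0 <= backtrack_ovl < ovl_gate < 1")
  }
  ok <- c("base_radius_nm", "spike_amplitude", "spike_sharpness")
  if (is.null(names(step_scales)) || !all(names(step_scales) %in% ok)) {
    abort(paste0("`step_scales` must be named among: ", paste(ok, collapse = ", ")))
  }
  structure(
    list(start = start, step_scales = step_scales, ovl_gate = ovl_gate,
         backtrack_ovl = backtrack_ovl, max_steps = as.integer(max_steps),
         seed = as.integer(seed), n_signature = n_signature,
         k_harmonics = k_harmonics, m = m, step_floor = step_floor),
    class = "trajectory_config"
  )
}

# Ensemble features at a given point of the searched parameter space.
trajectory_features <- function(cfg, par, seed) {
  ep <- ensemble_params(
    shape_params(base_radius_nm = par["base_radius_nm"],
                 n_spikes = cfg$start$mean$n_spikes,
                 spike_amplitude = par["spike_amplitude"],
                 spike_sharpness = par["spike_sharpness"],
                 angular_jitter = cfg$start$mean$angular_jitter,
                 roughness = cfg$start$mean$roughness),
    cv = cfg$start$cv, n_particles = cfg$start$n_particles, seed = seed
  )
  describe_contours(generate_ensemble(ep), n = cfg$n_signature,
                    k = cfg$k_harmonics)
}

#' The fixed shape-space chart of a trajectory
#'
#' A trajectory measures every step in one shape space, fit on the starting
#' ensemble and then held fixed so that centroids, overlaps and the readout
#' landscape share a stable coordinate system. This helper exposes that chart
#' before a run, so landscape bumps can be placed at meaningful coordinates
#' (e.g., at the projected centroid of a target ensemble).
#'
#' @param cfg a [trajectory_config()].
#' @return A list: `space` (the `shape_space`), `projection` (the start
#'   ensemble projected into it), `centroid` (start center of gravity).
#' @export
trajectory_space <- function(cfg) {
  stopifnot(inherits(cfg, "trajectory_config"))
  seeds <- derive_seeds(cfg$seed, cfg$max_steps + 1L)
  par0 <- c(base_radius_nm = cfg$start$mean$base_radius_nm,
            spike_amplitude = cfg$start$mean$spike_amplitude,
            spike_sharpness = cfg$start$mean$spike_sharpness)
  feats0 <- trajectory_features(cfg, par0, seeds[1])
  feats0 <- dplyr::mutate(feats0, label = "e000", .before = 1)
  space <- fit_shape_space(feats0)
  proj0 <- project_ensemble(feats0, space, cfg$m)
  list(space = space, projection = proj0,
       centroid = colMeans(projection_matrix(proj0)))
}

#' Project a generator parameter point into a trajectory's chart
#'
#' Synthesises an ensemble at the given continuous parameters (spike count
#' and the non-searched parameters come from the config's start) and returns
#' its center of gravity in the trajectory's fixed shape space. Used to place
#' landscape targets.
#'
#' @param cfg a [trajectory_config()].
#' @param space the `shape_space` from [trajectory_space()].
#' @param par named vector with `base_radius_nm`, `spike_amplitude`,
#'   `spike_sharpness`.
#' @param seed ensemble seed.
#' @return Centroid coordinate (length `m`).
#' @export
trajectory_centroid_at <- function(cfg, space, par, seed = 1) {
  feats <- trajectory_features(cfg, par, seed)
  proj <- project_ensemble(dplyr::mutate(feats, label = "t", .before = 1),
                           space, cfg$m)
  colMeans(projection_matrix(proj))
}

# Clamp proposed generator parameters into their valid domain.
clamp_params <- function(v) {
  v["base_radius_nm"] <- max(v["base_radius_nm"], 1)
  v["spike_amplitude"] <- min(max(v["spike_amplitude"], 0), 0.9)
  v["spike_sharpness"] <- max(v["spike_sharpness"], 0.02)
  v
}

#' Run an overlap-gated shape learning trajectory
#'
#' Derivative-free coordinate ascent over the generator parameters, with the
#' search geometry measured in shape space rather than in parameter space:
#'
#' * each proposal synthesises an ensemble and measures its overlap (OVL)
#'   with the previously accepted ensemble, in a shape space fit once on the
#'   starting ensemble and held fixed for the whole run;
#' * a proposal with OVL below `backtrack_ovl` is an overlarge discontinuous
#'   jump: the step is halved and the loop returns close to the previous
#'   coordinates (a `"backtrack"` record);
#' * the (surrogate) readout is only queried when the current ensemble's OVL
#'   with the last-queried ensemble has dropped to `ovl_gate` or below —
#'   readouts from strongly overlapping distributions carry no independent
#'   information;
#' * after a queried readout, an improvement keeps the step direction; a
#'   deterioration reverses it, and a second deterioration on the same
#'   parameter rotates to the next parameter.
#'
#' The run stops at `max_steps` or when every step scale has shrunk below
#' `step_floor` of its initial value. Identical config gives an identical
#' record.
#'
#' @param cfg a [trajectory_config()].
#' @param landscape a [readout_landscape()] over the first `m` PCs of the
#'   trajectory's shape space.
#' @return A `shape_trajectory`: `$record` (one row per proposal: parameters,
#'   centroid, OVLs, readout, action), `$space`, `$config`, `$manifest`.
#' @export
run_trajectory <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "trajectory_config"),
            inherits(landscape, "readout_landscape"))
  m_dim <- cfg$m
  seeds <- derive_seeds(cfg$seed, cfg$max_steps + 1L)
  make_features <- function(par, seed) trajectory_features(cfg, par, seed)

  par0 <- c(base_radius_nm = cfg$start$mean$base_radius_nm,
            spike_amplitude = cfg$start$mean$spike_amplitude,
            spike_sharpness = cfg$start$mean$spike_sharpness)
  chart <- trajectory_space(cfg)
  space <- chart$space
  proj_of <- function(feats, lb) {
    project_ensemble(dplyr::mutate(feats, label = lb, .before = 1), space, m_dim)
  }
  centroid_of <- function(proj) colMeans(projection_matrix(proj))

  proj0 <- chart$projection
  cen0 <- chart$centroid
  read0 <- surrogate_readout(cen0, landscape)

  active <- names(cfg$step_scales)
  steps <- cfg$step_scales
  init_steps <- steps
  coord <- 1L
  dir <- 1
  reversed_since_improve <- FALSE

  cur_par <- par0
  cur_proj <- proj0
  last_q_proj <- proj0
  last_read <- read0

  rec <- list(traj_record_row(0L, "query", par0, cen0, NA, NA, read0,
                              steps[coord]))
  projections <- list(proj0)
  queried_steps <- 0L

  for (s in seq_len(cfg$max_steps)) {
    if (all(steps < cfg$step_floor * init_steps)) break
    p_name <- active[coord]
    prop <- clamp_params(replace(cur_par, p_name,
                                 cur_par[p_name] + dir * steps[p_name]))
    if (isTRUE(all.equal(unname(prop[p_name]), unname(cur_par[p_name])))) {
      dir <- -dir            # pinned at the domain edge: turn around
      rec[[length(rec) + 1L]] <- traj_record_row(s, "reverse", cur_par,
                                                 centroid_of(cur_proj),
                                                 NA, NA, NA, steps[p_name])
      projections[[length(projections) + 1L]] <- cur_proj
      next
    }
    lb <- sprintf("e%03d", s)
    prop_proj <- proj_of(make_features(prop, seeds[s + 1L]), lb)
    both <- dplyr::bind_rows(
      dplyr::mutate(cur_proj, label = "prev"),
      dplyr::mutate(prop_proj, label = "prop")
    )
    ovl_prev <- overlap_coefficient(both, "prev", "prop",
                                    min_n = 2)$ovl
    cen <- centroid_of(prop_proj)

    if (ovl_prev < cfg$backtrack_ovl) {
      steps[p_name] <- steps[p_name] / 2
      rec[[length(rec) + 1L]] <- traj_record_row(s, "backtrack", prop, cen,
                                                 ovl_prev, NA, NA,
                                                 steps[p_name])
      projections[[length(projections) + 1L]] <- prop_proj
      next
    }

    # accept the step
    cur_par <- prop
    cur_proj <- prop_proj
    bothq <- dplyr::bind_rows(
      dplyr::mutate(last_q_proj, label = "lastq"),
      dplyr::mutate(prop_proj, label = "prop")
    )
    ovl_q <- overlap_coefficient(bothq, "lastq", "prop", min_n = 2)$ovl
    if (ovl_q <= cfg$ovl_gate) {
      read <- surrogate_readout(cen, landscape)
      queried_steps <- queried_steps + 1L
      if (read > last_read) {
        reversed_since_improve <- FALSE
      } else if (!reversed_since_improve) {
        dir <- -dir
        reversed_since_improve <- TRUE
      } else {
        coord <- (coord %% length(active)) + 1L
        dir <- 1
        reversed_since_improve <- FALSE
      }
      last_read <- read
      last_q_proj <- prop_proj
      rec[[length(rec) + 1L]] <- traj_record_row(s, "query", prop, cen,
                                                 ovl_prev, ovl_q, read,
                                                 steps[p_name])
    } else {
      rec[[length(rec) + 1L]] <- traj_record_row(s, "advance", prop, cen,
                                                 ovl_prev, ovl_q, NA,
                                                 steps[p_name])
    }
    projections[[length(projections) + 1L]] <- prop_proj
  }

  record <- dplyr::bind_rows(rec)
  manifest <- list(
    config = list(
      start = unclass(cfg$start$mean),
      cv = as.list(cfg$start$cv),
      n_particles = cfg$start$n_particles,
      start_seed = cfg$start$seed,
      step_scales = as.list(cfg$step_scales),
      ovl_gate = cfg$ovl_gate,
      backtrack_ovl = cfg$backtrack_ovl,
      max_steps = cfg$max_steps,
      seed = cfg$seed,
      n_signature = cfg$n_signature,
      k_harmonics = cfg$k_harmonics,
      m = cfg$m,
      step_floor = cfg$step_floor
    ),
    landscape = list(centers = landscape$centers,
                     amplitudes = landscape$amplitudes,
                     widths = landscape$widths),
    package_version = as.character(utils::packageVersion("nanoshape"))
  )
  structure(
    list(record = record, space = space, config = cfg, landscape = landscape,
         projections = projections, manifest = manifest),
    class = "shape_trajectory"
  )
}

traj_record_row <- function(step, action, par, cen, ovl_prev, ovl_q, readout,
                            step_scale) {
  tibble::tibble(
    step = step,
    action = action,
    base_radius_nm = unname(par["base_radius_nm"]),
    spike_amplitude = unname(par["spike_amplitude"]),
    spike_sharpness = unname(par["spike_sharpness"]),
    !!!stats::setNames(as.list(cen), paste0("pc", seq_along(cen))),
    ovl_prev = ovl_prev,
    ovl_last_query = ovl_q,
    readout = readout,
    step_scale = unname(step_scale)
  )
}

#' @export
print.shape_trajectory <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<shape_trajectory: %d proposals (%d queries, %d backtracks); readout %.4g -> %.4g>\n",
    nrow(r) - 1, sum(r$action == "query") - 1, sum(r$action == "backtrack"),
    r$readout[1], dplyr::last(stats::na.omit(r$readout))))
  invisible(x)
}

#' @export
tidy.shape_trajectory <- function(x, ...) x$record

#' @export
glance.shape_trajectory <- function(x, ...) {
  r <- x$record
  reads <- stats::na.omit(r$readout)
  tibble::tibble(
    n_proposals = nrow(r) - 1,
    n_queries = sum(r$action == "query"),
    n_backtracks = sum(r$action == "backtrack"),
    initial_readout = reads[1],
    final_readout = dplyr::last(reads),
    improvement = dplyr::last(reads) - reads[1]
  )
}

#' Structure-function table of mutually independent ensembles
#'
#' Distils the learning trajectory into the "shape trajectory" proper: the
#' greedy subsequence of readout-bearing steps whose ensembles are pairwise
#' independent (every pairwise OVL at or below the gate), each with its
#' readout. These rows are the investigator-controlled independent variable
#' against which biological readouts form a meaningful structure-function
#' relationship.
#'
#' @param trajectory a `shape_trajectory`.
#' @param gate pairwise OVL threshold (default: the run's `ovl_gate`).
#' @return Tibble of selected record rows plus the pairwise-maximum OVL of
#'   each row against the previously selected ones.
#' @export
structure_function_table <- function(trajectory, gate = NULL) {
  stopifnot(inherits(trajectory, "shape_trajectory"))
  gate <- gate %||% trajectory$config$ovl_gate
  rec <- trajectory$record
  qi <- which(rec$action == "query")
  sel <- integer(0)
  max_ovl <- numeric(0)
  for (i in qi) {
    if (!length(sel)) {
      sel <- i; max_ovl <- NA_real_
      next
    }
    ovls <- purrr::map_dbl(sel, function(j) {
      both <- dplyr::bind_rows(
        dplyr::mutate(trajectory$projections[[j]], label = "a"),
        dplyr::mutate(trajectory$projections[[i]], label = "b")
      )
      overlap_coefficient(both, "a", "b", min_n = 2)$ovl
    })
    if (all(ovls <= gate)) {
      sel <- c(sel, i)
      max_ovl <- c(max_ovl, max(ovls))
    }
  }
  dplyr::bind_cols(rec[sel, ], tibble::tibble(max_ovl_selected = max_ovl))
}
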