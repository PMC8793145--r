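#' Read and write contour tables
#'
#' Contours are exchanged as CSV (columns `particle_id`, `vertex_index`,
#' `x_nm`, `y_nm`) or JSON (a list of objects with `particle_id` and a
#' `points` array of `[x, y]` pairs, under a `metadata`/`contours` envelope).
#' The format is chosen by file extension. Loading validates every contour
#' against the closed-polygon contract (see [validate_contours()]) and
#' reports offending particles by id.
#'
#' @inheritParams contour_tbl
#' @param path `.csv` or `.json` file path.
#' @return `read_contours()` returns a validated contour table (empty table
#'   for a header-only file); `write_contours()` returns `path` invisibly.
#' @export
write_contours <- function(contours, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(contours, path)
  } else if (ext == "json") {
    mats <- contour_matrices(contours)
    obj <- list(
      metadata = list(format = "nanoshape-contours", units = "nm"),
      contours = purrr::imap(mats, function(xy, id) {
        list(particle_id = id, points = unname(apply(xy, 1, c, simplify = FALSE)))
      }) |> unname()
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("unsupported contour format: use .csv or .json")
  }
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            particle_id = readr::col_character(),
                            vertex_index = readr::col_integer(),
                            x_nm = readr::col_double(),
                            y_nm = readr::col_double()
                          ))
    if (nrow(df) == 0) return(tibble::as_tibble(df))
    validate_contours(tibble::as_tibble(df))
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path)
    rows <- purrr::map(obj$contours, function(ct) {
      xy <- do.call(rbind, purrr::map(ct$points, ~ as.numeric(unlist(.x))))
      contour_tbl(xy, ct$particle_id)
    })
    if (!length(rows)) return(contour_tbl(matrix(numeric(0), 0, 2))[0, ])
    validate_contours(dplyr::bind_rows(rows))
  } else {
    abort("unsupported contour format: use .csv or .json")
  }
}

#' Write a feature table with a parameter sidecar
#'
#' @param features a feature tibble from [describe_contours()].
#' @param path `.csv` output path; a `<path>.json` sidecar records the
#'   signature length and harmonic count.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  side <- list(n_signature = attr(features, "n_signature"),
               k_harmonics = attr(features, "k_harmonics"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Run the simulate - describe - space - overlap pipeline
#'
#' Executes the standard workflow from a configuration (a YAML file path or
#' an equivalent nested list): generate the configured preset ensembles,
#' describe them, fit the pooled shape space, project, and compute all
#' pairwise overlaps and confidence ellipses. All artifacts are written under
#' `out_dir` together with a manifest (inputs, parameters, seed, package
#' version, and an MD5 of every numeric output) from which the run can be
#' reproduced exactly.
#'
#' Configuration keys: `ensembles` (list of `name:`, `family:`, optional
#' `n_particles`, `cv`), `seed`, and optional `n`, `k`, `m`, `level`,
#' `threshold`.
#'
#' @param config YAML path or list.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`features`, `space`,
#'   `projection`, `overlaps`, `ellipses`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(n = 1024, k = 512, m = 3, level = 0.95, threshold = 0.05,
                   seed = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$ensembles) || length(config$ensembles) < 1) {
    abort("config must list at least one ensemble")
  }
  for (e in config$ensembles) {
    if (is.null(e$name) || is.null(e$family)) {
      abort("every ensemble needs `name` and `family`")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seeds <- derive_seeds(config$seed, length(config$ensembles))
  features <- purrr::imap(config$ensembles, function(e, i) {
    ep <- preset_ensemble(e$family,
                          n_particles = e$n_particles %||% 200,
                          seed = seeds[i], cv = e$cv %||% 0.1)
    generate_ensemble(ep, id_prefix = paste0(e$name, "_p")) |>
      describe_contours(n = config$n, k = config$k, label = e$name)
  }) |>
    dplyr::bind_rows()

  space <- fit_shape_space(features)
  projection <- project_ensemble(features, space, m = config$m)
  overlaps <- if (length(config$ensembles) > 1) {
    overlap_matrix(projection) |>
      dplyr::mutate(independent = .data$ovl <= config$threshold,
                    threshold = config$threshold)
  } else NULL
  ellipses <- confidence_ellipse(projection, level = config$level)

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    space = file.path(out_dir, "space.json"),
    projection = file.path(out_dir, "projection.csv"),
    ellipses = file.path(out_dir, "ellipses.json"),
    overlap = file.path(out_dir, "overlap.json")
  )
  write_features(features, paths$features)
  jsonlite::write_json(
    list(mean_vector = unname(space$mean_vector),
         components = unname(space$components),
         explained_variance_ratio = space$explained_variance_ratio,
         k = space$k, n_particles = space$n_particles),
    paths$space, digits = NA)
  readr::write_csv(projection, paths$projection)
  jsonlite::write_json(ellipses, paths$ellipses, auto_unbox = TRUE, digits = NA)
  if (!is.null(overlaps)) {
    jsonlite::write_json(overlaps, paths$overlap, auto_unbox = TRUE, digits = NA)
  }

  written <- unlist(paths[file.exists(unlist(paths))])
  manifest <- list(
    parameters = config,
    outputs = as.list(tools::md5sum(written)),
    package_version = as.character(utils::packageVersion("nanoshape"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = features, space = space, projection = projection,
                 overlaps = overlaps, ellipses = ellipses, manifest = manifest))
}
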