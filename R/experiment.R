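# Experiment runner: reproduces the two simulation studies (projection
# noise and sparse view) end-to-end from a single declarative config, at
# full scale or a fast reduced profile.

#' Experiment configuration
#'
#' Declarative description of a simulation study: grid, arc geometry,
#' phantom, degradation (noise and/or sparse-view subsampling), and the
#' solver parameter grids to scan. Defaults follow the reference setting —
#' a 256 x 256 grid of 0.1 mm pixels surrounded by 256 detectors on a
#' 270-degree arc of radius 40 mm — while `profile = "fast"` scales the
#' grid and detector count down for quick runs.
#'
#' @param profile `"full"` (256 x 256, 256 detectors) or `"fast"`
#'   (64 x 64, 64 detectors).
#' @param nx,ny,pixel_size,radius,coverage_deg,n_detectors geometry
#'   overrides (optional; profile defaults otherwise).
#' @param phantom_seed seed of the vessel phantom.
#' @param phantom_params a [vessel_phantom_params()]; its seed is replaced
#'   by `phantom_seed`.
#' @param input_image path to an image readable by [read_image()] to use
#'   instead of a generated phantom (optional).
#' @param noise_level projection noise std as a fraction of `max(|p|)`.
#' @param noise_seed seed of the projection noise.
#' @param subsample number of detectors to keep (`NULL` = keep all).
#' @param methods character vector of solver names to run.
#' @param lsqr_iters LSQR iteration count.
#' @param tvl1_grid data frame (or list of lists) of `mu`, `alpha` values
#'   to scan; `tvl1_iters` primal-dual iterations each.
#' @param a2tv_grid data frame of `lam`, `k` values to scan; `a2tv_iters`
#'   total inner iterations, `a2tv_outer` tensor updates each;
#'   `sigma`, `rho` smoothing scales.
#' @param tikhonov_lam Tikhonov weight (when `"tikhonov"` is requested).
#' @param samples_per_pixel arc quadrature density of the model matrix.
#' @param seed master seed for solver internals.
#' @param output_dir where [run_experiment()] writes results.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("fast", "full"),
                              nx = NULL, ny = NULL, pixel_size = 0.1,
                              radius = 40, coverage_deg = 270,
                              n_detectors = NULL,
                              phantom_seed = 1L,
                              phantom_params = vessel_phantom_params(),
                              input_image = NULL,
                              noise_level = 0, noise_seed = 2L,
                              subsample = NULL,
                              methods = c("lsqr", "tvl1", "a2tv"),
                              lsqr_iters = 50L,
                              tvl1_grid = data.frame(mu = 0.02, alpha = 0.1),
                              tvl1_iters = 200L,
                              a2tv_grid = data.frame(lam = 0.05, k = 0.1),
                              a2tv_iters = 200L, a2tv_outer = 2L,
                              sigma = 1.5, rho = 3,
                              tikhonov_lam = 1,
                              samples_per_pixel = 16L,
                              seed = 1L,
                              output_dir = tempfile("oatv_run_")) {
  profile <- match.arg(profile)
  dims <- if (profile == "full") c(256L, 256L, 256L) else c(64L, 64L, 64L)
  cfg <- list(profile = profile,
              nx = if (is.null(nx)) dims[1] else as.integer(nx),
              ny = if (is.null(ny)) dims[2] else as.integer(ny),
              pixel_size = pixel_size, radius = radius,
              coverage_deg = coverage_deg,
              n_detectors = if (is.null(n_detectors)) dims[3] else as.integer(n_detectors),
              phantom_seed = as.integer(phantom_seed),
              phantom_params = phantom_params,
              input_image = input_image,
              noise_level = noise_level, noise_seed = as.integer(noise_seed),
              subsample = if (is.null(subsample)) NULL else as.integer(subsample),
              methods = methods, lsqr_iters = as.integer(lsqr_iters),
              tvl1_grid = as.data.frame(tvl1_grid), tvl1_iters = as.integer(tvl1_iters),
              a2tv_grid = as.data.frame(a2tv_grid), a2tv_iters = as.integer(a2tv_iters),
              a2tv_outer = as.integer(a2tv_outer), sigma = sigma, rho = rho,
              tikhonov_lam = tikhonov_lam,
              samples_per_pixel = as.integer(samples_per_pixel),
              seed = as.integer(seed), output_dir = output_dir)
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  bad <- setdiff(cfg$methods, c("lsqr", "tikhonov", "tvl1", "a2tv"))
  if (length(bad)) stop("unknown methods in config: ", paste(bad, collapse = ", "))
  if (cfg$noise_level < 0) stop("noise_level must be non-negative")
  if (!is.null(cfg$subsample) && cfg$subsample > cfg$n_detectors)
    stop("subsample cannot exceed n_detectors")
  if (!is.null(cfg$input_image) && !file.exists(cfg$input_image))
    stop("input_image file not found: ", cfg$input_image)
  if (!all(c("mu", "alpha") %in% names(cfg$tvl1_grid)))
    stop("tvl1_grid needs columns mu and alpha")
  if (!all(c("lam", "k") %in% names(cfg$a2tv_grid)))
    stop("a2tv_grid needs columns lam and k")
  structure(cfg, class = "experiment_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' Unknown keys are rejected with an error naming them; omitted keys take
#' the [experiment_config()] defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("invalid config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$phantom_params))
    raw$phantom_params <- do.call(vessel_phantom_params, raw$phantom_params)
  do.call(experiment_config, raw)
}

#' Run a simulation study end-to-end
#'
#' Builds (and normalizes) the model matrix, simulates the sinogram from
#' the phantom, applies noise and/or sparse-view subsampling, runs every
#' requested solver over its parameter grid, and writes to
#' `config$output_dir`: one reconstruction per run (text array container),
#' the phantom, a `metrics.csv` table (method, parameters, MAD, relative
#' L2 error), a JSON echo of the config, and a short log. The run is fully
#' reproducible from the config: identical configs produce byte-identical
#' metrics tables.
#'
#' @param config an [experiment_config()].
#' @param matrix_cache optional directory for caching built model matrices
#'   keyed by a hash of (grid, geometry, time, quadrature).
#' @return the output directory, invisibly; the metrics table is also
#'   returned as the `metrics` attribute.
#' @export
run_experiment <- function(config, matrix_cache = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  grid <- image_grid(config$nx, config$ny, config$pixel_size)
  geom <- detection_geometry(config$radius, config$coverage_deg,
                             config$n_detectors)
  phantom <- if (!is.null(config$input_image)) {
    read_image(config$input_image)
  } else {
    pp <- config$phantom_params; pp$seed <- config$phantom_seed
    generate_vessel_phantom(grid, pp)
  }
  logf("phantom: %d x %d, foreground fraction %.3f", grid$ny, grid$nx,
       mean(phantom$values > 0.1))
  M <- build_cached_matrix(grid, geom, config$samples_per_pixel, matrix_cache,
                           logf)
  sino <- forward_project(M, phantom)
  if (!is.null(config$subsample)) {
    sino <- subsample_projections(sino, config$subsample)
    M <- subsample_model_matrix(M, config$subsample)
    logf("subsampled to %d projections", config$subsample)
  }
  if (config$noise_level > 0) {
    sino <- add_projection_noise(sino, config$noise_level, config$noise_seed)
    logf("added Gaussian noise, level %.3g x max|p|", config$noise_level)
  }
  write_image(phantom, file.path(out, "phantom.tsv"))
  write_sinogram(sino, file.path(out, "sinogram.tsv"))

  rows <- list()
  add_row <- function(method, params, res, fname) {
    write_image(res$image, file.path(out, fname))
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, params = params,
      mad = image_mad(phantom, res$image),
      rel_l2 = rel_l2_error(phantom, res$image),
      file = fname, stringsAsFactors = FALSE)
    logf("%s [%s]: MAD %.6g", method, params, rows[[length(rows)]]$mad)
  }
  if ("lsqr" %in% config$methods) {
    res <- reconstruct_lsqr(M, sino, n_iter = config$lsqr_iters)
    add_row("lsqr", sprintf("iters=%d", config$lsqr_iters), res, "recon_lsqr.tsv")
  }
  if ("tikhonov" %in% config$methods) {
    res <- reconstruct_tikhonov(M, sino, lam = config$tikhonov_lam,
                                n_iter = config$lsqr_iters)
    add_row("tikhonov", sprintf("lam=%g", config$tikhonov_lam), res,
            "recon_tikhonov.tsv")
  }
  if ("tvl1" %in% config$methods) {
    for (i in seq_len(nrow(config$tvl1_grid))) {
      g <- config$tvl1_grid[i, ]
      res <- reconstruct_tv_l1(M, sino, mu = g$mu, alpha = g$alpha,
                               n_iter = config$tvl1_iters, seed = config$seed)
      add_row("tvl1", sprintf("mu=%g,alpha=%g", g$mu, g$alpha), res,
              sprintf("recon_tvl1_%02d.tsv", i))
    }
  }
  if ("a2tv" %in% config$methods) {
    for (i in seq_len(nrow(config$a2tv_grid))) {
      g <- config$a2tv_grid[i, ]
      sc <- solver_config("a2tv", lam = g$lam, k = g$k, sigma = config$sigma,
                          rho = config$rho, n_iter = config$a2tv_iters,
                          n_outer = config$a2tv_outer, seed = config$seed)
      res <- reconstruct_a2tv(M, sino, sc)
      add_row("a2tv", sprintf("lam=%g,k=%g", g$lam, g$k), res,
              sprintf("recon_a2tv_%02d.tsv", i))
    }
  }
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  cfg_echo <- config
  cfg_echo$phantom_params <- unclass(cfg_echo$phantom_params)
  cfg_echo$tvl1_grid <- as.list(cfg_echo$tvl1_grid)
  cfg_echo$a2tv_grid <- as.list(cfg_echo$a2tv_grid)
  jsonlite::write_json(unclass(cfg_echo), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("wrote %d reconstructions to %s", nrow(metrics), out)
  structure(invisible(out), metrics = metrics)
}

# drop the sinogram rows of removed detectors from the model matrix
subsample_model_matrix <- function(M, n_keep) {
  geom <- subsample_projections(M$geometry, n_keep)
  nt <- M$time$nt
  n <- M$geometry$n_detectors
  idx <- 1L + floor((seq_len(n_keep) - 1L) * n / n_keep)
  keep_rows <- as.vector(outer(seq_len(nt), (idx - 1L) * nt, "+"))
  M$matrix <- M$matrix[keep_rows, , drop = FALSE]
  M$geometry <- geom
  M
}

build_cached_matrix <- function(grid, geom, spp, cache_dir, logf = message) {
  if (is.null(cache_dir)) {
    M <- build_model_matrix(grid, geom, samples_per_pixel = spp)
    return(normalize_model_matrix(M))
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(grid$nx, grid$ny, sprintf("%.8g", grid$pixel_size),
               sprintf("%.8g", grid$origin[1]), sprintf("%.8g", grid$origin[2]),
               sprintf("%.8g", geom$radius), sprintf("%.8g", geom$coverage_deg),
               geom$n_detectors, spp, sep = "_")
  path <- file.path(cache_dir, paste0("matrix_", key, ".mtx"))
  if (file.exists(path) && file.exists(meta_path(path))) {
    logf("loading cached model matrix: %s", path)
    return(load_matrix(path))
  }
  M <- normalize_model_matrix(build_model_matrix(grid, geom,
                                                 samples_per_pixel = spp))
  save_matrix(M, path)
  logf("built and cached model matrix: %s", path)
  M
}
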