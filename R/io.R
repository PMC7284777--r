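#' Read a grayscale image file
#'
#' Reads TIFF or PNG into an [image_grid()]. Multi-channel images are
#' averaged to one channel.
#'
#' @param path file path (`.tif`, `.tiff`, `.png`).
#' @param pixel_size um per pixel (image files do not carry it reliably).
#' @return an [image_grid()].
#' @export
read_image_file <- function(path, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  image_grid(a, pixel_size)
}

#' Write an image to TIFF
#'
#' Intensities are rescaled to \[0, 1\] (16-bit storage).
#'
#' @param img an [image_grid()] or matrix.
#' @param path output path (`.tif`/`.tiff`).
#' @export
write_image_file <- function(img, path) {
  m <- as_intensity_matrix(img)
  rng <- range(m)
  m01 <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  tiff::writeTIFF(m01, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a release curve from CSV
#'
#' Expects columns `time_h` and `conc_uM` (hours, micromolar).
#'
#' @param path CSV path.
#' @param c_load,substrate optional metadata (see [release_curve()]).
#' @return a [release_curve()].
#' @export
read_release_curve_csv <- function(path, c_load = NA_real_,
                                   substrate = NA_character_) {
  df <- read.csv(path)
  if (!all(c("time_h", "conc_uM") %in% names(df)))
    stop("CSV must contain columns time_h and conc_uM: ", path)
  release_curve(df$time_h, df$conc_uM, c_load = c_load, substrate = substrate)
}

#' Write a release curve to CSV
#' @param curve a [release_curve()].
#' @param path output path.
#' @export
write_release_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  write.csv(curve$data, path, row.names = FALSE)
  invisible(path)
}

#' Write detected nodes to CSV
#'
#' Columns: `node_id`, `row`, `col`, `x_um`, `y_um`, `occupancy` (0-based
#' physical origin at the image top-left corner).
#'
#' @param node_set a [detect_nodes()] result.
#' @param path output path.
#' @export
write_node_set_csv <- function(node_set, path) {
  stopifnot(inherits(node_set, "node_set"))
  write.csv(node_set$nodes, path, row.names = FALSE)
  invisible(path)
}

#' Write a spectral map to CSV
#'
#' First column `wavenumber_cm-1`, then one column per pixel (`px1`,
#' `px2`, ... in column-major grid order).
#'
#' @param map a [spectral_map()].
#' @param path output path.
#' @export
write_spectral_map_csv <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  df <- data.frame(wavenumber_cm.1 = map$wavenumbers, t(map$spectra))
  names(df) <- c("wavenumber_cm-1", paste0("px", seq_len(nrow(map$spectra))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral map from CSV
#'
#' Inverse of [write_spectral_map_csv()].
#'
#' @param path CSV path.
#' @param grid_shape c(rows, cols); defaults to a single column of pixels.
#' @param stepsize spatial step, um.
#' @return a [spectral_map()].
#' @export
read_spectral_map_csv <- function(path, grid_shape = NULL, stepsize = 0.5) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm-1")
    stop("first column must be wavenumber_cm-1: ", path)
  wn <- df[[1]]
  spectra <- t(as.matrix(df[, -1, drop = FALSE]))
  if (is.null(grid_shape)) grid_shape <- c(nrow(spectra), 1L)
  spectral_map(wn, unname(spectra), grid_shape, stepsize)
}

#' Write graph metrics (and full provenance) to JSON
#'
#' @param metrics a `graph_metrics` from [analyze_image()].
#' @param path output path.
#' @export
write_graph_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "graph_metrics"))
  payload <- list(
    N = metrics$N, edges = metrics$m, Cc = metrics$Cc, Cpl = metrics$Cpl,
    Cc_rand = metrics$Cc_rand, Cc_rand_sd = metrics$Cc_rand_sd,
    Cpl_rand = metrics$Cpl_rand, Cpl_rand_sd = metrics$Cpl_rand_sd,
    SW = metrics$SW, null_reps = metrics$null_reps, seed = metrics$seed,
    segmentation = unclass(metrics$seg_params),
    waxman = unclass(metrics$waxman_params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a cell graph's adjacency matrix in Matrix Market format
#'
#' @param g a `cell_graph` from [build_graph()].
#' @param path output `.mtx` path.
#' @export
write_adjacency_mtx <- function(g, path) {
  stopifnot(inherits(g, "cell_graph"))
  A <- Matrix::Matrix(adjacency(g), sparse = TRUE)
  Matrix::writeMM(A, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Validates top-level keys against the schema used by [run_pipeline()] and
#' fails naming any unknown key.
#'
#' @param path YAML path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

run_config_keys <- c("seed", "out_dir", "stages", "nuclei", "release",
                     "sers", "surface", "porous", "verbose")

#' Validate a pipeline configuration list
#' @param cfg named list (see [run_pipeline()]).
#' @return the validated list, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration must set an explicit `seed`")
  if (is.null(cfg$out_dir)) stop("configuration must set `out_dir`")
  if (is.null(cfg$stages))
    cfg$stages <- c("nuclei_network", "release", "sers", "surface", "porous")
  structure(cfg, class = "run_config")
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates synthetic inputs for the selected stages, runs the
#' corresponding analyses, writes their outputs (CSV/JSON) under
#' `cfg$out_dir`, and returns a consolidated run report. A provenance JSON
#' with the full configuration and seed is written alongside the outputs;
#' rerunning with the same configuration reproduces the numbers exactly.
#'
#' @param cfg a `run_config` (list with `seed`, `out_dir`, optional
#'   `stages` subset of `c("nuclei_network", "release", "sers", "surface",
#'   "porous")`, and per-stage parameter overrides).
#' @return list of per-stage results, invisibly classed `run_report`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  report <- list(seed = seed, stages = list())

  if ("nuclei_network" %in% cfg$stages) {
    np <- do.call(nuclei_layout_params,
                  c(list(seed = seed), cfg$nuclei))
    sim <- simulate_nuclei_image(np)
    gm <- analyze_image(sim$image, seed = seed + 1L)
    write_node_set_csv(gm$node_set, file.path(cfg$out_dir, "nodes.csv"))
    write_graph_metrics_json(gm, file.path(cfg$out_dir, "graph_metrics.json"))
    report$stages$nuclei_network <- list(
      N_planted = nrow(sim$positions), N = gm$N, Cc = gm$Cc,
      Cpl = gm$Cpl, SW = gm$SW)
  }

  if ("release" %in% cfg$stages) {
    rp <- cfg$release
    model <- release_model_params(
      c0 = 0,
      cs = if (is.null(rp$cs)) 4.94 else rp$cs,
      tau = if (is.null(rp$tau)) 46 else rp$tau)
    times <- seq(0, 240, by = 8)
    curve <- simulate_release_curve(model, times,
                                    noise_sd = 0.05 * model$cs,
                                    seed = seed + 2L, c_load = 30)
    write_release_curve_csv(curve, file.path(cfg$out_dir, "release_curve.csv"))
    fit <- fit_release(curve)
    res <- list(cs = fit$params$cs, tau = fit$params$tau,
                v = initial_velocity(fit$params),
                asymptotic_efficiency = release_efficiency(fit$params, 30)$asymptotic)
    jsonlite::write_json(res, file.path(cfg$out_dir, "release_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$release <- res
  }

  if ("sers" %in% cfg$stages) {
    map <- simulate_sers_map(seed = seed + 3L)
    norm <- area_normalize(map)
    pca <- fit_pca(norm)
    k_truth <- length(unique(as.vector(map$classes)))
    labels <- cluster_pixels(pca, k = k_truth, seed = seed + 4L)
    r <- loading_ratio(pca)
    write_spectral_map_csv(map, file.path(cfg$out_dir, "sers_map.csv"))
    res <- list(
      explained_variance_5pc = sum(pca$explained_variance_fraction),
      r_int = r$r_int,
      rand_index_vs_truth = rand_index(labels, as.vector(map$classes)))
    jsonlite::write_json(res, file.path(cfg$out_dir, "sers_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$sers <- res
  }

  if ("surface" %in% cfg$stages) {
    sp <- do.call(surface_synthesis_params,
                  c(list(seed = seed + 5L), cfg$surface))
    surf <- simulate_fractal_surface(sp)
    psd <- power_spectrum(surf)
    fd <- fractal_dimension(psd)
    write.csv(psd$bins, file.path(cfg$out_dir, "psd.csv"), row.names = FALSE)
    res <- list(Ra_nm = psd$Ra, Df = fd$Df, slope = fd$slope,
                r_squared = fd$r_squared)
    jsonlite::write_json(res, file.path(cfg$out_dir, "surface_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$surface <- res
  }

  if ("porous" %in% cfg$stages) {
    pp <- cfg$porous
    target <- if (is.null(pp$target_P)) 0.12 else pp$target_P
    img <- simulate_porous_image(target, seed = seed + 6L)
    sizes <- feature_size_stats(as_intensity_matrix(img))
    res <- list(porosity = porosity(img), target_P = target,
                mean_pore_diameter_px = sizes$mean_diameter,
                n_pores = sizes$n_features)
    jsonlite::write_json(res, file.path(cfg$out_dir, "porosity_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$porous <- res
  }

  provenance <- list(
    package = "theranosim",
    version = as.character(utils::packageVersion("theranosim")),
    seed = seed, config = unclass(cfg), timestamp = NA)
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(structure(report, class = "run_report"))
}

#' Two-group comparison report
#'
#' Thin reporting utility: a two-tailed unpaired Welch t-test on two metric
#' vectors (e.g. per-image N or Cc for two substrates). Standard
#' statistics, provided for convenience when tabulating results.
#'
#' @param x,y numeric vectors of per-replicate metric values.
#' @param labels length-2 character labels for the groups.
#' @return one-row data.frame: group means, difference, `t`, `df`,
#'   `p_value`, `significant` at 0.05.
#' @export
compare_groups <- function(x, y, labels = c("group1", "group2")) {
  ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  data.frame(
    group1 = labels[1], group2 = labels[2],
    mean1 = mean(x), mean2 = mean(y), difference = mean(x) - mean(y),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, significant = ht$p.value < 0.05
  )
}
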