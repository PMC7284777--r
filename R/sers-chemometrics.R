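#' Hyperspectral SERS map container
#'
#' Wavenumber-indexed spectra on a spatial grid. Pixels are stored in
#' column-major grid order (first all rows of column 1, then column 2, ...),
#' matching R's matrix vectorisation, so `matrix(v, grid_shape[1])` renders
#' any per-pixel vector `v` back onto the grid.
#'
#' @param wavenumbers strictly increasing axis, cm-1.
#' @param spectra numeric matrix, pixels x wavenumbers.
#' @param grid_shape c(rows, cols); `rows * cols` must equal `nrow(spectra)`.
#' @param stepsize spatial step between pixels, um.
#' @return a list of class `spectral_map`.
#' @export
spectral_map <- function(wavenumbers, spectra, grid_shape, stepsize = 0.5) {
  if (any(diff(wavenumbers) <= 0)) stop("`wavenumbers` must be strictly increasing")
  if (!is.matrix(spectra)) stop("`spectra` must be a matrix (pixels x wavenumbers)")
  if (ncol(spectra) != length(wavenumbers))
    stop("ncol(spectra) must equal length(wavenumbers)")
  if (prod(grid_shape) != nrow(spectra))
    stop("grid_shape does not match the number of pixels")
  structure(
    list(wavenumbers = as.numeric(wavenumbers), spectra = spectra,
         grid_shape = as.integer(grid_shape), stepsize = stepsize),
    class = "spectral_map"
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf(
    "<spectral_map> %d x %d pixels (%.2g um step), %d wavenumbers [%g, %g] cm-1\n",
    x$grid_shape[1], x$grid_shape[2], x$stepsize, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)
  ))
  invisible(x)
}

#' Normalise spectra to unit total area
#'
#' Divides each pixel spectrum by its trapezoidal integral over the
#' wavenumber axis, the standard pre-processing step that suppresses
#' pixel-to-pixel differences in fluorescence background and collection
#' efficiency. Spectra with non-positive area cannot be normalised; they
#' are excluded and recorded in the `excluded` attribute.
#'
#' @param map a [spectral_map()] object.
#' @return the normalised `spectral_map`; every retained spectrum
#'   integrates to 1. Attribute `excluded` lists dropped pixel indices (the
#'   grid shape is kept only when nothing was dropped).
#' @export
area_normalize <- function(map) {
  stopifnot(inherits(map, "spectral_map"))
  areas <- apply(map$spectra, 1, function(s) pracma::trapz(map$wavenumbers, s))
  bad <- which(!is.finite(areas) | areas <= 0)
  if (length(bad) > 0) {
    warning(sprintf("%d spectra with non-positive area excluded from normalization",
                    length(bad)))
    keep <- setdiff(seq_len(nrow(map$spectra)), bad)
    out <- structure(
      list(wavenumbers = map$wavenumbers,
           spectra = map$spectra[keep, , drop = FALSE] / areas[keep],
           grid_shape = c(length(keep), 1L), stepsize = map$stepsize),
      class = "spectral_map"
    )
    attr(out, "excluded") <- bad
    return(out)
  }
  out <- map
  out$spectra <- map$spectra / areas
  attr(out, "excluded") <- integer(0)
  out
}

#' Principal component analysis of a spectral map
#'
#' Mean-centred PCA of the pixel x wavenumber matrix. The sign of each
#' component is fixed deterministically: the loading element of largest
#' magnitude is made positive, so repeated runs and duplicated data give
#' identical models.
#'
#' @param map a [spectral_map()] object.
#' @param n_components number of components to retain (default 5).
#' @return an object of class `pca_model`: `loadings` (component x
#'   wavenumber), `scores` (pixel x component),
#'   `explained_variance_fraction` for the retained components,
#'   `all_variance_fractions` for every component, `wavenumbers`,
#'   `n_components`.
#' @export
fit_pca <- function(map, n_components = 5) {
  stopifnot(inherits(map, "spectral_map"))
  n_px <- nrow(map$spectra)
  if (n_px < n_components)
    stop("fewer pixels than requested components")
  pc <- prcomp(map$spectra, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- t(pc$rotation[, seq_len(k), drop = FALSE])   # component x wavenumber
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[j, ]))
    if (load[j, i_max] < 0) {
      load[j, ] <- -load[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(loadings = load, scores = scores,
         explained_variance_fraction = vf[seq_len(k)],
         all_variance_fractions = vf,
         center = pc$center, wavenumbers = map$wavenumbers,
         n_components = k),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d wavenumbers\n",
              x$n_components, ncol(x$loadings)))
  cat(sprintf("  explained variance: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", "),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Cluster map pixels on their component scores
#'
#' k-means on the retained principal-component scores, keeping the best of
#' `n_restarts` random initialisations by within-cluster sum of squares.
#' The paper-style default partitions a cell map into five chemometric
#' classes.
#'
#' @param scores pixel x component score matrix (or a `pca_model`).
#' @param k number of classes (default 5).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @param grid_shape optional c(rows, cols) to render labels as a matrix.
#' @return integer vector of class labels (1..k), or a matrix when
#'   `grid_shape` is given. Attribute `tot_withinss` carries the objective.
#' @export
cluster_pixels <- function(scores, k = 5, seed = NULL, n_restarts = 10,
                           grid_shape = NULL) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (nrow(scores) < k) stop("fewer pixels than classes")
  n_distinct <- nrow(unique(scores))
  if (n_distinct < k) {
    warning(sprintf(
      "only %d distinct score vectors for k = %d: returning %d effective classes",
      n_distinct, k, n_distinct))
    k <- n_distinct
  }
  labels <- if (k == 1L) {
    rep(1L, nrow(scores))
  } else {
    km <- with_seed_if(seed, kmeans(scores, centers = k, nstart = n_restarts,
                                    iter.max = 100))
    out <- km$cluster
    attr(out, "tot_withinss") <- km$tot.withinss
    out
  }
  if (!is.null(grid_shape)) {
    tw <- attr(labels, "tot_withinss")
    labels <- matrix(as.integer(labels), grid_shape[1], grid_shape[2])
    attr(labels, "tot_withinss") <- tw
  }
  labels
}

#' Integrin loading-ratio statistic
#'
#' The ratio between the loading intensity of a principal component at a
#' target band and its mean loading intensity over the full spectral
#' range: \eqn{r = \max |l(\nu)|_{\nu \in target \pm w} / \overline{|l|}}.
#' Applied to the 1569 cm-1 tryptophan band of the first component, r >> 1
#' indicates that this integrin-associated band dominates the spectral
#' variation. Absolute values make r invariant to the arbitrary loading
#' sign; the max-in-window is robust to axis discretisation.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param component_index which component's loading to use (default 1).
#' @param target target band position, cm-1 (default 1569).
#' @param window_halfwidth half-width of the search window, cm-1.
#' @return list of class `integrin_ratio`: `r_int`, `target_wavenumber`,
#'   `window_halfwidth`, `component_index`.
#' @export
loading_ratio <- function(model, component_index = 1, target = 1569,
                          window_halfwidth = 5) {
  stopifnot(inherits(model, "pca_model"))
  wn <- model$wavenumbers
  if (target < min(wn) || target > max(wn))
    stop("`target` lies outside the wavenumber axis")
  sel <- abs(wn - target) <= window_halfwidth
  if (!any(sel)) stop("window excludes every axis point; widen `window_halfwidth`")
  l <- abs(model$loadings[component_index, ])
  structure(
    list(r_int = max(l[sel]) / mean(l),
         target_wavenumber = target, window_halfwidth = window_halfwidth,
         component_index = component_index),
    class = "integrin_ratio"
  )
}

#' @export
print.integrin_ratio <- function(x, ...) {
  cat(sprintf("<integrin_ratio> r = %.3f at %g cm-1 (+/- %g, PC%d)\n",
              x$r_int, x$target_wavenumber, x$window_halfwidth,
              x$component_index))
  invisible(x)
}

#' Band-intensity image of a spectral map
#'
#' Per-pixel maximum spectral intensity within a window around the target
#' band, rendered on the spatial grid — the raw-intensity analogue of an
#' integrin distribution map.
#'
#' @param map a [spectral_map()] object.
#' @param target band position, cm-1 (default 1569).
#' @param window_halfwidth half-width, cm-1.
#' @return matrix `grid_shape` of band intensities.
#' @export
band_intensity_map <- function(map, target = 1569, window_halfwidth = 5) {
  stopifnot(inherits(map, "spectral_map"))
  wn <- map$wavenumbers
  if (target < min(wn) || target > max(wn))
    stop("`target` lies outside the wavenumber axis")
  sel <- abs(wn - target) <= window_halfwidth
  if (!any(sel)) stop("window excludes every axis point; widen `window_halfwidth`")
  v <- apply(map$spectra[, sel, drop = FALSE], 1, max)
  matrix(v, map$grid_shape[1], map$grid_shape[2])
}
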