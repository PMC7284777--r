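#' Raster image container
#'
#' Minimal container coupling a 2-D intensity raster with its physical pixel
#' size. Used for fluorescence micrographs (intensities in arbitrary units)
#' and for binary micrograph-like images (0/1).
#'
#' @param intensities numeric matrix, row-major raster, origin top-left.
#' @param pixel_size physical size of one pixel edge, micrometres.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(intensities, pixel_size) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(intensities = intensities, pixel_size = as.numeric(pixel_size)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<image_grid> %d x %d px, %.4g um/px (%.4g x %.4g um)\n",
    d[1], d[2], x$pixel_size, d[2] * x$pixel_size, d[1] * x$pixel_size
  ))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$intensities)

as_intensity_matrix <- function(img) {
  if (inherits(img, "image_grid")) img$intensities else img
}

# Run expr with a fixed RNG state when seed is given; leave the caller's
# RNG untouched either way.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %g", name, lower))
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

#' Remove the best-fit plane from a height map
#'
#' Least-squares linear detrend: fits `h ~ row + col` and subtracts the
#' fitted plane. Used before roughness and spectral estimates so that tilt
#' does not masquerade as long-wavelength power.
#'
#' @param h numeric matrix of heights.
#' @return matrix of residual heights (mean zero).
#' @export
detrend_plane <- function(h) {
  if (!is.matrix(h) || !is.numeric(h)) stop("`h` must be a numeric matrix")
  nr <- nrow(h)
  nc <- ncol(h)
  r <- rep(seq_len(nr), times = nc)
  c_ <- rep(seq_len(nc), each = nr)
  X <- cbind(1, r - mean(r), c_ - mean(c_))
  beta <- qr.coef(qr(X), as.vector(h))
  matrix(as.vector(h) - X %*% beta, nr, nc)
}

#' Rand index between two partitions
#'
#' Fraction of point pairs on which two labelings agree (both together or
#' both apart). Label-permutation invariant; 1 means identical partitions.
#' Used to score recovery of planted classes by the clustering stages.
#'
#' @param a,b label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_sq <- function(x) sum(x * (x - 1) / 2)
  n_pairs <- n * (n - 1) / 2
  s_both <- sum_sq(tab)
  s_a <- sum_sq(rowSums(tab))
  s_b <- sum_sq(colSums(tab))
  agree <- n_pairs + 2 * s_both - s_a - s_b
  agree / n_pairs
}
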