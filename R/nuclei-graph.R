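#' Parameters for nuclei segmentation and occupancy downsampling
#'
#' Controls the image-to-nodes stage: the intensity field is partitioned
#' into `k` classes by 1-D k-means, the `t` classes on the background side
#' are zeroed, the binary result is averaged over non-overlapping `r` x `r`
#' blocks (`r^2` approximating the area of one nucleus in pixels), and grid
#' cells whose occupancy probability exceeds `p_thresh` become nodes.
#'
#' @param k number of intensity classes (>= 2).
#' @param t number of background classes removed (1 <= t < k). With
#'   `invert = FALSE` the `t` darkest classes are background.
#' @param r downsampling block size in pixels (>= 1). The default, `NULL`,
#'   lets [analyze_image()] derive it from the expected nucleus diameter.
#' @param p_thresh occupancy probability threshold in (0, 1]. The default
#'   0.48 was calibrated once on synthetic images with planted ground truth
#'   to balance block-merge losses (clustered layouts) against block-split
#'   gains (isolated nuclei straddling block boundaries).
#' @param invert if `TRUE`, bright classes are treated as background (for
#'   images with dark objects on a bright field). Default `FALSE`: DAPI
#'   nuclei are bright on a dark background.
#' @param smooth_sd Gaussian pre-filter standard deviation in pixels
#'   (low-pass denoising before segmentation); 0 disables.
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(k = 3, t = 1, r = 6, p_thresh = 0.48,
                                invert = FALSE, smooth_sd = 1) {
  stopifnot_scalar_number(k, "k", lower = 2)
  stopifnot_scalar_number(t, "t", lower = 1, upper = k - 1)
  if (!is.null(r)) stopifnot_scalar_number(r, "r", lower = 1)
  stopifnot_scalar_number(p_thresh, "p_thresh", lower = 0, upper = 1,
                          strict_lower = TRUE)
  stopifnot_scalar_number(smooth_sd, "smooth_sd", lower = 0)
  structure(
    list(k = as.integer(k), t = as.integer(t),
         r = if (is.null(r)) NULL else as.integer(r),
         p_thresh = p_thresh, invert = isTRUE(invert), smooth_sd = smooth_sd),
    class = "segmentation_params"
  )
}

# deterministic 1-D k-means: quantile-seeded Lloyd iterations on the unique
# intensity values, weighted by their multiplicity
kmeans_1d <- function(x, k) {
  ux <- sort(unique(x))
  w <- tabulate(match(x, ux))
  centers <- unname(quantile(ux, probs = (seq_len(k) - 0.5) / k, type = 7))
  centers <- sort(unique(centers))
  for (it in seq_len(100)) {
    # assign each unique value to nearest centre (boundaries midway)
    bounds <- (head(centers, -1) + centers[-1]) / 2
    assign <- findInterval(ux, bounds) + 1L
    new_centers <- vapply(seq_along(centers), function(j) {
      sel <- assign == j
      if (any(sel)) sum(ux[sel] * w[sel]) / sum(w[sel]) else centers[j]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- sort(new_centers)
  }
  bounds <- (head(centers, -1) + centers[-1]) / 2
  list(centers = centers, class_of = findInterval(x, bounds) + 1L)
}

#' Segment a fluorescence image into a nuclei mask
#'
#' Pipeline: Gaussian low-pass filter, contrast stretch to \[0, 1\], 1-D
#' k-means partition of pixel intensities into `k` classes ranked from dark
#' to bright, removal of the `t` background classes (darkest by default),
#' remaining classes set to 1.
#'
#' @param img an [image_grid()] or numeric matrix.
#' @param params a [segmentation_params()] object.
#' @return binary matrix (1 = nucleus/foreground). A constant image yields
#'   an all-zero mask with a warning; `k` larger than the number of distinct
#'   intensities is reduced with a warning.
#' @export
segment_image <- function(img, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  m <- as_intensity_matrix(img)
  if (length(m) == 0) stop("empty image")

  if (params$smooth_sd > 0) {
    m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                           sigma = params$smooth_sd))
  }
  rng <- range(m)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant image: returning all-zero mask")
    return(matrix(0, nrow(m), ncol(m)))
  }
  m <- (m - rng[1]) / (rng[2] - rng[1])

  k <- params$k
  n_distinct <- length(unique(as.vector(m)))
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds %d distinct intensities; using k = %d",
                    k, n_distinct, n_distinct))
    k <- n_distinct
  }
  t_bg <- min(params$t, k - 1L)
  km <- kmeans_1d(as.vector(m), k)
  cls <- matrix(km$class_of, nrow(m), ncol(m))  # 1 = darkest ... k = brightest
  fg <- if (params$invert) cls <= (k - t_bg) else cls > t_bg
  mask <- matrix(0, nrow(m), ncol(m))
  mask[fg] <- 1
  mask
}

#' Downsample a binary mask into an occupancy grid
#'
#' Averages the mask over non-overlapping `r` x `r` blocks (stride `r`).
#' Trailing partial blocks at the right/bottom edges are averaged over their
#' actual pixel count, so the block-size-weighted mean of the occupancy grid
#' equals the foreground fraction of the mask exactly.
#'
#' @param mask binary matrix.
#' @param r block edge in pixels (>= 1).
#' @return matrix of occupancy probabilities in \[0, 1\], dimensions
#'   `ceiling(dim(mask) / r)`.
#' @export
downsample_occupancy <- function(mask, r) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  stopifnot_scalar_number(r, "r", lower = 1)
  r <- as.integer(r)
  gr <- (seq_len(nrow(mask)) - 1L) %/% r + 1L
  gc <- (seq_len(ncol(mask)) - 1L) %/% r + 1L
  sums <- rowsum(t(rowsum(mask, gr)), gc)          # col-block x row-block sums
  counts <- tcrossprod(tabulate(gc), tabulate(gr)) # matching pixel counts
  out <- t(sums / counts)
  dimnames(out) <- NULL
  out
}

#' Detect cell nodes from an occupancy grid
#'
#' Every grid cell whose occupancy probability exceeds `p_thresh` becomes a
#' node; its physical position is the centre of the corresponding pixel
#' block in micrometres (origin at the image's top-left corner, x rightward
#' along columns, y downward along rows).
#'
#' @param occupancy occupancy matrix from [downsample_occupancy()].
#' @param p_thresh probability threshold in (0, 1].
#' @param pixel_size um per original image pixel.
#' @param r block size used for the downsampling, pixels.
#' @param image_dim optional c(rows, cols) of the source image, used to
#'   truncate edge-block centres; defaults to `dim(occupancy) * r`.
#' @return an object of class `node_set`: list with `nodes` (data.frame
#'   `node_id`, `row`, `col`, `x_um`, `y_um`, `occupancy`), the `occupancy`
#'   grid, and the detection metadata.
#' @export
detect_nodes <- function(occupancy, p_thresh = 0.48, pixel_size = 1.72, r = 6,
                         image_dim = NULL) {
  if (!is.matrix(occupancy)) stop("`occupancy` must be a matrix")
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy values must lie in [0, 1]")
  stopifnot_scalar_number(p_thresh, "p_thresh", lower = 0, upper = 1)
  r <- as.integer(r)
  if (is.null(image_dim)) image_dim <- dim(occupancy) * r

  hit <- which(occupancy > p_thresh, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    # block b covers pixels (b-1)*r + 1 .. min(b*r, n); centre in um uses the
    # convention that pixel i spans [(i-1), i] * pixel_size
    row_lo <- (hit[, 1] - 1L) * r
    row_hi <- pmin(hit[, 1] * r, image_dim[1])
    col_lo <- (hit[, 2] - 1L) * r
    col_hi <- pmin(hit[, 2] * r, image_dim[2])
    nodes <- data.frame(
      node_id = seq_len(nrow(hit)),
      row = unname(hit[, 1]), col = unname(hit[, 2]),
      x_um = (col_lo + col_hi) / 2 * pixel_size,
      y_um = (row_lo + row_hi) / 2 * pixel_size,
      occupancy = occupancy[hit]
    )
  } else {
    nodes <- data.frame(node_id = integer(0), row = integer(0), col = integer(0),
                        x_um = numeric(0), y_um = numeric(0), occupancy = numeric(0))
  }
  structure(
    list(nodes = nodes, occupancy = occupancy,
         p_thresh = p_thresh, pixel_size = pixel_size, r = r,
         field_um = c(width = image_dim[2] * pixel_size,
                      height = image_dim[1] * pixel_size)),
    class = "node_set"
  )
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf(
    "<node_set> N = %d nodes on a %d x %d occupancy grid (r = %d px, p > %.2f)\n",
    nrow(x$nodes), nrow(x$occupancy), ncol(x$occupancy), x$r, x$p_thresh
  ))
  invisible(x)
}
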