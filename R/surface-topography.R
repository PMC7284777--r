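#' Surface height map container
#'
#' @param heights numeric matrix of heights, nm.
#' @param extent physical extent c(width, height), um (a scalar is recycled).
#' @return a list of class `surface_field`.
#' @export
surface_field <- function(heights, extent = c(1, 1)) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix")
  if (any(!is.finite(heights))) stop("`heights` must be finite")
  if (length(extent) == 1) extent <- c(extent, extent)
  if (any(extent <= 0)) stop("`extent` must be positive")
  structure(list(heights = heights, extent = as.numeric(extent)),
            class = "surface_field")
}

#' @export
print.surface_field <- function(x, ...) {
  cat(sprintf("<surface_field> %d x %d px over %.3g x %.3g um (Ra = %.3g nm)\n",
              nrow(x$heights), ncol(x$heights), x$extent[1], x$extent[2],
              roughness_Ra(x)))
  invisible(x)
}

#' Arithmetic average roughness Ra
#'
#' Mean absolute deviation of the heights from their mean plane, the plane
#' being the least-squares linear trend (so sample tilt does not inflate
#' roughness).
#'
#' @param surface a [surface_field()] object or a numeric matrix (nm).
#' @return Ra, nm.
#' @export
roughness_Ra <- function(surface) {
  h <- if (inherits(surface, "surface_field")) surface$heights else surface
  if (length(h) == 0) stop("empty surface")
  d <- detrend_plane(h)
  mean(abs(d - mean(d)))
}

#' Radially averaged power spectral density of a surface
#'
#' Linear detrend, optional Hann window, 2-D periodogram, and radial
#' averaging of the spectral power into logarithmically spaced frequency
#' bins. The periodogram is normalised so that (without a window, or after
#' the window-power correction in expectation) the total 2-D power equals
#' the variance of the detrended heights. Non-square inputs are zero-padded
#' to square with a warning before the transform.
#'
#' @param surface a [surface_field()] object.
#' @param window `"hann"` (default) or `"none"`.
#' @param n_bins number of logarithmic radial bins.
#' @return object of class `psd_result`: data.frame `bins` (`freq_um`,
#'   cycles/um; `power`; `n_modes`, Fourier modes averaged into the bin),
#'   `total_power` (sum of the 2-D periodogram),
#'   `height_variance` (of the detrended heights), `Ra` (nm), `window`,
#'   `freq_max`.
#' @export
power_spectrum <- function(surface, window = c("hann", "none"), n_bins = 26) {
  stopifnot(inherits(surface, "surface_field"))
  window <- match.arg(window)
  h <- surface$heights
  if (min(dim(h)) < 16) stop("grid must be at least 16 x 16")

  d <- detrend_plane(h)
  d <- d - mean(d)
  height_variance <- mean(d^2)
  if (nrow(d) != ncol(d)) {
    warning("non-square height map: zero-padding to square")
    n <- max(dim(d))
    pad <- matrix(0, n, n)
    pad[seq_len(nrow(d)), seq_len(ncol(d))] <- d
    d <- pad
  }
  n <- nrow(d)
  extent <- max(surface$extent)

  if (window == "hann") {
    w1 <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
    w <- outer(w1, w1)
    x <- d * w
    norm <- mean(w^2)
  } else {
    x <- d
    norm <- 1
  }
  P <- Mod(fft(x))^2 / (as.numeric(n)^4 * norm)

  k <- c(0:(n / 2), -((n / 2 - 1):1))
  if (length(k) != n) k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  q <- sqrt(outer(k^2, k^2, `+`)) / extent   # cycles per um
  q_min <- 1 / extent
  q_max <- (n / 2) / extent
  edges <- exp(seq(log(q_min * 0.999), log(q_max * 1.001), length.out = n_bins + 1))
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  ok <- q > 0 & bin >= 1 & bin <= n_bins
  pw <- tapply(P[ok], bin[ok], mean)
  fq <- tapply(q[ok], bin[ok], mean)
  nm <- tapply(P[ok], bin[ok], length)
  bins <- data.frame(freq_um = as.numeric(fq), power = as.numeric(pw),
                     n_modes = as.integer(nm))
  bins <- bins[is.finite(bins$power) & bins$power > 0, ]

  structure(
    list(bins = bins, total_power = sum(P), height_variance = height_variance,
         Ra = roughness_Ra(surface), window = window, freq_max = q_max),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d radial bins up to %.3g cycles/um; Ra = %.3g nm\n",
    nrow(x$bins), x$freq_max, x$Ra))
  invisible(x)
}

#' Fractal dimension from the power spectrum
#'
#' Fits the log-log slope of the radially averaged power over the
#' scale-free band and converts it with the self-affine convention for
#' isotropic surfaces, \eqn{P(q) \propto q^{-(8 - 2 D_f)}}, i.e.
#' \eqn{D_f = (8 - \beta)/2} where \eqn{-\beta} is the fitted slope. The
#' result is clamped to the geometric range \[2, 3\]. The default fit band
#' excludes the two lowest-frequency bins (detrending leakage) and the top
#' octave (discretisation noise floor).
#'
#' @param psd a `psd_result` from [power_spectrum()].
#' @param fit_band optional c(min, max) frequency range, cycles/um.
#' @return list of class `fractal_fit`: `Df`, `slope` (= -beta),
#'   `r_squared`, `low_confidence` (TRUE when R^2 < 0.8), `fit_band`,
#'   `n_bins_used`.
#' @export
fractal_dimension <- function(psd, fit_band = NULL) {
  stopifnot(inherits(psd, "psd_result"))
  b <- psd$bins
  if (is.null(fit_band)) {
    lo <- if (nrow(b) > 4) b$freq_um[3] else min(b$freq_um)
    hi <- psd$freq_max / 2
    fit_band <- c(lo, hi)
  }
  sel <- b$freq_um >= fit_band[1] & b$freq_um <= fit_band[2]
  if (sum(sel) < 5) stop("fewer than 5 PSD bins in the fit band")
  # weight bins by the number of Fourier modes they average: the sampling
  # variance of a periodogram bin scales as 1/n_modes
  w <- if ("n_modes" %in% names(b)) b$n_modes[sel] else rep(1, sum(sel))
  fit <- lm(log10(power) ~ log10(freq_um), data = b[sel, ], weights = w)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  beta <- -slope
  Df <- (8 - beta) / 2
  structure(
    list(Df = min(3, max(2, Df)), Df_unclamped = Df, slope = slope,
         r_squared = r2, low_confidence = r2 < 0.8,
         fit_band = fit_band, n_bins_used = sum(sel)),
    class = "fractal_fit"
  )
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf(
    "<fractal_fit> Df = %.3f (slope %.3f, R^2 = %.3f%s) over %d bins\n",
    x$Df, x$slope, x$r_squared,
    if (x$low_confidence) ", LOW CONFIDENCE" else "", x$n_bins_used))
  invisible(x)
}

#' Porosity of a binary image
#'
#' Fraction of void over total: void pixel count divided by total pixel
#' count, with void coded as 1.
#'
#' @param binary an [image_grid()] or matrix with values in \{0, 1\}.
#' @return void fraction in \[0, 1\].
#' @export
porosity <- function(binary) {
  m <- as_intensity_matrix(binary)
  if (!all(m %in% c(0, 1)))
    stop("input is not binary; threshold it first with segment_pores()")
  mean(m)
}

#' Threshold a grayscale micrograph into void and solid
#'
#' Automatic global threshold by Otsu's criterion; the dark phase is taken
#' as void by default (pores image darker than the solid matrix in SEM).
#'
#' @param img an [image_grid()] or numeric matrix.
#' @param invert if `TRUE` the bright phase is void.
#' @return binary matrix (void = 1).
#' @export
segment_pores <- function(img, invert = FALSE) {
  m <- as_intensity_matrix(img)
  rng <- range(m)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2])))
    stop("constant image: no threshold exists")
  m01 <- (m - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(m01), range = c(0, 1))
  mask <- if (invert) (m01 > thr) else (m01 < thr)
  mask * 1
}

#' Size statistics of connected features
#'
#' Labels connected components (8-connectivity) of a binary mask, converts
#' each component's area to an equivalent-circle diameter
#' \eqn{2\sqrt{A/\pi}}, and summarises. Components touching the image
#' border are excluded to avoid truncation bias; note that touching
#' features merge into one component under 8-connectivity.
#'
#' @param mask binary matrix (feature = 1).
#' @param pixel_size physical pixel edge, nm.
#' @return list of class `feature_sizes`: `mean_diameter`, `sd_diameter`
#'   (nm; `NA` when no feature), `n_features`, `diameters`.
#' @export
feature_size_stats <- function(mask, pixel_size = 1) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary")
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- setdiff(border_labels, 0)
  keep <- setdiff(seq_len(max(lab)), border_labels)
  if (length(keep) == 0) {
    return(structure(
      list(mean_diameter = NA_real_, sd_diameter = NA_real_,
           n_features = 0L, diameters = numeric(0)),
      class = "feature_sizes"
    ))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))[keep]
  diam <- 2 * sqrt(areas / pi) * pixel_size
  structure(
    list(mean_diameter = mean(diam),
         sd_diameter = if (length(diam) > 1) sd(diam) else 0,
         n_features = length(diam), diameters = diam),
    class = "feature_sizes"
  )
}

#' @export
print.feature_sizes <- function(x, ...) {
  if (x$n_features == 0) {
    cat("<feature_sizes> no interior features\n")
  } else {
    cat(sprintf("<feature_sizes> %d features, diameter %.3g +/- %.3g nm\n",
                x$n_features, x$mean_diameter, x$sd_diameter))
  }
  invisible(x)
}
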