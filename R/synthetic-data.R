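#' Parameters for synthetic nuclei-image generation
#'
#' Describes a simulated field of DAPI-stained nuclei. The defaults mirror a
#' typical confocal acquisition of MCF-7 cultures on a silicon chip: a
#' 1174 x 882 um region of interest sampled at 1.72 um/px, a few hundred
#' cells, and ~10 um nuclei rendered as Gaussian blobs.
#'
#' @param n_cells number of nuclei to plant (>= 0).
#' @param layout `"uniform"` (homogeneous Poisson-like, positions i.i.d.
#'   uniform) or `"clustered"` (Thomas process: uniform parent centres with
#'   isotropic Gaussian offspring displacements).
#' @param n_parents number of cluster parents (clustered layout only).
#' @param cluster_sd standard deviation of offspring displacement, um.
#' @param field_width,field_height field of view, um.
#' @param pixel_size um per pixel.
#' @param nucleus_radius Gaussian blob standard deviation, um. 3 um gives an
#'   apparent nucleus of roughly 10 um across, typical for MCF-7.
#' @param blob_amplitude peak intensity of one nucleus above background.
#' @param background constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed; the same seed reproduces the image bit for bit.
#' @return a list of class `nuclei_layout_params`.
#' @export
nuclei_layout_params <- function(n_cells = 200,
                                 layout = c("clustered", "uniform"),
                                 n_parents = 10,
                                 cluster_sd = 40,
                                 field_width = 1174,
                                 field_height = 882,
                                 pixel_size = 1.72,
                                 nucleus_radius = 3,
                                 blob_amplitude = 1,
                                 background = 0.1,
                                 noise_sd = 0.02,
                                 seed = NULL) {
  layout <- match.arg(layout)
  stopifnot_scalar_number(n_cells, "n_cells", lower = 0)
  stopifnot_scalar_number(field_width, "field_width", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(field_height, "field_height", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(nucleus_radius, "nucleus_radius", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (layout == "clustered") {
    stopifnot_scalar_number(n_parents, "n_parents", lower = 1)
    stopifnot_scalar_number(cluster_sd, "cluster_sd", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells), layout = layout,
      n_parents = as.integer(n_parents), cluster_sd = cluster_sd,
      field_width = field_width, field_height = field_height,
      pixel_size = pixel_size, nucleus_radius = nucleus_radius,
      blob_amplitude = blob_amplitude, background = background,
      noise_sd = noise_sd, seed = seed
    ),
    class = "nuclei_layout_params"
  )
}

#' Simulate a fluorescence image of stained nuclei
#'
#' Draws cell positions (uniform, or a Thomas cluster process with toroidal
#' wrapping so the point density is stationary up to the field edge), renders
#' each nucleus as an isotropic Gaussian blob on a constant background, and
#' adds Gaussian noise. The planted positions are returned alongside the
#' image so downstream node detection can be scored against ground truth.
#'
#' @param params a [nuclei_layout_params()] object.
#' @return list with `image` (an [image_grid()]), and `positions`
#'   (data.frame `x_um`, `y_um`; origin top-left, x rightward, y downward).
#' @export
simulate_nuclei_image <- function(params) {
  stopifnot(inherits(params, "nuclei_layout_params"))
  p <- params
  nx <- max(1L, round(p$field_width / p$pixel_size))
  ny <- max(1L, round(p$field_height / p$pixel_size))

  with_seed_if(p$seed, {
    if (p$n_cells == 0L) {
      pos <- data.frame(x_um = numeric(0), y_um = numeric(0))
    } else if (p$layout == "uniform") {
      pos <- data.frame(
        x_um = runif(p$n_cells, 0, p$field_width),
        y_um = runif(p$n_cells, 0, p$field_height)
      )
    } else {
      px <- runif(p$n_parents, 0, p$field_width)
      py <- runif(p$n_parents, 0, p$field_height)
      parent <- sample.int(p$n_parents, p$n_cells, replace = TRUE)
      x <- px[parent] + rnorm(p$n_cells, 0, p$cluster_sd)
      y <- py[parent] + rnorm(p$n_cells, 0, p$cluster_sd)
      pos <- data.frame(
        x_um = x %% p$field_width,
        y_um = y %% p$field_height
      )
    }

    img <- matrix(p$background, nrow = ny, ncol = nx)
    if (nrow(pos) > 0) {
      sd_px <- p$nucleus_radius / p$pixel_size
      half <- ceiling(4 * sd_px)
      for (i in seq_len(nrow(pos))) {
        # pixel centre of pixel (r, c), 1-based, is ((c-0.5), (r-0.5)) * pixel_size
        cc <- pos$x_um[i] / p$pixel_size + 0.5
        rc <- pos$y_um[i] / p$pixel_size + 0.5
        r0 <- max(1L, floor(rc - half))
        r1 <- min(ny, ceiling(rc + half))
        c0 <- max(1L, floor(cc - half))
        c1 <- min(nx, ceiling(cc + half))
        if (r0 > r1 || c0 > c1) next
        gr <- exp(-((r0:r1 - rc)^2) / (2 * sd_px^2))
        gc <- exp(-((c0:c1 - cc)^2) / (2 * sd_px^2))
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + p$blob_amplitude * outer(gr, gc)
      }
    }
    if (p$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, p$noise_sd), ny, nx)

    list(image = image_grid(img, p$pixel_size), positions = pos)
  })
}

#' Simulate a first-order drug-release curve
#'
#' Evaluates \eqn{c(t) = c_0 + c_s (1 - e^{-t/\tau})} at the requested times
#' and adds Gaussian measurement noise, emulating UV-spectroscopy monitoring
#' of cumulative drug release into water.
#'
#' @param model a [release_model_params()] object (c0, cs in uM, tau in h).
#' @param times sampling times, hours (non-negative).
#' @param noise_sd measurement noise standard deviation, uM (0 = noiseless).
#' @param seed integer seed.
#' @param c_load loading concentration, uM, carried as metadata.
#' @param substrate label carried as metadata.
#' @return a [release_curve()] object.
#' @export
simulate_release_curve <- function(model, times, noise_sd = 0, seed = NULL,
                                   c_load = NA_real_, substrate = NA_character_) {
  stopifnot(inherits(model, "release_model_params"))
  if (any(times < 0)) stop("`times` must be non-negative")
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  conc <- first_order_model(times, model)
  if (noise_sd > 0)
    conc <- with_seed_if(seed, conc + rnorm(length(times), 0, noise_sd))
  release_curve(times, pmax(conc, 0), c_load = c_load, substrate = substrate)
}

#' Reference peak table for synthetic SERS spectra
#'
#' Band positions follow the fingerprint frequencies typical of cell Raman
#' spectra (1126, 1175, 1306, 1506, 1645 cm-1) plus the 1569 cm-1 tryptophan
#' band used as an integrin marker. Class 1 pixels carry the fingerprint
#' bands only ("baseline cell" pixels); class 2 pixels additionally carry a
#' strong 1569 cm-1 band ("adhesion" pixels).
#'
#' @param adhesion_height peak height of the 1569 cm-1 band in class 2.
#' @param fingerprint_height common height of the fingerprint bands.
#' @return data.frame with columns `class`, `center_cm1`, `height`,
#'   `fwhm_cm1`, `shape`.
#' @export
sers_peak_table <- function(adhesion_height = 1.0, fingerprint_height = 0.3) {
  fp <- c(1126, 1175, 1306, 1506, 1645)
  rbind(
    data.frame(class = 1L, center_cm1 = fp, height = fingerprint_height,
               fwhm_cm1 = 18, shape = "gauss"),
    data.frame(class = 2L, center_cm1 = fp, height = fingerprint_height,
               fwhm_cm1 = 18, shape = "gauss"),
    data.frame(class = 2L, center_cm1 = 1569, height = adhesion_height,
               fwhm_cm1 = 14, shape = "lorentz")
  )
}

peak_profile <- function(wn, center, height, fwhm, shape) {
  if (shape == "lorentz") {
    g <- fwhm / 2
    height * g^2 / ((wn - center)^2 + g^2)
  } else {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    height * exp(-(wn - center)^2 / (2 * s^2))
  }
}

#' Simulate a SERS hyperspectral map
#'
#' Each pixel's spectrum is a smooth fluorescence-like baseline plus the peak
#' set of its planted class plus Gaussian noise, emulating a Raman map
#' acquired on a 0.5 um grid over a cell. Class labels are returned as
#' ground truth for scoring the chemometric pipeline.
#'
#' @param grid_shape c(rows, cols) of the spatial grid.
#' @param wavenumbers strictly increasing axis, cm-1 (default 700-3250).
#' @param class_layout integer matrix `grid_shape` of planted class labels;
#'   default splits the grid into a left half (class 1) and right half
#'   (class 2).
#' @param peak_table data.frame as returned by [sers_peak_table()].
#' @param baseline_scale amplitude of the fluorescence baseline.
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed.
#' @param stepsize spatial step, um.
#' @return a [spectral_map()] with a `classes` ground-truth matrix attached.
#' @export
simulate_sers_map <- function(grid_shape = c(16, 16),
                              wavenumbers = seq(700, 3250, by = 3),
                              class_layout = NULL,
                              peak_table = sers_peak_table(),
                              baseline_scale = 1,
                              noise_sd = 0.01,
                              seed = NULL,
                              stepsize = 0.5) {
  if (any(diff(wavenumbers) <= 0)) stop("`wavenumbers` must be strictly increasing")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (is.null(class_layout)) {
    class_layout <- matrix(1L, nr, nc)
    class_layout[, seq_len(nc) > nc / 2] <- 2L
  }
  if (!all(dim(class_layout) == grid_shape)) stop("`class_layout` does not match `grid_shape`")
  if (nrow(peak_table) > 0 &&
      (any(peak_table$center_cm1 < min(wavenumbers)) ||
       any(peak_table$center_cm1 > max(wavenumbers))))
    stop("peak centre outside the wavenumber axis")

  # broad fluorescence hump; identical in every pixel
  baseline <- baseline_scale * (0.4 + exp(-(wavenumbers - 1400)^2 / (2 * 800^2)))

  classes <- sort(unique(as.vector(class_layout)))
  class_spec <- lapply(classes, function(cl) {
    s <- baseline
    pk <- peak_table[peak_table$class == cl, , drop = FALSE]
    for (i in seq_len(nrow(pk)))
      s <- s + peak_profile(wavenumbers, pk$center_cm1[i], pk$height[i],
                            pk$fwhm_cm1[i], pk$shape[i])
    s
  })
  names(class_spec) <- as.character(classes)

  n_px <- nr * nc
  spectra <- matrix(0, n_px, length(wavenumbers))
  lab <- as.vector(class_layout)  # column-major pixel order
  for (i in seq_len(n_px)) spectra[i, ] <- class_spec[[as.character(lab[i])]]
  if (noise_sd > 0)
    spectra <- with_seed_if(seed,
      spectra + matrix(rnorm(length(spectra), 0, noise_sd), n_px))

  m <- spectral_map(wavenumbers, spectra, grid_shape = c(nr, nc), stepsize = stepsize)
  m$classes <- class_layout
  m
}

#' Parameters for self-affine surface synthesis
#'
#' @param target_Df target fractal dimension, in \[2, 3\].
#' @param target_Ra target arithmetic roughness, nm.
#' @param grid_n grid side length; must be a power of two (spectral synthesis).
#' @param extent physical side length, um.
#' @param seed integer seed.
#' @return a list of class `surface_synthesis_params`.
#' @export
surface_synthesis_params <- function(target_Df = 2.48, target_Ra = 7,
                                     grid_n = 512, extent = 1, seed = NULL) {
  stopifnot_scalar_number(target_Df, "target_Df", lower = 2, upper = 3)
  stopifnot_scalar_number(target_Ra, "target_Ra", lower = 0)
  stopifnot_scalar_number(extent, "extent", lower = 0, strict_lower = TRUE)
  if (grid_n < 2 || bitwAnd(as.integer(grid_n), as.integer(grid_n) - 1L) != 0L)
    stop("`grid_n` must be a power of two")
  structure(
    list(target_Df = target_Df, target_Ra = target_Ra,
         grid_n = as.integer(grid_n), extent = extent, seed = seed),
    class = "surface_synthesis_params"
  )
}

#' Simulate a self-affine fractal surface
#'
#' Spectral synthesis: a white Gaussian field is filtered in Fourier space
#' with amplitude proportional to \eqn{q^{-\beta/2}} where
#' \eqn{\beta = 8 - 2 D_f}, giving an isotropic power spectrum
#' \eqn{P(q) \propto q^{-(8-2D_f)}}. Heights are then rescaled so the
#' measured arithmetic roughness equals `target_Ra` exactly.
#'
#' @param params a [surface_synthesis_params()] object.
#' @return a [surface_field()] (heights in nm).
#' @export
simulate_fractal_surface <- function(params) {
  stopifnot(inherits(params, "surface_synthesis_params"))
  n <- params$grid_n
  beta <- 8 - 2 * params$target_Df

  h <- with_seed_if(params$seed, {
    eta <- matrix(rnorm(n * n), n, n)
    k <- c(0:(n / 2), -((n / 2 - 1):1))  # cycles per grid length
    q <- sqrt(outer(k^2, k^2, `+`))
    filt <- ifelse(q > 0, q^(-beta / 2), 0)
    Re(fft(fft(eta) * filt, inverse = TRUE)) / (n * n)
  })
  h <- h - mean(h)
  ra <- roughness_Ra(h)   # detrended, same definition the estimator uses
  if (ra > 0) h <- h * (params$target_Ra / ra)
  surface_field(h, extent = c(params$extent, params$extent))
}

#' Simulate a binary porous micrograph
#'
#' Stamps randomly placed circular voids (value 1) into a solid image
#' (value 0) until the void fraction reaches the target within 0.5%,
#' emulating an SEM image of a porous film for the porosity estimator.
#'
#' @param target_P target void fraction in \[0, 1\].
#' @param pore_radius_px pore radius in pixels (> 0).
#' @param image_shape c(rows, cols).
#' @param seed integer seed.
#' @return an [image_grid()] with binary intensities (void = 1) and
#'   `pixel_size = 1` (pixel units).
#' @export
simulate_porous_image <- function(target_P, pore_radius_px = 5,
                                  image_shape = c(512, 512), seed = NULL) {
  stopifnot_scalar_number(target_P, "target_P", lower = 0, upper = 1)
  stopifnot_scalar_number(pore_radius_px, "pore_radius_px", lower = 0,
                          strict_lower = TRUE)
  nr <- image_shape[1]; nc <- image_shape[2]
  mask <- matrix(0, nr, nc)
  if (target_P >= 1) return(image_grid(matrix(1, nr, nc), 1))
  if (target_P > 0) {
    r <- pore_radius_px
    off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
    off <- off[off$dr^2 + off$dc^2 <= r^2, ]
    mask <- with_seed_if(seed, {
      n_void <- 0L
      target_n <- target_P * nr * nc
      while (n_void < target_n - 0.005 * nr * nc) {
        cr <- sample.int(nr, 1L)
        cc <- sample.int(nc, 1L)
        rr <- cr + off$dr; ccol <- cc + off$dc
        keep <- rr >= 1 & rr <= nr & ccol >= 1 & ccol <= nc
        idx <- cbind(rr[keep], ccol[keep])
        new <- idx[mask[idx] == 0, , drop = FALSE]
        mask[new] <- 1
        n_void <- n_void + nrow(new)
      }
      mask
    })
  }
  image_grid(mask, 1)
}
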