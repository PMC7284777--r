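test_that("area normalisation has its closed forms and invariances", {
  wn <- seq(700, 3250, by = 5)
  span <- max(wn) - min(wn)
  const <- spectral_map(wn, matrix(3.7, 2, length(wn)), c(2, 1))
  norm <- area_normalize(const)
  expect_equal(unique(as.vector(norm$spectra)), 1 / span, tolerance = 1e-12)

  withr::with_seed(2, {
    sp <- matrix(runif(5 * length(wn), 0.1, 2), 5)
    m1 <- spectral_map(wn, sp, c(5, 1))
    m7 <- spectral_map(wn, 7 * sp, c(5, 1))
    expect_equal(area_normalize(m1)$spectra, area_normalize(m7)$spectra)

    # post-call integrals are exactly one; normalisation is idempotent
    n1 <- area_normalize(m1)
    ints <- apply(n1$spectra, 1, function(s) pracma::trapz(wn, s))
    expect_true(all(abs(ints - 1) < 1e-9))
    expect_equal(area_normalize(n1)$spectra, n1$spectra, tolerance = 1e-12)
  })

  # zero-area spectra are excluded with a warning
  bad <- spectral_map(wn, rbind(rep(1, length(wn)), rep(0, length(wn))), c(2, 1))
  expect_warning(nb <- area_normalize(bad), "excluded")
  expect_equal(nrow(nb$spectra), 1)
  expect_equal(attr(nb, "excluded"), 2L)
})

test_that("PCA identifies planted low-rank structure deterministically", {
  wn <- seq(700, 3250, by = 5)
  base1 <- exp(-(wn - 1200)^2 / (2 * 300^2))
  base2 <- exp(-(wn - 2500)^2 / (2 * 200^2))
  withr::with_seed(4, {
    mix <- runif(40)
    sp <- outer(mix, base1) + outer(1 - mix, base2) +
      matrix(rnorm(40 * length(wn), 0, 1e-4), 40)
  })
  m <- spectral_map(wn, sp, c(40, 1))
  pca <- fit_pca(m, n_components = 5)
  # two distinct generating spectra -> rank-1 centered data dominates
  expect_gt(sum(pca$all_variance_fractions[1:2]), 0.99)
  expect_equal(sum(pca$all_variance_fractions), 1, tolerance = 1e-9)
  # explained fractions non-increasing
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  # loadings unit norm, deterministic sign convention
  expect_equal(unname(rowSums(pca$loadings^2)), rep(1, 5), tolerance = 1e-9)
  pca2 <- fit_pca(m, n_components = 5)
  expect_identical(pca$loadings, pca2$loadings)
  for (j in 1:5) {
    expect_gt(pca$loadings[j, which.max(abs(pca$loadings[j, ]))], 0)
  }
  expect_error(fit_pca(spectral_map(wn, sp[1:3, ], c(3, 1)), 5), "fewer pixels")
})

test_that("PCA reconstruction with all components reproduces the data", {
  wn <- seq(800, 1800, by = 10)
  withr::with_seed(9, sp <- matrix(runif(12 * length(wn)), 12))
  m <- spectral_map(wn, sp, c(12, 1))
  pca <- fit_pca(m, n_components = 12)
  centered <- sweep(sp, 2, pca$center)
  recon <- pca$scores %*% pca$loadings
  expect_lt(sqrt(mean((recon - centered)^2)), 1e-9)
})

test_that("score clustering recovers planted partitions", {
  withr::with_seed(3, {
    blob1 <- matrix(rnorm(30 * 2, mean = 0, sd = 0.1), 30)
    blob2 <- matrix(rnorm(30 * 2, mean = 5, sd = 0.1), 30)
  })
  scores <- rbind(blob1, blob2)
  labels <- cluster_pixels(scores, k = 2, seed = 1)
  truth <- rep(1:2, each = 30)
  expect_equal(rand_index(labels, truth), 1)
  expect_identical(cluster_pixels(scores, k = 2, seed = 1),
                   cluster_pixels(scores, k = 2, seed = 1))
  # degenerate input: identical scores collapse to one class with a warning
  expect_warning(one <- cluster_pixels(matrix(1, 10, 2), k = 3), "distinct")
  expect_true(all(one == 1L))
})

test_that("full chemometric pipeline separates planted spectral classes", {
  ri <- vapply(1:5, function(s) {
    m <- simulate_sers_map(seed = s)
    pca <- fit_pca(area_normalize(m))
    labels <- cluster_pixels(pca, k = 2, seed = s + 100)
    rand_index(labels, as.vector(m$classes))
  }, numeric(1))
  expect_true(all(ri > 0.9))
})

test_that("loading ratio has its closed forms and invariances", {
  wn <- seq(700, 3250, by = 5)
  n <- length(wn)
  flat <- structure(
    list(loadings = matrix(1 / sqrt(n), 1, n), scores = matrix(0, 5, 1),
         explained_variance_fraction = 1, all_variance_fractions = 1,
         center = rep(0, n), wavenumbers = wn, n_components = 1L),
    class = "pca_model")
  expect_equal(loading_ratio(flat)$r_int, 1)

  onehot <- flat
  onehot$loadings <- matrix(0, 1, n)
  onehot$loadings[1, which.min(abs(wn - 1569))] <- 1
  expect_equal(loading_ratio(onehot)$r_int, n)  # max / mean of a one-hot

  # sign and scale invariance
  neg <- onehot
  neg$loadings <- -3 * onehot$loadings
  expect_equal(loading_ratio(neg)$r_int, loading_ratio(onehot)$r_int)

  expect_error(loading_ratio(flat, target = 500), "outside")
  expect_error(loading_ratio(flat, window_halfwidth = 0.1), "window")
})

test_that("planted 1569 band dominates the first component loading", {
  m <- simulate_sers_map(seed = 6)
  pca <- fit_pca(area_normalize(m))
  expect_gt(loading_ratio(pca, component_index = 1)$r_int, 2)
})

test_that("band intensity maps localise the planted band", {
  m <- simulate_sers_map(grid_shape = c(8, 8), noise_sd = 0, seed = 2)
  bm <- band_intensity_map(m)
  in2 <- m$classes == 2L
  expect_gt(mean(bm[in2]), mean(bm[!in2]))

  # window covering the whole axis gives the per-pixel global maximum
  whole <- band_intensity_map(m, target = 1569, window_halfwidth = 1e4)
  expect_equal(as.vector(whole), apply(m$spectra, 1, max))

  zero <- spectral_map(m$wavenumbers,
                       matrix(0, 4, length(m$wavenumbers)), c(2, 2))
  expect_true(all(band_intensity_map(zero) == 0))
})
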