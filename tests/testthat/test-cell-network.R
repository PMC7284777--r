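test_that("Waxman cutoff matches its closed form and monotonicity", {
  p <- waxman_params(alpha = 1, beta = 0.025, R = 0.1, L = 100)
  expect_equal(waxman_cutoff(p), 2.5 * log(10))

  # cutoff shrinks to 0 as R approaches alpha
  expect_lt(waxman_cutoff(waxman_params(alpha = 1, beta = 0.025,
                                        R = 1 - 1e-9, L = 100)), 1e-6)
  # strictly increasing in beta and L
  expect_gt(waxman_cutoff(waxman_params(beta = 0.05, L = 100)),
            waxman_cutoff(waxman_params(beta = 0.025, L = 100)))
  expect_gt(waxman_cutoff(waxman_params(beta = 0.025, L = 200)),
            waxman_cutoff(waxman_params(beta = 0.025, L = 100)))
  expect_error(waxman_params(alpha = 0.5, R = 0.6, L = 10), "smaller")
})

test_that("graph construction is exact distance thresholding", {
  p <- waxman_params(L = 100)
  dstar <- waxman_cutoff(p)
  near <- data.frame(x_um = c(0, 0.5 * dstar), y_um = c(0, 0))
  far <- data.frame(x_um = c(0, 2 * dstar), y_um = c(0, 0))
  expect_equal(sum(adjacency(build_graph(near, p))), 2)
  expect_equal(sum(adjacency(build_graph(far, p))), 0)

  # complete graph when all nodes mutually within d*
  tight <- data.frame(x_um = runif(10, 0, dstar / 2),
                      y_um = runif(10, 0, dstar / 2))
  g <- build_graph(tight, p)
  expect_equal(igraph::ecount(g$graph), 10 * 9 / 2)
})

test_that("adjacency equals the pairwise Waxman decision rule", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(2:25, 1)
      nodes <- data.frame(x_um = runif(n, 0, 50), y_um = runif(n, 0, 50))
      p <- waxman_params(alpha = 1, beta = 0.2, R = 0.3, L = 40)
      A <- adjacency(build_graph(nodes, p))
      # independent route: evaluate alpha*exp(-d/(beta L)) - R >= 0 per pair
      B <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j) next
          d <- sqrt((nodes$x_um[i] - nodes$x_um[j])^2 +
                    (nodes$y_um[i] - nodes$y_um[j])^2)
          if (p$alpha * exp(-d / (p$beta * p$L)) - p$R >= 0) B[i, j] <- 1
        }
      }
      expect_identical(unname(A), B)
    }
  })
})

test_that("clustering coefficient and path length match textbook cases", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  g <- cell_graph_from_adjacency(K5)
  expect_equal(clustering_coefficient(g), 1)
  expect_equal(characteristic_path_length(g), 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(cell_graph_from_adjacency(star)), 0)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(characteristic_path_length(cell_graph_from_adjacency(path3)),
               4 / 3)

  empty <- matrix(0, 4, 4)
  expect_equal(clustering_coefficient(cell_graph_from_adjacency(empty)), 0)
  expect_true(is.na(characteristic_path_length(cell_graph_from_adjacency(empty))))
})

test_that("metrics agree with brute-force oracles on small graphs", {
  withr::with_seed(5, {
    for (rep in 1:60) {
      n <- sample(2:8, 1)
      A <- random_adjacency(n, runif(1, 0.1, 0.9))
      g <- cell_graph_from_adjacency(A)
      expect_equal(clustering_coefficient(g), brute_clustering(A))
      cpl <- characteristic_path_length(g)
      oracle <- brute_path_length(A)
      if (is.na(oracle)) expect_true(is.na(cpl)) else expect_equal(cpl, oracle)
    }
  })
})

test_that("ER null reproduces the analytic clustering expectation", {
  null <- er_null_metrics(100, 500, reps = 50, seed = 3)
  p_edge <- 2 * 500 / (100 * 99)
  # ensemble mean Cc of G(n,m) concentrates on the edge density
  expect_lt(abs(null$Cc_rand - p_edge), 3 * null$Cc_rand_sd / sqrt(50) + 0.01)

  # m = max: every realisation complete
  full <- er_null_metrics(6, 15, reps = 5, seed = 1)
  expect_equal(full$Cc_rand, 1)
  expect_equal(full$Cpl_rand, 1)

  none <- er_null_metrics(6, 0, reps = 5, seed = 1)
  expect_equal(none$Cc_rand, 0)
  expect_true(is.na(none$Cpl_rand))

  expect_identical(er_null_metrics(30, 60, reps = 10, seed = 7),
                   er_null_metrics(30, 60, reps = 10, seed = 7))
})

test_that("small-world-ness algebra and guards", {
  expect_equal(small_world_ness(0.5, 0.5, 2, 2), 1)
  expect_equal(small_world_ness(0.74, 0.37, 2.43, 1.215), 1)
  expect_true(is.na(small_world_ness(0.5, 0, 2, 2)))
  expect_true(is.na(small_world_ness(0.5, 0.2, NA, 2)))
})

test_that("an ER graph scored against its own ensemble has SW near 1", {
  g <- withr::with_seed(7, igraph::sample_gnm(100, 500))
  null <- er_null_metrics(100, 500, reps = 50, seed = 11)
  SW <- small_world_ness(clustering_coefficient(g), null$Cc_rand,
                         characteristic_path_length(g), null$Cpl_rand)
  sd_prop <- SW * sqrt((null$Cc_rand_sd / null$Cc_rand)^2 +
                       (null$Cpl_rand_sd / null$Cpl_rand)^2)
  expect_lt(abs(SW - 1), 3 * sd_prop)
})

test_that("image analysis pipeline composes and is deterministic", {
  blank <- image_grid(matrix(0.5, 60, 60), 1.72)
  suppressWarnings(gm <- analyze_image(blank, seed = 1))
  expect_equal(gm$N, 0)
  expect_true(is.na(gm$SW))

  sim <- simulate_nuclei_image(nuclei_layout_params(n_cells = 120, seed = 3))
  a <- analyze_image(sim$image, seed = 5)
  b <- analyze_image(sim$image, seed = 5)
  expect_equal(a$N, b$N)
  expect_equal(a$SW, b$SW)
  expect_equal(a$Cc_rand, b$Cc_rand)
  expect_gt(a$N, 0)
  expect_true(a$Cc >= 0 && a$Cc <= 1)
  expect_gte(a$Cpl, 1)
})
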