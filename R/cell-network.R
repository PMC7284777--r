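#' Waxman connection-rule parameters
#'
#' In the Waxman model the probability that two nodes are connected decays
#' exponentially with their Euclidean distance,
#' \eqn{P(u,v) = \alpha e^{-d_{u,v} / (\beta L)}}, where `L` is the largest
#' possible distance between two nodes of the grid. Applying the decision
#' rule \eqn{\alpha e^{-d/(\beta L)} - R \ge 0} with a fixed constant `R`
#' makes connectivity deterministic: nodes are linked exactly when their
#' distance is below the cutoff returned by [waxman_cutoff()].
#'
#' @param alpha,beta Waxman parameters in (0, 1].
#' @param R acceptance constant in (0, alpha).
#' @param L largest possible Euclidean distance between grid nodes, um
#'   (typically the field diagonal).
#' @return a list of class `waxman_params`.
#' @export
waxman_params <- function(alpha = 1, beta = 0.025, R = 0.1, L) {
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar_number(beta, "beta", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar_number(R, "R", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(L, "L", lower = 0, strict_lower = TRUE)
  if (R >= alpha) stop("`R` must be smaller than `alpha` (cutoff undefined otherwise)")
  structure(list(alpha = alpha, beta = beta, R = R, L = L),
            class = "waxman_params")
}

#' Distance cutoff implied by the Waxman decision rule
#'
#' Solves \eqn{\alpha e^{-d/(\beta L)} = R} for the distance at which the
#' connection rule switches off: \eqn{d^* = \beta L \ln(\alpha / R)}. Two
#' nodes are connected iff their distance is at most `d*`.
#'
#' @param params a [waxman_params()] object.
#' @return cutoff distance, um.
#' @export
waxman_cutoff <- function(params) {
  stopifnot(inherits(params, "waxman_params"))
  params$beta * params$L * log(params$alpha / params$R)
}

#' Build the Waxman cell graph on detected nodes
#'
#' Connects every pair of nodes whose Euclidean distance (um) does not
#' exceed the Waxman cutoff. The graph is undirected and simple: the
#' adjacency matrix is symmetric, binary, with a zero diagonal.
#'
#' @param nodes a [detect_nodes()] `node_set`, or a data.frame with columns
#'   `x_um`, `y_um`.
#' @param params a [waxman_params()] object. If `L` is omitted and `nodes`
#'   is a `node_set`, use [waxman_params_for_field()].
#' @return an object of class `cell_graph`: list with `graph` (igraph),
#'   `coords` (x_um, y_um), `cutoff_um`, and `params`.
#' @export
build_graph <- function(nodes, params) {
  stopifnot(inherits(params, "waxman_params"))
  coords <- if (inherits(nodes, "node_set")) nodes$nodes else nodes
  if (!all(c("x_um", "y_um") %in% names(coords)))
    stop("`nodes` must provide x_um and y_um coordinates")
  n <- nrow(coords)
  dstar <- waxman_cutoff(params)
  if (n > 1) {
    d <- as.matrix(dist(coords[, c("x_um", "y_um")]))
    A <- (d <= dstar) * 1
    diag(A) <- 0
  } else {
    A <- matrix(0, n, n)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(
    list(graph = g, coords = coords[, c("x_um", "y_um"), drop = FALSE],
         cutoff_um = dstar, params = params),
    class = "cell_graph"
  )
}

#' Default Waxman parameterisation for a rectangular field
#'
#' Sets `L` to the diagonal of the field of view — the largest possible
#' distance between two grid nodes — computed from the field extent rather
#' than from the realised node positions, so the rule is stable under sparse
#' detections.
#'
#' @param field_width,field_height field extent, um.
#' @param alpha,beta,R see [waxman_params()].
#' @return a [waxman_params()] object.
#' @export
waxman_params_for_field <- function(field_width, field_height,
                                    alpha = 1, beta = 0.025, R = 0.1) {
  waxman_params(alpha, beta, R, L = sqrt(field_width^2 + field_height^2))
}

#' Adjacency matrix of a cell graph
#' @param g a `cell_graph`.
#' @return dense symmetric binary matrix with zero diagonal.
#' @export
adjacency <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  as.matrix(igraph::as_adjacency_matrix(g$graph, sparse = TRUE))
}

as_igraph_input <- function(g) {
  if (inherits(g, "cell_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else stop("expected a `cell_graph` or an igraph object")
}

#' Average clustering coefficient
#'
#' Watts–Strogatz local clustering (realised links among a node's
#' neighbours over the possible \eqn{deg(deg-1)/2}), averaged over all
#' nodes; nodes of degree < 2 contribute 0.
#'
#' @param g a `cell_graph` or igraph object.
#' @return Cc in \[0, 1\]; 0 for an empty graph.
#' @export
clustering_coefficient <- function(g) {
  ig <- as_igraph_input(g)
  if (igraph::vcount(ig) == 0) return(0)
  cc <- igraph::transitivity(ig, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) 0 else cc
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all reachable node pairs (self-pairs
#' excluded). In a disconnected graph only pairs joined by some path enter
#' the mean; with no edges at all the quantity is undefined and `NA` is
#' returned.
#'
#' @param g a `cell_graph` or igraph object.
#' @return Cpl (>= 1 when any edge exists), or `NA_real_`.
#' @export
characteristic_path_length <- function(g) {
  ig <- as_igraph_input(g)
  if (igraph::ecount(ig) == 0) return(NA_real_)
  igraph::mean_distance(ig, directed = FALSE, unconnected = TRUE)
}

#' Erdős–Rényi null-model metrics
#'
#' Generates `reps` uniform G(n, m) graphs — the same number of nodes and
#' edges as the observed graph — and returns the ensemble mean and standard
#' deviation of the clustering coefficient and the characteristic path
#' length (each realisation's Cpl averaged over its reachable pairs).
#'
#' @param n node count.
#' @param m edge count (0 <= m <= n(n-1)/2).
#' @param reps ensemble size (>= 1).
#' @param seed integer seed.
#' @return list `Cc_rand`, `Cc_rand_sd`, `Cpl_rand`, `Cpl_rand_sd`, `reps`.
#' @export
er_null_metrics <- function(n, m, reps = 20, seed = NULL) {
  stopifnot_scalar_number(n, "n", lower = 0)
  stopifnot_scalar_number(m, "m", lower = 0, upper = n * (n - 1) / 2)
  stopifnot_scalar_number(reps, "reps", lower = 1)
  if (m == 0) {
    return(list(Cc_rand = 0, Cc_rand_sd = 0,
                Cpl_rand = NA_real_, Cpl_rand_sd = NA_real_, reps = reps))
  }
  res <- with_seed_if(seed, {
    vapply(seq_len(reps), function(i) {
      gi <- igraph::sample_gnm(n, m)
      c(clustering_coefficient(gi), characteristic_path_length(gi))
    }, numeric(2))
  })
  list(
    Cc_rand = mean(res[1, ]), Cc_rand_sd = sd(res[1, ]),
    Cpl_rand = mean(res[2, ], na.rm = TRUE), Cpl_rand_sd = sd(res[2, ], na.rm = TRUE),
    reps = as.integer(reps)
  )
}

#' Small-world-ness
#'
#' \eqn{SW = (Cc / Cc_{rand}) / (Cpl / Cpl_{rand})}: the trade-off between
#' high local clustering and short path length relative to an Erdős–Rényi
#' graph of equal size. SW > 1 indicates small-world organisation.
#'
#' @param Cc,Cpl observed clustering coefficient and path length.
#' @param Cc_rand,Cpl_rand null-model means from [er_null_metrics()].
#' @return SW, or `NA_real_` if any input is missing or non-positive.
#' @export
small_world_ness <- function(Cc, Cc_rand, Cpl, Cpl_rand) {
  vals <- c(Cc, Cc_rand, Cpl, Cpl_rand)
  if (any(!is.finite(vals)) || any(vals <= 0)) return(NA_real_)
  (Cc / Cc_rand) / (Cpl / Cpl_rand)
}

#' Full image-to-network analysis
#'
#' Composes the whole pipeline: segmentation, occupancy downsampling, node
#' detection, Waxman graph construction, topology metrics and the
#' Erdős–Rényi null comparison.
#'
#' @param img an [image_grid()] (fluorescence nuclei image).
#' @param seg_params a [segmentation_params()] object.
#' @param waxman a [waxman_params()] object, or `NULL` to derive `L` from
#'   the image field diagonal with the default alpha/beta/R.
#' @param reps null-model ensemble size.
#' @param seed integer seed for the null ensemble.
#' @return an object of class `graph_metrics`: list with `N`, `Cc`, `Cpl`,
#'   `Cc_rand`, `Cpl_rand` (means and sds), `SW`, `m` (edge count), the
#'   `cell_graph` and `node_set`, and all parameters.
#' @export
analyze_image <- function(img, seg_params = segmentation_params(),
                          waxman = NULL, reps = 20, seed = NULL) {
  stopifnot(inherits(img, "image_grid"))
  mask <- segment_image(img, seg_params)
  occ <- downsample_occupancy(mask, seg_params$r)
  ns <- detect_nodes(occ, seg_params$p_thresh, img$pixel_size, seg_params$r,
                     image_dim = dim(img$intensities))
  if (is.null(waxman)) {
    waxman <- waxman_params_for_field(ns$field_um[["width"]],
                                      ns$field_um[["height"]])
  }
  cg <- build_graph(ns, waxman)
  N <- nrow(ns$nodes)
  m <- igraph::ecount(cg$graph)
  Cc <- clustering_coefficient(cg)
  Cpl <- characteristic_path_length(cg)
  null <- er_null_metrics(N, m, reps = reps, seed = seed)
  SW <- small_world_ness(Cc, null$Cc_rand, Cpl, null$Cpl_rand)
  structure(
    list(N = N, m = m, Cc = Cc, Cpl = Cpl,
         Cc_rand = null$Cc_rand, Cc_rand_sd = null$Cc_rand_sd,
         Cpl_rand = null$Cpl_rand, Cpl_rand_sd = null$Cpl_rand_sd,
         SW = SW, null_reps = null$reps, seed = seed,
         graph = cg, node_set = ns,
         seg_params = seg_params, waxman_params = waxman),
    class = "graph_metrics"
  )
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat("<graph_metrics>\n")
  cat(sprintf("  N   = %d nodes, %d edges\n", x$N, x$m))
  cat(sprintf("  Cc  = %.4f  (ER null %.4f +/- %.4f)\n",
              x$Cc, x$Cc_rand, x$Cc_rand_sd))
  cat(sprintf("  Cpl = %.4f  (ER null %.4f +/- %.4f)\n",
              x$Cpl, x$Cpl_rand, x$Cpl_rand_sd))
  cat(sprintf("  SW  = %.4f\n", x$SW))
  invisible(x)
}
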