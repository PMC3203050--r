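## Geodesic geometry of a gridworld: all-pairs shortest-path distances on
## the state transition graph, capping of infinite (disconnected) pairs at
## their Euclidean distances, and a 2-D Sammon-stress MDS embedding whose
## Euclidean inter-point distances approximate the geodesic ones.

#' Euclidean cell-center coordinates
#'
#' The baseline coordinate set: cell centers at integer `(x, y)` positions.
#'
#' @param gw a `grid_world`.
#' @return A `coord_embedding`: list with `coords` (`M` x 2), `metric_tag`
#'   (`"euclidean"`), `stress` (0) and `seed` (`NA`).
#' @export
euclidean_coords <- function(gw) {
  co <- cell_xy(gw, seq_len(n_states(gw)))
  storage.mode(co) <- "double"
  new_embedding(co, "euclidean", stress = 0, seed = NA_integer_)
}

new_embedding <- function(coords, metric_tag, stress, seed) {
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, metric_tag = metric_tag,
                 stress = stress, seed = seed),
            class = "coord_embedding")
}

#' @export
print.coord_embedding <- function(x, ...) {
  cat(sprintf("<coord_embedding> %d states, metric '%s', stress %.3g\n",
              nrow(x$coords), x$metric_tag, x$stress))
  invisible(x)
}

#' All-pairs geodesic distances on the transition graph
#'
#' Shortest-path distance, measured as the number of edges (states stepped
#' through), between every pair of states; `Inf` where two states are in
#' different connected components.
#'
#' @param adjacency symmetric binary adjacency matrix with zero diagonal
#'   (see [adjacency_matrix()]).
#' @return A `geo_dist` object: list with `values` (`M` x `M` numeric) and
#'   `capped_mask` (logical `M` x `M`, all `FALSE` until
#'   [cap_disconnected()] is applied).
#' @export
geodesic_distances <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  D <- igraph::distances(g)
  dimnames(D) <- NULL
  structure(list(values = D,
                 capped_mask = matrix(FALSE, nrow(D), ncol(D))),
            class = "geo_dist")
}

#' Cap infinite distances at Euclidean distances
#'
#' When the transition graph has several connected components the geodesic
#' distance between components is infinite, which makes MDS inestimable.
#' Each infinite entry is replaced by the Euclidean distance between the two
#' cell centers; finite entries are untouched and `capped_mask` records the
#' replacements.
#'
#' @param D a `geo_dist` from [geodesic_distances()].
#' @param gw the `grid_world` the distances came from.
#' @return A `geo_dist` with finite `values` and updated `capped_mask`.
#' @export
cap_disconnected <- function(D, gw) {
  stopifnot(inherits(D, "geo_dist"))
  inf <- !is.finite(D$values)
  if (any(inf)) {
    E <- as.matrix(dist(cell_xy(gw, seq_len(n_states(gw)))))
    D$values[inf] <- E[inf]
    D$capped_mask <- D$capped_mask | inf
  }
  D
}

#' Sammon stress of a configuration
#'
#' `sum((d - delta)^2 / delta) / sum(delta)` over distinct pairs, where
#' `delta` are the target distances and `d` the configuration's Euclidean
#' distances.
#'
#' @param coords `M` x 2 coordinate matrix.
#' @param target `M` x `M` target distance matrix (finite, symmetric, zero
#'   diagonal).
#' @return Nonnegative scalar.
#' @export
sammon_stress <- function(coords, target) {
  d <- dist(coords)
  delta <- stats::as.dist(target)
  sum((d - delta)^2 / delta) / sum(delta)
}

#' Embed a geodesic distance matrix into 2-D coordinates
#'
#' Nonmetric (iterative) multidimensional scaling under Sammon's stress
#' criterion, started from the classical (Torgerson) scaling solution.  The
#' result is a set of `(x, y)` coordinates whose pairwise Euclidean
#' distances approximate the target geodesic distances.  Optionally the
#' configuration is rigidly aligned (translation, rotation, reflection and
#' one global scale factor -- none of which affect the relative geometry the
#' bases see) to a reference coordinate set so that basis parameters remain
#' comparable across metrics.
#'
#' @param D a `geo_dist` with finite values (apply [cap_disconnected()]
#'   first if the world is partitioned).
#' @param seed integer; only used to perturb degenerate starting
#'   configurations (duplicate or collinear classical-scaling solutions).
#' @param niter,tol iteration cap and relative stress-change tolerance of
#'   the descent.
#' @param ref_coords optional `M` x 2 matrix (e.g. `euclidean_coords(gw)$coords`)
#'   to Procrustes-align the embedding to.
#' @return A `coord_embedding` with `metric_tag = "geodesic"` and the final
#'   Sammon stress.
#' @export
embed_geodesic <- function(D, seed = 1L, niter = 500L, tol = 1e-6,
                           ref_coords = NULL) {
  stopifnot(inherits(D, "geo_dist"))
  V <- D$values
  if (!all(is.finite(V))) stop("distance matrix has non-finite entries; cap_disconnected() first")
  M <- nrow(V)
  dd <- stats::as.dist(V)
  init <- cmdscale(dd, k = 2)
  if (ncol(init) < 2) init <- cbind(init, 0)[, 1:2, drop = FALSE]
  # Sammon descent needs distinct starting points; perturb deterministically
  if (anyDuplicated(round(init, 10))) {
    init <- init + withr_seed_noise(M, seed)
  }
  fit <- MASS::sammon(dd, y = init, k = 2, niter = niter, tol = tol,
                      trace = FALSE)
  co <- fit$points
  s0 <- sammon_stress(init, V)
  if (fit$stress > s0 + 1e-12) {
    warning("Sammon descent did not improve on the classical-scaling start; returning the start")
    co <- init
    fit$stress <- s0
  }
  if (!is.null(ref_coords)) co <- procrustes_align(co, ref_coords)
  new_embedding(co, "geodesic", stress = fit$stress, seed = as.integer(seed))
}

# deterministic small jitter from a seed, without touching the global RNG
withr_seed_noise <- function(M, seed, sd = 1e-4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(2 * M, sd = sd), M, 2)
}

# rigid + single global scale alignment of coords to a reference frame
procrustes_align <- function(coords, ref) {
  pr <- vegan::procrustes(X = ref, Y = coords, scale = TRUE, symmetric = FALSE)
  co <- pr$Yrot + matrix(pr$translation, nrow(coords), 2, byrow = TRUE)
  colnames(co) <- c("x", "y")
  unname(co)
}

#' Geodesic coordinate embedding of a gridworld
#'
#' Convenience chain: adjacency graph, all-pairs shortest paths, Euclidean
#' capping of disconnected pairs, Sammon-stress embedding, Procrustes
#' alignment to the cell-center frame.  The result is cached per layout so
#' the (static) transformation is computed once per environment.
#'
#' @param gw a `grid_world`.
#' @param seed integer passed to [embed_geodesic()].
#' @return A `coord_embedding` with `metric_tag = "geodesic"`.
#' @export
geodesic_embedding <- function(gw, seed = 1L) {
  key <- sprintf("emb_%s_%d", layout_checksum(gw), seed)
  if (!is.null(.navbasis_cache[[key]])) return(.navbasis_cache[[key]])
  D <- cap_disconnected(geodesic_distances(adjacency_matrix(gw)), gw)
  emb <- embed_geodesic(D, seed = seed, ref_coords = euclidean_coords(gw)$coords)
  .navbasis_cache[[key]] <- emb
  emb
}

#' Coordinates for a given metric
#'
#' @param gw a `grid_world`.
#' @param metric `"euclidean"` or `"geodesic"`.
#' @param seed embedding seed (geodesic only).
#' @return A `coord_embedding`.
#' @export
coords_for_metric <- function(gw, metric = c("euclidean", "geodesic"), seed = 1L) {
  metric <- match.arg(metric)
  if (metric == "euclidean") euclidean_coords(gw) else geodesic_embedding(gw, seed)
}

#' Tidy a coordinate embedding
#' @param x a `coord_embedding`.
#' @param ... unused.
#' @return A tibble with `state`, `x`, `y`, `metric`.
#' @export
tidy.coord_embedding <- function(x, ...) {
  tibble::tibble(state = seq_len(nrow(x$coords)),
                 x = x$coords[, 1], y = x$coords[, 2],
                 metric = x$metric_tag)
}

#' Plot an embedding as a distorted lattice
#' @param object a `coord_embedding`.
#' @param ... unused.
#' @return A ggplot of the per-state coordinates.
#' @export
autoplot.coord_embedding <- function(object, ...) {
  ggplot2::ggplot(tidy.coord_embedding(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s coordinates (stress %.3g)",
                                  object$metric_tag, object$stress)) +
    ggplot2::theme_minimal()
}
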