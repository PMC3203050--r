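## Basis-function construction.  A basis set is an M (states) x N (basis
## functions) activation matrix Phi.  Families: tabular (identity),
## multiscale Gaussian place-cell-like fields, and hexagonal three-cosine
## grid-cell-like fields.  Place and grid bases can be evaluated at either
## Euclidean or geodesic coordinates; rows are L2-normalized for learning so
## that the learning rate acts as a fractional step size in every state.

new_basis_set <- function(raw, family, metric_tag, params) {
  norm <- l2_row_normalize(raw)
  structure(list(Phi = norm, raw = raw, family = family,
                 metric_tag = metric_tag, params = params),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %s (%s): %d states x %d functions\n",
              x$family, x$metric_tag, nrow(x$Phi), ncol(x$Phi)))
  invisible(x)
}

#' Row-wise L2 normalization
#'
#' Divides every row with nonzero norm by its L2 norm; all-zero rows are
#' left as zero with a warning.
#'
#' @param Phi numeric matrix.
#' @return Matrix of the same shape with unit (or zero) row norms.
#' @export
l2_row_normalize <- function(Phi) {
  nrm <- sqrt(rowSums(Phi^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero row(s) left unnormalized", sum(zero)))
    nrm[zero] <- 1
  }
  Phi / nrm
}

#' Tabular (identity) basis
#'
#' One indicator function per state: the M x M identity matrix.  TD(lambda)
#' over this basis is exactly classic tabular TD(lambda).
#'
#' @param M number of states.
#' @return A `basis_set` with `family = "tabular"`.
#' @export
tabular_basis <- function(M) {
  stopifnot(M >= 1)
  Phi <- diag(M)
  new_basis_set(Phi, "tabular", "euclidean",
                tibble::tibble(column = seq_len(M), kind = "indicator",
                               state = seq_len(M)))
}

# environment extent in state units: width/height for the lattice frame,
# bounding box (+1 cell) for a stretched geodesic embedding
basis_extent <- function(embedding, gw) {
  if (embedding$metric_tag == "euclidean") {
    max(gw$width, gw$height)
  } else {
    max(diff(range(embedding$coords[, 1])),
        diff(range(embedding$coords[, 2]))) + 1
  }
}

# k x k square tiling of centers over [0, n-1] with half-spacing margins
tile_centers <- function(k, w, h) {
  cx <- (w - 1) * (2 * seq_len(k) - 1) / (2 * k)
  cy <- (h - 1) * (2 * seq_len(k) - 1) / (2 * k)
  as.matrix(expand.grid(cx = cx, cy = cy))
}

#' Multiscale place-cell-like basis
#'
#' Isotropic 2-D Gaussians `exp(-||x(s) - c||^2 / (2 sigma^2))` evaluated at
#' the embedding's per-state coordinates.  Four scales with standard
#' deviations 0.25, 0.15, 0.1 and 0.075 of the environment extent are tiled
#' on square lattices of 5x5, 7x7, 10x10 and 15x15 centers (25, 49, 100 and
#' 225 functions from large to small), plus one constant function: 400
#' columns in total for the default scales.  Center positions come from the
#' world's own frame so Euclidean and geodesic variants share identical
#' per-column parameters; only the evaluation coordinates (and the extent
#' that converts fractional widths to state units) differ.
#'
#' @param embedding a `coord_embedding` for the world.
#' @param gw the `grid_world`.
#' @param sigma_fracs Gaussian standard deviations as fractions of the
#'   environment extent.
#' @param tiles numbers of centers per side at each scale.
#' @param constant include the constant function (value 1 everywhere).
#' @return A `basis_set` with `family = "place"`.
#' @export
place_basis <- function(embedding, gw,
                        sigma_fracs = c(0.25, 0.15, 0.1, 0.075),
                        tiles = c(5L, 7L, 10L, 15L),
                        constant = TRUE) {
  stopifnot(inherits(embedding, "coord_embedding"),
            nrow(embedding$coords) == n_states(gw),
            length(sigma_fracs) == length(tiles))
  co <- embedding$coords
  extent <- basis_extent(embedding, gw)
  cols <- list(); par <- list()
  for (i in seq_along(sigma_fracs)) {
    cen <- tile_centers(tiles[i], gw$width, gw$height)
    sigma <- sigma_fracs[i] * extent
    d2 <- outer(co[, 1], cen[, 1], "-")^2 + outer(co[, 2], cen[, 2], "-")^2
    cols[[i]] <- exp(-d2 / (2 * sigma^2))
    par[[i]] <- tibble::tibble(kind = "gaussian", sigma_frac = sigma_fracs[i],
                               sigma = sigma, cx = cen[, 1], cy = cen[, 2])
  }
  Phi <- do.call(cbind, cols)
  params <- dplyr::bind_rows(par)
  if (constant) {
    Phi <- cbind(Phi, 1)
    params <- dplyr::bind_rows(params,
      tibble::tibble(kind = "constant", sigma_frac = NA, sigma = NA,
                     cx = NA, cy = NA))
  }
  params <- dplyr::mutate(params, column = dplyr::row_number(),
                          .before = 1)
  new_basis_set(unname(Phi), "place", embedding$metric_tag, params)
}

# the three plane-wave directions of a hexagonal grid with orientation theta
GRID_DIR_OFFSETS <- c(pi / 2, -pi / 6, pi / 6)

#' Grid-cell activation at coordinates
#'
#' Sum of three 2-D cosine plane waves whose wave vectors share magnitude
#' `f = 4 * pi / (lambda * sqrt(3))` and point along `theta + pi/2`,
#' `theta - pi/6` and `theta + pi/6`, with spatial phases `p1`, `p2` and
#' `p3 = p1 + p2` (the constructive-interference condition).  A constant
#' shift of 1.5 makes the activation nonnegative: the minimum of
#' `cos a + cos b + cos(a + b)` is -1.5, so values span 0 to 4.5.
#'
#' @param x numeric 2-vector or `n` x 2 matrix of coordinates (state units).
#' @param theta grid orientation, radians.
#' @param lambda node spacing in state units (distance between neighboring
#'   firing fields).
#' @param p1,p2 spatial phases in radians.
#' @return Activation value(s), nonnegative.
#' @export
grid_value <- function(x, theta, lambda, p1, p2) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  f <- 4 * pi / (lambda * sqrt(3))
  phases <- c(p1, p2, p1 + p2)
  v <- 0
  for (j in 1:3) {
    ang <- theta + GRID_DIR_OFFSETS[j]
    v <- v + cos(f * (cos(ang) * x[, 1] + sin(ang) * x[, 2]) + phases[j])
  }
  v + 1.5
}

#' Hexagonal grid-cell-like basis
#'
#' One column for every combination of orientation, node spacing and phase
#' pair, evaluated with [grid_value()] at the embedding's coordinates, plus
#' one constant function.  Defaults follow the multiscale construction:
#' four orientations (0, pi/12, pi/6, pi/4), four spacings `4/(3n)` of the
#' environment extent for `n = 1..4`, and 25 phase pairs on a 5 x 5 lattice
#' evenly sampling `[0, 2*pi)^2` -- 401 columns in total.
#'
#' @inheritParams place_basis
#' @param orientations grid orientations in radians.
#' @param spacing_ns integers `n` giving spacings `4/(3n)` environment
#'   extents.
#' @param n_phase phases per axis (`n_phase^2` pairs).
#' @return A `basis_set` with `family = "grid"`.
#' @export
grid_basis <- function(embedding, gw,
                       orientations = c(0, pi / 12, pi / 6, pi / 4),
                       spacing_ns = 1:4,
                       n_phase = 5L,
                       constant = TRUE) {
  stopifnot(inherits(embedding, "coord_embedding"),
            nrow(embedding$coords) == n_states(gw))
  co <- embedding$coords
  extent <- basis_extent(embedding, gw)
  ph <- seq(0, 2 * pi, length.out = n_phase + 1)[seq_len(n_phase)]
  par <- expand.grid(p2 = ph, p1 = ph, n = spacing_ns, theta = orientations)
  par <- par[, c("theta", "n", "p1", "p2")]
  Phi <- matrix(0, nrow(co), nrow(par))
  lam <- 4 / (3 * par$n) * extent
  for (j in seq_len(nrow(par))) {
    Phi[, j] <- grid_value(co, par$theta[j], lam[j], par$p1[j], par$p2[j])
  }
  params <- tibble::tibble(kind = "grid", theta = par$theta,
                           lambda_frac = 4 / (3 * par$n), lambda = lam,
                           p1 = par$p1, p2 = par$p2, p3 = par$p1 + par$p2)
  if (constant) {
    Phi <- cbind(Phi, 1)
    params <- dplyr::bind_rows(params,
      tibble::tibble(kind = "constant", theta = NA, lambda_frac = NA,
                     lambda = NA, p1 = NA, p2 = NA, p3 = NA))
  }
  params <- dplyr::mutate(params, column = dplyr::row_number(), .before = 1)
  new_basis_set(unname(Phi), "grid", embedding$metric_tag, params)
}

#' Build a basis set by family and metric
#'
#' @param gw a `grid_world`.
#' @param family `"tabular"`, `"place"` or `"grid"`.
#' @param metric `"euclidean"` or `"geodesic"` (ignored for tabular).
#' @param seed embedding seed for the geodesic metric.
#' @return A `basis_set`.  Results are cached per layout.
#' @export
build_basis <- function(gw, family = c("tabular", "place", "grid"),
                        metric = c("euclidean", "geodesic"), seed = 1L) {
  family <- match.arg(family); metric <- match.arg(metric)
  if (family == "tabular") return(tabular_basis(n_states(gw)))
  key <- sprintf("basis_%s_%s_%s_%d", layout_checksum(gw), family, metric, seed)
  if (!is.null(.navbasis_cache[[key]])) return(.navbasis_cache[[key]])
  emb <- coords_for_metric(gw, metric, seed)
  b <- if (family == "place") place_basis(emb, gw) else grid_basis(emb, gw)
  .navbasis_cache[[key]] <- b
  b
}
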