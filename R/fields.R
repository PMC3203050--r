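## Firing-rate maps of basis functions and the barrier demonstrations:
## wall-bisection field disappearance, barrier-induced field gain, and the
## corridor / hairpin field-shape reproductions.  Rendering always uses the
## raw (pre-row-normalization) activations: row L2 normalization is a
## learning-time device, not a firing-rate claim.

# the peak-rate ratio below which a field counts as "disappeared"
DISAPPEARANCE_RATIO <- 0.5

new_rate_map <- function(rates, gw, column = NA_integer_) {
  structure(list(rates = rates, world = gw, column = column),
            class = "rate_map")
}

#' Render one basis column as a firing-rate map
#'
#' @param basis a `basis_set`.
#' @param column column index.
#' @param gw the `grid_world` the basis was built on.
#' @return A `rate_map`: nonnegative per-cell rates (arbitrary units).
#' @export
render_field <- function(basis, column, gw) {
  if (column < 1 || column > ncol(basis$raw)) stop("invalid column")
  new_rate_map(basis$raw[, column], gw, column)
}

#' Evaluate a single place field at an embedding
#'
#' @param embedding a `coord_embedding`.
#' @param center length-2 numeric `(x, y)` field center in state units.
#' @param sigma Gaussian standard deviation in state units.
#' @return Numeric activation vector over states.
#' @export
place_field_at <- function(embedding, center, sigma) {
  co <- embedding$coords
  exp(-((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2) / (2 * sigma^2))
}

#' Wall-bisection experiment
#'
#' Evaluates the same geodesic place field before and after inserting a
#' wall.  When the wall bisects the field's center, nearby locations on the
#' two sides are pulled apart in geodesic coordinates and no state remains
#' close to the center: the field's peak rate collapses (a ratio below 0.5,
#' the `DISAPPEARANCE_RATIO` convention, counts as disappearance); a field
#' far from the wall is barely affected.
#'
#' @param gw_open the world before wall insertion (typically an open box).
#' @param wall_spec blocked-edge matrix (two columns of adjacent state
#'   indices) defining the inserted wall, or a ready-made `grid_world`.
#' @param place_params list with `center` (`(x, y)`) and `sigma` (states).
#' @param seed embedding seed (shared by both worlds).
#' @return One-row tibble: `peak_before`, `peak_after`, `ratio`,
#'   `intersects_wall` (whether the wall passes within one sigma of the
#'   field center).
#' @export
bisection_experiment <- function(gw_open, wall_spec, place_params, seed = 1L) {
  gw_wall <- if (inherits(wall_spec, "grid_world")) {
    wall_spec
  } else if (is.null(wall_spec) || (is.matrix(wall_spec) && !nrow(wall_spec))) {
    gw_open
  } else {
    grid_world(gw_open$width, gw_open$height,
               blocked = rbind(gw_open$blocked, wall_spec),
               goal = gw_open$goal, reward = gw_open$reward)
  }
  emb0 <- geodesic_embedding(gw_open, seed)
  emb1 <- geodesic_embedding(gw_wall, seed)
  f0 <- place_field_at(emb0, place_params$center, place_params$sigma)
  f1 <- place_field_at(emb1, place_params$center, place_params$sigma)
  new_walls <- setdiff(edge_key(gw_wall$blocked[, 1], gw_wall$blocked[, 2]),
                       if (nrow(gw_open$blocked))
                         edge_key(gw_open$blocked[, 1], gw_open$blocked[, 2])
                       else character(0))
  intersects <- FALSE
  if (length(new_walls)) {
    idx <- do.call(rbind, lapply(strsplit(new_walls, " "), as.integer))
    mids <- (cell_xy(gw_wall, idx[, 1]) + cell_xy(gw_wall, idx[, 2])) / 2
    dmin <- min(sqrt((mids[, 1] - place_params$center[1])^2 +
                       (mids[, 2] - place_params$center[2])^2))
    intersects <- dmin <= place_params$sigma
  }
  if (!intersects && length(new_walls))
    message("inserted wall does not intersect the field (reported anyway)")
  tibble::tibble(peak_before = max(f0), peak_after = max(f1),
                 ratio = max(f1) / max(f0), intersects_wall = intersects)
}

#' Barrier-induced rate changes across a whole place basis
#'
#' Compares the peak rate of every Gaussian place column between two
#' variants of the same grid (e.g. before and after adding a wall), using
#' each variant's own geodesic embedding.  Suppressed columns (ratio < 1)
#' concentrate near the changed walls; a minority of columns can gain
#' activity (ratio > 1) when the geometric distortion pushes state
#' coordinates into regions that previously carried none.
#'
#' @param gw_before,gw_after two `grid_world`s with identical dimensions.
#' @param seed embedding seed (shared).
#' @return A tibble with one row per Gaussian column: `column`, `cx`, `cy`,
#'   `sigma`, `peak_before`, `peak_after`, `ratio`, `dist_to_change`
#'   (Euclidean distance from the field center to the nearest changed
#'   edge; `NA` when the layouts are identical).
#' @export
barrier_gain_experiment <- function(gw_before, gw_after, seed = 1L) {
  stopifnot(gw_before$width == gw_after$width,
            gw_before$height == gw_after$height)
  b0 <- place_basis(geodesic_embedding(gw_before, seed), gw_before)
  b1 <- place_basis(geodesic_embedding(gw_after, seed), gw_after)
  keep <- b0$params$kind == "gaussian"
  p0 <- apply(b0$raw[, keep, drop = FALSE], 2, max)
  p1 <- apply(b1$raw[, keep, drop = FALSE], 2, max)
  par <- b0$params[keep, ]
  key0 <- edge_key(gw_before$blocked[, 1], gw_before$blocked[, 2])
  key1 <- edge_key(gw_after$blocked[, 1], gw_after$blocked[, 2])
  changed <- union(setdiff(key0, key1), setdiff(key1, key0))
  dist_to_change <- rep(NA_real_, nrow(par))
  if (length(changed)) {
    idx <- do.call(rbind, lapply(strsplit(changed, " "), as.integer))
    mids <- (cell_xy(gw_before, idx[, 1]) + cell_xy(gw_before, idx[, 2])) / 2
    dist_to_change <- vapply(seq_len(nrow(par)), function(i) {
      min(sqrt((mids[, 1] - par$cx[i])^2 + (mids[, 2] - par$cy[i])^2))
    }, numeric(1))
  }
  tibble::tibble(column = par$column, cx = par$cx, cy = par$cy,
                 sigma = par$sigma, peak_before = p0, peak_after = p1,
                 ratio = p1 / p0, dist_to_change = dist_to_change)
}

#' Tidy a rate map
#' @param x a `rate_map`.
#' @param ... unused.
#' @return Tibble with `state`, `x`, `y`, `rate`.
#' @export
tidy.rate_map <- function(x, ...) {
  xy <- cell_xy(x$world, seq_along(x$rates))
  tibble::tibble(state = seq_along(x$rates), x = xy[, 1], y = xy[, 2],
                 rate = x$rates)
}

#' Plot a firing-rate map
#'
#' Black-to-white scale, low to high rate, with walls drawn on top.
#'
#' @param object a `rate_map`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rate_map <- function(object, ...) {
  df <- tidy.rate_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_segment(data = wall_segments(object$world),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "red", linewidth = 1.2, inherit.aes = FALSE) +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}
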