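## Discrete gridworld environments: states are cells of a width x height
## lattice, actions are the four cardinal moves, walls are *blocked edges*
## between orthogonally adjacent cells (thin walls, not occupied cells).

# fixed action order used everywhere (R and the compiled engine)
ACTIONS <- c("north", "south", "east", "west")
ACTION_DX <- c(north = 0L, south = 0L, east = 1L, west = -1L)
ACTION_DY <- c(north = 1L, south = -1L, east = 0L, west = 0L)

#' Construct a gridworld
#'
#' A gridworld is a `width` x `height` lattice of cells.  Cells are addressed
#' either by 0-based `(x, y)` coordinates (`x` = column, `y` = row, cell
#' centers at integer coordinates) or by 1-based state index under the
#' row-major bijection `index = y * width + x + 1`.  Walls are unordered
#' pairs of adjacent cells whose shared edge cannot be crossed.  Exactly one
#' cell, the goal, carries a reward; reaching it ends a trial (the goal is
#' absorbing).
#'
#' @param width,height positive integers, grid dimensions in cells.
#' @param blocked a two-column matrix (or data frame) of 1-based state index
#'   pairs, each row one blocked edge between orthogonally adjacent cells.
#'   `NULL` for no walls.
#' @param goal 1-based state index of the goal cell.
#' @param reward scalar reward delivered at the goal (default 1).
#' @return An object of class `grid_world`.
#' @examples
#' gw <- grid_world(4, 3, goal = 12)
#' n_states(gw)
#' @export
grid_world <- function(width, height, blocked = NULL, goal, reward = 1) {
  stopifnot(width >= 1, height >= 1, length(goal) == 1)
  width <- as.integer(width); height <- as.integer(height)
  M <- width * height
  if (goal < 1 || goal > M) stop("goal is not a valid cell index")
  if (is.null(blocked)) {
    blocked <- matrix(integer(0), ncol = 2)
  } else {
    blocked <- as.matrix(blocked)
    storage.mode(blocked) <- "integer"
    if (ncol(blocked) != 2) stop("blocked must have two columns")
  }
  if (nrow(blocked)) {
    if (any(blocked < 1 | blocked > M)) stop("wall segment outside the grid")
    # canonical order (small index first) and orthogonal-adjacency check
    blocked <- t(apply(blocked, 1, sort))
    xy1 <- index_to_xy(blocked[, 1], width)
    xy2 <- index_to_xy(blocked[, 2], width)
    adj <- abs(xy1[, 1] - xy2[, 1]) + abs(xy1[, 2] - xy2[, 2])
    if (any(adj != 1)) stop("blocked edges must join orthogonally adjacent cells")
    blocked <- unique(blocked)
    blocked <- blocked[order(blocked[, 1], blocked[, 2]), , drop = FALSE]
  }
  dimnames(blocked) <- NULL
  structure(
    list(width = width, height = height, blocked = blocked,
         goal = as.integer(goal), reward = as.numeric(reward)),
    class = "grid_world")
}

#' Number of states in a gridworld
#' @param gw a `grid_world`.
#' @return Integer, `width * height`.
#' @export
n_states <- function(gw) gw$width * gw$height

#' Convert between cell coordinates and state indices
#'
#' Coordinates are 0-based `(x, y)` with `x` the column and `y` the row;
#' state indices are 1-based and row-major (`index = y * width + x + 1`).
#'
#' @param gw a `grid_world`.
#' @param x,y integer vectors of 0-based cell coordinates.
#' @param s integer vector of 1-based state indices.
#' @return `cell_index` returns indices; `cell_xy` a two-column matrix of
#'   coordinates.
#' @export
cell_index <- function(gw, x, y) {
  stopifnot(all(x >= 0), all(x < gw$width), all(y >= 0), all(y < gw$height))
  as.integer(y) * gw$width + as.integer(x) + 1L
}

#' @rdname cell_index
#' @export
cell_xy <- function(gw, s) {
  if (any(s < 1 | s > n_states(gw))) stop("invalid cell index")
  index_to_xy(s, gw$width)
}

index_to_xy <- function(s, width) {
  s0 <- as.integer(s) - 1L
  cbind(x = s0 %% width, y = s0 %/% width)
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

is_blocked <- function(gw, i, j) {
  if (!nrow(gw$blocked)) return(rep(FALSE, length(i)))
  edge_key(i, j) %in% edge_key(gw$blocked[, 1], gw$blocked[, 2])
}

#' Actions available in a cell
#'
#' Moves that would leave the grid or cross a blocked edge are excluded.
#'
#' @param gw a `grid_world`.
#' @param s 1-based state index.
#' @return Character vector, a subset of `c("north","south","east","west")`
#'   (north is +y, east is +x).
#' @export
available_actions <- function(gw, s) {
  stopifnot(length(s) == 1)
  if (s < 1 || s > n_states(gw)) stop("invalid cell")
  nb <- neighbors_matrix(gw)[s, ]
  ACTIONS[!is.na(nb)]
}

#' Take one step in a gridworld
#'
#' Applies action `a` in state `s`.  The reward is `gw$reward` iff the move
#' enters the goal, which is absorbing (`terminal = TRUE`).
#'
#' @param gw a `grid_world`.
#' @param s 1-based state index (must not be the goal).
#' @param a one of `"north"`, `"south"`, `"east"`, `"west"`, and available
#'   in `s`.
#' @return A list with `state` (next state index), `reward`, `terminal`.
#' @export
gw_step <- function(gw, s, a) {
  a <- match.arg(a, ACTIONS)
  if (s == gw$goal) stop("cannot step from the absorbing goal state")
  if (!(a %in% available_actions(gw, s)))
    stop(sprintf("action '%s' is unavailable in state %d", a, s))
  nb <- unname(neighbors_matrix(gw)[s, match(a, ACTIONS)])
  list(state = nb,
       reward = if (nb == gw$goal) gw$reward else 0,
       terminal = nb == gw$goal)
}

#' Neighbor table of a gridworld
#'
#' @param gw a `grid_world`.
#' @return An `M` x 4 integer matrix; entry `[s, a]` is the state reached by
#'   action `a` (columns ordered north, south, east, west) or `NA` when the
#'   move is off-grid or blocked.
#' @export
neighbors_matrix <- function(gw) {
  M <- n_states(gw)
  xy <- index_to_xy(seq_len(M), gw$width)
  nb <- matrix(NA_integer_, M, 4, dimnames = list(NULL, ACTIONS))
  for (a in ACTIONS) {
    nx <- xy[, 1] + ACTION_DX[[a]]
    ny <- xy[, 2] + ACTION_DY[[a]]
    ok <- nx >= 0 & nx < gw$width & ny >= 0 & ny < gw$height
    tgt <- rep(NA_integer_, M)
    tgt[ok] <- ny[ok] * gw$width + nx[ok] + 1L
    if (nrow(gw$blocked)) {
      bl <- rep(FALSE, M)
      bl[ok] <- is_blocked(gw, which(ok), tgt[ok])
      tgt[bl] <- NA_integer_
    }
    nb[, a] <- tgt
  }
  nb
}

#' Adjacency matrix of the state transition graph
#'
#' @param gw a `grid_world`.
#' @return Symmetric binary `M` x `M` matrix with zero diagonal; entry 1 iff
#'   the two cells are orthogonally adjacent and the edge is not blocked.
#' @export
adjacency_matrix <- function(gw) {
  M <- n_states(gw)
  nb <- neighbors_matrix(gw)
  A <- matrix(0L, M, M)
  idx <- which(!is.na(nb), arr.ind = TRUE)
  A[cbind(idx[, 1], nb[!is.na(nb)])] <- 1L
  A
}

#' Build an archetype layout
#'
#' Parametric constructors for the six archetype environments used
#' throughout: an open field, a simple barrier world, a narrow-aperture
#' world (full dividing wall with a one-cell doorway), two rooms joined by a
#' narrow corridor, a bisecting-barrier world (a free-standing wall in the
#' middle of an open box), and a hairpin (serpentine) maze.  Deterministic
#' for fixed parameters.
#'
#' @param archetype one of `"open_field"`, `"simple_barrier"`,
#'   `"narrow_aperture"`, `"two_rooms_corridor"`, `"bisecting_barrier"`,
#'   `"hairpin"`.
#' @param width,height grid dimensions (default 20 x 20).
#' @param goal 1-based goal state index; `NULL` for the archetype default.
#' @param ... archetype parameters: `wall_x`/`wall_y` (0-based wall
#'   position), `wall_span` (integer range of cells covered),
#'   `gap` (0-based position of the opening), `corridor` (0-based columns of
#'   the two-rooms corridor), `arm_width` (hairpin arm width).
#' @return A `grid_world`.
#' @export
build_layout <- function(archetype, width = 20, height = 20, goal = NULL, ...) {
  archetype <- match.arg(archetype,
    c("open_field", "simple_barrier", "narrow_aperture",
      "two_rooms_corridor", "bisecting_barrier", "hairpin"))
  dots <- list(...)
  p <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  W <- as.integer(width); H <- as.integer(height)
  vwall <- function(x, yspan) {   # wall between columns x and x+1, rows yspan
    if (x < 0 || x >= W - 1 || any(yspan < 0) || any(yspan >= H))
      stop("wall segment outside the grid")
    cbind(yspan * W + x + 1L, yspan * W + x + 2L)
  }
  hwall <- function(y, xspan) {   # wall between rows y and y+1, columns xspan
    if (y < 0 || y >= H - 1 || any(xspan < 0) || any(xspan >= W))
      stop("wall segment outside the grid")
    cbind(y * W + xspan + 1L, (y + 1L) * W + xspan + 1L)
  }
  mid <- function(n) (n %/% 2L) - 1L   # 9 for n = 20
  blocked <- NULL; gdef <- NULL
  if (archetype == "open_field") {
    gdef <- cell0(W, H, W %/% 2L, H %/% 2L)
  } else if (archetype == "simple_barrier") {
    y <- p("wall_y", mid(H))
    span <- p("wall_span", seq.int(W %/% 4L, W - 1L - W %/% 4L))
    blocked <- hwall(y, span)
    gdef <- cell0(W, H, W %/% 2L, min(H - 1L, y + 3L))
  } else if (archetype == "narrow_aperture") {
    # full dividing wall with a one-cell doorway at the top; the goal hugs
    # the far side of the wall near the bottom, so the straight line to the
    # goal crosses the wall as far as possible from the opening and the
    # value function is sharply discontinuous across the wall
    x <- p("wall_x", mid(W)); gap <- p("gap", H - 1L)
    blocked <- vwall(x, setdiff(0:(H - 1L), gap))
    gdef <- cell0(W, H, min(W - 1L, x + 1L), 2L)
  } else if (archetype == "two_rooms_corridor") {
    band <- p("band", seq.int(H %/% 2L - 2L, H %/% 2L + 1L))  # rows 8..11
    corridor <- p("corridor", c(W %/% 2L - 1L, W %/% 2L))     # columns 9,10
    y0 <- min(band); y1 <- max(band)
    blocked <- rbind(
      hwall(y0 - 1L, setdiff(0:(W - 1L), corridor)),
      hwall(y1, setdiff(0:(W - 1L), corridor)),
      vwall(min(corridor) - 1L, band),
      vwall(max(corridor), band))
    gdef <- cell0(W, H, W %/% 2L, H %/% 2L - 7L)
  } else if (archetype == "bisecting_barrier") {
    x <- p("wall_x", mid(W))
    span <- p("wall_span", seq.int(H %/% 4L, H - 1L - H %/% 4L))
    blocked <- vwall(x, span)
    gdef <- cell0(W, H, min(W - 1L, x + 7L), H %/% 2L)
  } else if (archetype == "hairpin") {
    aw <- p("arm_width", 2L)
    xs <- seq.int(aw - 1L, W - aw - 1L, by = aw)
    blocked <- do.call(rbind, lapply(seq_along(xs), function(k) {
      span <- if (k %% 2L == 1L) 0:(H - 2L) else 1:(H - 1L)  # open top / bottom
      vwall(xs[k], span)
    }))
    gdef <- cell0(W, H, W - 1L, 0L)
  }
  grid_world(W, H, blocked = blocked,
             goal = if (is.null(goal)) gdef else goal,
             reward = p("reward", 1))
}

cell0 <- function(W, H, x, y) as.integer(y) * W + as.integer(x) + 1L

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world> %d x %d (%d states), %d blocked edges, goal %d (x=%d, y=%d), reward %g\n",
              x$width, x$height, n_states(x), nrow(x$blocked), x$goal,
              cell_xy(x, x$goal)[1], cell_xy(x, x$goal)[2], x$reward))
  invisible(x)
}

#' Tidy a gridworld into a cell table
#'
#' @param x a `grid_world`.
#' @param ... unused.
#' @return A tibble with one row per cell: `state`, `x`, `y`, `is_goal`,
#'   `n_actions`.
#' @export
tidy.grid_world <- function(x, ...) {
  xy <- cell_xy(x, seq_len(n_states(x)))
  nb <- neighbors_matrix(x)
  tibble::tibble(state = seq_len(n_states(x)),
                 x = xy[, 1], y = xy[, 2],
                 is_goal = seq_len(n_states(x)) == x$goal,
                 n_actions = rowSums(!is.na(nb)))
}

# blocked edges as wall segments for plotting: each blocked edge is drawn as
# the shared cell boundary, perpendicular to the move it blocks
wall_segments <- function(gw) {
  if (!nrow(gw$blocked)) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          xend = numeric(0), yend = numeric(0)))
  }
  a <- cell_xy(gw, gw$blocked[, 1]); b <- cell_xy(gw, gw$blocked[, 2])
  mx <- (a[, 1] + b[, 1]) / 2; my <- (a[, 2] + b[, 2]) / 2
  horiz <- a[, 2] != b[, 2]   # horizontal wall blocks a vertical move
  tibble::tibble(
    x    = ifelse(horiz, mx - 0.5, mx),
    xend = ifelse(horiz, mx + 0.5, mx),
    y    = ifelse(horiz, my, my - 0.5),
    yend = ifelse(horiz, my, my + 0.5))
}

#' Plot a gridworld layout
#'
#' @param object a `grid_world`.
#' @param ... unused.
#' @return A ggplot: cells, walls as thick segments, goal as a star.
#' @export
autoplot.grid_world <- function(object, ...) {
  cells <- tidy.grid_world(object)
  walls <- wall_segments(object)
  goal <- cells[cells$is_goal, ]
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "grey95", colour = "grey85") +
    ggplot2::geom_segment(data = walls,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 1.6, colour = "black", inherit.aes = FALSE) +
    ggplot2::geom_point(data = goal, shape = 8, size = 3, colour = "red3") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
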