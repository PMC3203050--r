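## Frozen archetype fixtures and random worlds for oracle testing.  The six
## 20 x 20 fixtures approximate classic experimental enclosures: an open
## field, a simple barrier, a full dividing wall with a one-cell doorway, a
## two-rooms-with-corridor arena, a free-standing bisecting barrier, and a
## hairpin (serpentine) maze.  Each ships as a layout file under
## inst/extdata with a checksum; generate_fixture() rebuilds it from
## parameters and documents its provenance.

FIXTURE_NAMES <- c("open_field_20", "simple_barrier_20", "narrow_aperture_20",
                   "two_rooms_20", "bisect_20", "hairpin_20")

#' Names of the built-in fixture worlds
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() FIXTURE_NAMES

# frozen layout checksums; regeneration must reproduce these
FIXTURE_CHECKSUMS <- c(
  open_field_20      = "01084dde",
  simple_barrier_20  = "467bfcf3",
  narrow_aperture_20 = "314d6c80",
  two_rooms_20       = "34a80dd5",
  bisect_20          = "0502d266",
  hairpin_20         = "123b612a")

#' Layout checksum
#'
#' Polynomial rolling hash (mod the Mersenne prime 2^31 - 1) of the
#' dimensions, goal, reward and sorted blocked-edge list; stable across
#' platforms, used to pin fixture layouts.
#'
#' @param gw a `grid_world`.
#' @return Eight-character lowercase hex string.
#' @export
layout_checksum <- function(gw) {
  ints <- c(gw$width, gw$height, gw$goal, round(gw$reward * 1e6), t(gw$blocked))
  h <- 17
  for (v in ints) h <- (h * 31 + as.numeric(v)) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Construct a fixture world from its frozen parameters
#'
#' Deterministically rebuilds one of the six archetype worlds and verifies
#' its layout checksum.
#'
#' @param name one of [fixture_names()].
#' @return A `grid_world`.
#' @export
make_fixture <- function(name) {
  gw <- generate_fixture(name)
  want <- FIXTURE_CHECKSUMS[[name]]
  got <- layout_checksum(gw)
  if (got != want)
    stop(sprintf("fixture '%s' checksum mismatch: %s != %s", name, got, want))
  gw
}

#' @rdname make_fixture
#' @export
generate_fixture <- function(name) {
  name <- match.arg(name, FIXTURE_NAMES)
  switch(name,
    open_field_20      = build_layout("open_field"),
    simple_barrier_20  = build_layout("simple_barrier"),
    narrow_aperture_20 = build_layout("narrow_aperture"),
    two_rooms_20       = build_layout("two_rooms_corridor"),
    bisect_20          = build_layout("bisecting_barrier"),
    hairpin_20         = build_layout("hairpin"))
}

#' Random world for oracle testing
#'
#' Draws random unit wall segments, keeping only those that leave the
#' goal's connected component covering at least half the states.
#' Deterministic per seed; does not disturb the caller's RNG state.
#'
#' @param width,height grid dimensions (each `>= 2`).
#' @param n_wall_segments number of unit wall segments to attempt.
#' @param seed integer seed.
#' @param goal goal state index (default: last cell).
#' @return A `grid_world`.
#' @export
random_world <- function(width, height, n_wall_segments, seed, goal = NULL) {
  stopifnot(width >= 2, height >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  M <- width * height
  if (is.null(goal)) goal <- M
  # all undirected lattice edges
  base <- grid_world(width, height, goal = goal)
  A <- adjacency_matrix(base)
  edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  blocked <- matrix(integer(0), ncol = 2)
  attempts <- edges[sample.int(nrow(edges)), , drop = FALSE]
  for (i in seq_len(nrow(attempts))) {
    if (nrow(blocked) >= n_wall_segments) break
    cand <- rbind(blocked, attempts[i, ])
    gw_try <- grid_world(width, height, blocked = cand, goal = goal)
    g <- igraph::graph_from_adjacency_matrix(adjacency_matrix(gw_try),
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    if (sum(comp == comp[goal]) >= M / 2) blocked <- cand
  }
  grid_world(width, height, blocked = blocked, goal = goal)
}
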