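test_that("rendered fields are nonnegative, finite, and unimodal for place", {
  gw <- make_fixture("open_field_20")
  bp <- build_basis(gw, "place", "euclidean")
  j <- with(bp$params, which(kind == "gaussian" & sigma_frac == 0.15))[10]
  rm <- render_field(bp, j, gw)
  expect_true(all(rm$rates >= 0 & is.finite(rm$rates)))
  # isotropic unimodal: a single connected set of cells above half-max
  top <- which(rm$rates > 0.5 * max(rm$rates))
  A <- adjacency_matrix(gw)[top, top, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1)

  bg <- build_basis(gw, "grid", "euclidean")
  k <- with(bg$params, which(kind == "grid" & lambda_frac == 4 / 9))[1]
  rg <- render_field(bg, k, gw)
  # periodic multi-peaked: several separated above-threshold blobs
  topg <- which(rg$rates > 0.8 * max(rg$rates))
  Ag <- adjacency_matrix(gw)[topg, topg, drop = FALSE]
  gg <- igraph::graph_from_adjacency_matrix(Ag, mode = "undirected")
  expect_gte(igraph::components(gg)$no, 3)
  expect_error(render_field(bp, 0, gw), "invalid column")
})

test_that("hairpin grid fields track arms rather than crossing walls", {
  gw <- make_fixture("hairpin_20")
  b <- build_basis(gw, "grid", "geodesic")
  j <- with(b$params, which(kind == "grid" & lambda_frac == 4 / 3))[13]
  rates <- b$raw[, j]
  xy <- cell_xy(gw, seq_len(n_states(gw)))
  arm <- xy[, 1] %/% 2          # arms are two columns wide
  # correlation of rate profiles (by row y) between adjacent arms, which are
  # separated by a wall, versus within the two columns of the same arm
  prof <- vapply(0:9, function(a) {
    vapply(0:19, function(y) mean(rates[arm == a & xy[, 2] == y]), numeric(1))
  }, numeric(20))
  across <- mean(diag(cor(prof)[-1, -10]))   # arm a vs a+1
  within <- mean(vapply(0:9, function(a) {
    c1 <- rates[arm == a & xy[, 1] %% 2 == 0]
    c2 <- rates[arm == a & xy[, 1] %% 2 == 1]
    cor(c1, c2)
  }, numeric(1)))
  expect_gt(within, across)
})

test_that("bisection experiment: identity without a wall, collapse with one", {
  open <- make_fixture("open_field_20")
  wall <- make_fixture("bisect_20")$blocked
  centre_params <- list(center = c(9.5, 9.5), sigma = 2)
  none <- bisection_experiment(open, NULL, centre_params)
  expect_equal(none$ratio, 1)

  hit <- bisection_experiment(open, wall, centre_params)
  expect_true(hit$intersects_wall)
  expect_lt(hit$ratio, 0.5)

  far_params <- list(center = c(3, 3), sigma = 2)
  expect_message(far <- bisection_experiment(open, wall, far_params),
                 "does not intersect")
  expect_false(far$intersects_wall)
  expect_lt(abs(far$ratio - 1), 0.1)
})

test_that("barrier insertion: identity, gains exist, suppression is local", {
  open <- make_fixture("open_field_20")
  walled <- make_fixture("bisect_20")
  same <- barrier_gain_experiment(open, open)
  expect_equal(same$ratio, rep(1, nrow(same)))
  expect_true(all(is.na(same$dist_to_change)))

  res <- barrier_gain_experiment(open, walled)
  expect_true(any(res$ratio > 1))           # field appearance/strengthening
  suppressed <- res$ratio < 0.9
  expect_gt(sum(suppressed), 0)
  expect_lt(mean(res$dist_to_change[suppressed]),
            mean(res$dist_to_change[!suppressed]))
})

test_that("corridor place fields stay confined to one room and the passage", {
  gw <- make_fixture("two_rooms_20")   # rooms joined by a 2-wide corridor
  emb <- geodesic_embedding(gw)
  # field centered at the corridor mouth of the bottom room
  f <- place_field_at(emb, center = c(9.5, 6), sigma = 2)
  xy <- cell_xy(gw, seq_len(n_states(gw)))
  bottom <- xy[, 2] <= 7; top <- xy[, 2] >= 12
  # activity in the far room is a small fraction of the near-room peak,
  # even though the rooms are Euclidean-close across the dividing band
  expect_lt(max(f[top]), 0.2 * max(f[bottom]))
  expect_gt(max(f[bottom]), 0.5)
})

test_that("field experiments are deterministic given the embedding seed", {
  open <- make_fixture("open_field_20")
  walled <- make_fixture("bisect_20")
  r1 <- barrier_gain_experiment(open, walled, seed = 1)
  r2 <- barrier_gain_experiment(open, walled, seed = 1)
  expect_identical(r1, r2)
})
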