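test_that("geodesic distances match a BFS oracle on random worlds", {
  for (seed in 1:5) {
    gw <- random_world(8, 8, n_wall_segments = 10, seed = seed)
    A <- adjacency_matrix(gw)
    D <- geodesic_distances(A)
    expect_equal(D$values, bfs_all_pairs(A))
  }
})

test_that("geodesic distance basics: adjacency, diagonal, symmetry", {
  gw <- build_layout("open_field", 2, 2, goal = 4)
  D <- geodesic_distances(adjacency_matrix(gw))$values
  expect_equal(diag(D), rep(0, 4))
  expect_equal(D[1, 2], 1)   # adjacent pair
  expect_equal(D[1, 4], 2)   # diagonal of a 2x2: two cardinal steps
  expect_equal(D, t(D))
  expect_error(geodesic_distances(matrix(0, 2, 3)), "square")
})

test_that("capping replaces exactly the disconnected pairs by Euclidean", {
  gw <- make_fixture("open_field_20")
  D <- geodesic_distances(adjacency_matrix(gw))
  D2 <- cap_disconnected(D, gw)
  expect_identical(D2$values, D$values)
  expect_false(any(D2$capped_mask))

  # 3x3 grid fully split by a vertical wall
  gw3 <- grid_world(3, 3, blocked = cbind(c(1L, 4L, 7L), c(2L, 5L, 8L)),
                    goal = 9)
  Dc <- cap_disconnected(geodesic_distances(adjacency_matrix(gw3)), gw3)
  expect_true(all(is.finite(Dc$values)))
  # pair (0,1)-(2,1): states 4 and 6, Euclidean distance 2
  expect_equal(Dc$values[4, 6], 2)
  expect_true(Dc$capped_mask[4, 6])
  expect_equal(Dc$values, t(Dc$values))
  expect_equal(Dc$capped_mask, t(Dc$capped_mask))
})

test_that("a corridor embeds as a straight evenly spaced line", {
  gw <- grid_world(12, 1, goal = 12)
  D <- geodesic_distances(adjacency_matrix(gw))
  emb <- embed_geodesic(D, seed = 1)
  co <- emb$coords
  # collinear: second principal component carries ~no variance
  pc <- prcomp(co)
  expect_lt(pc$sdev[2] / pc$sdev[1], 1e-3)
  gaps <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  expect_true(all(abs(gaps - mean(gaps)) / mean(gaps) < 0.05))
  expect_lt(emb$stress, 1e-6)
})

test_that("open-field embedding reproduces the target distances closely", {
  gw <- build_layout("open_field", 10, 10, goal = 100)
  D <- geodesic_distances(adjacency_matrix(gw))
  emb <- embed_geodesic(D, seed = 1)
  De <- as.matrix(dist(emb$coords))
  ut <- upper.tri(De)
  expect_gte(cor(De[ut], D$values[ut]), 0.95)
  # descent property: no worse than the classical-scaling start
  init <- cmdscale(as.dist(D$values), k = 2)
  expect_lte(emb$stress, sammon_stress(init, D$values) + 1e-12)
})

test_that("embedding quality is invariant under state relabeling", {
  gw <- random_world(5, 4, n_wall_segments = 4, seed = 11)
  D <- geodesic_distances(adjacency_matrix(gw))$values
  s1 <- embed_geodesic(structure(list(values = D,
                                      capped_mask = matrix(FALSE, 20, 20)),
                                 class = "geo_dist"), seed = 1)$stress
  set.seed(99)
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  s2 <- embed_geodesic(structure(list(values = Dp,
                                      capped_mask = matrix(FALSE, 20, 20)),
                                 class = "geo_dist"), seed = 1)$stress
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("euclidean coordinates are the exact cell centers", {
  gw <- make_fixture("open_field_20")
  emb <- euclidean_coords(gw)
  expect_equal(dim(emb$coords), c(400, 2))
  expect_equal(range(emb$coords[, 1]), c(0, 19))
  expect_equal(range(emb$coords[, 2]), c(0, 19))
  expect_equal(emb$stress, 0)
  expect_identical(emb$metric_tag, "euclidean")
  # adjacent cells at unit distance; idempotent
  expect_equal(sqrt(sum((emb$coords[2, ] - emb$coords[1, ])^2)), 1)
  expect_identical(euclidean_coords(gw), emb)
})

test_that("embedding is deterministic for a fixed seed and reused per world", {
  gw <- make_fixture("bisect_20")
  e1 <- geodesic_embedding(gw, seed = 1)
  e2 <- geodesic_embedding(gw, seed = 1)
  expect_identical(e1, e2)
  expect_identical(e1$metric_tag, "geodesic")
  expect_gte(e1$stress, 0)
})
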