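test_that("tabular basis is the identity", {
  b <- tabular_basis(3)
  expect_equal(b$Phi, diag(3))
  # one-hot: phi_s(s) = 1, phi_s(s') = 0
  expect_equal(b$Phi[2, 2], 1)
  expect_equal(sum(b$Phi[2, -2]), 0)
})

test_that("place basis has 400 columns with the stated scale structure", {
  gw <- make_fixture("open_field_20")
  b <- place_basis(euclidean_coords(gw), gw)
  expect_equal(ncol(b$Phi), 400)
  counts <- table(b$params$sigma_frac, useNA = "ifany")
  expect_equal(unname(c(counts)), c(225, 100, 49, 25, 1))
  # largest scale: sigma = 0.25 * 20 states
  expect_equal(max(b$params$sigma, na.rm = TRUE), 5)
  # every Gaussian column peaks at the state nearest its center
  co <- euclidean_coords(gw)$coords
  gauss <- which(b$params$kind == "gaussian")
  for (j in sample(gauss, 25)) {
    cen <- c(b$params$cx[j], b$params$cy[j])
    nearest <- which.min((co[, 1] - cen[1])^2 + (co[, 2] - cen[2])^2)
    expect_equal(which.max(b$raw[, j]), nearest)
  }
})

test_that("the grid-cell shift constant 1.5 is the numerical minimum", {
  # dense minimization of cos a + cos b + cos(a + b) over the phase torus
  a <- seq(0, 2 * pi, length.out = 721)
  g <- expand.grid(a = a, b = a)
  vals <- cos(g$a) + cos(g$b) + cos(g$a + g$b)
  expect_equal(min(vals), -1.5, tolerance = 1e-6)
  expect_equal(max(vals), 3, tolerance = 1e-6)
  # so grid_value spans [0, 4.5]
  xs <- as.matrix(expand.grid(x = seq(0, 20, by = 0.05),
                              y = seq(0, 20, by = 0.05)))
  v <- grid_value(xs, theta = 0, lambda = 5, p1 = 0, p2 = 0)
  expect_gte(min(v), 0)
  expect_equal(max(v), 4.5, tolerance = 1e-6)
})

test_that("grid_value is periodic along the lattice vectors", {
  lam <- 6.5; th <- pi / 7
  x0 <- matrix(runif(20, 0, 20), ncol = 2)
  # lattice translation: lam along theta (normal to the first wave vector
  # pair's mean) leaves all three plane waves unchanged
  shift <- lam * c(cos(th), sin(th))
  v0 <- grid_value(x0, th, lam, 1.1, 2.3)
  v1 <- grid_value(sweep(x0, 2, -shift), th, lam, 1.1, 2.3)
  expect_equal(v0, v1, tolerance = 1e-9)
})

test_that("grid basis has 401 columns, nonnegative, 5x5 phase lattice", {
  gw <- make_fixture("open_field_20")
  b <- grid_basis(euclidean_coords(gw), gw)
  expect_equal(ncol(b$Phi), 401)
  expect_true(all(b$raw >= 0))
  gridpar <- b$params[b$params$kind == "grid", ]
  expect_equal(nrow(gridpar), 400)
  expect_equal(length(unique(gridpar$theta)), 4)
  expect_equal(length(unique(gridpar$lambda_frac)), 4)
  phases <- unique(gridpar[, c("p1", "p2")])
  expect_equal(nrow(phases), 25)
  expect_equal(sort(unique(gridpar$p1)), seq(0, 2 * pi, length.out = 6)[1:5])
  expect_equal(gridpar$p3, gridpar$p1 + gridpar$p2)
})

test_that("row L2 normalization", {
  expect_equal(l2_row_normalize(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  expect_equal(l2_row_normalize(diag(4)), diag(4))
  m <- matrix(runif(30), 5)
  nrm <- sqrt(rowSums(l2_row_normalize(m)^2))
  expect_equal(nrm, rep(1, 5), tolerance = 1e-12)
  expect_warning(out <- l2_row_normalize(rbind(c(1, 1), c(0, 0))), "zero")
  expect_equal(out[2, ], c(0, 0))
})

test_that("geodesic and Euclidean bases share identical per-column params", {
  gw <- make_fixture("bisect_20")
  be <- build_basis(gw, "place", "euclidean")
  bg <- build_basis(gw, "place", "geodesic")
  expect_equal(be$params$cx, bg$params$cx)
  expect_equal(be$params$cy, bg$params$cy)
  expect_equal(be$params$sigma_frac, bg$params$sigma_frac)
  ge <- build_basis(gw, "grid", "euclidean")
  gg <- build_basis(gw, "grid", "geodesic")
  expect_equal(ge$params[, c("theta", "lambda_frac", "p1", "p2")],
               gg$params[, c("theta", "lambda_frac", "p1", "p2")])
})

test_that("open-field geodesic fields match their Euclidean counterparts", {
  gw <- build_layout("open_field", 10, 10, goal = 100)
  for (fam in c("place", "grid")) {
    be <- build_basis(gw, fam, "euclidean")
    bg <- build_basis(gw, fam, "geodesic")
    keep <- be$params$kind != "constant"
    cors <- vapply(which(keep),
                   function(j) cor(be$raw[, j], bg$raw[, j]), numeric(1))
    expect_gte(min(cors), 0.9)
  }
})

test_that("a barrier bisecting a place field lowers its geodesic peak", {
  open <- make_fixture("open_field_20")
  walled <- make_fixture("bisect_20")
  # the place column nearest the barrier midline (x = 9.5)
  b0 <- place_basis(geodesic_embedding(open), open)
  b1 <- place_basis(geodesic_embedding(walled), walled)
  j <- with(b0$params, which(kind == "gaussian" & sigma_frac == 0.1))
  j <- j[which.min((b0$params$cx[j] - 9.5)^2 + (b0$params$cy[j] - 9.5)^2)]
  expect_lt(max(b1$raw[, j]), max(b0$raw[, j]))
})
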