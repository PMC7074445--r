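test_that("knn connectivity: collinear chain, complete graph, row normalization", {
  pts <- tibble::tibble(lat = c(40, 40, 40), lon = c(-6, -5, -4))
  net <- knn_network(pts, k = 1, row_normalize = FALSE)
  w <- net$w
  # middle point is linked to both ends after symmetrization
  expect_equal(unname(w[2, ]), c(1, 0, 1))
  expect_equal(unname(w[, 2]), c(1, 0, 1))

  set.seed(40)
  pts2 <- rand_coords(7)
  full <- knn_network(pts2, k = 6, row_normalize = FALSE)
  expect_equal(unname(full$w), 1 - diag(7))

  rn <- knn_network(pts2, k = 3, row_normalize = TRUE)
  expect_equal(unname(rowSums(rn$w)), rep(1, 7), tolerance = 1e-12)
  expect_equal(unname(diag(rn$w)), rep(0, 7))
})

test_that("duplicate coordinates warn and resolve ties by index", {
  pts <- tibble::tibble(lat = c(40, 40, 41), lon = c(-6, -6, -6))
  expect_warning(knn_network(pts, k = 1), "duplicate coordinates")
})

test_that("Moran's I is -1 for an alternating signal on an even cycle", {
  n <- 6
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, (i %% n) + 1] <- 0.5
    w[i, ((i - 2) %% n) + 1] <- 0.5
  }
  x <- rep(c(1, -1), n / 2)
  # direct summation oracle
  xc <- x - mean(x)
  oracle <- (n / sum(w)) * sum(outer(xc, xc) * w) / sum(xc^2)
  expect_equal(oracle, -1)
  expect_equal(morans_i(x, w), -1, tolerance = 1e-12)
  expect_equal(morans_i(x, w), oracle, tolerance = 1e-14)
})

test_that("Moran's I agrees with ape::Moran.I on a random network", {
  skip_if_not_installed("ape")
  set.seed(41)
  net <- knn_network(rand_coords(25), k = 4, row_normalize = TRUE)
  x <- rnorm(25)
  ours <- morans_i(x, net)
  theirs <- ape::Moran.I(x, weight = net$w, scaled = FALSE)$observed
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("Moran's I rejects constant input", {
  set.seed(42)
  net <- knn_network(rand_coords(10), k = 3)
  expect_error(morans_i(rep(2, 10), net), "constant")
})

test_that("the Moran eigenbasis is orthonormal, centred, and complete", {
  set.seed(43)
  net <- knn_network(rand_coords(12), k = 3)
  basis <- moran_eigenbasis(net)
  v <- basis$vectors
  expect_equal(ncol(v), 11)
  expect_equal(crossprod(v), diag(11), tolerance = 1e-10)
  expect_lt(max(abs(colSums(v))), 1e-10)

  # 4-node path graph: n - 1 = 3 vectors
  path <- matrix(0, 4, 4)
  path[cbind(1:3, 2:4)] <- 1
  path <- path + t(path)
  expect_equal(ncol(moran_eigenbasis(path)$vectors), 3)
})

test_that("eigenvector Moran's I obeys I = n*lambda/sum(W) and is monotone", {
  set.seed(44)
  net <- knn_network(rand_coords(15), k = 4, row_normalize = TRUE)
  basis <- moran_eigenbasis(net)
  n <- 15
  for (j in seq_len(ncol(basis$vectors))) {
    expect_equal(
      morans_i(basis$vectors[, j], net),
      n * basis$eigenvalues[j] / sum(net$w),
      tolerance = 1e-10
    )
  }
  expect_equal(basis$morans_i, sort(basis$morans_i, decreasing = TRUE))
  expect_equal(basis$eigenvalues, sort(basis$eigenvalues, decreasing = TRUE))
})

test_that("attainable Moran's I extremes on a row-normalized KNN network cover [-1, 1] claims", {
  set.seed(45)
  net <- knn_network(rand_coords(20), k = 5, row_normalize = TRUE)
  basis <- moran_eigenbasis(net)
  # extremes equal n*lambda/sum(W) by construction; check they bound every
  # observed I and straddle zero (network-dependent, not exactly +-1)
  x <- rnorm(20)
  i_obs <- morans_i(x, net)
  expect_lte(i_obs, max(basis$morans_i) + 1e-12)
  expect_gte(i_obs, min(basis$morans_i) - 1e-12)
  expect_gt(max(basis$morans_i), 0)
  expect_lt(min(basis$morans_i), 0)
})

test_that("IDW interpolation is exact at samples, constant-preserving, and matches its formula", {
  set.seed(46)
  coords <- rand_coords(8)
  scores <- rnorm(8)

  const <- interpolate_scores(rep(2.5, 8), coords, n_lat = 10, n_lon = 10)
  expect_true(all(abs(const$value[!is.na(const$value)] - 2.5) < 1e-12))

  # put one sample exactly at the bounding-box corner so it lands on a grid node
  coords$lat[1] <- min(coords$lat) - 0.1
  coords$lon[1] <- min(coords$lon) - 0.1
  g <- interpolate_scores(scores, coords, n_lat = 25, n_lon = 25)
  hit <- g[abs(g$lat - coords$lat[1]) < 1e-9 & abs(g$lon - coords$lon[1]) < 1e-9, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$value, scores[1], tolerance = 1e-12)

  # direct IDW recomputation at random interior cells
  gg <- g[!is.na(g$value), ]
  idx <- sample(nrow(gg), 10)
  for (i in idx) {
    d <- geosphere::distHaversine(c(gg$lon[i], gg$lat[i]),
                                  cbind(coords$lon, coords$lat))
    if (min(d) < 1e-6) next
    expect_equal(gg$value[i], sum(scores / d^2) / sum(1 / d^2),
                 tolerance = 1e-10)
  }
})

test_that("interpolation masks cells outside the convex hull", {
  # L-shaped sample cloud leaves the far corner of the bounding box outside
  coords <- tibble::tibble(
    lat = c(40, 40, 40, 41, 42, 42),
    lon = c(-6, -5, -4, -6, -6, -5.5)
  )
  g <- interpolate_scores(rnorm(6), coords, n_lat = 20, n_lon = 20)
  far_corner <- g[g$lat > 41.8 & g$lon > -4.2, ]
  expect_true(all(is.na(far_corner$value)))
  expect_true(any(!is.na(g$value)))
})
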