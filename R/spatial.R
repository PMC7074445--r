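#' K-nearest-neighbour connection network
#'
#' Models spatial connectivity among sampling units: each node is linked to
#' its `k` nearest neighbours by great-circle (haversine) distance, the
#' binary adjacency is symmetrized (an edge is kept if present in either
#' direction), and the rows are optionally normalized to sum to one (the
#' weighting used by the sPCA). Ties in neighbour distance are broken by node
#' index order, with a warning when exact coordinate duplicates make the
#' neighbour set ill-defined.
#'
#' @param coords Tibble with `lat`, `lon` in decimal degrees (id column, if
#'   any, is kept as node names), or a 2-column lon/lat matrix.
#' @param k Number of nearest neighbours (default 5).
#' @param row_normalize Normalize rows of the symmetrized adjacency
#'   (default `TRUE`).
#' @return Object of class `cline_network`: `w` (n x n weight matrix),
#'   `coords` (tibble `lat`, `lon`), `k`, `row_normalized`.
#' @export
knn_network <- function(coords, k = 5L, row_normalize = TRUE) {
  if (is.matrix(coords)) {
    coords <- tibble(lon = coords[, 1], lat = coords[, 2])
  }
  stopifnot(all(c("lat", "lon") %in% names(coords)))
  n <- nrow(coords)
  if (n < k + 1) abort("need at least k + 1 nodes")
  ids <- if ("colony_id" %in% names(coords)) coords$colony_id
  else if ("site_id" %in% names(coords)) coords$site_id
  else as.character(seq_len(n))
  ll <- cbind(coords$lon, coords$lat)
  if (anyDuplicated(ll)) {
    warn("duplicate coordinates: nearest neighbours resolved by node index order")
  }
  d <- geosphere::distm(ll, fun = geosphere::distHaversine)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # order() is stable, so equal distances resolve by index
    nb <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  w <- adj
  if (row_normalize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  dimnames(w) <- list(ids, ids)
  structure(
    list(w = w, coords = tibble(lat = coords$lat, lon = coords$lon),
         k = as.integer(k), row_normalized = row_normalize),
    class = "cline_network"
  )
}

#' @export
print.cline_network <- function(x, ...) {
  cat(sprintf("KNN connection network: %d nodes, k = %d, %d undirected edges%s\n",
              nrow(x$w), x$k, sum(x$w > 0) / 2,
              if (x$row_normalized) ", row-normalized" else ""))
  invisible(x)
}

network_w <- function(network) {
  if (inherits(network, "cline_network")) network$w else as.matrix(network)
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = \frac{n}{\sum_{ij} W_{ij}} \;
#'   \frac{\sum_{ij} W_{ij} (x_i - \bar x)(x_j - \bar x)}
#'        {\sum_i (x_i - \bar x)^2}}
#'
#' Positive values mean neighbours carry more similar values than randomly
#' chosen nodes (global structure: clines, patches); negative values mean
#' neighbours are more different (local structure).
#'
#' @param x Numeric vector, one value per network node; must not be constant.
#' @param network A `cline_network` (or raw weight matrix).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, network) {
  w <- network_w(network)
  n <- length(x)
  stopifnot(nrow(w) == n)
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss < .Machine$double.eps) {
    abort("Moran's I is undefined for a constant vector (zero variance)")
  }
  (n / sum(w)) * as.numeric(t(xc) %*% w %*% xc) / ss
}

#' Moran eigenvector basis of a connection network
#'
#' Eigen-analysis of the doubly centred symmetric weight operator
#' `(I - 11'/n) (W + W')/2 (I - 11'/n)`: the n - 1 orthonormal eigenvectors
#' orthogonal to the constant vector, each a spatial pattern with its own
#' Moran's I (`I = n * lambda / sum(W)`). These are the spatial predictors
#' regressed against the data columns in [structure_test()].
#'
#' @param network A `cline_network` (or weight matrix).
#' @return Object of class `moran_eigenbasis`: `vectors` (n x (n-1),
#'   orthonormal, eigenvalue-descending), `eigenvalues`, `morans_i`
#'   (per vector).
#' @export
moran_eigenbasis <- function(network) {
  w <- network_w(network)
  n <- nrow(w)
  if (n < 3) abort("need at least 3 nodes for a Moran eigenbasis")
  sym <- (w + t(w)) / 2
  # restrict to the orthogonal complement of the constant vector via an
  # explicit orthonormal basis, so the n-1 vectors are exactly orthogonal to 1
  q <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  e <- eigen(crossprod(q, sym %*% q), symmetric = TRUE)
  vec <- q %*% e$vectors
  structure(
    list(
      vectors = vec,
      eigenvalues = e$values,
      morans_i = n * e$values / sum(w)
    ),
    class = "moran_eigenbasis"
  )
}

#' @export
print.moran_eigenbasis <- function(x, ...) {
  cat(sprintf("Moran eigenbasis: %d vectors, Moran's I in [%.3f, %.3f]\n",
              ncol(x$vectors), min(x$morans_i), max(x$morans_i)))
  invisible(x)
}

#' Inverse-distance interpolation of scores onto a geographic grid
#'
#' Interpolates per-node scores (typically the first global sPCA score) onto
#' a regular latitude/longitude grid by inverse great-circle-distance
#' weighting with power 2. Interpolation is exact at sample locations; grid
#' cells outside the samples' convex hull are masked to `NA` so the surface
#' is not extrapolated.
#'
#' @param scores Numeric vector, one value per location.
#' @param coords Tibble `lat`, `lon` of the sample locations.
#' @param n_lat,n_lon Grid resolution (cells per axis).
#' @param power IDW exponent (default 2).
#' @return Tibble `lat`, `lon`, `value` (NA outside the convex hull).
#' @export
interpolate_scores <- function(scores, coords, n_lat = 50L, n_lon = 50L,
                               power = 2) {
  stopifnot(length(scores) == nrow(coords), n_lat >= 1, n_lon >= 1)
  pts <- cbind(coords$lon, coords$lat)
  if (nrow(unique(pts)) < 3) abort("need at least 3 distinct points")
  lat_seq <- seq(min(coords$lat), max(coords$lat), length.out = n_lat)
  lon_seq <- seq(min(coords$lon), max(coords$lon), length.out = n_lon)
  grid <- expand.grid(lon = lon_seq, lat = lat_seq)
  d <- geosphere::distm(as.matrix(grid), pts, fun = geosphere::distHaversine)
  val <- numeric(nrow(grid))
  exact <- apply(d, 1, function(r) {
    hit <- which(r < 1e-6)
    if (length(hit) > 0) hit[1] else NA_integer_
  })
  on_pt <- !is.na(exact)
  val[on_pt] <- scores[exact[on_pt]]
  if (any(!on_pt)) {
    wts <- 1 / d[!on_pt, , drop = FALSE]^power
    val[!on_pt] <- (wts %*% scores) / rowSums(wts)
  }
  hull <- grDevices::chull(pts)
  inside <- mgcv::in.out(rbind(pts[hull, , drop = FALSE], pts[hull[1], ]),
                         as.matrix(grid))
  val[!inside & !on_pt] <- NA_real_
  tibble(lat = grid$lat, lon = grid$lon, value = val)
}
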