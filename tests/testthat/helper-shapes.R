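# shared fixtures: random shapes, similarity transforms, rotation oracles

rand_shape <- function(k = 19) {
  matrix(rnorm(2 * k), ncol = 2)
}

# apply rotation (radians), scale, and offset to a k x 2 shape
sim_transform <- function(shape, angle = 0, scale = 1, shift = c(0, 0)) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(shape %*% r * scale, 2, shift, "+")
}

rand_transform <- function(shape) {
  sim_transform(shape,
                angle = runif(1, -pi, pi),
                scale = exp(runif(1, -1, 1)),
                shift = rnorm(2, sd = 5))
}

# independent rotation oracle: residual sum of squares of a onto b minimised
# over a grid of rotation angles
grid_rotation_rss <- function(a, b, step = 0.001) {
  angles <- seq(-pi, pi, by = step)
  rss <- vapply(angles, function(th) {
    sum((sim_transform(a, angle = th) - b)^2)
  }, numeric(1))
  list(angle = angles[which.min(rss)], rss = min(rss))
}

# long landmark tibble from a list of k x 2 matrices
shapes_to_tibble <- function(shapes, ids = NULL) {
  ids <- ids %||% paste0("w", seq_along(shapes))
  dplyr::bind_rows(lapply(seq_along(shapes), function(i) {
    tibble::tibble(
      wing_id = ids[i],
      lm = seq_len(nrow(shapes[[i]])),
      x = shapes[[i]][, 1],
      y = shapes[[i]][, 2]
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic design used where full scale is not needed
tiny_sim <- function(seed, ...) {
  simulate_cline(sim_config(
    sites_per_transect = c(2, 2, 2), apiaries_per_site = 2,
    colonies_per_apiary = 2, wings_per_colony = 3, n_loci = 40,
    seed = seed, ...
  ))
}

# scattered coordinates for network fixtures
rand_coords <- function(n, lat0 = 38, lon0 = -6, spread = 3) {
  tibble::tibble(
    lat = lat0 + runif(n, 0, spread),
    lon = lon0 + runif(n, 0, spread)
  )
}

# rebuild the flattened (x1..xk, y1..yk) matrix from a long shape tibble the
# same way the ordination functions see it
flatten_via_pkg <- function(shapes) {
  ids <- unique(shapes$colony_id)
  k <- length(unique(shapes$lm))
  s <- shapes[order(match(shapes$colony_id, ids), shapes$lm), ]
  cbind(matrix(s$x, length(ids), k, byrow = TRUE),
        matrix(s$y, length(ids), k, byrow = TRUE))
}
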