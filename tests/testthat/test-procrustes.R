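test_that("filter_missing partitions wings exhaustively and disjointly", {
  set.seed(2)
  wings <- shapes_to_tibble(replicate(6, rand_shape(), simplify = FALSE))
  wings$missing <- FALSE
  wings$missing[wings$wing_id == "w2" & wings$lm == 4] <- TRUE
  wings$missing[wings$wing_id == "w5" & wings$lm %in% c(1, 9)] <- TRUE
  out <- filter_missing(wings)
  expect_setequal(unique(out$kept$wing_id), c("w1", "w3", "w4", "w6"))
  expect_setequal(unique(out$removed$wing_id), c("w2", "w5"))
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(wings))

  wings$missing <- FALSE
  expect_equal(nrow(filter_missing(wings)$removed), 0)
  empty <- wings[0, ]
  out0 <- filter_missing(empty)
  expect_equal(nrow(out0$kept), 0)
  expect_equal(nrow(out0$removed), 0)
})

test_that("preshape centres, scales, and is translation invariant", {
  sq <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), ncol = 2)  # corners (+-1, +-1)
  ps <- preshape(sq)
  expect_equal(colMeans(ps$coords), c(0, 0))
  expect_equal(ps$centroid_size, sqrt(8))
  expect_equal(abs(ps$coords), matrix(1 / sqrt(8), 4, 2))

  expect_equal(preshape(ps$coords)$coords, ps$coords)
  expect_equal(preshape(ps$coords)$centroid_size, 1)

  set.seed(3)
  s <- rand_shape()
  shifted <- sweep(s, 2, c(13.5, -2.25), "+")
  expect_equal(preshape(shifted)$coords, preshape(s)$coords)

  expect_error(preshape(matrix(1, 19, 2)), "degenerate")
})

test_that("optimal_rotation recovers a known rotation and the identity", {
  set.seed(4)
  a <- preshape(rand_shape())$coords
  b <- sim_transform(a, angle = 30 * pi / 180)
  r <- optimal_rotation(a, b)
  expect_equal(det(r), 1)
  expect_lt(sum((a %*% r - b)^2), 1e-12)
  expect_equal(optimal_rotation(a, a), diag(2), tolerance = 1e-12)
})

test_that("closed-form rotation matches a 0.001-rad grid search (5-landmark pairs)", {
  set.seed(5)
  for (i in 1:5) {
    a <- preshape(rand_shape(5))$coords
    b <- preshape(rand_shape(5))$coords
    rss_closed <- sum((a %*% optimal_rotation(a, b) - b)^2)
    rss_grid <- grid_rotation_rss(a, b)$rss
    expect_lt(abs(rss_closed - rss_grid), 1e-5)
    expect_lte(rss_closed, rss_grid + 1e-12)
  }
})

test_that("gpa aligns similarity-transformed copies of one shape exactly", {
  set.seed(6)
  base <- rand_shape()
  shapes <- c(list(base), replicate(7, rand_transform(base), simplify = FALSE))
  fit <- gpa(shapes_to_tibble(shapes))
  expect_true(fit$converged)
  aligned <- split(fit$aligned, fit$aligned$wing_id)
  mats <- lapply(aligned, function(a) cbind(a$x, a$y))
  for (m in mats[-1]) expect_lt(max(abs(m - mats[[1]])), 1e-9)
  for (m in mats[-1]) expect_lt(procrustes_distance(m, mats[[1]]), 1e-9)
})

test_that("gpa consensus is order-invariant up to rotation", {
  set.seed(7)
  # random shapes are far more dispersed than wings, so allow extra iterations
  shapes <- replicate(6, rand_shape(), simplify = FALSE)
  f1 <- gpa(shapes_to_tibble(shapes), tol = 1e-12, max_iter = 2000)
  f2 <- gpa(shapes_to_tibble(rev(shapes), ids = paste0("w", 6:1)),
            tol = 1e-12, max_iter = 2000)
  expect_true(f1$converged && f2$converged)
  c1 <- cbind(f1$consensus$x, f1$consensus$y)
  c2 <- cbind(f2$consensus$x, f2$consensus$y)
  expect_lt(procrustes_distance(c1, c2), 1e-8)
})

test_that("gpa aligned shapes have origin centroids and a unit-size consensus", {
  set.seed(8)
  fit <- gpa(shapes_to_tibble(replicate(5, rand_shape(), simplify = FALSE)))
  cents <- fit$aligned |>
    dplyr::group_by(wing_id) |>
    dplyr::summarise(cx = mean(x), cy = mean(y))
  expect_lt(max(abs(c(cents$cx, cents$cy))), 1e-12)
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  expect_equal(sqrt(sum(sweep(cons, 2, colMeans(cons))^2)), 1, tolerance = 1e-10)
})

test_that("gpa matches an independent alternating-optimization oracle", {
  # oracle: same model, but rotations found by 1-D numerical optimization and
  # iterated to a 10x tighter tolerance
  oracle_gpa_variance <- function(shapes, tol = 1e-11) {
    mats <- lapply(shapes, function(s) preshape(s)$coords)
    cons <- mats[[1]]
    repeat {
      mats <- lapply(mats, function(m) {
        f <- function(th) sum((sim_transform(m, angle = th) - cons)^2)
        th <- stats::optimize(f, c(-pi, pi), tol = 1e-12)$minimum
        sim_transform(m, angle = th)
      })
      new_cons <- Reduce(`+`, mats) / length(mats)
      new_cons <- preshape(new_cons)$coords
      if (sqrt(mean((new_cons - cons)^2)) < tol) break
      cons <- new_cons
    }
    sum(vapply(mats, function(m) sum((m - cons)^2), numeric(1)))
  }
  set.seed(9)
  shapes <- replicate(3, rand_shape(), simplify = FALSE)
  fit <- gpa(shapes_to_tibble(shapes))
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  v_pkg <- fit$aligned |>
    dplyr::group_by(wing_id) |>
    dplyr::summarise(ss = sum((x - cons[, 1])^2 + (y - cons[, 2])^2)) |>
    dplyr::pull(ss) |>
    sum()
  expect_equal(v_pkg, oracle_gpa_variance(shapes), tolerance = 1e-6)
})

test_that("total distance to consensus is non-increasing over gpa iterations", {
  set.seed(10)
  shapes <- replicate(8, rand_shape(), simplify = FALSE)
  # track the objective by running gpa with increasing iteration caps
  obj <- vapply(1:6, function(it) {
    fit <- gpa(shapes_to_tibble(shapes), max_iter = it)
    cons <- cbind(fit$consensus$x, fit$consensus$y)
    fit$aligned |>
      dplyr::group_by(wing_id) |>
      dplyr::summarise(ss = sum((x - cons[, 1])^2 + (y - cons[, 2])^2)) |>
      dplyr::pull(ss) |>
      sum()
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-12))
})

test_that("procrustes_distance is a similarity-invariant metric", {
  set.seed(11)
  s1 <- rand_shape()
  expect_lt(procrustes_distance(s1, rand_transform(s1)), 1e-10)
  for (i in 1:10) {
    a <- rand_shape(); b <- rand_shape(); c <- rand_shape()
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-12)
    expect_lte(
      procrustes_distance(a, c),
      procrustes_distance(a, b) + procrustes_distance(b, c) + 1e-9
    )
  }
})

test_that("procrustes_distance agrees with the rotation grid-search oracle", {
  t1 <- rbind(c(0, 0), c(1, 0), c(0.3, 0.9), matrix(0.5, 16, 2) + cbind(seq(0, 0.75, length.out = 16), 0))
  t2 <- rbind(c(0, 0), c(1.2, 0.1), c(0.1, 1.1), matrix(0.4, 16, 2) + cbind(0, seq(0, 0.75, length.out = 16)))
  a <- preshape(t1)$coords
  b <- preshape(t2)$coords
  expect_equal(procrustes_distance(t1, t2), sqrt(grid_rotation_rss(a, b)$rss),
               tolerance = 1e-5)
})

test_that("colony means average aligned wings per landmark", {
  set.seed(12)
  base <- preshape(rand_shape())$coords
  aligned <- shapes_to_tibble(list(base, base, sweep(base, 2, c(0.2, 0), "+")),
                              ids = c("w1", "w2", "w3"))
  meta <- tibble::tibble(wing_id = c("w1", "w2", "w3"),
                         colony_id = c("c1", "c1", "c2"))
  out <- colony_means(aligned, meta)
  m1 <- out[out$colony_id == "c1", ]
  expect_equal(m1$x, base[, 1])
  expect_equal(unique(m1$n_wings), 2L)
  m2 <- out[out$colony_id == "c2", ]
  expect_equal(m2$x, base[, 1] + 0.2)

  # linearity: colony of a shape and a +0.2-shifted copy averages to +0.1
  aligned2 <- shapes_to_tibble(list(base, sweep(base, 2, c(0.2, 0), "+")))
  meta2 <- tibble::tibble(wing_id = c("w1", "w2"), colony_id = "c")
  expect_equal(colony_means(aligned2, meta2)$x, base[, 1] + 0.1)

  expect_warning(
    colony_means(aligned, dplyr::bind_rows(meta, tibble::tibble(wing_id = "w9", colony_id = "c9"))),
    "zero aligned wings"
  )
})
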