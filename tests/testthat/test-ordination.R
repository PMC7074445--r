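# helper: synthetic colony-mean shapes with a group mean difference along a
# known deformation axis
make_group_shapes <- function(n_per_group, delta, noise_sd = 0.01) {
  template <- template_wing()
  axis <- default_deformation_axis(template)
  shapes <- list()
  groups <- tibble::tibble(colony_id = character(), site_id = character())
  for (g in 1:2) {
    offset <- if (g == 2) delta else 0
    for (i in seq_len(n_per_group)) {
      id <- paste0("g", g, "_", i)
      s <- template + offset * axis +
        matrix(rnorm(38, sd = noise_sd), ncol = 2)
      shapes[[id]] <- s
      groups <- dplyr::bind_rows(groups,
                                 tibble::tibble(colony_id = id, site_id = paste0("S", g)))
    }
  }
  tbl <- shapes_to_tibble(shapes, ids = names(shapes))
  names(tbl)[1] <- "colony_id"
  list(shapes = tbl, groups = groups, axis = axis)
}

test_that("with identical group means the leading CVA eigenvalue sits in the permutation null", {
  set.seed(20)
  d <- make_group_shapes(30, delta = 0)
  fit <- cva(d$shapes, d$groups, n_pca_keep = 10)
  null_l1 <- vapply(1:199, function(b) {
    g <- d$groups
    g$site_id <- sample(g$site_id)
    cva(d$shapes, g, n_pca_keep = 10)$eigenvalues[1]
  }, numeric(1))
  expect_lt(fit$eigenvalues[1], quantile(null_l1, 0.95))
})

test_that("CV1 recovers a known between-group deformation axis", {
  set.seed(21)
  d <- make_group_shapes(200, delta = 0.05, noise_sd = 0.005)
  fit <- cva(d$shapes, d$groups, n_pca_keep = 10)
  # the difference vector between group means, flattened in x1..x19,y1..y19 order
  diff_vec <- as.vector(d$axis)
  cv1 <- fit$loadings[, 1]
  cosine <- sum(cv1 * diff_vec) / sqrt(sum(cv1^2) * sum(diff_vec^2))
  expect_gt(abs(cosine), 0.99)
})

test_that("canonical eigenvalues are invariant to invertible linear maps of the variables", {
  set.seed(22)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6)
  g <- rep(c("A", "B"), each = n / 2)
  x[g == "B", 1] <- x[g == "B", 1] + 1.5
  # wrap plain variables as fake landmark data (3 landmark pairs)
  as_shape_tbl <- function(m) {
    tibble::tibble(
      colony_id = rep(paste0("c", seq_len(nrow(m))), each = 3),
      lm = rep(1:3, nrow(m)),
      x = as.vector(t(m[, 1:3])),
      y = as.vector(t(m[, 4:6]))
    )
  }
  a <- matrix(rnorm(36), 6, 6) + diag(6) * 2
  f1 <- cva(as_shape_tbl(x), g, n_pca_keep = 6)
  f2 <- cva(as_shape_tbl(x %*% a), g, n_pca_keep = 6)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
})

test_that("CVA scores are centred and the leading axis matches MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(23)
  d <- make_group_shapes(40, delta = 0.04)
  fit <- cva(d$shapes, d$groups, n_pca_keep = 8)
  sc <- as.matrix(fit$scores[paste0("CV", seq_along(fit$eigenvalues))])
  expect_lt(max(abs(colMeans(sc))), 1e-10)

  # independent route: lda on the same PCA projection
  x <- stats::prcomp(scale(flatten_via_pkg(d$shapes), center = TRUE, scale = FALSE))$x[, 1:8]
  g <- d$groups$site_id[match(unique(d$shapes$colony_id), d$groups$colony_id)]
  ld <- MASS::lda(x, grouping = g)
  s_lda <- as.vector(x %*% ld$scaling[, 1])
  cosine <- abs(cor(s_lda, sc[, 1]))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("site mean shapes average colony means, excluding empty sites", {
  set.seed(24)
  base <- template_wing()
  shapes <- shapes_to_tibble(
    list(base, base, sweep(base, 2, c(0.1, 0), "+")),
    ids = c("c1", "c2", "c3")
  )
  names(shapes)[1] <- "colony_id"
  groups <- tibble::tibble(colony_id = c("c1", "c2", "c3"),
                           site_id = c("S1", "S1", "S2"))
  out <- site_mean_shapes(shapes, groups)
  expect_equal(out$x[out$site_id == "S1"], base[, 1])
  expect_equal(out$x[out$site_id == "S2"], base[, 1] + 0.1)
  expect_equal(unique(out$n_colonies[out$site_id == "S1"]), 2L)

  # one colony in a site: the site mean is that colony's mean
  single <- site_mean_shapes(shapes[shapes$colony_id == "c3", ],
                             groups[groups$colony_id == "c3", ])
  expect_equal(single$x, base[, 1] + 0.1)
})

test_that("pairwise_procrustes matches per-pair calls and is a valid distance matrix", {
  set.seed(25)
  sites <- paste0("S", 1:4)
  means <- lapply(sites, function(s) template_wing() + matrix(rnorm(38, sd = 0.01), ncol = 2))
  tbl <- shapes_to_tibble(means, ids = sites)
  names(tbl)[1] <- "site_id"
  dm <- pairwise_procrustes(tbl)
  m <- as.matrix(dm)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 4), sites))
  for (i in 2:4) {
    expect_equal(m[i, 1], procrustes_distance(means[[i]], means[[1]]),
                 tolerance = 1e-12)
  }
  # identical means give a zero matrix
  tbl0 <- shapes_to_tibble(list(means[[1]], means[[1]]), ids = c("A", "B"))
  names(tbl0)[1] <- "site_id"
  expect_lt(max(as.matrix(pairwise_procrustes(tbl0))), 1e-10)
})

test_that("tidy() on a distance matrix returns the lower triangle", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  td <- tidy(dist_matrix(m))
  expect_equal(nrow(td), 3)
  expect_equal(td$distance[td$item1 == "a" & td$item2 == "c"], 2)
})
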