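#' Distance matrix container
#'
#' Small labelled symmetric-matrix class shared by the shape-distance and
#' F_ST outputs. `tidy()` returns the lower triangle as a long tibble.
#'
#' @param values m x m symmetric numeric matrix, zero diagonal.
#' @param labels Row/column labels (defaults to dimnames).
#' @return Object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  if (max(abs(values - t(values))) > 1e-12) {
    abort("distance matrix is not symmetric within 1e-12")
  }
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "dist_matrix")
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix over %d units\n", length(x$labels)))
  print(round(x$values, 5))
  invisible(x)
}

#' @rdname dist_matrix
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dist_matrix <- function(x, ...) {
  m <- x$values
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble(
    item1 = x$labels[idx[, 2]],
    item2 = x$labels[idx[, 1]],
    distance = m[idx]
  )
}

# long colony-shape tibble -> n x 2k matrix of flattened coordinates
flatten_shapes <- function(shapes, id_col = "colony_id") {
  stopifnot(all(c(id_col, "lm", "x", "y") %in% names(shapes)))
  ids <- unique(shapes[[id_col]])
  k <- length(unique(shapes$lm))
  ord <- order(match(shapes[[id_col]], ids), shapes$lm)
  s <- shapes[ord, ]
  m <- cbind(
    matrix(s$x, nrow = length(ids), ncol = k, byrow = TRUE),
    matrix(s$y, nrow = length(ids), ncol = k, byrow = TRUE)
  )
  colnames(m) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  rownames(m) <- ids
  m
}

#' Canonical variate analysis of colony mean shapes
#'
#' Ordination maximising between-group relative to pooled within-group
#' variance of the flattened Procrustes coordinates. Superimposed coordinates
#' are rank deficient (4 dimensions lost to translation/scale/rotation, rank
#' at most 2k - 4), so the variables are first projected onto leading
#' principal components — by default enough to explain `var_keep` of the
#' variance — before solving the whitened between-group eigenproblem.
#'
#' @param shapes Colony mean shapes (tibble `colony_id`, `lm`, `x`, `y`,
#'   e.g. from [colony_means()]).
#' @param groups Tibble mapping `colony_id` to `site_id` (the CVA grouping),
#'   or a vector of group labels in colony order.
#' @param n_pca_keep Number of principal components retained before the CVA;
#'   `NULL` (default) keeps components explaining at least `var_keep` of the
#'   total variance.
#' @param var_keep Variance fraction for automatic component retention.
#' @return Object of class `wing_cva`: `scores` tibble (`colony_id`,
#'   `site_id`, `CV1`, ...), `loadings` (variables x axes, original
#'   coordinate space), `eigenvalues` (descending), `n_pca_used`.
#' @export
cva <- function(shapes, groups, n_pca_keep = NULL, var_keep = 0.999) {
  x <- flatten_shapes(shapes)
  if (is.data.frame(groups)) {
    stopifnot(all(c("colony_id", "site_id") %in% names(groups)))
    g <- groups$site_id[match(rownames(x), groups$colony_id)]
    if (anyNA(g)) abort("colonies without a site_id in `groups`")
  } else {
    stopifnot(length(groups) == nrow(x))
    g <- as.character(groups)
  }
  g <- factor(g)
  if (nlevels(g) < 2) abort("CVA needs at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 colonies")

  xc <- scale(x, center = TRUE, scale = FALSE)
  pc <- prcomp(xc, center = FALSE)
  if (is.null(n_pca_keep)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pca_keep <- which(cum >= var_keep)[1]
  }
  n_pca_keep <- min(n_pca_keep, sum(pc$sdev > 1e-10 * pc$sdev[1]))
  p <- pc$rotation[, seq_len(n_pca_keep), drop = FALSE]
  z <- xc %*% p

  n <- nrow(z)
  gm <- rowsum(z, g) / as.vector(table(g))
  zb <- gm[g, , drop = FALSE]           # group means per row
  within <- z - zb
  sw <- crossprod(within) / (n - nlevels(g))
  sb <- crossprod(sweep(gm, 2, colMeans(z)) * sqrt(as.vector(table(g)))) /
    (nlevels(g) - 1)
  ew <- eigen(sw, symmetric = TRUE)
  if (min(ew$values) < 1e-10 * max(ew$values)) {
    abort("singular pooled within-group covariance; reduce n_pca_keep")
  }
  wh <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pca_keep) %*% t(ew$vectors)
  eb <- eigen(wh %*% sb %*% wh, symmetric = TRUE)
  n_axes <- min(nlevels(g) - 1, n_pca_keep)
  vecs <- wh %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  loadings <- p %*% vecs
  colnames(loadings) <- paste0("CV", seq_len(n_axes))
  scores <- xc %*% loadings
  colnames(scores) <- colnames(loadings)

  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(colony_id = rownames(x), site_id = as.character(g)),
        as_tibble(scores)
      ),
      loadings = loadings,
      eigenvalues = eb$values[seq_len(n_axes)],
      n_pca_used = n_pca_keep,
      groups = levels(g)
    ),
    class = "wing_cva"
  )
}

#' @export
print.wing_cva <- function(x, ...) {
  cat(sprintf(
    "Canonical variate analysis: %d colonies, %d groups, %d axes (on %d PCs)\n",
    nrow(x$scores), length(x$groups), length(x$eigenvalues), x$n_pca_used
  ))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cva
#' @param x A `wing_cva`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wing_cva <- function(x, ...) x$scores

#' @rdname cva
#' @exportS3Method generics::glance
glance.wing_cva <- function(x, ...) {
  tibble(
    n_colonies = nrow(x$scores),
    n_groups = length(x$groups),
    n_axes = length(x$eigenvalues),
    n_pca_used = x$n_pca_used,
    lambda1 = x$eigenvalues[1]
  )
}

#' Per-site mean shapes
#'
#' Averages colony mean shapes within each site, giving the site-level
#' configurations between which pairwise Procrustes distances are reported.
#'
#' @param shapes Colony mean shapes (tibble with `colony_id`, `lm`, `x`, `y`).
#' @param groups Tibble `colony_id`, `site_id`, or vector of site labels in
#'   colony order.
#' @return Tibble `site_id`, `lm`, `x`, `y`, `n_colonies`.
#' @export
site_mean_shapes <- function(shapes, groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble(colony_id = unique(shapes$colony_id),
                     site_id = as.character(groups))
  }
  unmapped <- setdiff(unique(shapes$colony_id), groups$colony_id)
  if (length(unmapped) > 0) {
    abort(paste0("colonies without a site: ", paste(head(unmapped, 5), collapse = ", ")))
  }
  shapes$site_id <- NULL  # the grouping is taken from `groups`
  shapes |>
    left_join(groups[c("colony_id", "site_id")], by = "colony_id") |>
    group_by(.data$site_id, .data$lm) |>
    summarise(
      x = mean(.data$x), y = mean(.data$y),
      n_colonies = length(unique(.data$colony_id)), .groups = "drop"
    )
}

#' Pairwise Procrustes distances between site mean shapes
#'
#' @param site_means Tibble `site_id`, `lm`, `x`, `y` (from
#'   [site_mean_shapes()]).
#' @return A [dist_matrix()] of partial Procrustes distances.
#' @export
pairwise_procrustes <- function(site_means) {
  ids <- unique(site_means$site_id)
  if (length(ids) < 2) abort("need at least 2 sites")
  arrs <- lapply(ids, function(s) {
    w <- site_means[site_means$site_id == s, ]
    w <- w[order(w$lm), ]
    cbind(w$x, w$y)
  })
  m <- matrix(0, length(ids), length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      d <- procrustes_distance(arrs[[i]], arrs[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  dist_matrix(m, ids)
}
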