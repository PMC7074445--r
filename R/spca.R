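#' Spatial principal component analysis (sPCA)
#'
#' A modification of PCA whose axes maximise the product of the variance of
#' the scores and their spatial autocorrelation (Moran's I) on a connection
#' network, instead of variance alone. With column-centred data `Xc` and
#' row-normalized weights `L`, the analysed operator is
#' `H = Xc' (L + L') Xc / (2n)`; eigenvectors with positive eigenvalues are
#' *global* axes (clines, patches — neighbours similar), negative ones are
#' *local* axes (neighbours contrasting). For every axis the eigenvalue
#' equals `var(score) * I(score)` exactly (population variance, 1/n).
#'
#' @param features Feature tibble (one row per network node; id/`lat`/`lon`
#'   columns are ignored as features) or numeric matrix.
#' @param network A `cline_network` over the same nodes, in the same order.
#' @return Object of class `spca_fit`: `eigenvalues` (descending),
#'   `loadings`, `scores` tibble (node id + one column per axis, named
#'   `Axis1`...), `lag_scores` (network-smoothed scores), `axis_stats`
#'   tibble (`axis`, `eigenvalue`, `variance`, `morans_i`, `type`
#'   global/local).
#' @export
#' @examples
#' sim <- simulate_cline(sim_config(sites_per_transect = c(2, 2, 2),
#'                                  apiaries_per_site = 2, seed = 7))
#' net <- knn_network(sim$colonies, k = 5)
#' fit <- spca(sim$genotypes, net)
#' head(tidy(fit))
spca <- function(features, network) {
  x <- if (is.matrix(features)) features else feature_values(features)
  w <- network_w(network)
  n <- nrow(x)
  if (nrow(w) != n) abort("feature rows and network nodes differ in number")
  keep <- apply(x, 2, function(col) sd(col) > 0)
  if (!all(keep)) {
    warn(paste0("dropping zero-variance feature column(s): ",
                paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) abort("no non-constant feature columns")
  xc <- scale(x, center = TRUE, scale = FALSE)
  h <- crossprod(xc, (w + t(w)) %*% xc) / (2 * n)
  h <- (h + t(h)) / 2
  e <- eigen(h, symmetric = TRUE)
  scores <- xc %*% e$vectors
  lag <- w %*% scores
  variance <- colSums(scores^2) / n
  mi <- vapply(seq_len(ncol(scores)), function(j) {
    if (variance[j] < 1e-14) NA_real_ else morans_i(scores[, j], w)
  }, numeric(1))
  axes <- paste0("Axis", seq_len(ncol(scores)))
  colnames(scores) <- axes
  colnames(lag) <- axes
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(x), axes)
  ids <- rownames(x) %||% as.character(seq_len(n))
  structure(
    list(
      eigenvalues = e$values,
      loadings = loadings,
      scores = dplyr::bind_cols(tibble(id = ids), as_tibble(scores)),
      lag_scores = dplyr::bind_cols(tibble(id = ids), as_tibble(lag)),
      axis_stats = tibble(
        axis = axes,
        eigenvalue = e$values,
        variance = variance,
        morans_i = mi,
        type = ifelse(e$values >= 0, "global", "local")
      ),
      network = if (inherits(network, "cline_network")) network else NULL
    ),
    class = "spca_fit"
  )
}

#' @export
print.spca_fit <- function(x, ...) {
  cat(sprintf("sPCA: %d axes over %d nodes\n",
              length(x$eigenvalues), nrow(x$scores)))
  cat(sprintf("  first global axis: eigenvalue %.4g, Moran's I %.3f\n",
              x$eigenvalues[1], x$axis_stats$morans_i[1]))
  neg <- which(x$eigenvalues < 0)
  if (length(neg) > 0) {
    j <- neg[length(neg)]
    cat(sprintf("  first local axis:  eigenvalue %.4g, Moran's I %.3f\n",
                x$eigenvalues[j], x$axis_stats$morans_i[j]))
  }
  invisible(x)
}

#' @rdname spca
#' @param x An `spca_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spca_fit <- function(x, ...) x$axis_stats

#' @rdname spca
#' @exportS3Method generics::glance
glance.spca_fit <- function(x, ...) {
  neg <- which(x$eigenvalues < 0)
  tibble(
    n = nrow(x$scores),
    n_axes = length(x$eigenvalues),
    lambda_global1 = x$eigenvalues[1],
    morans_i_global1 = x$axis_stats$morans_i[1],
    lambda_local1 = if (length(neg)) x$eigenvalues[neg[length(neg)]] else NA_real_,
    morans_i_local1 = if (length(neg)) x$axis_stats$morans_i[neg[length(neg)]] else NA_real_
  )
}

#' Extract the first global (or local) score vector
#'
#' @param fit An `spca_fit`.
#' @param type `"global"` (most positive eigenvalue, the default) or
#'   `"local"` (most negative).
#' @return Tibble `id`, `score`.
#' @export
first_score <- function(fit, type = c("global", "local")) {
  type <- match.arg(type)
  j <- if (type == "global") 1L else length(fit$eigenvalues)
  if (type == "global" && fit$eigenvalues[j] < 0) {
    abort("no global (positive-eigenvalue) axis")
  }
  if (type == "local" && fit$eigenvalues[j] > 0) {
    abort("no local (negative-eigenvalue) axis")
  }
  tibble(id = fit$scores$id, score = fit$scores[[j + 1L]])
}

# 3-point moving average over a profile, edge-truncated
smooth_profile <- function(r2, window = 3L) {
  if (window <= 1L) return(r2)
  half <- (window - 1L) %/% 2L
  n <- length(r2)
  vapply(seq_len(n), function(j) {
    mean(r2[max(1L, j - half):min(n, j + half)])
  }, numeric(1))
}

# smoothed mean-R^2 profile(s) from standardized data and eigenbasis.
# us: n x (n-1) unit-norm centred eigenvectors; xs: n x p unit-norm centred
# columns. cor(col, u) is then just the cross product.
.max_t <- function(us, xs, pos, neg, window) {
  r2 <- rowMeans(crossprod(us, xs)^2)
  sm <- smooth_profile(r2, window)
  c(global = if (any(pos)) max(sm[pos]) else NA_real_,
    local = if (any(neg)) max(sm[neg]) else NA_real_)
}

#' Monte-Carlo test for global or local spatial structure
#'
#' Tests whether multivariate variation is distributed at random on the
#' connection network (null) or shows global/local spatial structure
#' (alternative). For each Moran eigenvector of the network, the mean over
#' feature columns of the squared correlation (coefficient of determination,
#' R-squared) between column and eigenvector is computed; the profile is
#' smoothed by a 3-point moving average over eigenvectors adjacent in
#' eigenvalue order (edge-truncated), and the test statistic max(t) is the
#' profile maximum over eigenvectors with positive Moran's I (global) or
#' negative (local). The null distribution comes from jointly permuting the
#' rows of the feature matrix; the p-value uses the
#' `(1 + b) / (1 + B)` estimator, so with B = 10,000 permutations the
#' attainable significance threshold is 1e-4.
#'
#' @param features Feature tibble or matrix (rows = network nodes, in order).
#' @param network A `cline_network`.
#' @param kind `"global"`, `"local"`, or `"both"` (shares one permutation
#'   pass between the two statistics and returns a list of two results).
#' @param nperm Number of Monte-Carlo permutations (default 10000).
#' @param seed Integer seed for the permutation stream (required: stochastic
#'   outputs must be reproducible).
#' @param window Smoothing window over the R-squared profile (default 3).
#' @return For a single kind, an object of class `structure_test` with
#'   `kind`, `observed_max_t`, `permuted_max_t`, `p_value`, `nperm`, `seed`;
#'   for `kind = "both"`, a named list `global`, `local` of such objects.
#' @export
structure_test <- function(features, network, kind = c("global", "local", "both"),
                           nperm = 10000L, seed, window = 3L) {
  kind <- match.arg(kind)
  if (missing(seed)) abort("`seed` is required for the permutation stream")
  if (nperm < 99) abort("use at least 99 permutations")
  x <- if (is.matrix(features)) features else feature_values(features)
  w <- network_w(network)
  n <- nrow(x)
  if (nrow(w) != n) abort("feature rows and network nodes differ in number")
  keep <- apply(x, 2, function(col) sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) abort("no non-constant feature columns")

  basis <- moran_eigenbasis(network)
  pos <- basis$morans_i > 0
  neg <- basis$morans_i < 0
  if (kind == "global" && !any(pos)) abort("network has no positive-I eigenvectors")
  if (kind == "local" && !any(neg)) abort("network has no negative-I eigenvectors")

  xc <- scale(x, center = TRUE, scale = FALSE)
  xs <- sweep(xc, 2, sqrt(colSums(xc^2)), "/")
  us <- basis$vectors  # unit-norm, centred by construction

  obs <- .max_t(us, xs, pos, neg, window)
  set.seed(seed)
  perm <- matrix(NA_real_, nrow = nperm, ncol = 2,
                 dimnames = list(NULL, c("global", "local")))
  for (b in seq_len(nperm)) {
    # permuting rows jointly keeps column means/norms, so xs stays standardized
    perm[b, ] <- .max_t(us, xs[sample.int(n), , drop = FALSE], pos, neg, window)
  }
  one <- function(kd) {
    structure(
      list(
        kind = kd,
        observed_max_t = unname(obs[kd]),
        permuted_max_t = unname(perm[, kd]),
        p_value = (1 + sum(perm[, kd] >= obs[kd])) / (1 + nperm),
        nperm = as.integer(nperm),
        seed = seed,
        window = as.integer(window)
      ),
      class = "structure_test"
    )
  }
  if (kind == "both") {
    list(global = one("global"), local = one("local"))
  } else {
    one(kind)
  }
}

#' @export
print.structure_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo %s structure test (%d permutations, seed %s)\n",
              x$kind, x$nperm, format(x$seed)))
  cat(sprintf("  observed max(t) = %.5g, p = %.4g\n", x$observed_max_t, x$p_value))
  invisible(x)
}

#' @rdname structure_test
#' @param x A `structure_test`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.structure_test <- function(x, ...) {
  tibble(
    kind = x$kind,
    observed_max_t = x$observed_max_t,
    p_value = x$p_value,
    nperm = x$nperm,
    seed = x$seed
  )
}
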