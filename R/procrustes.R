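#' Split wings into complete and incomplete sets
#'
#' Wings with one or more missing landmarks cannot enter Procrustes
#' superimposition and are removed from analysis; the partition is returned in
#' full so nothing is silently dropped. Haploid drones express wing-venation
#' anomalies (missing vein junctions) more often than diploid workers, so the
#' removed set is typically larger for drones.
#'
#' @param wings Landmark tibble (see [read_tps()]).
#' @return A list with tibbles `kept` (wings whose landmarks are all present)
#'   and `removed` (the complement); together they partition the input.
#' @export
filter_missing <- function(wings) {
  stopifnot(is.data.frame(wings))
  if (nrow(wings) == 0) {
    return(list(kept = wings, removed = wings))
  }
  check_landmark_cols(wings)
  bad_ids <- unique(wings$wing_id[wings$missing])
  list(
    kept = wings[!wings$wing_id %in% bad_ids, , drop = FALSE],
    removed = wings[wings$wing_id %in% bad_ids, , drop = FALSE]
  )
}

# long landmark tibble -> n x k x 2 array (wings in first-appearance order)
lm_array <- function(wings) {
  check_landmark_cols(wings, require_missing = FALSE)
  ids <- unique(wings$wing_id)
  k <- length(unique(wings$lm))
  ord <- order(match(wings$wing_id, ids), wings$lm)
  w <- wings[ord, ]
  if (nrow(w) != length(ids) * k) {
    abort("wings do not share a common landmark count")
  }
  arr <- array(NA_real_, dim = c(length(ids), k, 2),
               dimnames = list(ids, NULL, c("x", "y")))
  arr[, , 1] <- matrix(w$x, nrow = length(ids), ncol = k, byrow = TRUE)
  arr[, , 2] <- matrix(w$y, nrow = length(ids), ncol = k, byrow = TRUE)
  arr
}

lm_tibble <- function(arr, id_col = "wing_id") {
  ids <- dimnames(arr)[[1]] %||% as.character(seq_len(dim(arr)[1]))
  k <- dim(arr)[2]
  out <- tibble(
    rep(ids, each = k),
    lm = rep(seq_len(k), times = length(ids)),
    x = as.vector(t(arr[, , 1, drop = TRUE])),
    y = as.vector(t(arr[, , 2, drop = TRUE]))
  )
  names(out)[1] <- id_col
  out
}

#' Centre and scale one configuration to a preshape
#'
#' Translates the landmark configuration so its centroid sits at the origin
#' and scales it to unit centroid size. Centroid size is the square root of
#' the summed squared distances of the landmarks from their centroid — the
#' size measure removed by superimposition.
#'
#' @param coords k x 2 numeric matrix of landmark coordinates.
#' @return A list: `coords` (k x 2 preshape, centroid at origin, centroid
#'   size 1) and `centroid_size` (the original size, in input units).
#' @export
preshape <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  centred <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centred^2))
  if (cs < .Machine$double.eps^0.5) {
    abort("degenerate shape: all landmarks coincide (centroid size 0)")
  }
  list(coords = centred / cs, centroid_size = cs)
}

centroid_size <- function(coords) {
  centred <- sweep(as.matrix(coords), 2, colMeans(coords))
  sqrt(sum(centred^2))
}

#' Optimal rotation of one preshape onto another
#'
#' Closed-form orthogonal (Kabsch/SVD) solution for the proper rotation R
#' (det +1) minimising ||A R - B||_F. Reflections are suppressed: all wings
#' are right forewings, so an improper alignment is never meaningful.
#'
#' @param a,b k x 2 preshapes (see [preshape()]).
#' @return 2 x 2 rotation matrix R such that `a %*% R` best matches `b`.
#' @export
optimal_rotation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(dim(a) == dim(b), ncol(a) == 2)
  m <- crossprod(a, b)
  sv <- svd(m)
  s <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  r <- sv$u %*% s %*% t(sv$v)
  if (min(sv$d) < 1e-12 * max(sv$d, .Machine$double.eps)) {
    warn("rank-deficient cross-covariance: rotation optimum is ambiguous; smallest-angle solution returned")
  }
  r
}

# rotation angles aligning each row-shape (n x k x 2) onto target (k x 2);
# vectorized closed form: theta = atan2(sum(x*ty - y*tx), sum(x*tx + y*ty))
# gives the same proper rotation as the SVD route in 2D.
.rotation_angles <- function(arr, target) {
  xs <- arr[, , 1, drop = TRUE]
  ys <- arr[, , 2, drop = TRUE]
  if (is.null(dim(xs))) { xs <- matrix(xs, nrow = 1); ys <- matrix(ys, nrow = 1) }
  num <- xs %*% target[, 2] - ys %*% target[, 1]
  den <- xs %*% target[, 1] + ys %*% target[, 2]
  atan2(num, den)
}

.rotate_arr <- function(arr, theta) {
  ct <- cos(theta); st <- sin(theta)
  xs <- arr[, , 1, drop = TRUE]
  ys <- arr[, , 2, drop = TRUE]
  if (is.null(dim(xs))) { xs <- matrix(xs, nrow = 1); ys <- matrix(ys, nrow = 1) }
  out <- arr
  out[, , 1] <- xs * c(ct) - ys * c(st)
  out[, , 2] <- xs * c(st) + ys * c(ct)
  out
}

#' Generalized Procrustes superimposition
#'
#' Iteratively removes size, position and orientation from a set of landmark
#' configurations, leaving pure shape: (1) every wing is reduced to a
#' preshape; (2) the consensus starts at the first shape; (3) every shape is
#' rotated onto the consensus by the closed-form optimal rotation; (4) the
#' consensus is recomputed as the per-landmark mean and rescaled to unit
#' centroid size; (5) repeat until the consensus moves less than `tol`
#' (root-mean-square landmark displacement) or `max_iter` is reached.
#'
#' @param wings Landmark tibble with complete configurations only
#'   (apply [filter_missing()] first).
#' @param tol Convergence tolerance on RMS consensus displacement.
#' @param max_iter Iteration cap.
#' @return An object of class `gpa_fit`: list with `aligned` (tibble
#'   `wing_id`, `lm`, `x`, `y`), `consensus` (tibble `lm`, `x`, `y`, unit
#'   centroid size), `centroid_sizes` (tibble `wing_id`, `centroid_size`, in
#'   original units), `iterations`, `converged`.
#' @export
#' @examples
#' sim <- simulate_cline(sim_config(sites_per_transect = c(2, 2, 2),
#'                                  apiaries_per_site = 2, wings_per_colony = 2,
#'                                  seed = 1))
#' fit <- gpa(filter_missing(sim$wings[sim$wings$caste == "worker", ])$kept)
#' glance(fit)
gpa <- function(wings, tol = 1e-10, max_iter = 100L) {
  check_landmark_cols(wings, require_missing = FALSE)
  if ("missing" %in% names(wings) && any(wings$missing)) {
    abort("gpa() requires complete configurations; run filter_missing() first")
  }
  arr <- lm_array(wings)
  n <- dim(arr)[1]; k <- dim(arr)[2]
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    ps <- preshape(arr[i, , ])
    arr[i, , ] <- ps$coords
    sizes[i] <- ps$centroid_size
  }
  consensus <- arr[1, , ]
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    theta <- .rotation_angles(arr, consensus)
    arr <- .rotate_arr(arr, theta)
    new_cons <- apply(arr, c(2, 3), mean)
    new_cons <- new_cons / sqrt(sum(sweep(new_cons, 2, colMeans(new_cons))^2))
    move <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (move < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  # final rotation pass onto the converged consensus
  arr <- .rotate_arr(arr, .rotation_angles(arr, consensus))
  structure(
    list(
      aligned = lm_tibble(arr),
      consensus = tibble(lm = seq_len(k), x = consensus[, 1], y = consensus[, 2]),
      centroid_sizes = tibble(wing_id = dimnames(arr)[[1]], centroid_size = sizes),
      iterations = iterations,
      converged = converged,
      tol = tol
    ),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  n <- length(unique(x$aligned$wing_id))
  cat("Generalized Procrustes superimposition\n")
  cat(sprintf("  %d configurations, %d landmarks\n", n, nrow(x$consensus)))
  cat(sprintf("  %d iterations, converged: %s\n", x$iterations, x$converged))
  invisible(x)
}

#' Partial Procrustes distance between two configurations
#'
#' The root of the minimised sum of squared differences between the two
#' centred, unit-centroid-size, optimally rotated configurations (the MorphoJ
#' convention for group-mean distances). Zero exactly when the shapes are
#' identical up to translation, scale and rotation.
#'
#' @param s1,s2 k x 2 coordinate matrices.
#' @return Non-negative shape distance.
#' @export
procrustes_distance <- function(s1, s2) {
  a <- preshape(s1)$coords
  b <- preshape(s2)$coords
  r <- optimal_rotation(a, b)
  sqrt(sum((a %*% r - b)^2))
}

#' Per-colony mean shapes from aligned wings
#'
#' Averages the Procrustes-aligned landmark coordinates of all wings of each
#' colony, one joint superimposition over the whole caste dataset having been
#' done first. Colony means are the analysis unit for ordination and the
#' spatial analyses.
#'
#' @param fit A `gpa_fit` from [gpa()], or an aligned landmark tibble.
#' @param meta Wing metadata: tibble with `wing_id`, `colony_id` (extra
#'   columns such as `site_id`, `caste` are carried through if constant
#'   within colony).
#' @return Tibble `colony_id`, `lm`, `x`, `y`, `n_wings` (plus carried
#'   metadata), one row per colony x landmark.
#' @export
colony_means <- function(fit, meta) {
  aligned <- if (inherits(fit, "gpa_fit")) fit$aligned else fit
  check_landmark_cols(aligned, require_missing = FALSE)
  stopifnot(all(c("wing_id", "colony_id") %in% names(meta)))
  unmapped <- setdiff(unique(aligned$wing_id), meta$wing_id)
  if (length(unmapped) > 0) {
    abort(paste0("wings without colony metadata: ",
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  carry <- intersect(c("colony_id", "site_id", "caste"), names(meta))
  dat <- left_join(aligned, meta[c("wing_id", carry)], by = "wing_id")
  out <- dat |>
    group_by(dplyr::across(dplyr::all_of(c(carry, "lm")))) |>
    summarise(
      x = mean(.data$x), y = mean(.data$y),
      n_wings = length(unique(.data$wing_id)), .groups = "drop"
    )
  empty <- setdiff(unique(meta$colony_id), out$colony_id)
  if (length(empty) > 0) {
    warn(paste0("colonies with zero aligned wings excluded: ",
                paste(head(empty, 5), collapse = ", ")))
  }
  out
}
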