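#' Default proximal landmark pair list
#'
#' "Proximal" landmark pairs are pairs adjacent along the forewing venation
#' graph: vein junctions joined by a vein segment. The sPCA input for
#' morphometric data is the vector of Euclidean distances between these
#' pairs, computed on aligned colony mean shapes. The default list ships as
#' an editable CSV (`inst/extdata/proximal_pairs.csv`, columns `i,j`,
#' 1-based) tracing a stylized 19-landmark venation; any alternative list
#' can be passed wherever pairs are accepted.
#'
#' @param path Optional CSV with columns `i`, `j`; defaults to the shipped
#'   list.
#' @return Tibble with integer columns `i`, `j` (`i < j`), no duplicates.
#' @export
proximal_pairs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "proximal_pairs.csv", package = "wingcline")
  }
  pairs <- readr::read_csv(path, show_col_types = FALSE)
  validate_pairs(pairs)
}

validate_pairs <- function(pairs, k = 19L) {
  stopifnot(all(c("i", "j") %in% names(pairs)))
  pairs <- tibble(i = as.integer(pmin(pairs$i, pairs$j)),
                  j = as.integer(pmax(pairs$i, pairs$j)))
  if (any(pairs$i == pairs$j)) abort("self-pairs are not allowed")
  if (any(pairs$i < 1L) || any(pairs$j > k)) {
    abort(paste0("landmark indices must lie in 1..", k))
  }
  if (anyDuplicated(pairs)) abort("duplicate landmark pairs")
  pairs
}

#' Inter-landmark distances for one configuration
#'
#' @param coords k x 2 matrix (one shape, e.g. an aligned colony mean).
#' @param pairs Pair list (tibble `i`, `j`), e.g. [proximal_pairs()].
#' @return Named numeric vector of Euclidean distances, names `d_i_j`, in
#'   pair-list order.
#' @export
proximal_distances <- function(coords, pairs = proximal_pairs()) {
  coords <- as.matrix(coords)
  pairs <- validate_pairs(pairs, k = nrow(coords))
  d <- sqrt((coords[pairs$i, 1] - coords[pairs$j, 1])^2 +
              (coords[pairs$i, 2] - coords[pairs$j, 2])^2)
  names(d) <- paste0("d_", pairs$i, "_", pairs$j)
  d
}

#' Build the per-colony feature matrix for the spatial analyses
#'
#' One row per colony, one column per proximal landmark pair, each entry the
#' Euclidean distance between the pair on that colony's aligned mean shape.
#' Computed on unit-centroid-size aligned means, the features capture shape,
#' not size. Geographic coordinates are attached per row so the result plugs
#' straight into [knn_network()], [spca()] and [structure_test()].
#'
#' @param shapes Colony mean shapes (tibble `colony_id`, `lm`, `x`, `y`).
#' @param coords Tibble `colony_id`, `lat`, `lon` (decimal degrees).
#' @param pairs Pair list; defaults to [proximal_pairs()].
#' @return Tibble `colony_id`, `lat`, `lon`, then `d_i_j` feature columns,
#'   rows in input colony order.
#' @export
build_feature_matrix <- function(shapes, coords, pairs = proximal_pairs()) {
  m <- flatten_shapes(shapes)
  k <- ncol(m) / 2
  pairs <- validate_pairs(pairs, k = k)
  dx <- m[, pairs$i, drop = FALSE] - m[, pairs$j, drop = FALSE]
  dy <- m[, k + pairs$i, drop = FALSE] - m[, k + pairs$j, drop = FALSE]
  feats <- sqrt(dx^2 + dy^2)
  colnames(feats) <- paste0("d_", pairs$i, "_", pairs$j)
  ids <- rownames(m)
  missing_coords <- setdiff(ids, coords$colony_id)
  if (length(missing_coords) > 0) {
    abort(paste0("colonies without coordinates: ",
                 paste(head(missing_coords, 10), collapse = ", ")))
  }
  cc <- coords[match(ids, coords$colony_id), ]
  dplyr::bind_cols(
    tibble(colony_id = ids, lat = cc$lat, lon = cc$lon),
    as_tibble(feats)
  )
}

# extract the numeric feature columns of a feature tibble (drops the
# id/coordinate bookkeeping columns by name)
feature_values <- function(features,
                           drop = c("colony_id", "sample_id", "site_id",
                                    "wing_id", "lat", "lon")) {
  stopifnot(is.data.frame(features))
  keep <- setdiff(names(features), drop)
  m <- as.matrix(features[keep])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) abort("feature matrix contains non-finite values")
  rownames(m) <- if ("colony_id" %in% names(features)) features$colony_id
  else if ("sample_id" %in% names(features)) features$sample_id
  else NULL
  m
}
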