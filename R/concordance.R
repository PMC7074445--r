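#' Correlation between two score vectors (cross-marker / cross-caste)
#'
#' Pearson correlation between two per-unit score vectors (e.g. the first
#' global sPCA scores of drone wings and SNPs), matched by id. sPCA axes are
#' sign-arbitrary, so both the signed r and the sign-aligned |r| are
#' reported, with the flip recorded: axis b is flipped when its correlation
#' with axis a is negative. The two-sided p-value uses the t transform with
#' n - 2 degrees of freedom.
#'
#' @param scores_a,scores_b Tibbles with columns `id`, `score` (e.g. from
#'   [first_score()]), or plain numeric vectors of equal length (matched by
#'   position).
#' @param labels Length-2 character naming the two score sets.
#' @return One-row tibble: `label_a`, `label_b`, `r` (signed), `r_aligned`,
#'   `flipped`, `p_value`, `n`, `method`.
#' @export
score_correlation <- function(scores_a, scores_b,
                              labels = c("a", "b")) {
  if (is.data.frame(scores_a) || is.data.frame(scores_b)) {
    stopifnot(is.data.frame(scores_a), is.data.frame(scores_b))
    stopifnot(all(c("id", "score") %in% names(scores_a)),
              all(c("id", "score") %in% names(scores_b)))
    un_a <- setdiff(scores_a$id, scores_b$id)
    un_b <- setdiff(scores_b$id, scores_a$id)
    if (length(un_a) + length(un_b) > 0) {
      abort(paste0(
        "unmatched ids between score sets: ",
        paste(head(c(un_a, un_b), 10), collapse = ", ")
      ))
    }
    b <- scores_b$score[match(scores_a$id, scores_b$id)]
    a <- scores_a$score
  } else {
    stopifnot(length(scores_a) == length(scores_b))
    a <- scores_a
    b <- scores_b
  }
  n <- length(a)
  if (n < 3) abort("need at least 3 matched scores")
  if (sd(a) == 0 || sd(b) == 0) abort("constant score vector: correlation undefined")
  r <- cor(a, b)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  tibble(
    label_a = labels[1], label_b = labels[2],
    r = r, r_aligned = abs(r), flipped = r < 0,
    p_value = p, n = n, method = "vector_pearson"
  )
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the lower-triangle entries of two distance
#' matrices on the same units (e.g. pairwise Procrustes distances vs pairwise
#' F_ST). The parametric t-based p-value treats the entries as independent,
#' which distance-matrix entries are not; a Mantel permutation p-value
#' (joint row/column permutations of one matrix, `(1 + b)/(1 + B)`
#' estimator) is therefore reported alongside whenever `mantel_nperm > 0`.
#'
#' @param d1,d2 [dist_matrix()] objects with identical labels in identical
#'   order.
#' @param mantel_nperm Mantel permutations (0 disables; default 999).
#' @param seed Seed for the Mantel permutation stream (required if
#'   `mantel_nperm > 0`).
#' @param labels Length-2 character naming the matrices.
#' @return One-row tibble: `label_a`, `label_b`, `r`, `p_value` (parametric),
#'   `p_mantel` (NA if disabled), `n` (number of pairs), `method`.
#' @export
matrix_correlation <- function(d1, d2, mantel_nperm = 999L, seed = NULL,
                               labels = c("a", "b")) {
  stopifnot(inherits(d1, "dist_matrix"), inherits(d2, "dist_matrix"))
  if (!identical(d1$labels, d2$labels)) {
    abort("distance matrices have different labels or label order")
  }
  m <- length(d1$labels)
  if (m < 4) abort("need at least 4 units")
  lt <- lower.tri(d1$values)
  v1 <- d1$values[lt]
  v2 <- d2$values[lt]
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("constant distance matrix: correlation undefined")
  }
  r <- cor(v1, v2)
  n_pairs <- length(v1)
  tt <- r * sqrt((n_pairs - 2) / (1 - r^2))
  p <- 2 * pt(abs(tt), df = n_pairs - 2, lower.tail = FALSE)
  p_mantel <- NA_real_
  if (mantel_nperm > 0) {
    if (is.null(seed)) abort("`seed` is required when mantel_nperm > 0")
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(mantel_nperm)) {
      perm <- sample.int(m)
      rp <- cor(v1, d2$values[perm, perm][lt])
      if (rp >= r) exceed <- exceed + 1L
    }
    p_mantel <- (1 + exceed) / (1 + mantel_nperm)
  }
  tibble(
    label_a = labels[1], label_b = labels[2],
    r = r, p_value = p, p_mantel = p_mantel,
    n = n_pairs, method = "matrix_pearson"
  )
}
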