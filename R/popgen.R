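#' Per-site allele frequencies from haploid genotypes
#'
#' For every site and locus, the allele-1 frequency is the mean of the
#' non-missing haploid calls of the site's samples, with the contributing
#' sample size recorded. Sites where a locus is entirely missing get `NA`
#' frequency and `n = 0`.
#'
#' @param genotypes Tibble from [read_genotypes()] (`sample_id`, `site_id`,
#'   locus columns coded 0/1/NA).
#' @return Long tibble `site_id`, `locus`, `freq`, `n`.
#' @export
site_allele_freqs <- function(genotypes) {
  stopifnot(all(c("sample_id", "site_id") %in% names(genotypes)))
  loci <- setdiff(names(genotypes), c("sample_id", "site_id"))
  calls <- as.matrix(genotypes[loci])
  storage.mode(calls) <- "double"
  sites <- unique(genotypes$site_id)
  out <- lapply(sites, function(s) {
    m <- calls[genotypes$site_id == s, , drop = FALSE]
    n <- colSums(!is.na(m))
    freq <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
    tibble(site_id = s, locus = loci, freq = unname(freq), n = as.integer(unname(n)))
  })
  bind_rows(out)
}

# Hudson-type haploid FST for one site pair: ratio of averages across loci.
# per locus: num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
#            den = p1(1-p2) + p2(1-p1)
hudson_fst_pair <- function(p1, p2, n1, n2) {
  use <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  if (!any(use)) {
    abort("no locus with n >= 2 in both sites; cannot estimate F_ST")
  }
  p1 <- p1[use]; p2 <- p2[use]; n1 <- n1[use]; n2 <- n2[use]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Pairwise F_ST between sites (Hudson estimator, haploid)
#'
#' Hudson-type F_ST adapted to haploid samples, combined across loci as a
#' ratio of averages (sum of per-locus numerators over sum of per-locus
#' denominators), the combination that is robust when per-locus
#' denominators are small. Per locus, the numerator is the squared frequency
#' difference minus the within-site sampling corrections
#' `p(1-p)/(n-1)`; the denominator is `p1(1-p2) + p2(1-p1)`. Loci lacking
#' two non-missing calls in either site are excluded pairwise-complete.
#' Values are clamped to [0, 1]; the raw (possibly slightly negative)
#' matrix is kept in attribute `raw`.
#'
#' @param freqs Long frequency tibble from [site_allele_freqs()].
#' @return A [dist_matrix()] of pairwise F_ST, with attribute `raw`.
#' @export
pairwise_fst <- function(freqs) {
  stopifnot(all(c("site_id", "locus", "freq", "n") %in% names(freqs)))
  sites <- unique(freqs$site_id)
  if (length(sites) < 2) abort("need at least 2 sites")
  loci <- unique(freqs$locus)
  p <- matrix(NA_real_, length(sites), length(loci),
              dimnames = list(sites, loci))
  nn <- p
  p[cbind(match(freqs$site_id, sites), match(freqs$locus, loci))] <- freqs$freq
  nn[cbind(match(freqs$site_id, sites), match(freqs$locus, loci))] <- freqs$n
  raw <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    for (j in seq_len(i - 1L)) {
      f <- hudson_fst_pair(p[i, ], p[j, ], nn[i, ], nn[j, ])
      raw[i, j] <- f
      raw[j, i] <- f
    }
  }
  out <- dist_matrix(pmin(pmax(raw, 0), 1), sites)
  attr(out, "raw") <- raw
  out
}
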