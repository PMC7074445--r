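#' Template wing landmark configuration
#'
#' A fixed 19-point configuration tracing a stylized honey bee forewing
#' venation (vein junctions from the wing base, landmark 1, towards the
#' distal margin), centred and scaled to unit centroid size. Its exact
#' geometry is arbitrary — it serves as the mean shape of the synthetic
#' generator, not as a measurement of any real wing.
#'
#' @return 19 x 2 matrix, centroid at origin, centroid size 1.
#' @export
template_wing <- function() {
  m <- matrix(c(
    0.00, 0.10,   # 1  wing base
    0.55, 0.42,   # 2  costal region
    1.05, 0.52,   # 3
    1.55, 0.55,   # 4
    2.05, 0.50,   # 5  distal costal
    2.45, 0.38,   # 6  wing tip region
    2.25, 0.18,   # 7
    1.90, 0.10,   # 8
    1.60, 0.22,   # 9  radial cell junctions
    1.30, 0.30,   # 10
    1.05, 0.18,   # 11
    0.80, 0.28,   # 12
    0.60, 0.12,   # 13
    1.35, 0.02,   # 14 cubital junctions
    1.70, -0.08,  # 15
    1.25, -0.22,  # 16
    0.85, -0.18,  # 17
    0.50, -0.10,  # 18
    0.25, -0.25   # 19 anal region
  ), ncol = 2, byrow = TRUE)
  preshape(m)$coords
}

#' Default clinal deformation axis
#'
#' A smooth shape deformation displacing distal landmarks relative to
#' proximal ones: displacement grows linearly with the landmark's position
#' along the wing's long axis. Components along the similarity
#' transformations of the template (translations, rotation, scaling) are
#' projected out, so the axis is a pure shape change that survives
#' Procrustes superimposition; it is normalized to unit Frobenius norm.
#'
#' @param template 19 x 2 base configuration (default [template_wing()]).
#' @return 19 x 2 unit-norm deformation matrix.
#' @export
default_deformation_axis <- function(template = template_wing()) {
  k <- nrow(template)
  wgt <- (template[, 1] - min(template[, 1]))
  wgt <- wgt / max(wgt) - 0.5
  d <- cbind(0.4 * wgt, wgt)
  # tangent directions of similarity transforms at the template
  basis <- cbind(
    c(rep(1, k), rep(0, k)),            # x translation
    c(rep(0, k), rep(1, k)),            # y translation
    c(template[, 1], template[, 2]),    # scaling
    c(-template[, 2], template[, 1])    # rotation
  )
  v <- as.vector(d)
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j] / sqrt(sum(basis[, j]^2))
    v <- v - sum(v * b) * b
  }
  d <- matrix(v, ncol = 2)
  d / sqrt(sum(d^2))
}

#' Configuration for the synthetic clinal generator
#'
#' Defaults emulate the Iberian sampling design: 23 sites on three
#' north-south transects (Atlantic 8, Central 9, Mediterranean 6), 10
#' apiaries per site, 3 colonies per apiary, 5 wings per colony per caste,
#' 19 landmarks, 383 biallelic haploid loci, and a shared northeast-southwest
#' latent cline (bearing 45 degrees) driving both wing shape and SNP allele
#' frequencies. Per-landmark missing rates are caste-specific and higher for
#' haploid drones.
#'
#' @param sites_per_transect Integer 3-vector: sites on the Atlantic,
#'   Central and Mediterranean transects.
#' @param apiaries_per_site,colonies_per_apiary,wings_per_colony Sampling
#'   design counts.
#' @param n_loci Number of biallelic haploid SNP loci.
#' @param cline_bearing Compass bearing (degrees) of the cline axis;
#'   45 = northeast-southwest.
#' @param cline_steepness Logistic steepness applied to the standardized
#'   projection of colony coordinates onto the cline axis.
#' @param cline_strength_shape Shape displacement (in units of the
#'   unit-centroid-size template) between the cline's extremes (beta).
#' @param cline_strength_snp Log-odds swing of allele frequencies across the
#'   cline (gamma).
#' @param colony_sd,wing_sd,digitize_sd Isotropic per-coordinate standard
#'   deviations of colony effects, per-wing biological noise, and digitizing
#'   noise (same shape units).
#' @param missing_rate_drone,missing_rate_worker Per-landmark missing
#'   probabilities; drones must be >= workers.
#' @param seed Integer seed; one seed drives every draw, so equal seeds give
#'   bit-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sites_per_transect = c(8L, 9L, 6L),
                       apiaries_per_site = 10L,
                       colonies_per_apiary = 3L,
                       wings_per_colony = 5L,
                       n_loci = 383L,
                       cline_bearing = 45,
                       cline_steepness = 2,
                       cline_strength_shape = 0.08,
                       cline_strength_snp = 4,
                       colony_sd = 0.0025,
                       wing_sd = 0.005,
                       digitize_sd = 0.002,
                       missing_rate_drone = 0.003,
                       missing_rate_worker = 0.0002,
                       seed = 1L) {
  cfg <- list(
    sites_per_transect = as.integer(sites_per_transect),
    apiaries_per_site = as.integer(apiaries_per_site),
    colonies_per_apiary = as.integer(colonies_per_apiary),
    wings_per_colony = as.integer(wings_per_colony),
    n_landmarks = 19L,
    n_loci = as.integer(n_loci),
    cline_bearing = cline_bearing,
    cline_steepness = cline_steepness,
    cline_strength_shape = cline_strength_shape,
    cline_strength_snp = cline_strength_snp,
    colony_sd = colony_sd,
    wing_sd = wing_sd,
    digitize_sd = digitize_sd,
    missing_rate_drone = missing_rate_drone,
    missing_rate_worker = missing_rate_worker,
    seed = as.integer(seed)
  )
  if (length(cfg$sites_per_transect) != 3 || any(cfg$sites_per_transect < 1)) {
    abort("sites_per_transect must be three positive counts (AT, CT, MT)")
  }
  if (cfg$apiaries_per_site < 1 || cfg$colonies_per_apiary < 1 ||
      cfg$wings_per_colony < 1 || cfg$n_loci < 1) {
    abort("design counts must be positive")
  }
  rates <- c(cfg$missing_rate_drone, cfg$missing_rate_worker)
  if (any(rates < 0) || any(rates > 1)) abort("missing rates must lie in [0, 1]")
  if (cfg$missing_rate_drone < cfg$missing_rate_worker) {
    abort("missing_rate_drone must be >= missing_rate_worker (haploid drones express anomalies more often)")
  }
  if (any(c(cfg$colony_sd, cfg$wing_sd, cfg$digitize_sd) < 0) ||
      cfg$cline_strength_shape < 0 || cfg$cline_strength_snp < 0) {
    abort("noise sds and cline strengths must be nonnegative")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a clinal wing-and-SNP dataset with known truth
#'
#' Generates the full study design: sites laid out north-south on three
#' Iberian-like transects, apiaries and colonies scattered around each site,
#' a latent cline value q per colony (logistic in the projection of its
#' coordinates onto the cline bearing), wing landmark configurations for
#' both castes (template + q * beta * deformation + colony + wing +
#' digitizing noise, rendered into image units by a random similarity
#' transform per wing, with caste-specific missing landmarks), and one
#' haploid drone genotype per colony with allele frequencies following the
#' same cline.
#'
#' @param config A [sim_config()].
#' @return List: `wings` (landmark tibble with `caste`), `meta` (wing
#'   metadata), `colonies` (`colony_id`, `apiary_id`, `site_id`, `lat`,
#'   `lon`, `q`), `sites` (site table), `genotypes` (haploid genotype
#'   tibble), `truth` (latent q, deformation axis, per-locus baseline and
#'   slope, the config).
#' @export
simulate_cline <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  transects <- tibble(
    transect = c("AT", "CT", "MT"),
    lon0 = c(-8.6, -5.5, -2.2),
    n = config$sites_per_transect
  )
  sites <- purrr::pmap_dfr(transects, function(transect, lon0, n) {
    tibble(
      site_id = paste0(transect, seq_len(n)),
      transect = transect,
      latitude = seq(42.8, 37.0, length.out = n) + runif(n, -0.15, 0.15),
      longitude = lon0 + runif(n, -0.35, 0.35)
    )
  })

  colonies <- sites |>
    tidyr::expand_grid(apiary = seq_len(config$apiaries_per_site)) |>
    mutate(
      ap_lat = .data$latitude + runif(dplyr::n(), -0.08, 0.08),
      ap_lon = .data$longitude + runif(dplyr::n(), -0.08, 0.08)
    ) |>
    tidyr::expand_grid(colony = seq_len(config$colonies_per_apiary)) |>
    mutate(
      apiary_id = paste0(.data$site_id, "_A", .data$apiary),
      colony_id = paste0(.data$site_id, "_A", .data$apiary, "_C", .data$colony),
      lat = .data$ap_lat + runif(dplyr::n(), -0.01, 0.01),
      lon = .data$ap_lon + runif(dplyr::n(), -0.01, 0.01)
    ) |>
    select("colony_id", "apiary_id", "site_id", "lat", "lon")

  b <- config$cline_bearing * pi / 180
  proj <- colonies$lon * sin(b) + colonies$lat * cos(b)
  z <- (proj - mean(proj)) / sd(proj)
  colonies$q <- stats::plogis(config$cline_steepness * z)

  template <- template_wing()
  axis <- default_deformation_axis(template)
  k <- config$n_landmarks
  n_col <- nrow(colonies)

  # colony mean shapes per caste (shared clinal signal, independent colony
  # effects per caste)
  colony_shape <- function() {
    base <- outer(colonies$q * config$cline_strength_shape, as.vector(axis))
    sweep(base, 2, as.vector(template), "+") +
      matrix(rnorm(n_col * 2 * k, sd = config$colony_sd), n_col)
  }

  make_wings <- function(caste, colony_mat, missing_rate) {
    nw <- config$wings_per_colony
    n_wing <- n_col * nw
    col_idx <- rep(seq_len(n_col), each = nw)
    flat <- colony_mat[col_idx, , drop = FALSE] +
      matrix(rnorm(n_wing * 2 * k, sd = config$wing_sd), n_wing) +
      matrix(rnorm(n_wing * 2 * k, sd = config$digitize_sd), n_wing)
    # render into image units: random scale, rotation and offset per wing
    sc <- runif(n_wing, 350, 450)
    th <- runif(n_wing, -0.3, 0.3)
    ox <- runif(n_wing, 400, 600)
    oy <- runif(n_wing, 300, 500)
    xs <- flat[, seq_len(k), drop = FALSE]
    ys <- flat[, k + seq_len(k), drop = FALSE]
    xr <- (xs * cos(th) - ys * sin(th)) * sc + ox
    yr <- (xs * sin(th) + ys * cos(th)) * sc + oy
    miss <- matrix(runif(n_wing * k) < missing_rate, n_wing, k)
    wing_id <- paste0(colonies$colony_id[col_idx], "_", caste, rep(seq_len(nw), n_col))
    tibble(
      wing_id = rep(wing_id, each = k),
      colony_id = rep(colonies$colony_id[col_idx], each = k),
      caste = caste,
      lm = rep(seq_len(k), n_wing),
      x = as.vector(t(xr)),
      y = as.vector(t(yr)),
      missing = as.vector(t(miss))
    )
  }

  wings <- bind_rows(
    make_wings("drone", colony_shape(), config$missing_rate_drone),
    make_wings("worker", colony_shape(), config$missing_rate_worker)
  )
  meta <- distinct(wings, .data$wing_id, .data$colony_id, .data$caste) |>
    left_join(colonies[c("colony_id", "site_id")], by = "colony_id")

  # haploid genotypes: one drone per colony
  baseline <- stats::qlogis(runif(config$n_loci, 0.2, 0.8))
  slope <- config$cline_strength_snp *
    sample(c(-1, 1), config$n_loci, replace = TRUE) *
    runif(config$n_loci, 0.5, 1.5)
  eta <- outer(colonies$q - 0.5, slope) +
    matrix(baseline, n_col, config$n_loci, byrow = TRUE)
  calls <- matrix(rbinom(n_col * config$n_loci, 1, stats::plogis(eta)),
                  n_col, config$n_loci)
  colnames(calls) <- sprintf("locus_%03d", seq_len(config$n_loci))
  genotypes <- dplyr::bind_cols(
    tibble(sample_id = colonies$colony_id, site_id = colonies$site_id),
    as_tibble(calls)
  )

  list(
    wings = wings,
    meta = meta,
    colonies = colonies,
    sites = sites,
    genotypes = genotypes,
    truth = list(
      q = tibble(colony_id = colonies$colony_id, q = colonies$q),
      deformation_axis = axis,
      locus_baseline = baseline,
      locus_slope = slope,
      config = config
    )
  )
}

#' Cline recovery score
#'
#' Absolute Pearson correlation between the generator's latent cline value q
#' and a score vector (typically the first global sPCA score), matched by
#' colony id. sPCA axes are sign-arbitrary, so the absolute value is the
#' meaningful recovery measure.
#'
#' @param truth The `truth` element of a [simulate_cline()] result (or a
#'   tibble `colony_id`, `q`).
#' @param scores Tibble `id`, `score` (e.g. [first_score()]).
#' @return |r| between q and the scores.
#' @export
recovery_score <- function(truth, scores) {
  q <- if (is.data.frame(truth)) truth else truth$q
  stopifnot(all(c("colony_id", "q") %in% names(q)),
            all(c("id", "score") %in% names(scores)))
  un <- setdiff(scores$id, q$colony_id)
  if (length(un) > 0) {
    abort(paste0("scores for unknown colonies: ", paste(head(un, 5), collapse = ", ")))
  }
  matched <- q$q[match(scores$id, q$colony_id)]
  abs(cor(matched, scores$score))
}
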