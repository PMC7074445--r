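#' Read a TPS landmark file
#'
#' Parses the TPS format produced by the tpsUtil/tpsDig family of digitizing
#' tools: each record starts with an `LM=<count>` line, followed by `<count>`
#' whitespace-separated `x y` coordinate lines, optionally followed by
#' `IMAGE=`, `ID=` and `SCALE=` lines. One row per landmark is returned, so a
#' file with `n` wings of 19 landmarks yields a tibble of `19 * n` rows.
#'
#' A `SCALE=` line is applied multiplicatively to the record's coordinates at
#' read time; records without one keep dimensionless digitizer units
#' (scale 1). TPS has no standard missing-landmark code; this package writes
#' (and recognises on read) the sentinel pair `-1.0 -1.0`, which is flagged in
#' the `missing` column and left untouched by `SCALE=`.
#'
#' Records whose landmark count differs from `n_landmarks` (19 for honey bee
#' forewings) are returned with `flagged = TRUE` rather than silently dropped,
#' so the caller decides their fate.
#'
#' @param path Path to a TPS file.
#' @param n_landmarks Expected landmark count per wing; records deviating from
#'   it are flagged, not dropped. Default 19.
#' @param missing_sentinel Length-2 numeric; a coordinate pair equal to it is
#'   read as a missing landmark. Default `c(-1, -1)`.
#'
#' @return A tibble with columns `wing_id`, `lm` (1-based landmark index),
#'   `x`, `y`, `missing`, `image`, `scale`, `n_landmarks`, `flagged`.
#'   Record and landmark order follow the file.
#' @export
#' @examples
#' tps <- system.file("extdata", "example_wings.tps", package = "wingcline")
#' read_tps(tps)
read_tps <- function(path, n_landmarks = 19L, missing_sentinel = c(-1, -1)) {
  if (!file.exists(path)) {
    abort(paste0("TPS file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lm_at <- grep("^\\s*LM\\s*=", lines)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) > 0 && length(lm_at) == 0) {
    abort(paste0("line 1: expected an LM=<count> line to open the first record"))
  }
  if (length(non_blank) > 0 && non_blank[1] < lm_at[1]) {
    abort(paste0("line ", non_blank[1], ": content before the first LM= line"))
  }

  records <- vector("list", length(lm_at))
  bounds <- c(lm_at, length(lines) + 1L)
  for (r in seq_along(lm_at)) {
    start <- lm_at[r]
    end <- bounds[r + 1L] - 1L
    k_str <- sub("^\\s*LM\\s*=\\s*", "", lines[start])
    k <- suppressWarnings(as.integer(k_str))
    if (is.na(k) || k < 0) {
      abort(paste0("line ", start, ": malformed LM= line: '", lines[start], "'"))
    }
    body <- lines[(start + 1L):end]
    body_lineno <- (start + 1L):end
    keep <- nzchar(trimws(body))
    body <- body[keep]
    body_lineno <- body_lineno[keep]
    if (length(body) < k) {
      abort(paste0(
        "line ", start, ": record declares LM=", k,
        " but only ", length(body), " lines follow before the next record"
      ))
    }
    coord_lines <- body[seq_len(k)]
    coord_lineno <- body_lineno[seq_len(k)]
    xy <- matrix(NA_real_, nrow = max(k, 0L), ncol = 2)
    for (i in seq_len(k)) {
      parts <- strsplit(trimws(coord_lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        abort(paste0(
          "line ", coord_lineno[i], ": expected two numeric coordinates, got '",
          coord_lines[i], "'"
        ))
      }
      xy[i, ] <- vals
    }
    meta <- body[k + seq_len(length(body) - k)]
    meta_lineno <- body_lineno[k + seq_len(length(body) - k)]
    image <- NA_character_
    id <- NA_character_
    scale <- NA_real_
    for (j in seq_along(meta)) {
      line <- trimws(meta[j])
      if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", line,
                                                 ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0) {
          abort(paste0("line ", meta_lineno[j], ": SCALE= must be a positive number"))
        }
      } else {
        abort(paste0(
          "line ", meta_lineno[j],
          ": unexpected line inside record (not a coordinate or IMAGE=/ID=/SCALE=): '",
          line, "'"
        ))
      }
    }
    miss <- xy[, 1] == missing_sentinel[1] & xy[, 2] == missing_sentinel[2]
    eff_scale <- if (is.na(scale)) 1 else scale
    xy[!miss, ] <- xy[!miss, , drop = FALSE] * eff_scale
    wing_id <- if (!is.na(id)) id else if (!is.na(image)) image else paste0("wing_", r)
    is_flagged <- k != n_landmarks
    records[[r]] <- tibble(
      wing_id = wing_id,
      lm = seq_len(k),
      x = xy[, 1],
      y = xy[, 2],
      missing = miss,
      image = image,
      scale = eff_scale,
      n_landmarks = k,
      flagged = is_flagged
    )
  }
  out <- bind_rows(records)
  if (nrow(out) == 0) {
    out <- tibble(
      wing_id = character(), lm = integer(), x = double(), y = double(),
      missing = logical(), image = character(), scale = double(),
      n_landmarks = integer(), flagged = logical()
    )
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written with 6 decimal places so a
#' write/read round trip is lossless to that precision. Missing landmarks are
#' written as the sentinel pair (default `-1.0 -1.0`), keeping files loadable
#' by tpsDig-family tools while preserving the mask on re-read. No `SCALE=`
#' line is emitted: coordinates are written in their current (already scaled)
#' units.
#'
#' @param wings Landmark tibble as returned by [read_tps()] (columns
#'   `wing_id`, `lm`, `x`, `y`; `missing` and `image` optional).
#' @param path Output file path.
#' @param missing_sentinel Coordinate pair written for missing landmarks.
#'
#' @return `path`, invisibly.
#' @export
write_tps <- function(wings, path, missing_sentinel = c(-1, -1)) {
  stopifnot(is.data.frame(wings))
  if (nrow(wings) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  check_landmark_cols(wings, require_missing = FALSE)
  if (!"missing" %in% names(wings)) wings$missing <- FALSE
  bad <- !wings$missing & (!is.finite(wings$x) | !is.finite(wings$y))
  if (any(bad)) {
    abort(paste0(
      "non-finite coordinates at non-missing landmarks of wing(s): ",
      paste(unique(wings$wing_id[bad]), collapse = ", ")
    ))
  }
  groups <- split(wings, factor(wings$wing_id, levels = unique(wings$wing_id)))
  out <- unlist(lapply(groups, function(w) {
    w <- w[order(w$lm), ]
    x <- ifelse(w$missing, missing_sentinel[1], w$x)
    y <- ifelse(w$missing, missing_sentinel[2], w$y)
    rec <- c(
      sprintf("LM=%d", nrow(w)),
      sprintf("%.6f %.6f", x, y)
    )
    if ("image" %in% names(w) && !is.na(w$image[1])) {
      rec <- c(rec, paste0("IMAGE=", w$image[1]))
    }
    c(rec, paste0("ID=", w$wing_id[1]))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

check_landmark_cols <- function(x, require_missing = TRUE) {
  need <- c("wing_id", "lm", "x", "y", if (require_missing) "missing")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("landmark table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(x)
}

#' Read the sampling-site table
#'
#' Expects a comma-separated file with header
#' `site_id,transect,latitude,longitude`: one row per site, transects coded
#' `AT` (Atlantic), `CT` (Central) or `MT` (Mediterranean), coordinates in
#' WGS84 decimal degrees.
#'
#' @param path CSV path.
#' @return A tibble of validated site records.
#' @export
read_site_table <- function(path) {
  sites <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("site_id", "transect", "latitude", "longitude")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    abort(paste0("site table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_sites(sites)
}

validate_sites <- function(sites) {
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate site_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_tr <- setdiff(unique(sites$transect), c("AT", "CT", "MT"))
  if (length(bad_tr) > 0) {
    abort(paste0("unknown transect code(s): ", paste(bad_tr, collapse = ", "),
                 " (expected AT, CT or MT)"))
  }
  if (any(sites$latitude < -90 | sites$latitude > 90) ||
      any(sites$longitude < -180 | sites$longitude > 180)) {
    abort("site coordinates outside WGS84 decimal-degree bounds")
  }
  as_tibble(sites)
}

#' Read a haploid genotype table
#'
#' Expects CSV with header `sample_id,site_id,<locus>,<locus>,...` and haploid
#' biallelic calls coded 0/1 (empty or `NA` for missing). A value of 2
#' anywhere is rejected with a pointer to haploid coding: drones are haploid,
#' so diploid dosage coding indicates the wrong input.
#'
#' @param path CSV path.
#' @param sites Optional site table (from [read_site_table()]); if given,
#'   every sample's `site_id` must appear in it.
#' @return A tibble: `sample_id`, `site_id`, then one 0/1/NA column per locus.
#' @export
read_genotypes <- function(path, sites = NULL) {
  geno <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "site_id")
  miss <- setdiff(need, names(geno))
  if (length(miss) > 0) {
    abort(paste0("genotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  loci <- setdiff(names(geno), need)
  if (length(loci) == 0) abort("genotype table has no locus columns")
  calls <- as.matrix(geno[loci])
  storage.mode(calls) <- "double"
  bad <- calls[!is.na(calls) & !(calls %in% c(0, 1))]
  if (length(bad) > 0) {
    abort(paste0(
      "genotype calls must be haploid-coded 0/1/NA; found value(s) ",
      paste(unique(bad), collapse = ", "),
      ". Recode diploid dosages (2) to haploid alleles before import."
    ))
  }
  if (anyDuplicated(geno$sample_id)) {
    abort("duplicate sample_id in genotype table")
  }
  if (!is.null(sites)) {
    unknown <- setdiff(unique(geno$site_id), sites$site_id)
    if (length(unknown) > 0) {
      abort(paste0("samples reference unknown site_id: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  as_tibble(geno)
}
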