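# Seeded generator of a synthetic study system: nested census geographies
# (block groups partitioning tracts partitioning a square region), hospital
# referral regions (HRRs) as Voronoi cells whose boundaries are misaligned
# with census boundaries, zip polygons as an offset grid misaligned with
# both, overlap-derived many-to-many crosswalks, transplant-center points,
# and patient waitlist records.
#
# The generator stands in for the restricted/bulky real inputs (registry
# waitlists, referral-region shapefiles, census polygon files, zip
# crosswalks) while preserving the structural properties the analysis
# relies on: nesting, tessellation, boundary misalignment, split zips, and
# facility-identifier aliasing.

#' Configuration for the synthetic geography
#'
#' @param side Region side length (abstract planar units; the region is the
#'   square `[0, side]^2`).
#' @param n Block-group grid size: `n x n` square block groups.
#' @param k Tract aggregation factor: each tract is a `k x k` block of block
#'   groups; `n` must be divisible by `k`.
#' @param h Number of HRRs (Voronoi cells of `h` seed points).
#' @param m Zip grid size before offsetting; with `delta > 0` the offset grid
#'   clipped to the region yields `(m+1)^2` zips.
#' @param delta Zip offset fraction in `[0, 1)`: the zip grid is shifted by
#'   `delta` times a zip cell in both axes. `delta = 0` puts zip boundaries
#'   on block-group boundaries.
#' @param n_centers Number of transplant centers (>= 2).
#' @param cluster_p Probability that a new center is placed within 10
#'   distance units of an existing one (creates mergeable center pairs).
#' @param seed Integer seed; all layers derive per-layer subseeds from it.
#' @param hrr_seeds Optional `h x 2` matrix of HRR Voronoi seed points;
#'   overrides random placement (used to align HRR boundaries with tract
#'   lines in the fully aligned limit).
#' @return A `geography_config` list.
#' @export
geography_config <- function(side = 100, n = 30, k = 3, h = 8, m = 10,
                             delta = 0.3, n_centers = 12, cluster_p = 0.3,
                             seed = 1, hrr_seeds = NULL) {
  if (n %% k != 0) stop("n must be divisible by k")
  if (h < 2) stop("h must be >= 2")
  if (n_centers < 2) stop("n_centers must be >= 2")
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  if (!is.null(hrr_seeds)) {
    hrr_seeds <- as.matrix(hrr_seeds)
    if (nrow(hrr_seeds) != h || ncol(hrr_seeds) != 2)
      stop("hrr_seeds must be an h x 2 matrix")
  }
  structure(list(side = side, n = n, k = k, h = h, m = m, delta = delta,
                 n_centers = n_centers, cluster_p = cluster_p, seed = seed,
                 hrr_seeds = hrr_seeds),
            class = "geography_config")
}

#' Configuration for the synthetic waitlist
#'
#' @param n_patients Number of patients.
#' @param p_multi Per-patient probability of listing at a second center.
#' @param p_repeat Per-listing probability of an extra (repeat) entry at the
#'   same center, exercising the once-per-patient-per-center counting rule.
#' @param p_missing_end Probability a record's end date is missing
#'   (administratively censored downstream).
#' @param p_minor Fraction of patients whose 18th birthday falls inside the
#'   study period, exercising the adult-portion trimming rule.
#' @param p_missing_start Probability the start date is missing (excluded
#'   downstream).
#' @param p_reversed Probability start and end dates are swapped so the start
#'   follows the recorded end (excluded downstream).
#' @param alias_fraction Fraction of entries recorded under a facility alias
#'   id rather than the canonical center id.
#' @param study_start,study_end Study period bounds (ISO dates). Entry dates
#'   are drawn from a window extending one year past each bound so censoring
#'   and exclusion rules are all exercised.
#' @param decay_scale Distance-decay scale for center choice: a patient picks
#'   a center with probability proportional to `exp(-distance / decay_scale)`.
#' @param seed Integer seed.
#' @return A `waitlist_config` list.
#' @export
waitlist_config <- function(n_patients = 2000, p_multi = 0.15,
                            p_repeat = 0.10, p_missing_end = 0.10,
                            p_minor = 0.05, p_missing_start = 0.02,
                            p_reversed = 0.02, alias_fraction = 0.2,
                            study_start = "2008-01-01",
                            study_end = "2018-12-31",
                            decay_scale = 15, seed = 1) {
  probs <- c(p_multi, p_repeat, p_missing_end, p_minor, p_missing_start,
             p_reversed, alias_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  structure(list(n_patients = n_patients, p_multi = p_multi,
                 p_repeat = p_repeat, p_missing_end = p_missing_end,
                 p_minor = p_minor, p_missing_start = p_missing_start,
                 p_reversed = p_reversed, alias_fraction = alias_fraction,
                 study_start = study_start, study_end = study_end,
                 decay_scale = decay_scale, seed = seed),
            class = "waitlist_config")
}

# A single global seed fans out to fixed per-layer subseeds so adding a
# layer never perturbs earlier layers.
subseed <- function(seed, offset) {
  s <- (as.numeric(seed) * 1009 + offset) %% 2147483647
  as.integer(s)
}

grid_cells <- function(breaks_x, breaks_y, id_fun) {
  geoms <- list()
  for (j in seq_len(length(breaks_y) - 1)) {
    for (i in seq_len(length(breaks_x) - 1)) {
      id <- id_fun(i, j)
      geoms[[id]] <- rect_poly(breaks_x[i], breaks_y[j],
                               breaks_x[i + 1], breaks_y[j + 1], id = id)
    }
  }
  geoms
}

# Voronoi cell of seeds[i, ] within the square [0, side]^2, by successive
# half-plane clipping against each perpendicular bisector.
voronoi_cell <- function(seeds, i, side) {
  ring <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  si <- seeds[i, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == i) next
    v <- seeds[j, ] - si
    mid <- (seeds[j, ] + si) / 2
    # keep the s_i side: left of the directed line mid -> mid + perp(v)
    ring <- clip_halfplane(ring, mid, mid + c(-v[2], v[1]))
    if (nrow(ring) < 3) stop("degenerate Voronoi cell (coincident seeds?)")
  }
  ring
}

# Overlap-derived crosswalk between two convex-cell layers: one row per
# (a, b) pair whose intersection area exceeds a sliver tolerance.
overlap_crosswalk <- function(geoms_a, geoms_b, name_a, name_b) {
  bb_b <- lapply(geoms_b, function(g) bbox_of(g$rings[[1]]))
  rows <- vector("list", length(geoms_a))
  for (ia in seq_along(geoms_a)) {
    ga <- geoms_a[[ia]]
    bba <- bbox_of(ga$rings[[1]])
    tol <- 1e-9 * geo_area(ga)
    hits <- character(0)
    for (ib in seq_along(geoms_b)) {
      if (bboxes_disjoint(bba, bb_b[[ib]])) next
      ia_area <- geo_intersection_area(ga, geoms_b[[ib]])
      if (ia_area > tol) hits <- c(hits, names(geoms_b)[ib])
    }
    if (length(hits))
      rows[[ia]] <- data.frame(a = names(geoms_a)[ia], b = hits,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c(name_a, name_b)
  rownames(out) <- NULL
  out
}

#' Generate the synthetic geography
#'
#' Deterministic for a fixed seed. Produces block-group, tract, HRR and zip
#' polygon layers, overlap-derived zip-HRR and zip-tract crosswalks, a
#' facility alias crosswalk, and transplant-center coordinates.
#'
#' @param cfg A [geography_config()].
#' @return A `trr_system` list with elements `blockgroups`, `tracts`, `hrrs`,
#'   `zips` (each `list(geoms, props)`), `zip_hrr`, `zip_tract`,
#'   `facility_xwalk`, `centers`, and `config`.
#' @export
generate_geography <- function(cfg) {
  stopifnot(inherits(cfg, "geography_config"))
  side <- cfg$side; n <- cfg$n; k <- cfg$k
  nt <- n / k

  bg_breaks <- seq(0, side, length.out = n + 1)
  tract_id <- function(i, j) sprintf("T%02d%02d", i, j)
  bg_geoms <- grid_cells(bg_breaks, bg_breaks,
                         function(i, j) sprintf("B%02d%02d", i, j))
  bg_parent <- character(length(bg_geoms))
  idx <- 1
  for (j in seq_len(n)) for (i in seq_len(n)) {
    bg_parent[idx] <- tract_id((i - 1) %/% k + 1, (j - 1) %/% k + 1)
    idx <- idx + 1
  }
  bg_props <- data.frame(id = names(bg_geoms), tract = bg_parent,
                         stringsAsFactors = FALSE)

  tract_breaks <- seq(0, side, length.out = nt + 1)
  tract_geoms <- grid_cells(tract_breaks, tract_breaks, tract_id)
  tract_props <- data.frame(id = names(tract_geoms), stringsAsFactors = FALSE)

  # HRRs: Voronoi cells of h seed points clipped to the region
  if (is.null(cfg$hrr_seeds)) {
    set.seed(subseed(cfg$seed, 1))
    seeds <- cbind(stats::runif(cfg$h, 0.05 * side, 0.95 * side),
                   stats::runif(cfg$h, 0.05 * side, 0.95 * side))
  } else seeds <- cfg$hrr_seeds
  hrr_geoms <- list()
  for (i in seq_len(cfg$h)) {
    id <- sprintf("H%02d", i)
    hrr_geoms[[id]] <- trr_polygon(voronoi_cell(seeds, i, side), id = id)
  }
  hrr_props <- data.frame(id = names(hrr_geoms), stringsAsFactors = FALSE)

  # zips: m x m grid shifted by delta of a cell, clipped to the region
  cz <- side / cfg$m
  starts <- -cfg$delta * cz + (0:cfg$m) * cz
  breaks_z <- sort(unique(pmin(pmax(c(starts, side), 0), side)))
  breaks_z <- breaks_z[c(TRUE, diff(breaks_z) > 1e-12 * side)]
  zip_geoms <- grid_cells(breaks_z, breaks_z,
                          function(i, j) sprintf("Z%02d%02d", i, j))
  zip_props <- data.frame(id = names(zip_geoms), stringsAsFactors = FALSE)

  zip_hrr <- overlap_crosswalk(zip_geoms, hrr_geoms, "zip", "hrr")
  zip_tract <- overlap_crosswalk(zip_geoms, tract_geoms, "zip", "tract")

  # centers: sequential placement with proximity clustering
  set.seed(subseed(cfg$seed, 2))
  cx <- matrix(0, cfg$n_centers, 2)
  cx[1, ] <- stats::runif(2, 0, side)
  for (i in seq_len(cfg$n_centers)[-1]) {
    if (stats::runif(1) < cfg$cluster_p) {
      anchor <- cx[sample.int(i - 1, 1), ]
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 10)
      cand <- anchor + rad * c(cos(ang), sin(ang))
      cx[i, ] <- pmin(pmax(cand, 0), side)
    } else {
      cx[i, ] <- stats::runif(2, 0, side)
    }
  }
  centers <- data.frame(id = sprintf("C%02d", seq_len(cfg$n_centers)),
                        x = cx[, 1], y = cx[, 2], stringsAsFactors = FALSE)

  facility_xwalk <- data.frame(alias_id = paste0("X", centers$id),
                               canonical_id = centers$id,
                               stringsAsFactors = FALSE)

  structure(list(blockgroups = list(geoms = bg_geoms, props = bg_props),
                 tracts = list(geoms = tract_geoms, props = tract_props),
                 hrrs = list(geoms = hrr_geoms, props = hrr_props),
                 zips = list(geoms = zip_geoms, props = zip_props),
                 zip_hrr = zip_hrr, zip_tract = zip_tract,
                 facility_xwalk = facility_xwalk, centers = centers,
                 config = cfg),
            class = "trr_system")
}

#' Generate synthetic waitlist records
#'
#' Each record is one patient-center listing interval with a home zip,
#' facility id (sometimes an alias), birth date, start date, and an end date
#' that is missing with configured probability. Patients choose centers with
#' probability decaying exponentially in the distance from their home-zip
#' centroid, so each HRR has a well-defined plurality center.
#'
#' @param sys A `trr_system` from [generate_geography()].
#' @param cfg A [waitlist_config()].
#' @return Data frame with columns `patient_id`, `facility_id`, `zip`,
#'   `birth_date`, `start_date`, `end_date` (Date columns; `NA` = missing).
#' @export
generate_waitlist <- function(sys, cfg) {
  stopifnot(inherits(sys, "trr_system"), inherits(cfg, "waitlist_config"))
  if (!nrow(sys$centers)) stop("center table is empty")
  set.seed(subseed(cfg$seed, 3))

  zips <- names(sys$zips$geoms)
  zc <- t(vapply(sys$zips$geoms, geo_centroid, numeric(2)))
  cc <- as.matrix(sys$centers[, c("x", "y")])
  # distance-decay choice weights, zips x centers
  d <- sqrt(outer(zc[, 1], cc[, 1], "-")^2 + outer(zc[, 2], cc[, 2], "-")^2)
  w <- exp(-d / cfg$decay_scale)

  np <- cfg$n_patients
  pat_zip_idx <- sample.int(length(zips), np, replace = TRUE)
  pick_center <- function(zi, exclude = 0L) {
    wt <- w[zi, ]
    if (exclude > 0L) wt[exclude] <- 0
    sample.int(nrow(cc), 1L, prob = wt)
  }
  primary <- vapply(pat_zip_idx, pick_center, integer(1))
  second <- rep(NA_integer_, np)
  multi <- stats::runif(np) < cfg$p_multi
  second[multi] <- mapply(pick_center, pat_zip_idx[multi], primary[multi])

  # birth dates: adults aged 25-75 at study start; a p_minor fraction have
  # their 18th birthday uniformly inside the study period
  study_len <- as.numeric(cfg$study_end - cfg$study_start)
  birth <- cfg$study_start - round(stats::runif(np, 25, 75) * 365.25)
  minor <- stats::runif(np) < cfg$p_minor
  bday18 <- cfg$study_start + floor(stats::runif(sum(minor)) * study_len)
  birth[minor] <- lubridate::`%m-%`(bday18, lubridate::years(18))

  listing <- data.frame(
    pat = c(seq_len(np), which(multi)),
    ctr = c(primary, second[multi]))
  rep_extra <- which(stats::runif(nrow(listing)) < cfg$p_repeat)
  entries <- rbind(listing, listing[rep_extra, ])
  ne <- nrow(entries)

  start <- cfg$study_start - 365 + floor(stats::runif(ne) * (study_len + 730))
  dur <- 30 + pmin(round(stats::rexp(ne, 1 / 400)), 3000)
  end <- start + dur
  rev_sel <- stats::runif(ne) < cfg$p_reversed
  tmp <- start[rev_sel]; start[rev_sel] <- end[rev_sel]; end[rev_sel] <- tmp
  start[stats::runif(ne) < cfg$p_missing_start] <- NA
  end[stats::runif(ne) < cfg$p_missing_end] <- NA

  fid <- sys$centers$id[entries$ctr]
  alias <- stats::runif(ne) < cfg$alias_fraction
  fid[alias] <- paste0("X", fid[alias])

  out <- data.frame(patient_id = sprintf("P%05d", entries$pat),
                    facility_id = fid,
                    zip = zips[pat_zip_idx[entries$pat]],
                    birth_date = birth[entries$pat],
                    start_date = start,
                    end_date = end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$facility_id, out$start_date), ]
  rownames(out) <- NULL
  out
}

# ---- serialization --------------------------------------------------------

date_chr <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

#' Write a synthetic system's layers and tables to a directory
#'
#' Emits `blockgroups.geojson`, `tracts.geojson`, `hrrs.geojson`,
#' `zips.geojson`, `zip_hrr.csv`, `zip_tract.csv`, `facility_xwalk.csv`,
#' and `centers.csv`.
#'
#' @param sys A `trr_system`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_system <- function(sys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_geojson(sys$blockgroups$geoms, file.path(dir, "blockgroups.geojson"),
                props = sys$blockgroups$props)
  write_geojson(sys$tracts$geoms, file.path(dir, "tracts.geojson"),
                props = sys$tracts$props)
  write_geojson(sys$hrrs$geoms, file.path(dir, "hrrs.geojson"),
                props = sys$hrrs$props)
  write_geojson(sys$zips$geoms, file.path(dir, "zips.geojson"),
                props = sys$zips$props)
  utils::write.csv(sys$zip_hrr, file.path(dir, "zip_hrr.csv"),
                   row.names = FALSE)
  utils::write.csv(sys$zip_tract, file.path(dir, "zip_tract.csv"),
                   row.names = FALSE)
  utils::write.csv(sys$facility_xwalk, file.path(dir, "facility_xwalk.csv"),
                   row.names = FALSE)
  utils::write.csv(sys$centers, file.path(dir, "centers.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a system directory written by [write_system()]
#'
#' @param dir Directory containing the layer and table files.
#' @return A `trr_system` (without `config`).
#' @export
read_system <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                                    colClasses = "character")
  structure(list(blockgroups = read_geojson(file.path(dir, "blockgroups.geojson")),
                 tracts = read_geojson(file.path(dir, "tracts.geojson")),
                 hrrs = read_geojson(file.path(dir, "hrrs.geojson")),
                 zips = read_geojson(file.path(dir, "zips.geojson")),
                 zip_hrr = rd("zip_hrr.csv"),
                 zip_tract = rd("zip_tract.csv"),
                 facility_xwalk = rd("facility_xwalk.csv"),
                 centers = transform(rd("centers.csv"),
                                     x = as.numeric(x), y = as.numeric(y)),
                 config = NULL),
            class = "trr_system")
}

#' Write waitlist records as CSV (ISO-8601 dates, empty string = missing)
#'
#' @param wl Waitlist data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_waitlist <- function(wl, path) {
  out <- wl
  for (col in c("birth_date", "start_date", "end_date"))
    out[[col]] <- date_chr(out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a waitlist CSV written by [write_waitlist()]
#'
#' @param path Input file.
#' @return Waitlist data frame with Date columns (`NA` = missing).
#' @export
read_waitlist <- function(path) {
  wl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("birth_date", "start_date", "end_date"))
    wl[[col]] <- as.Date(ifelse(wl[[col]] == "", NA, wl[[col]]))
  wl
}
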