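# Transplant referral region (TRR) derivation: centers within 10 straight-
# line miles of each other (directly or through a chain) are merged into
# center groups; waitlist entries are allocated to HRRs through the zip
# crosswalk (split zips go to every HRR they touch); each HRR goes to the
# center group with the most distinct waitlisted patients; a group's TRR is
# the dissolve of its HRRs.

#' Group transplant centers by proximity
#'
#' Connected components of the graph whose edges join centers at distance
#' `<= threshold` (default 10, the straight-line-miles merging rule), so two
#' distant centers linked by a third near both land in one group.
#'
#' @param centers Data frame with columns `id`, `x`, `y`.
#' @param threshold Merge distance (> 0).
#' @param lonlat Treat coordinates as lon/lat degrees and distances as
#'   great-circle miles.
#' @return Data frame with columns `group_id`, `center_id`, `group_x`,
#'   `group_y` (group representative = mean of member coordinates). The
#'   grouping is invariant to the input row order.
#' @export
group_centers <- function(centers, threshold = 10, lonlat = FALSE) {
  if (threshold <= 0) stop("threshold must be positive")
  if (anyDuplicated(centers$id))
    stop(sprintf("duplicate center id(s): %s",
                 paste(unique(centers$id[duplicated(centers$id)]),
                       collapse = ", ")))
  centers <- centers[order(centers$id), , drop = FALSE]
  nc <- nrow(centers)
  xy <- as.matrix(centers[, c("x", "y")])
  edges <- NULL
  if (nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (geo_distance(xy[i, ], xy[j, ], lonlat = lonlat) <= threshold)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # deterministic labels: groups ordered by their smallest member center id
  first_id <- tapply(centers$id, comp, min)
  ord <- order(first_id)
  relabel <- stats::setNames(seq_along(ord), names(first_id)[ord])
  gidx <- relabel[as.character(comp)]
  gid <- sprintf("G%02d", gidx)
  gx <- tapply(centers$x, gid, mean)[gid]
  gy <- tapply(centers$y, gid, mean)[gid]
  data.frame(group_id = gid, center_id = centers$id,
             group_x = unname(gx), group_y = unname(gy),
             stringsAsFactors = FALSE)
}

#' Allocate cohort entries to HRRs through the zip crosswalk
#'
#' An entry whose home zip maps to several HRRs is emitted once per HRR
#' (split zips go to all relevant HRRs). Entries whose zip is absent from
#' the crosswalk are dropped and tallied.
#'
#' @param cohort Filtered cohort data frame (needs `patient_id`,
#'   `facility_id`, `zip`).
#' @param zip_hrr Crosswalk data frame with columns `zip`, `hrr`.
#' @return List with `pairs` (cohort columns plus `hrr`) and
#'   `n_unmatched_zip` (entries dropped).
#' @export
allocate_entries_to_hrrs <- function(cohort, zip_hrr) {
  matched <- cohort$zip %in% zip_hrr$zip
  pairs <- merge(cohort[matched, , drop = FALSE], zip_hrr, by = "zip")
  pairs <- pairs[order(pairs$hrr, pairs$patient_id, pairs$facility_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, n_unmatched_zip = sum(!matched))
}

#' Count distinct patients per (HRR, center group)
#'
#' Within one HRR a patient contributes at most 1 to a center group however
#' many entries they have at that group's centers; a patient listed at
#' centers in two groups contributes 1 to each.
#'
#' @param pairs `(entry, HRR)` pairs from [allocate_entries_to_hrrs()].
#' @param groups Center grouping from [group_centers()].
#' @return Data frame with columns `hrr`, `group_id`, `n_patients`.
#' @export
count_patients <- function(pairs, groups) {
  gmap <- stats::setNames(groups$group_id, groups$center_id)
  unknown <- setdiff(unique(pairs$facility_id), names(gmap))
  if (length(unknown))
    stop(sprintf("entries at center(s) missing from grouping: %s",
                 paste(unknown, collapse = ", ")))
  key <- unique(data.frame(hrr = pairs$hrr,
                           group_id = unname(gmap[pairs$facility_id]),
                           patient_id = pairs$patient_id,
                           stringsAsFactors = FALSE))
  agg <- stats::aggregate(patient_id ~ hrr + group_id, data = key, FUN = length)
  names(agg)[3] <- "n_patients"
  agg[order(agg$hrr, agg$group_id), , drop = FALSE]
}

#' Assign each HRR to the center group with the most patients
#'
#' Plurality (argmax) assignment. Exact count ties go to the group whose
#' representative point is nearest the HRR centroid, then to the smallest
#' group id; ties are flagged. HRRs with zero waitlisted patients stay
#' unassigned.
#'
#' @param counts Output of [count_patients()].
#' @param hrr_geoms Named list of HRR polygons (for centroids).
#' @param groups Center grouping from [group_centers()].
#' @return Data frame with columns `hrr_id`, `trr_id` (winning group),
#'   `winning_count`, `runner_up_count`, `tie_flag`.
#' @export
assign_hrrs <- function(counts, hrr_geoms, groups) {
  gxy <- unique(groups[, c("group_id", "group_x", "group_y")])
  rows <- lapply(split(counts, counts$hrr), function(cc) {
    hrr <- cc$hrr[1]
    top <- max(cc$n_patients)
    cand <- cc$group_id[cc$n_patients == top]
    tie <- length(cand) > 1
    if (tie) {
      cen <- geo_centroid(hrr_geoms[[hrr]])
      gm <- gxy[match(cand, gxy$group_id), ]
      dd <- sqrt((gm$group_x - cen[1])^2 + (gm$group_y - cen[2])^2)
      cand <- cand[order(dd, cand)]
    }
    runner <- if (nrow(cc) > 1) {
      sort(cc$n_patients, decreasing = TRUE)[2]
    } else 0L
    data.frame(hrr_id = hrr, trr_id = cand[1], winning_count = top,
               runner_up_count = runner, tie_flag = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$hrr_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dissolve each winning group's HRRs into its TRR
#'
#' @param assignments Output of [assign_hrrs()].
#' @param hrr_geoms Named list of HRR polygons.
#' @param groups Center grouping from [group_centers()].
#' @return Named list of TRRs; each a list with `id`, `geom`
#'   (`trr_multipolygon`), `member_hrrs`, `member_centers`.
#' @export
build_trrs <- function(assignments, hrr_geoms, groups) {
  missing_hrr <- setdiff(assignments$hrr_id, names(hrr_geoms))
  if (length(missing_hrr))
    stop(sprintf("assignment references unknown HRR(s): %s",
                 paste(missing_hrr, collapse = ", ")))
  out <- list()
  for (gid in sort(unique(assignments$trr_id))) {
    hrrs <- assignments$hrr_id[assignments$trr_id == gid]
    geom <- geo_dissolve(hrr_geoms[hrrs], id = gid)
    out[[gid]] <- list(id = gid, geom = geom, member_hrrs = hrrs,
                       member_centers = groups$center_id[groups$group_id == gid])
  }
  out
}

#' Derive TRRs end to end
#'
#' Convenience wrapper: group centers, allocate the cohort to HRRs, count
#' distinct patients, assign HRRs, dissolve.
#'
#' @param cohort Filtered cohort data frame.
#' @param sys A `trr_system` (for the zip-HRR crosswalk, HRR geometries and
#'   centers).
#' @param threshold Center-merging distance (default 10).
#' @param lonlat Passed to [group_centers()].
#' @return List with `groups`, `assignments`, `trrs`, `counts`,
#'   `n_unmatched_zip`, and `unassigned_hrrs` (zero-patient HRRs).
#' @export
derive_trrs <- function(cohort, sys, threshold = 10, lonlat = FALSE) {
  groups <- group_centers(sys$centers, threshold = threshold, lonlat = lonlat)
  alloc <- allocate_entries_to_hrrs(cohort, sys$zip_hrr)
  counts <- count_patients(alloc$pairs, groups)
  assignments <- assign_hrrs(counts, sys$hrrs$geoms, groups)
  trrs <- build_trrs(assignments, sys$hrrs$geoms, groups)
  list(groups = groups, assignments = assignments, trrs = trrs,
       counts = counts, n_unmatched_zip = alloc$n_unmatched_zip,
       unassigned_hrrs = setdiff(names(sys$hrrs$geoms), assignments$hrr_id))
}

#' Write TRR geometries and HRR assignments
#'
#' @param derived Result of [derive_trrs()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trrs <- function(derived, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geoms <- lapply(derived$trrs, function(t) t$geom)
  props <- data.frame(
    id = names(derived$trrs),
    member_hrrs = vapply(derived$trrs,
                         function(t) paste(t$member_hrrs, collapse = ";"),
                         character(1)),
    member_centers = vapply(derived$trrs,
                            function(t) paste(t$member_centers, collapse = ";"),
                            character(1)),
    stringsAsFactors = FALSE)
  write_geojson(geoms, file.path(dir, "trrs.geojson"), props = props)
  utils::write.csv(derived$assignments,
                   file.path(dir, "hrr_assignments.csv"), row.names = FALSE)
  invisible(dir)
}
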