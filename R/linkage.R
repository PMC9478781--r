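# The two competing census-unit -> TRR linkage methods.
#
# Zip method: chain the zip-tract crosswalk through the zip-HRR crosswalk
# and the HRR -> TRR assignment; every reachable TRR is kept (the real
# crosswalks are many-to-many, and preserving all chains is what produces
# multiplets). Block groups inherit the parent tract's TRR set.
#
# Spatial method: clip units to the HRR coverage, intersect each with every
# TRR, and assign the single TRR with the largest intersection area.

# Internal fast constructor for a multipolygon known to have pairwise
# interior-disjoint members (tessellation pieces): skips the union-area
# computation.
mp_disjoint <- function(polys, id = NULL) {
  structure(list(polys = polys, id = id,
                 area = sum(vapply(polys, geo_area, numeric(1))),
                 overlapping = FALSE),
            class = "trr_multipolygon")
}

#' Clip census units to the HRR coverage
#'
#' Dissolves the HRR layer into one coverage geometry and replaces each unit
#' by its intersection with it (dropping coastline-like slivers outside any
#' HRR). The per-HRR decomposition of every clipped unit is retained as an
#' overlap table, which downstream linkage and error metrics reuse.
#'
#' @param units Named list of unit polygons (tracts or block groups).
#' @param hrr_geoms Non-empty named list of HRR polygons (interior-disjoint).
#' @return List with `clipped` (named list of clipped unit geometries),
#'   `areas` (named vector of clipped areas), `overlap` (data frame
#'   `unit_id`, `hrr_id`, `area`), and `dropped` (ids of units wholly
#'   outside the coverage).
#' @export
clip_units_to_coverage <- function(units, hrr_geoms) {
  if (!length(hrr_geoms)) stop("HRR layer is empty")
  hrr_pieces <- lapply(hrr_geoms, convex_pieces)
  hrr_bb <- lapply(hrr_geoms, function(g) bbox_of(g$rings[[1]]))
  clipped <- list()
  areas <- numeric(0)
  dropped <- character(0)
  ov <- vector("list", length(units))
  for (ui in seq_along(units)) {
    uid <- names(units)[ui]
    u <- units[[ui]]
    up <- convex_pieces(u)
    ubb <- bbox_of(u$rings[[1]])
    tol <- 1e-9 * geo_area(u)
    pieces <- list()
    hit_hrr <- character(0)
    hit_area <- numeric(0)
    for (hi in seq_along(hrr_geoms)) {
      if (bboxes_disjoint(ubb, hrr_bb[[hi]])) next
      a_hrr <- 0
      for (pu in up) for (ph in hrr_pieces[[hi]]) {
        clp <- convex_clip(pu$coords, ph$coords)
        pa <- piece_area(clp)
        if (pa > tol) {
          a_hrr <- a_hrr + pa
          pieces[[length(pieces) + 1L]] <-
            trr_polygon(clp, validate = FALSE)
        }
      }
      if (a_hrr > tol) {
        hit_hrr <- c(hit_hrr, names(hrr_geoms)[hi])
        hit_area <- c(hit_area, a_hrr)
      }
    }
    if (!length(pieces)) {
      dropped <- c(dropped, uid)
      next
    }
    clipped[[uid]] <- mp_disjoint(pieces, id = uid)
    areas[uid] <- clipped[[uid]]$area
    ov[[ui]] <- data.frame(unit_id = uid, hrr_id = hit_hrr, area = hit_area,
                           stringsAsFactors = FALSE)
  }
  overlap <- do.call(rbind, ov[!vapply(ov, is.null, logical(1))])
  rownames(overlap) <- NULL
  list(clipped = clipped, areas = areas, overlap = overlap, dropped = dropped)
}

#' Link census units to TRRs through the zip crosswalk chain
#'
#' Tract assignments are every TRR reachable via a tract -> zip -> HRR ->
#' TRR chain; block groups inherit the parent tract's TRR set. Units whose
#' chains reach no TRR are unassigned and logged.
#'
#' @param tract_ids Character vector of tract ids.
#' @param bg_parent Named character vector: block-group id -> parent tract id.
#' @param zip_tract Crosswalk data frame (`zip`, `tract`).
#' @param zip_hrr Crosswalk data frame (`zip`, `hrr`).
#' @param hrr_assignments Data frame from [assign_hrrs()] (`hrr_id`,
#'   `trr_id`).
#' @return List with `tract` and `blockgroup` assignment data frames
#'   (`unit_id`, `trr_id`; one row per pair) and `unassigned` (list of id
#'   vectors per scale).
#' @export
link_zip_method <- function(tract_ids, bg_parent, zip_tract, zip_hrr,
                            hrr_assignments) {
  chain <- merge(zip_tract, zip_hrr, by = "zip")
  chain <- merge(chain, hrr_assignments[, c("hrr_id", "trr_id")],
                 by.x = "hrr", by.y = "hrr_id")
  tr <- unique(chain[, c("tract", "trr_id")])
  names(tr) <- c("unit_id", "trr_id")
  tr <- tr[tr$unit_id %in% tract_ids, , drop = FALSE]
  tr <- tr[order(tr$unit_id, tr$trr_id), , drop = FALSE]
  rownames(tr) <- NULL

  unknown <- setdiff(unique(unname(bg_parent)), tract_ids)
  if (length(unknown))
    stop(sprintf("block group(s) with unknown parent tract: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  bg_ids <- names(bg_parent)
  hit <- bg_parent[bg_ids] %in% tr$unit_id
  bgl <- lapply(bg_ids[hit], function(b) {
    data.frame(unit_id = b,
               trr_id = tr$trr_id[tr$unit_id == bg_parent[[b]]],
               stringsAsFactors = FALSE)
  })
  bg <- do.call(rbind, bgl)
  if (is.null(bg)) bg <- data.frame(unit_id = character(0),
                                    trr_id = character(0))
  bg <- bg[order(bg$unit_id, bg$trr_id), , drop = FALSE]
  rownames(bg) <- NULL
  list(tract = tr, blockgroup = bg,
       unassigned = list(tract = setdiff(tract_ids, tr$unit_id),
                         blockgroup = bg_ids[!hit]))
}

#' Link clipped census units to TRRs by largest spatial overlap
#'
#' For each clipped unit the intersection area with every TRR is computed
#' (from the per-HRR overlap table; a TRR's area of intersection is the sum
#' over its member HRRs) and the unit is assigned to the argmax. Areas below
#' a sliver tolerance (1e-9 of the unit area) are zeroed first. Exact ties
#' go to the smallest TRR id and are logged.
#'
#' @param clip Result of [clip_units_to_coverage()] for one unit scale.
#' @param trrs Named TRR list from [build_trrs()].
#' @return List with `assignments` (data frame `unit_id`, `trr_id`; exactly
#'   one row per assigned unit), `unassigned` (ids intersecting no TRR), and
#'   `ties` (data frame of tie events).
#' @export
link_spatial_method <- function(clip, trrs) {
  hrr_to_trr <- do.call(rbind, lapply(trrs, function(t)
    data.frame(hrr_id = t$member_hrrs, trr_id = t$id,
               stringsAsFactors = FALSE)))
  ov <- merge(clip$overlap, hrr_to_trr, by = "hrr_id")
  if (nrow(ov)) {
    ut <- stats::aggregate(area ~ unit_id + trr_id, data = ov, FUN = sum)
  } else {
    ut <- data.frame(unit_id = character(0), trr_id = character(0),
                     area = numeric(0))
  }
  rows <- vector("list", 0)
  ties <- vector("list", 0)
  for (piece in split(ut, ut$unit_id)) {
    uid <- piece$unit_id[1]
    tol <- 1e-9 * clip$areas[[uid]]
    piece <- piece[piece$area > tol, , drop = FALSE]
    if (!nrow(piece)) next
    top <- max(piece$area)
    cand <- sort(piece$trr_id[piece$area == top])
    if (length(cand) > 1)
      ties[[length(ties) + 1L]] <- data.frame(unit_id = uid,
                                              tied_trrs = paste(cand, collapse = ";"),
                                              stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(unit_id = uid, trr_id = cand[1],
                                            stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- data.frame(unit_id = character(0), trr_id = character(0))
  assignments <- assignments[order(assignments$unit_id), , drop = FALSE]
  rownames(assignments) <- NULL
  tie_df <- if (length(ties)) do.call(rbind, ties) else
    data.frame(unit_id = character(0), tied_trrs = character(0))
  list(assignments = assignments,
       unassigned = setdiff(names(clip$clipped), assignments$unit_id),
       ties = tie_df)
}
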