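# GeoJSON (RFC 7946) reading and writing, one FeatureCollection per layer.
# Every feature carries a mandatory "id" property; extra per-feature
# properties round-trip through the `props` data frame.

close_ring <- function(m) rbind(m, m[1, , drop = FALSE])

geom_to_geojson <- function(g) {
  if (inherits(g, "trr_polygon")) {
    list(type = "Polygon",
         coordinates = lapply(g$rings, close_ring))
  } else if (inherits(g, "trr_multipolygon")) {
    list(type = "MultiPolygon",
         coordinates = lapply(g$polys, function(p) lapply(p$rings, close_ring)))
  } else stop("not a geometry object")
}

geojson_to_geom <- function(gj, id = NULL) {
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(xy)
      c(as.numeric(xy[[1]]), as.numeric(xy[[2]]))))
    storage.mode(m) <- "double"
    m
  }
  if (gj$type == "Polygon") {
    rings <- lapply(gj$coordinates, ring_mat)
    trr_polygon(rings[[1]], holes = rings[-1], id = id)
  } else if (gj$type == "MultiPolygon") {
    polys <- lapply(gj$coordinates, function(pc) {
      rings <- lapply(pc, ring_mat)
      trr_polygon(rings[[1]], holes = rings[-1])
    })
    trr_multipolygon(polys, id = id)
  } else stop(sprintf("unsupported GeoJSON geometry type '%s'", gj$type))
}

#' Write a layer of geometries as a GeoJSON FeatureCollection
#'
#' @param geoms Named list of `trr_polygon`/`trr_multipolygon` objects; names
#'   are feature ids.
#' @param path Output file.
#' @param props Optional data frame of per-feature properties with an `id`
#'   column matching `names(geoms)`.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geoms, path, props = NULL) {
  stopifnot(!is.null(names(geoms)), !any(names(geoms) == ""))
  feats <- lapply(names(geoms), function(id) {
    pr <- list(id = id)
    if (!is.null(props)) {
      row <- props[props$id == id, setdiff(names(props), "id"), drop = FALSE]
      if (nrow(row) == 1) pr <- c(pr, as.list(row))
    }
    list(type = "Feature",
         properties = pr,
         geometry = geom_to_geojson(geoms[[id]]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_geojson()]
#'
#' @param path Input file.
#' @return List with `geoms` (named list of geometries) and `props` (data
#'   frame of feature properties, one row per feature).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a FeatureCollection")
  ids <- vapply(fc$features, function(f) as.character(f$properties$id),
                character(1))
  geoms <- stats::setNames(
    lapply(seq_along(fc$features),
           function(i) geojson_to_geom(fc$features[[i]]$geometry, id = ids[i])),
    ids)
  prop_rows <- lapply(fc$features, function(f) {
    pr <- f$properties
    pr[vapply(pr, is.list, logical(1))] <-
      lapply(pr[vapply(pr, is.list, logical(1))],
             function(x) paste(unlist(x), collapse = ";"))
    as.data.frame(pr, stringsAsFactors = FALSE)
  })
  props <- do.call(rbind, prop_rows)
  list(geoms = geoms, props = props)
}
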