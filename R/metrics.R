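# Error metrics for the two linkage methods: multiplet counts (units
# assigned to more than one TRR, whose data would be aggregated twice),
# per-TRR misassigned area decomposed into assigned-but-outside and
# uncovered components, summary tables, and the paired Wilcoxon signed-rank
# comparison between methods.

#' Count multiplets (units assigned to more than one TRR)
#'
#' @param assignments Assignment data frame (`unit_id`, `trr_id`; one row
#'   per pair) for one method and scale.
#' @param unit_areas Named vector of (clipped) unit areas.
#' @param total_trr_area Total area covered by TRRs (denominator of the
#'   percentage).
#' @return List with `n_multiplets`, `area_double_assigned`, and
#'   `pct_of_trr_area`.
#' @export
count_multiplets <- function(assignments, unit_areas, total_trr_area) {
  if (!nrow(assignments))
    return(list(n_multiplets = 0L, area_double_assigned = 0,
                pct_of_trr_area = 0))
  k <- table(assignments$unit_id)
  multi <- names(k)[k >= 2]
  area <- sum(unit_areas[multi])
  list(n_multiplets = length(multi),
       area_double_assigned = unname(area),
       pct_of_trr_area = unname(100 * area / total_trr_area))
}

#' Misassigned area of one TRR given its assigned units
#'
#' Decomposes the symmetric difference between the TRR polygon and the union
#' of the units assigned to it: `outside` is the assigned-unit area lying
#' outside the TRR, `uncovered` is the TRR area covered by no assigned unit.
#' Units are assumed pairwise interior-disjoint (census units of one scale).
#'
#' @param trr_geom TRR geometry (`trr_polygon` or `trr_multipolygon`).
#' @param unit_geoms List of assigned (clipped) unit geometries; may be
#'   empty, in which case the whole TRR is uncovered.
#' @return List with `outside`, `uncovered`, `total`, `percent`.
#' @export
misassigned_area <- function(trr_geom, unit_geoms) {
  t_area <- geo_area(trr_geom)
  if (t_area <= 0) stop("TRR has zero area")
  if (!length(unit_geoms)) {
    return(list(outside = 0, uncovered = t_area, total = t_area,
                percent = 100))
  }
  u_area <- vapply(unit_geoms, geo_area, numeric(1))
  i_area <- vapply(unit_geoms, function(u) geo_intersection_area(u, trr_geom),
                   numeric(1))
  outside <- max(sum(u_area) - sum(i_area), 0)
  uncovered <- max(t_area - sum(i_area), 0)
  total <- outside + uncovered
  list(outside = outside, uncovered = uncovered, total = total,
       percent = 100 * total / t_area)
}

# Pipeline fast path: per-TRR misassignment from the per-HRR overlap table
# produced by clip_units_to_coverage(). For a unit assigned to a TRR, its
# intersection with that TRR is the sum of its overlaps with the TRR's
# member HRRs; its outside portion is its clipped area minus that.
misassignment_from_overlap <- function(assignments, clip, trrs,
                                       method, scale) {
  ov <- clip$overlap
  rows <- lapply(names(trrs), function(tid) {
    t_area <- geo_area(trrs[[tid]]$geom)
    units <- assignments$unit_id[assignments$trr_id == tid]
    if (length(units)) {
      sel <- ov$unit_id %in% units & ov$hrr_id %in% trrs[[tid]]$member_hrrs
      inter <- sum(ov$area[sel])
      u_tot <- sum(clip$areas[units])
    } else {
      inter <- 0; u_tot <- 0
    }
    outside <- max(u_tot - inter, 0)
    uncovered <- max(t_area - inter, 0)
    data.frame(method = method, scale = scale, trr_id = tid,
               area_outside = outside, area_uncovered = uncovered,
               area_total = outside + uncovered,
               pct = 100 * (outside + uncovered) / t_area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (standard signed-rank convention); absolute
#' differences are ranked with mean ranks for ties; `W` is the sum of the
#' ranks of the positive differences. For `n <= 12` the two-sided p-value is
#' exact, by enumerating all `2^n` sign patterns of the observed ranks (so
#' ties are handled exactly); beyond that a normal approximation with tie
#' correction and continuity correction is used. p is clamped to [0, 1].
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact enumeration is used.
#' @return List with `statistic` (W), `p_value`, `n` (nonzero differences),
#'   `n_zero_dropped`, and `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 12) {
  d <- d[is.finite(d)]
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) stop("all differences are zero; signed-rank test is degenerate")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)   # all 2^n signed-rank sums
    p <- 2 * min(mean(sums <= W + 1e-12), mean(sums >= W - 1e-12))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = W, p_value = min(max(p, 0), 1), n = n,
       n_zero_dropped = n_zero, method = method)
}

#' Summarize per-TRR misassignment and compare methods
#'
#' Produces the per-method, per-scale summary (mean, sample SD, median,
#' range, for percent and absolute misassigned area) and the paired
#' signed-rank p-value comparing methods within each scale (pairing per-TRR
#' values, zip minus spatial).
#'
#' @param records Data frame of per-TRR misassignment rows (as produced by
#'   the pipeline; columns `method`, `scale`, `trr_id`, `area_total`,
#'   `pct`).
#' @return Data frame, one row per method x scale, with summary columns, an
#'   `sd_undefined` flag for single-record cells, and `p_value` (on zip
#'   rows; comparison against the spatial method at the same scale).
#' @export
summarize_misassignment <- function(records) {
  if (!nrow(records)) stop("no misassignment records to summarize")
  cells <- split(records, list(records$method, records$scale), drop = TRUE)
  rows <- lapply(cells, function(cc) {
    s <- function(x) {
      c(mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else 0,
        median = stats::median(x), min = min(x), max = max(x))
    }
    sp <- s(cc$pct); sa <- s(cc$area_total)
    data.frame(method = cc$method[1], scale = cc$scale[1], n = nrow(cc),
               mean_pct = sp["mean"], sd_pct = sp["sd"],
               median_pct = sp["median"], min_pct = sp["min"],
               max_pct = sp["max"],
               mean_area = sa["mean"], sd_area = sa["sd"],
               median_area = sa["median"], min_area = sa["min"],
               max_area = sa["max"],
               sd_undefined = nrow(cc) < 2,
               p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # paired comparison per scale: zip minus spatial on per-TRR percent
  for (sc in unique(out$scale)) {
    zi <- records[records$method == "zip" & records$scale == sc, ]
    sp <- records[records$method == "spatial" & records$scale == sc, ]
    common <- intersect(zi$trr_id, sp$trr_id)
    if (length(common) < 1) next
    dif <- zi$pct[match(common, zi$trr_id)] - sp$pct[match(common, sp$trr_id)]
    if (all(dif == 0)) next
    w <- wilcoxon_signed_rank(dif)
    out$p_value[out$method == "zip" & out$scale == sc] <- w$p_value
  }
  out[order(out$method, out$scale), , drop = FALSE]
}

#' Build the multiplet (Table 1 analogue) report for all methods and scales
#'
#' @param assignment_sets Named list of assignment data frames keyed
#'   `"method.scale"` (e.g. `zip.tract`), each with columns `unit_id`,
#'   `trr_id`.
#' @param clip_by_scale Named list of [clip_units_to_coverage()] results,
#'   keyed by scale.
#' @param trrs TRR list (for the total TRR area).
#' @return Data frame with columns `method`, `scale`, `n_double_assigned`,
#'   `area_double_assigned`, `pct_of_total_trr_area`.
#' @export
multiplet_table <- function(assignment_sets, clip_by_scale, trrs) {
  total_area <- sum(vapply(trrs, function(t) geo_area(t$geom), numeric(1)))
  rows <- lapply(names(assignment_sets), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    method <- parts[1]; scale <- parts[2]
    mp <- count_multiplets(assignment_sets[[key]],
                           clip_by_scale[[scale]]$areas, total_area)
    data.frame(method = method, scale = scale,
               n_double_assigned = mp$n_multiplets,
               area_double_assigned = mp$area_double_assigned,
               pct_of_total_trr_area = mp$pct_of_trr_area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$method, out$scale), , drop = FALSE]
}
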