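# End-to-end pipeline: simulate -> cohort -> derive TRRs -> link census
# units by both methods -> error metrics -> tables + provenance manifest.
# Identical configuration and seed reproduce byte-identical artifacts.

#' Pipeline run configuration
#'
#' @param geography A [geography_config()].
#' @param waitlist A [waitlist_config()].
#' @param threshold Center-merging distance (default 10 straight-line
#'   units/miles).
#' @param scales Unit scales to evaluate; subset of
#'   `c("tract", "blockgroup")`.
#' @param seed Optional master seed overriding the seeds inside both
#'   sub-configurations.
#' @return A `run_config` list.
#' @export
run_config <- function(geography = geography_config(),
                       waitlist = waitlist_config(),
                       threshold = 10,
                       scales = c("tract", "blockgroup"),
                       seed = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!length(scales) || !all(scales %in% c("tract", "blockgroup")))
    stop("scales must be a non-empty subset of c('tract', 'blockgroup')")
  if (!is.null(seed)) {
    geography$seed <- seed
    waitlist$seed <- seed
  }
  structure(list(geography = geography, waitlist = waitlist,
                 threshold = threshold, scales = scales),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a freshly generated (or supplied) synthetic
#' system and returns all intermediate products and summary tables. When
#' `outdir` is given, writes the standard artifact set: the system layers
#' and crosswalks, `waitlist.csv`, `cohort.csv` + `exclusions.json`,
#' `trrs.geojson` + `hrr_assignments.csv`, per-method/scale assignment and
#' misassignment CSVs, `table1.csv`, `table2.csv`, and `manifest.json`
#' recording the configuration, seed and every drop/tie count.
#'
#' @param cfg A [run_config()].
#' @param outdir Optional output directory.
#' @param system Optional pre-built `trr_system` (e.g. read back from disk
#'   via [read_system()]); skips geography generation.
#' @param waitlist Optional pre-built waitlist data frame; skips waitlist
#'   generation.
#' @return List with `system`, `waitlist`, `cohort`, `derived`, `clip`,
#'   `assignments`, `records`, `table1`, `table2`, and `manifest`.
#' @export
run_pipeline <- function(cfg, outdir = NULL, system = NULL, waitlist = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  sys <- system %||% stage("simulate", generate_geography(cfg$geography))
  wl <- waitlist %||% stage("simulate", generate_waitlist(sys, cfg$waitlist))

  period <- study_period(cfg$waitlist$study_start, cfg$waitlist$study_end)
  canon <- stage("cohort",
                 canonicalize_facilities(wl, sys$facility_xwalk,
                                         sys$centers$id))
  filt <- stage("cohort", filter_waitlist(canon$entries, period))

  derived <- stage("derive-trr",
                   derive_trrs(filt$cohort, sys, threshold = cfg$threshold))

  clip <- list()
  unit_layers <- list(tract = sys$tracts$geoms, blockgroup = sys$blockgroups$geoms)
  for (sc in cfg$scales)
    clip[[sc]] <- stage("link",
                        clip_units_to_coverage(unit_layers[[sc]],
                                               sys$hrrs$geoms))

  bg_parent <- stats::setNames(sys$blockgroups$props$tract,
                               sys$blockgroups$props$id)
  zl <- stage("link", link_zip_method(names(sys$tracts$geoms), bg_parent,
                                      sys$zip_tract, sys$zip_hrr,
                                      derived$assignments))
  assignments <- list()
  ties <- list()
  unassigned <- list()
  for (sc in cfg$scales) {
    assignments[[paste0("zip.", sc)]] <- zl[[sc]]
    unassigned[[paste0("zip.", sc)]] <- zl$unassigned[[sc]]
    sp <- stage("link", link_spatial_method(clip[[sc]], derived$trrs))
    assignments[[paste0("spatial.", sc)]] <- sp$assignments
    unassigned[[paste0("spatial.", sc)]] <- sp$unassigned
    ties[[paste0("spatial.", sc)]] <- sp$ties
  }

  records <- do.call(rbind, lapply(names(assignments), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    stage("evaluate",
          misassignment_from_overlap(assignments[[key]], clip[[parts[2]]],
                                     derived$trrs, parts[1], parts[2]))
  }))
  table1 <- stage("evaluate", multiplet_table(assignments, clip, derived$trrs))
  table2 <- stage("evaluate", summarize_misassignment(records))

  manifest <- list(
    config = list(geography = unclass(cfg$geography),
                  waitlist = lapply(unclass(cfg$waitlist), as.character),
                  threshold = cfg$threshold, scales = cfg$scales),
    tool_version = as.character(utils::packageVersion("trrlink")),
    counts = list(
      waitlist_entries = nrow(wl),
      dropped_inactive_facility = canon$n_dropped,
      cohort_tally = as.list(filt$tally),
      entries_unmatched_zip = derived$n_unmatched_zip,
      n_center_groups = length(unique(derived$groups$group_id)),
      n_trrs = length(derived$trrs),
      unassigned_hrrs = derived$unassigned_hrrs,
      hrr_assignment_ties = sum(derived$assignments$tie_flag),
      spatial_ties = lapply(ties, nrow),
      units_dropped_by_clip = lapply(clip, function(cl) length(cl$dropped)),
      units_unassigned = lapply(unassigned, length)))

  res <- list(system = sys, waitlist = wl, cohort = filt$cohort,
              derived = derived, clip = clip, assignments = assignments,
              records = records, table1 = table1, table2 = table2,
              manifest = manifest)
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' Write all pipeline artifacts to a directory
#'
#' @param res Result of [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_system(res$system, outdir)
  write_waitlist(res$waitlist, file.path(outdir, "waitlist.csv"))
  co <- res$cohort
  for (col in c("birth_date", "start_date", "end_date",
                "interval_start", "interval_end"))
    co[[col]] <- date_chr(co[[col]])
  utils::write.csv(co, file.path(outdir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest$counts$cohort_tally,
                       file.path(outdir, "exclusions.json"),
                       auto_unbox = TRUE)
  write_trrs(res$derived, outdir)
  for (key in names(res$assignments)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    utils::write.csv(res$assignments[[key]],
                     file.path(outdir, sprintf("assignments_%s_%s.csv",
                                               parts[1], parts[2])),
                     row.names = FALSE)
  }
  for (key in unique(paste(res$records$method, res$records$scale))) {
    parts <- strsplit(key, " ")[[1]]
    sel <- res$records$method == parts[1] & res$records$scale == parts[2]
    utils::write.csv(res$records[sel, , drop = FALSE],
                     file.path(outdir, sprintf("misassignment_%s_%s.csv",
                                               parts[1], parts[2])),
                     row.names = FALSE)
  }
  utils::write.csv(res$table1, file.path(outdir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(res$table2, file.path(outdir, "table2.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
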