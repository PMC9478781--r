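#!/usr/bin/env Rscript
# Stage 4: link census units to TRRs by both methods, at both scales.
#
# Zip method: tract -> zip -> HRR -> TRR chains, all of them (split zips
# propagate a tract to several TRRs); block groups inherit the parent
# tract's TRR set. Spatial method: units clipped to the HRR coverage, then
# assigned to the single TRR with the largest intersection area.

library(trrlink)

outdir <- "results/run"
sys <- read_system(outdir)
tr <- read_geojson(file.path(outdir, "trrs.geojson"))
assignments <- utils::read.csv(file.path(outdir, "hrr_assignments.csv"),
                               stringsAsFactors = FALSE)
trrs <- lapply(seq_len(nrow(tr$props)), function(i) {
  list(id = tr$props$id[i], geom = tr$geoms[[tr$props$id[i]]],
       member_hrrs = strsplit(tr$props$member_hrrs[i], ";")[[1]],
       member_centers = strsplit(tr$props$member_centers[i], ";")[[1]])
})
names(trrs) <- tr$props$id

bg_parent <- stats::setNames(sys$blockgroups$props$tract,
                             sys$blockgroups$props$id)
zl <- link_zip_method(names(sys$tracts$geoms), bg_parent, sys$zip_tract,
                      sys$zip_hrr, assignments)

unit_layers <- list(tract = sys$tracts$geoms,
                    blockgroup = sys$blockgroups$geoms)
for (sc in c("tract", "blockgroup")) {
  cl <- clip_units_to_coverage(unit_layers[[sc]], sys$hrrs$geoms)
  sp <- link_spatial_method(cl, trrs)
  utils::write.csv(zl[[sc]],
                   file.path(outdir, sprintf("assignments_zip_%s.csv", sc)),
                   row.names = FALSE)
  utils::write.csv(sp$assignments,
                   file.path(outdir, sprintf("assignments_spatial_%s.csv", sc)),
                   row.names = FALSE)
  n_multi <- sum(table(zl[[sc]]$unit_id) > 1)
  cat(sprintf("%s: zip chains assign %d units (%d to >1 TRR); spatial assigns %d, ties %d\n",
              sc, length(unique(zl[[sc]]$unit_id)), n_multi,
              nrow(sp$assignments), nrow(sp$ties)))
}
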