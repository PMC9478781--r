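#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system and waitlist.
#
# Produces a 30 x 30 block-group grid (3 x 3 block groups per tract), 8
# Voronoi HRRs, a 10 x 10 zip grid offset by 0.3 of a cell (so zips
# straddle census and HRR boundaries), 12 transplant centers with proximity
# clustering, and 2000 patients' waitlist entries over 2008-2018.

library(trrlink)

outdir <- "results/run"
seed <- 1

sys <- generate_geography(geography_config(seed = seed))
wl <- generate_waitlist(sys, waitlist_config(seed = seed))

write_system(sys, outdir)
write_waitlist(wl, file.path(outdir, "waitlist.csv"))

split_zips <- sum(table(sys$zip_hrr$zip) > 1)
cat(sprintf("layers: %d block groups, %d tracts, %d HRRs, %d zips\n",
            length(sys$blockgroups$geoms), length(sys$tracts$geoms),
            length(sys$hrrs$geoms), length(sys$zips$geoms)))
cat(sprintf("%d of %d zips straddle more than one HRR\n",
            split_zips, length(sys$zips$geoms)))
cat(sprintf("waitlist: %d entries for %d patients at %d centers\n",
            nrow(wl), length(unique(wl$patient_id)), nrow(sys$centers)))
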