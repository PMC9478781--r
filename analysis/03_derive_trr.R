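#!/usr/bin/env Rscript
# Stage 3: derive transplant referral regions.
#
# Centers within 10 straight-line units of each other (directly or through
# a chain) merge into groups; cohort entries fan out to every HRR their zip
# touches; each HRR goes to the group with the most distinct waitlisted
# patients; a group's TRR is the dissolve of its HRRs.

library(trrlink)

outdir <- "results/run"
sys <- read_system(outdir)
cohort <- utils::read.csv(file.path(outdir, "cohort.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")

derived <- derive_trrs(cohort, sys, threshold = 10)
write_trrs(derived, outdir)

cat(sprintf("%d centers -> %d groups\n", nrow(sys$centers),
            length(unique(derived$groups$group_id))))
cat(sprintf("entries dropped (zip not in crosswalk): %d\n",
            derived$n_unmatched_zip))
cat(sprintf("%d of %d HRRs assigned (%d tie(s)); %d TRRs formed\n",
            nrow(derived$assignments), length(sys$hrrs$geoms),
            sum(derived$assignments$tie_flag), length(derived$trrs)))
for (t in derived$trrs)
  cat(sprintf("  %s: HRRs {%s}, area %.0f\n", t$id,
              paste(t$member_hrrs, collapse = ","), geo_area(t$geom)))
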