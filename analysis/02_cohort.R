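#!/usr/bin/env Rscript
# Stage 2: apply the waitlist inclusion rules.
#
# Facility aliases are folded into canonical center ids (entries at centers
# absent from the active list are dropped); entries need a valid start date,
# an adult day inside 2008-2018; open-ended entries are censored on the last
# study day.

library(trrlink)

outdir <- "results/run"
sys <- read_system(outdir)
wl <- read_waitlist(file.path(outdir, "waitlist.csv"))

canon <- canonicalize_facilities(wl, sys$facility_xwalk, sys$centers$id)
filt <- filter_waitlist(canon$entries, study_period())
write_cohort(filt, outdir)

t <- filt$tally
cat(sprintf("input entries:            %d\n", nrow(wl)))
cat(sprintf("dropped (inactive center): %d\n", canon$n_dropped))
cat(sprintf("excluded (bad dates):      %d\n", t[["excluded_bad_dates"]]))
cat(sprintf("excluded (no adult day in period): %d\n",
            t[["excluded_no_adult_overlap"]]))
cat(sprintf("censored at study end:     %d\n", t[["n_censored"]]))
cat(sprintf("cohort:                    %d entries\n", t[["included"]]))
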