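# trrlink

Transplant referral regions (TRRs) are the catchment areas of US transplant
centers: the region of patients most commonly referred to each center. They
are conventionally derived from patient waitlist records by chaining zip
codes through the Dartmouth zip-to-HRR (hospital referral region) crosswalk.
Linking census-based social-determinants data (tracts, block groups) to TRRs
can then be done two ways, and they disagree:

* **zip crosswalk method** — join the zip-to-tract crosswalk with the
  zip-to-HRR crosswalk, then with the HRR-to-TRR assignment. Because zip
  boundaries respect neither census nor HRR boundaries, one census unit can
  reach several TRRs (a *multiplet*, double-counting its population) and
  large areas end up ascribed to the wrong region.
* **spatial intersection method** — clip census units to the HRR coverage
  and assign each unit to the single TRR with the largest area of
  intersection. Multiplets are impossible by construction.

`trrlink` implements the whole pipeline for researchers in health-services
geography and transplant equity — TRR derivation, both linkage methods, and
the error metrics that compare them — together with a seeded generator of
synthetic study systems (nested census grids, misaligned Voronoi HRRs,
offset zip tessellations, crosswalks, centers, waitlist records), since the
real inputs are restricted registry data and bulky shapefiles.

## Method

1. **Cohort.** Waitlist entries are kept if the start date is present and
   not after the recorded end date, and if at least one day of the listing
   falls inside the study period (2008-01-01 to 2018-12-31 by default) while
   the patient is ≥ 18; missing end dates are administratively censored on
   the last study day. Facility aliases are folded into canonical center
   ids; entries at inactive centers are dropped and counted.
2. **TRR derivation.** Centers within 10 straight-line miles — directly or
   linked through a third center — merge into groups (connected components).
   Each cohort entry is allocated to every HRR its home zip touches. Each
   HRR is assigned to the group with the most *distinct* waitlisted patients
   (a patient counts once per group per HRR, but counts for every group they
   are listed at); count ties break to the group nearest the HRR centroid,
   then to the smallest group id, and are logged. A group's TRR is the
   dissolve (geometric union) of its HRRs.
3. **Error metrics.** For each method and unit scale: the number of units
   assigned to more than one TRR and their total (double-assigned) area; and
   per TRR the symmetric difference between the TRR polygon T and the union
   U of units assigned to it, decomposed as

       outside   = |U \ T|        (assigned but beyond the TRR)
       uncovered = |T \ U|        (TRR area with no assigned data)
       percent   = 100 · (outside + uncovered) / |T|

   Methods are compared per scale with a paired Wilcoxon signed-rank test on
   per-TRR percentages (exact by full sign enumeration for n ≤ 12, normal
   approximation with tie and continuity corrections beyond).

All geometry is planar and exact: convex decomposition plus
Sutherland–Hodgman clipping for intersection areas, and a vertical-slab
decomposition for exact union areas. No spatial simplification or raster
approximation is involved.

## Worked example

The numbered drivers under `analysis/` run the default study system stage
by stage and write every artifact under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cohort.R
Rscript analysis/03_derive_trr.R
Rscript analysis/04_link.R
Rscript analysis/05_evaluate.R
```

`01` reports, for seed 1: 900 block groups, 100 tracts, 8 HRRs, 121 zips,
of which 49 straddle more than one HRR, and 2514 waitlist entries for 2000
patients. `02` keeps 2139 entries (93 excluded for bad dates, 282 with no
adult day inside the study period, 219 censored at the study end). `03`
merges 12 centers into 8 groups and forms 7 TRRs from the 8 HRRs. `05`
prints the two summary tables; abbreviated:

```
  method      scale n_double_assigned pct_of_total_trr_area
 spatial blockgroup                 0                     0
 spatial      tract                 0                     0
     zip blockgroup               594                    66
     zip      tract                66                    66

  method      scale n median_pct  p_value
 spatial blockgroup 7       6.45       NA
 spatial      tract 7      19.35       NA
     zip blockgroup 7     121.41 0.015625
     zip      tract 7     121.41 0.015625
```

Read: the spatial method assigned every unit exactly once, while the zip
chains double-assigned 66 of 100 tracts (66% of TRR-covered area); the
spatial method's median misassigned share of a TRR is 6.4% (block groups)
and 19.4% (tracts) against 121% for the zip method, and the paired
signed-rank test across the 7 TRRs gives p = 0.0156 at each scale (the
smallest p attainable with n = 7). The zip method's identical rows at the
two scales are structural, not a coincidence: block groups inherit their
parent tract's TRR set and tile the tract exactly, so the unioned geometry
per TRR is the same.

The same run is available in one call:

```r
library(trrlink)
res <- run_pipeline(run_config(seed = 1), outdir = "results/run")
res$table1; res$table2
```

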