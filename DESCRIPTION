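Package: trrlink
Title: Transplant Referral Regions and Census-Linkage Error Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives transplant referral regions (TRRs) from patient
    waitlist records and hospital referral region (HRR) polygons, links
    census tracts and block groups to TRRs by a zip-code crosswalk method
    and by direct spatial intersection with largest-overlap assignment,
    and quantifies each method's error through duplicate-assignment
    (multiplet) counts and per-region misassigned area, with a paired
    Wilcoxon signed-rank comparison. Includes a seeded generator of
    synthetic nested census geographies, misaligned referral-region and
    zip tessellations, crosswalks, transplant-center locations, and
    waitlist records, plus an exact planar polygon engine (area,
    intersection, dissolve, union area) used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    lubridate,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
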