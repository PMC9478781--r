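# The two census-unit -> TRR linkage methods and coverage clipping.

# A tiny hand-built world: two rectangular HRRs splitting [0,2]x[0,1],
# each its own TRR.
two_trr_world <- function(split = 1) {
  hrr_geoms <- list(H1 = trrlink:::rect_poly(0, 0, split, 1, id = "H1"),
                    H2 = trrlink:::rect_poly(split, 0, 2, 1, id = "H2"))
  groups <- data.frame(group_id = c("G01", "G02"),
                       center_id = c("C01", "C02"),
                       group_x = c(0.2, 1.8), group_y = 0.5,
                       stringsAsFactors = FALSE)
  assignments <- data.frame(hrr_id = c("H1", "H2"),
                            trr_id = c("G01", "G02"),
                            winning_count = 1, runner_up_count = 0,
                            tie_flag = FALSE, stringsAsFactors = FALSE)
  list(hrr_geoms = hrr_geoms, groups = groups, assignments = assignments,
       trrs = build_trrs(assignments, hrr_geoms, groups))
}

test_that("clipping to coverage keeps, halves, and drops units as expected", {
  w <- two_trr_world()
  units <- list(inside = trrlink:::rect_poly(0.2, 0.2, 0.8, 0.8, id = "inside"),
                half = trrlink:::rect_poly(1.5, 0, 2.5, 1, id = "half"),
                outside = trrlink:::rect_poly(3, 0, 4, 1, id = "outside"))
  cl <- clip_units_to_coverage(units, w$hrr_geoms)
  expect_equal(unname(cl$areas["inside"]), 0.36)
  expect_equal(unname(cl$areas["half"]), 0.5)
  expect_equal(cl$dropped, "outside")
  expect_error(clip_units_to_coverage(units, list()), "empty")
})

test_that("spatial linkage assigns the largest-overlap TRR with logged ties", {
  # unit covering [0,1]^2 against a 0.4 / 0.6 split
  w <- two_trr_world(split = 0.4)
  units <- list(U = trrlink:::rect_poly(0, 0, 1, 1, id = "U"))
  cl <- clip_units_to_coverage(units, w$hrr_geoms)
  sp <- link_spatial_method(cl, w$trrs)
  expect_equal(sp$assignments$trr_id, "G02")   # 0.6 beats 0.4

  # wholly inside one TRR
  w2 <- two_trr_world()
  units2 <- list(U = trrlink:::rect_poly(1.1, 0.1, 1.9, 0.9, id = "U"))
  sp2 <- link_spatial_method(clip_units_to_coverage(units2, w2$hrr_geoms),
                             w2$trrs)
  expect_equal(sp2$assignments$trr_id, "G02")

  # exact 50/50 split: smallest TRR id, tie logged
  units3 <- list(U = trrlink:::rect_poly(0.5, 0, 1.5, 1, id = "U"))
  sp3 <- link_spatial_method(clip_units_to_coverage(units3, w2$hrr_geoms),
                             w2$trrs)
  expect_equal(sp3$assignments$trr_id, "G01")
  expect_equal(sp3$ties$unit_id, "U")
})

test_that("spatial assignments are single-valued for every clipped unit", {
  res <- run_pipeline(run_config(geography_config(n = 12, k = 3, h = 4,
                                                  m = 5, delta = 0.3,
                                                  n_centers = 6, seed = 23),
                                 waitlist_config(n_patients = 400,
                                                 seed = 23)))
  for (sc in c("tract", "blockgroup")) {
    a <- res$assignments[[paste0("spatial.", sc)]]
    expect_false(any(duplicated(a$unit_id)))
    n_unassigned <- res$manifest$counts$units_unassigned[[paste0("spatial.", sc)]]
    expect_equal(nrow(a) + n_unassigned, length(res$clip[[sc]]$clipped))
  }
})

test_that("zip chains reach every TRR and block groups inherit the parent set", {
  zip_tract <- data.frame(zip = c("Z1", "Z2", "Z2"),
                          tract = c("T1", "T1", "T2"),
                          stringsAsFactors = FALSE)
  zip_hrr <- data.frame(zip = c("Z1", "Z2"), hrr = c("H1", "H2"),
                        stringsAsFactors = FALSE)
  assignments <- data.frame(hrr_id = c("H1", "H2"),
                            trr_id = c("G01", "G02"),
                            stringsAsFactors = FALSE)
  bg_parent <- c(B1 = "T1", B2 = "T1", B3 = "T2")
  out <- link_zip_method(c("T1", "T2", "T3"), bg_parent, zip_tract, zip_hrr,
                         assignments)
  # T1 reaches both TRRs through its two zips: a multiplet
  expect_setequal(out$tract$trr_id[out$tract$unit_id == "T1"],
                  c("G01", "G02"))
  expect_equal(out$tract$trr_id[out$tract$unit_id == "T2"], "G02")
  expect_equal(out$unassigned$tract, "T3")
  # block groups inherit the parent tract's TRR set verbatim
  expect_setequal(out$blockgroup$trr_id[out$blockgroup$unit_id == "B1"],
                  c("G01", "G02"))
  expect_equal(out$blockgroup$trr_id[out$blockgroup$unit_id == "B3"], "G02")
  bad_parent <- c(B1 = "T9")
  expect_error(link_zip_method(c("T1"), bad_parent, zip_tract, zip_hrr,
                               assignments), "unknown parent")
})

test_that("block-group spatial assignments can disagree with the parent tract", {
  # boundary-straddling tracts make the scale effect observable
  res <- run_pipeline(run_config(geography_config(n = 12, k = 3, h = 4,
                                                  m = 5, delta = 0.3,
                                                  n_centers = 6, seed = 23),
                                 waitlist_config(n_patients = 400,
                                                 seed = 23)))
  bgp <- stats::setNames(res$system$blockgroups$props$tract,
                         res$system$blockgroups$props$id)
  tr <- res$assignments[["spatial.tract"]]
  bg <- res$assignments[["spatial.blockgroup"]]
  parent_trr <- tr$trr_id[match(bgp[bg$unit_id], tr$unit_id)]
  expect_gt(sum(bg$trr_id != parent_trr, na.rm = TRUE), 0)
})
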