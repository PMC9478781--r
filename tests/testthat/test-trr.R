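# Center grouping, entry allocation, distinct-patient counting, HRR
# assignment and TRR dissolution.

centers_df <- function(...) {
  m <- rbind(...)
  data.frame(id = rownames(m), x = m[, 1], y = m[, 2],
             stringsAsFactors = FALSE)
}

test_that("centers within the threshold merge, including through a chain", {
  two <- centers_df(A = c(0, 0), B = c(8, 0))
  g <- group_centers(two, threshold = 10)
  expect_equal(length(unique(g$group_id)), 1)

  # A-B at 8, B-C at 9, A-C at 17: one group through the chain
  chain <- centers_df(A = c(0, 0), B = c(8, 0), C = c(17, 0))
  g <- group_centers(chain, threshold = 10)
  expect_equal(length(unique(g$group_id)), 1)

  far <- centers_df(A = c(0, 0), B = c(30, 0), C = c(60, 0))
  g <- group_centers(far, threshold = 10)
  expect_equal(length(unique(g$group_id)), 3)
})

test_that("grouping is invariant to center input order and rejects duplicates", {
  cs <- centers_df(A = c(0, 0), B = c(8, 0), C = c(40, 40), D = c(45, 40))
  g1 <- group_centers(cs, threshold = 10)
  g2 <- group_centers(cs[c(3, 1, 4, 2), ], threshold = 10)
  expect_equal(g1, g2)
  dup <- rbind(cs, cs[1, ])
  expect_error(group_centers(dup), "duplicate")
})

test_that("entries fan out to every HRR of a split zip; unmatched zips drop", {
  cohort <- data.frame(patient_id = c("P1", "P2", "P3"),
                       facility_id = "C01",
                       zip = c("Z1", "Z2", "Z9"),
                       stringsAsFactors = FALSE)
  xw <- data.frame(zip = c("Z1", "Z2", "Z2"), hrr = c("H1", "H1", "H2"),
                   stringsAsFactors = FALSE)
  out <- allocate_entries_to_hrrs(cohort, xw)
  expect_equal(nrow(out$pairs), 3)
  expect_equal(sort(out$pairs$hrr[out$pairs$patient_id == "P2"]),
               c("H1", "H2"))
  expect_equal(out$n_unmatched_zip, 1)
})

test_that("a patient counts once per center group per HRR", {
  groups <- data.frame(group_id = c("G01", "G01", "G02"),
                       center_id = c("C01", "C02", "C03"),
                       group_x = 0, group_y = 0, stringsAsFactors = FALSE)
  pairs <- data.frame(
    patient_id = c("P1", "P1", "P1", "P1", "P2"),
    facility_id = c("C01", "C01", "C02", "C03", "C03"),
    hrr = "H1", stringsAsFactors = FALSE)
  cts <- count_patients(pairs, groups)
  # P1 has three entries across G01's two centers: still 1 for G01,
  # plus 1 for G02; P2 adds 1 to G02
  expect_equal(cts$n_patients[cts$group_id == "G01"], 1)
  expect_equal(cts$n_patients[cts$group_id == "G02"], 2)
})

test_that("plurality assignment picks the argmax and reports the runner-up", {
  counts <- data.frame(hrr = c("H1", "H1"), group_id = c("G01", "G02"),
                       n_patients = c(6, 4), stringsAsFactors = FALSE)
  hrr_geoms <- list(H1 = trrlink:::rect_poly(0, 0, 10, 10, id = "H1"))
  groups <- data.frame(group_id = c("G01", "G02"),
                       center_id = c("C01", "C02"),
                       group_x = c(2, 20), group_y = c(2, 20),
                       stringsAsFactors = FALSE)
  a <- assign_hrrs(counts, hrr_geoms, groups)
  expect_equal(a$trr_id, "G01")
  expect_equal(a$winning_count, 6)
  expect_equal(a$runner_up_count, 4)
  expect_false(a$tie_flag)
})

test_that("count ties break by distance to the HRR centroid, then id", {
  hrr_geoms <- list(H1 = trrlink:::rect_poly(0, 0, 10, 10, id = "H1"))
  counts <- data.frame(hrr = "H1", group_id = c("G01", "G02"),
                       n_patients = c(5, 5), stringsAsFactors = FALSE)
  # HRR centroid is (5, 5); G02 at (6, 5) is nearer than G01 at (0, 0)
  groups <- data.frame(group_id = c("G01", "G02"),
                       center_id = c("C01", "C02"),
                       group_x = c(0, 6), group_y = c(0, 5),
                       stringsAsFactors = FALSE)
  a <- assign_hrrs(counts, hrr_geoms, groups)
  expect_equal(a$trr_id, "G02")
  expect_true(a$tie_flag)
  # equidistant representatives: lexicographically smallest id wins
  groups_eq <- transform(groups, group_x = c(4, 6), group_y = 5)
  a2 <- assign_hrrs(counts, hrr_geoms, groups_eq)
  expect_equal(a2$trr_id, "G01")
})

test_that("TRR geometry conserves assigned-HRR area; non-adjacent HRRs split", {
  hrr_geoms <- list(H1 = trrlink:::rect_poly(0, 0, 1, 1, id = "H1"),
                    H2 = trrlink:::rect_poly(1, 0, 2, 1, id = "H2"),
                    H3 = trrlink:::rect_poly(5, 5, 6, 6, id = "H3"))
  groups <- data.frame(group_id = "G01", center_id = "C01",
                       group_x = 0, group_y = 0, stringsAsFactors = FALSE)
  adj <- data.frame(hrr_id = c("H1", "H2"), trr_id = "G01",
                    winning_count = 1, runner_up_count = 0, tie_flag = FALSE,
                    stringsAsFactors = FALSE)
  trrs <- build_trrs(adj, hrr_geoms, groups)
  expect_equal(geo_area(trrs$G01$geom), 2)
  split <- data.frame(hrr_id = c("H1", "H3"), trr_id = "G01",
                      winning_count = 1, runner_up_count = 0,
                      tie_flag = FALSE, stringsAsFactors = FALSE)
  trrs2 <- build_trrs(split, hrr_geoms, groups)
  expect_length(trrs2$G01$geom$polys, 2)
  expect_equal(geo_area(trrs2$G01$geom), 2)
  bad <- transform(adj, hrr_id = c("H1", "H9"))
  expect_error(build_trrs(bad, hrr_geoms, groups), "unknown HRR")
})

test_that("end-to-end derivation conserves area and assigns HRRs uniquely", {
  cfg <- run_config(geography_config(n = 12, k = 3, h = 4, m = 5,
                                     delta = 0.3, n_centers = 6, seed = 13),
                    waitlist_config(n_patients = 400, seed = 13))
  res <- run_pipeline(cfg)
  d <- res$derived
  # every HRR assigned to at most one TRR
  expect_false(any(duplicated(d$assignments$hrr_id)))
  member <- unlist(lapply(d$trrs, function(t) t$member_hrrs))
  expect_false(any(duplicated(member)))
  # assigned-HRR area conserved in the dissolved TRRs
  hrr_area <- sum(vapply(res$system$hrrs$geoms[d$assignments$hrr_id],
                         geo_area, numeric(1)))
  trr_area <- sum(vapply(d$trrs, function(t) geo_area(t$geom), numeric(1)))
  expect_equal(trr_area, hrr_area, tolerance = 1e-9)
})
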