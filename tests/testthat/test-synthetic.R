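# Synthetic study-system generator: tessellation, nesting, crosswalk
# completeness, misalignment behaviour, and waitlist record properties.

test_that("config invariants are enforced", {
  expect_error(geography_config(n = 5, k = 2), "divisible")
  expect_error(geography_config(h = 1), "h must be")
  expect_error(geography_config(delta = 1), "delta")
  expect_error(waitlist_config(p_multi = 1.2), "probabilities")
  expect_error(waitlist_config(study_start = "2019-01-01",
                               study_end = "2018-01-01"), "precede")
})

test_that("census and HRR layers tessellate the region and nest correctly", {
  cfg <- geography_config(n = 12, k = 3, h = 5, m = 4, delta = 0.35,
                          n_centers = 4, seed = 21)
  sys <- generate_geography(cfg)
  region <- cfg$side^2
  for (layer in c("blockgroups", "tracts", "hrrs", "zips")) {
    areas <- vapply(sys[[layer]]$geoms, geo_area, numeric(1))
    expect_equal(sum(areas), region, tolerance = 1e-9)
  }
  # each block group is contained in its parent tract
  for (i in seq_len(nrow(sys$blockgroups$props))) {
    bg <- sys$blockgroups$geoms[[sys$blockgroups$props$id[i]]]
    tr <- sys$tracts$geoms[[sys$blockgroups$props$tract[i]]]
    expect_equal(geo_intersection_area(bg, tr), geo_area(bg),
                 tolerance = 1e-9)
  }
  # tract equals the union of its block groups
  kids <- split(sys$blockgroups$props$id, sys$blockgroups$props$tract)
  for (tid in names(kids)) {
    expect_equal(sum(vapply(sys$blockgroups$geoms[kids[[tid]]], geo_area,
                            numeric(1))),
                 geo_area(sys$tracts$geoms[[tid]]), tolerance = 1e-9)
  }
})

test_that("crosswalks are complete and overlap-derived", {
  sys <- generate_geography(geography_config(n = 8, k = 2, h = 4, m = 4,
                                             delta = 0.3, n_centers = 3,
                                             seed = 5))
  expect_setequal(unique(sys$zip_hrr$zip), names(sys$zips$geoms))
  # brute-force check of every zip x HRR pair against the crosswalk
  for (z in names(sys$zips$geoms)) {
    for (h in names(sys$hrrs$geoms)) {
      a <- geo_intersection_area(sys$zips$geoms[[z]], sys$hrrs$geoms[[h]])
      listed <- any(sys$zip_hrr$zip == z & sys$zip_hrr$hrr == h)
      if (a > 1e-6) expect_true(listed, label = paste(z, h, "listed"))
      if (!listed) expect_lt(a, 1e-6)
    }
  }
  # every tract overlapped by a zip appears in zip_tract
  expect_setequal(unique(sys$zip_tract$tract), names(sys$tracts$geoms))
})

test_that("aligned limit gives one HRR per zip; misalignment splits zips", {
  al <- generate_geography(aligned_geography(seed = 2))
  per_zip <- table(al$zip_hrr$zip)
  expect_true(all(per_zip == 1))
  # every tract lies wholly inside one HRR
  for (tid in names(al$tracts$geoms)) {
    covers <- vapply(al$hrrs$geoms, function(h)
      geo_intersection_area(al$tracts$geoms[[tid]], h), numeric(1))
    expect_equal(sum(covers > 1e-9), 1)
  }
  mis <- generate_geography(geography_config(side = 40, n = 4, k = 2, h = 4,
                                             m = 2, delta = 0.3,
                                             n_centers = 4, seed = 2,
                                             hrr_seeds = rbind(c(10, 10),
                                                               c(30, 10),
                                                               c(10, 30),
                                                               c(30, 30))))
  expect_gt(max(table(mis$zip_hrr$zip)), 1)
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- geography_config(n = 6, k = 3, h = 3, m = 3, delta = 0.2,
                          n_centers = 3, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_system(generate_geography(cfg), d1)
  write_system(generate_geography(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("waitlist honors boundary probabilities and binomial rates", {
  sys <- generate_geography(geography_config(n = 6, k = 3, h = 3, m = 3,
                                             delta = 0.2, n_centers = 4,
                                             seed = 8))
  all_missing <- generate_waitlist(sys, waitlist_config(n_patients = 50,
                                                        p_missing_end = 1,
                                                        p_missing_start = 0,
                                                        seed = 8))
  expect_true(all(is.na(all_missing$end_date)))
  single <- generate_waitlist(sys, waitlist_config(n_patients = 80,
                                                   p_multi = 0, p_repeat = 0,
                                                   seed = 8))
  per_pat <- table(single$patient_id)
  expect_true(all(per_pat == 1))
  # multi-center fraction within 3 SE of the configured probability
  p <- 0.2; n <- 1000
  wl <- generate_waitlist(sys, waitlist_config(n_patients = n, p_multi = p,
                                               p_repeat = 0, seed = 12))
  n_multi <- sum(tapply(wl$facility_id, wl$patient_id,
                        function(f) length(unique(sub("^X", "", f)))) > 1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(n_multi / n - p), 3 * se)
})

test_that("waitlist generation fails without centers", {
  sys <- generate_geography(geography_config(n = 4, k = 2, h = 2, m = 2,
                                             n_centers = 2, seed = 1))
  sys$centers <- sys$centers[0, , drop = FALSE]
  expect_error(generate_waitlist(sys, waitlist_config(n_patients = 10)),
               "empty")
})
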