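test_that("cohort generation is seed-deterministic and respects config", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(seed = 6)))
  expect_equal(nrow(a), 18)
  expect_equal(sort(unique(a$subspecies)), c("atlantica", "melodia"))
  expect_equal(a$total_area, a$bill_total_area + a$legs_area + a$body_area)
  expect_equal(a$body_volume, a$mass / 0.913)
  expect_error(cohort_config(n_per_subspecies = 1), "n_per_subspecies")
})

test_that("large cohorts recover the configured morphometric means", {
  big <- generate_cohort(cohort_config(n_per_subspecies = 1e4), seed = 9)
  atl <- big[big$subspecies == "atlantica", ]
  east <- big[big$subspecies == "melodia", ]
  expect_lt(abs(mean(atl$bill_total_area) - 148.70) / 148.70, 0.01)
  expect_lt(abs(mean(east$bill_total_area) - 127.46) / 127.46, 0.01)
  expect_lt(abs(sd(east$bill_total_area) - 10.41) / 10.41, 0.05)
})

test_that("zero-SD cohorts collapse to the configured means", {
  cfg <- cohort_config()
  cfg$sds <- lapply(cfg$sds, function(s) s * 0)
  flat <- generate_cohort(cfg, seed = 3)
  east <- flat[flat$subspecies == "melodia", ]
  expect_true(all(east$bill_total_area == 127.46))
  expect_true(all(east$mass == 18.89))
})

test_that("experiment generation matches the protocol bookkeeping", {
  cohort <- generate_cohort(seed = 21)
  obs <- generate_experiment(cohort, seed = 22)
  # 18 birds x 12 ambient steps x 5 frames
  expect_equal(nrow(obs), 18 * 12 * 5)
  expect_equal(sort(unique(obs$ta)), seq(15, 37, by = 2))
  expect_equal(sort(unique(obs$frame)), 1:5)
  expect_identical(obs, generate_experiment(cohort, seed = 22))
  # activity and humidity are step-level: constant across frames in a step
  one <- obs[obs$bird_id == obs$bird_id[1] & obs$ta == 15, ]
  expect_equal(length(unique(one$activity)), 1)
  expect_equal(length(unique(one$relative_humidity)), 1)
  expect_true(all(obs$activity >= 0))
})

test_that("noise-free generation hits the configured elevations exactly", {
  cfg <- cohort_config()
  resp <- response_config(ranef_sd = 0, frame_sd = 0, activity_sd = 0,
                          rh_sd = 0)
  cohort <- generate_cohort(cfg, seed = 1)
  obs <- generate_experiment(cohort, response = resp, seed = 2)
  east15 <- obs[obs$subspecies == "melodia" & obs$ta == 15, ]
  expect_equal(unique(east15$t_bill - east15$ta), 9.8)
  east37 <- obs[obs$subspecies == "melodia" & obs$ta == 37, ]
  expect_equal(unique(east37$t_bill - east37$ta), 4.7)
  expect_equal(unique(east15$t_body - east15$ta), 4.4)
  expect_equal(unique(east37$t_body - east37$ta), 2.6)
  # coastal birds carry the whole-bill offset and the base interaction
  atl15 <- obs[obs$subspecies == "atlantica" & obs$ta == 15, ]
  expect_equal(unique(atl15$t_bill - atl15$ta), 9.8 + 0.3)
  expect_equal(unique(atl15$t_base) - east15$t_base[1], 1.2)
  atl37 <- obs[obs$subspecies == "atlantica" & obs$ta == 37, ]
  expect_equal(unique(atl37$t_base) - unique(east37$t_base), 0.2)
})

test_that("mean bill elevation declines monotonically across steps", {
  cohort <- generate_cohort(seed = 31)
  obs <- generate_experiment(cohort, seed = 32)
  elev <- tapply(obs$t_bill - obs$ta, obs$ta, mean)
  expect_true(all(diff(elev) < 0))
  # humidity anticorrelated with ambient temperature
  expect_lt(cor(obs$relative_humidity, obs$ta), -0.8)
})

test_that("ROI means average the masked pixels", {
  grid <- matrix(25, 4, 4)
  expect_equal(roi_mean_temperature(grid, matrix(TRUE, 4, 4)), 25)
  g <- matrix(c(20, 40, 30, 50), 2, 2, byrow = FALSE)
  mask_row1 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(roi_mean_temperature(g, mask_row1), 25)
  # disjoint-mask decomposition: union mean is the area-weighted mean
  set.seed(1)
  big <- matrix(runif(100, 10, 40), 10, 10)
  a <- matrix(FALSE, 10, 10); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:10, ] <- TRUE
  m_union <- roi_mean_temperature(big, a | b)
  w <- c(sum(a), sum(b))
  expect_equal(m_union,
               sum(w * c(roi_mean_temperature(big, a),
                         roi_mean_temperature(big, b))) / sum(w))
  expect_error(roi_mean_temperature(big, matrix(FALSE, 10, 10)), "mask")
  expect_error(roi_mean_temperature(big, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("frame selection takes minute-boundary frames, falling back to nearest good", {
  times <- seq(0.1, 5, by = 0.1)  # 10 frames per minute
  all_good <- select_frames(times)
  expect_equal(times[all_good], 1:5)
  # boundary frame of minute 2 flagged bad: nearest good neighbour wins
  flags <- rep(TRUE, length(times))
  flags[times == 2] <- FALSE
  picked <- select_frames(times, flags)
  expect_equal(times[picked[2]], 1.9)
  # tie in distance: earlier frame
  times2 <- c(0.5, 1.0, 1.5, 2.5, 3.5, 4.5, 5.0)
  flags2 <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  flags2[times2 == 5.0] <- FALSE
  # minute 5 contains only 4.5 (good) and 5.0 (bad) -> 4.5
  expect_equal(times2[select_frames(times2, flags2)[5]], 4.5)
  # two good frames at the same distance from the boundary: earlier index
  tie_times <- c(1, 1.9, 1.9, 2.0, 3, 4, 5)
  tie_flags <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(select_frames(tie_times, tie_flags)[2], 2L)
  # a minute with no good frame is a missing-frame marker
  times3 <- c(0.9, 1.8, 3.0, 4.0, 5.0)
  flags3 <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_true(is.na(select_frames(times3, flags3)[2]))
  expect_error(select_frames(c(0.5, 1.5)), "shorter")
})
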