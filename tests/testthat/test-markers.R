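test_that("moving average handles constants, impulses, and edges", {
  expect_equal(moving_average(rep(7, 50), 1, 3600), c(rep(7, 50)))
  x <- c(rep(0, 10), 1, rep(0, 10))
  ma <- moving_average(x, 3, 3600)  # 3-bin window at 1-h bins
  expect_equal(which(!is.na(ma) & ma > 0), 10:12)
  expect_equal(ma[10:12], rep(1 / 3, 3))
  expect_true(all(is.na(moving_average(rep(1, 10), 3, 3600)[c(1, 10)])))
  expect_error(moving_average(1:5, 24, 3600), "shorter")
})

test_that("moving average equals brute-force recomputation on a long random series", {
  set.seed(42)
  x <- rpois(2000, 8)
  for (win_h in c(1, 3, 24)) {
    w <- win_h * 3600 / 300
    got <- moving_average(x, win_h, 300)
    want <- ma_brute(x, w)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("square-wave markers land on onset ZT12, offset ZT24, midpoint ZT18, peak ZT12.5", {
  rec <- square_wave_record(days = 4)
  mk <- detect_markers(rec)
  mk <- mk[mk$valid, ]
  expect_gte(nrow(mk), 2)
  bin_h <- 300 / 3600 + 1e-9
  expect_true(all(abs(mk$onset_zt - 12) <= bin_h))
  expect_true(all(abs(mk$offset_zt - 24) <= bin_h))
  expect_true(all(abs(mk$midpoint_zt - 18) <= bin_h))
  expect_true(all(abs(mk$peak_zt - 12.5) <= bin_h))
  expect_true(all(abs(mk$alpha_h - 12) <= 2 * bin_h))
})

test_that("markers are equivariant under circular shifts and invariant under scaling", {
  base <- detect_markers(square_wave_record(days = 5))
  base <- base[base$valid, ]
  for (k in c(3L, 12L, 24L)) {
    shifted <- detect_markers(square_wave_record(days = 5, shift_bins = k))
    shifted <- shifted[shifted$valid, ]
    days <- intersect(base$day_index, shifted$day_index)
    for (col in c("onset_zt", "offset_zt", "midpoint_zt", "peak_zt")) {
      expect_equal(shifted[match(days, shifted$day_index), col],
                   base[match(days, base$day_index), col] + k * 300 / 3600,
                   tolerance = 1e-9)
    }
  }
  for (c_scale in c(3, 17)) {
    scaled <- detect_markers(square_wave_record(days = 5, scale = c_scale))
    expect_equal(scaled$onset_zt, base$onset_zt[match(scaled$day_index, base$day_index)])
    expect_equal(scaled$peak_zt, base$peak_zt[match(scaled$day_index, base$day_index)])
  }
})

test_that("detected crossings equal a naive first-principles recomputation on random records", {
  pr <- genotype_presets()
  sch <- light_schedule("LD")
  for (seed in 1:20) {
    rec <- simulate_animal(pr$wt_like, sch, days = 4, seed = seed)
    got <- detect_markers(rec)
    want <- markers_naive(rec)
    days <- intersect(got$day_index, want$day_index)
    g <- got[match(days, got$day_index), ]
    w <- want[match(days, want$day_index), ]
    expect_equal(g$valid, w$valid)
    expect_equal(g$onset_zt[g$valid], w$onset_zt[w$valid], tolerance = 1e-9)
    expect_equal(g$offset_zt[g$valid], w$offset_zt[w$valid], tolerance = 1e-9)
  }
})

test_that("detected onset recovers the drive's half-rise time in deterministic LD simulation", {
  sch <- light_schedule("LD")
  for (lat in c(15, 40)) {
    p <- sim_params(onset_latency = lat, deterministic = TRUE)
    rec <- simulate_animal(p, sch, days = 5)
    mk <- detect_markers(rec)
    mk <- mk[mk$valid, ]
    half_rise_zt <- 12 + (lat + log(2) * p$rise_time) / 60
    expect_true(all(abs(mk$onset_zt - half_rise_zt) <= 2 * 300 / 3600))
  }
})

test_that("per-animal summaries average valid days and drop empty animals", {
  mk <- data.frame(animal_id = rep(c("a", "b"), each = 3), group = "g",
                   day_index = rep(1:3, 2),
                   onset_zt = c(12, 12, 12, 12, 11.7, 11.4),
                   offset_zt = 24, midpoint_zt = 18, peak_zt = 13,
                   alpha_h = 12, valid = TRUE)
  s <- summarize_markers(mk)
  expect_equal(s$onset_zt, c(12, 11.7))
  expect_equal(s$n_days, c(3, 3))
  mk$valid[mk$animal_id == "b"] <- FALSE
  expect_warning(s2 <- summarize_markers(mk), "no valid")
  expect_equal(s2$animal_id, "a")
  # mean of 11.5 and 12.5 is 12
  mk3 <- mk[mk$animal_id == "a", ]
  mk3$onset_zt <- c(11.5, 12.5, 12)
  expect_equal(summarize_markers(mk3)$onset_zt, 12)
})
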