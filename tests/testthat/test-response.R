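make_const_record <- function(id, value, days = 2, temp = 37,
                              sch = light_schedule("LD")) {
  n <- days * 288L
  actigraphy_record(id, "g", rep.int(as.integer(value), n), rep(temp, n),
                    bin_seconds = 300L, schedule = sch)
}

test_that("rebinning sums counts, averages temperature missing-aware, and is identity at same width", {
  sch <- light_schedule("LD")
  act <- rep(1:3, 96 * 2)
  temp <- rep(c(36, 37, NA), 96 * 2)
  rec <- actigraphy_record("r", "g", act, temp, bin_seconds = 300L, schedule = sch)
  rb <- rebin(rec, 15)
  expect_equal(rb$activity[1], 6L)
  expect_equal(rb$temperature[1], 36.5)
  expect_equal(rb$n_bins, rec$n_bins / 3)
  # a coarse bin is missing only when all fine bins are missing
  temp2 <- temp; temp2[1:3] <- NA
  rec2 <- actigraphy_record("r", "g", act, temp2, bin_seconds = 300L, schedule = sch)
  expect_true(is.na(rebin(rec2, 15)$temperature[1]))
  expect_identical(rebin(rec, 5)$activity, rec$activity)
  expect_error(rebin(rec, 7), "multiple")
})

test_that("group daily profiles give exact mean and SEM for constant animals", {
  recs <- list(make_const_record("a", 3), make_const_record("b", 5))
  pr <- daily_profile(recs, "activity", bin_minutes = 60)
  expect_equal(nrow(pr), 24)
  expect_equal(pr$mean, rep(4 * 12, 24))   # 12 five-min bins summed per hour
  expect_equal(pr$sem, rep(12, 24))        # sd(36, 60)/sqrt(2) = 12
  same <- list(make_const_record("a", 2), make_const_record("b", 2))
  expect_true(all(daily_profile(same, "activity", 60)$sem == 0))
  expect_error(daily_profile(recs[1], "activity"), "2 animals")
})

test_that("daily profile equals a naive per-bin recomputation on simulated animals", {
  sch <- light_schedule("LD")
  co <- simulate_cohort(list(list(group = "wt", n = 5, params = sim_params())),
                        sch, days = 3, master_seed = 21)
  pr <- daily_profile(co$records, "activity", bin_minutes = 5)
  # naive: per animal, mean across days for each of the 288 ZT bins
  mat <- t(vapply(co$records, function(r)
    rowMeans(matrix(as.numeric(r$activity), nrow = 288)), numeric(288)))
  expect_equal(pr$mean, colMeans(mat), tolerance = 1e-12)
  expect_equal(pr$sem, apply(mat, 2, sd) / sqrt(5), tolerance = 1e-12)
  # a deterministic record's profile is its own single-day pattern
  det <- simulate_animal(sim_params(deterministic = TRUE), sch, days = 3,
                         animal_id = "d1")
  pa <- daily_profile(list(det, det), "activity", 5)
  expect_equal(pa$mean, rowMeans(matrix(as.numeric(det$activity), nrow = 288)),
               tolerance = 1e-12)
  expect_true(all(pa$sem == 0))
})

test_that("transition alignment puts bin 0 first after the event and averages days exactly", {
  sch <- light_schedule("LD")
  rec <- square_wave_record(days = 4, high = 7L)
  rec$animal_id <- "sq1"
  rm <- align_to_transition(list(rec), event = "lights_off",
                            window = c(60, 120), bin_minutes = 15)
  pre <- rm$values[1, rm$rel_min_start < 0]
  post <- rm$values[1, rm$rel_min_start >= 0]
  expect_true(all(pre == 0))
  expect_true(all(post == 21))          # 3 five-min bins of 7 per 15-min bin
  expect_equal(rm$rel_min_start, seq(-60, 105, by = 15))
  # one day vs the average of several identical days
  one <- square_wave_record(days = 3, high = 7L)
  rm1 <- align_to_transition(list(one), window = c(60, 120), bin_minutes = 15)
  expect_equal(rm$values, rm1$values, ignore_attr = TRUE)
  expect_error(align_to_transition(list(simulate_animal(
    sim_params(deterministic = TRUE), light_schedule("DD"), 3))), "LD schedule")
})

test_that("per-bin comparisons match the t-test, are symmetric, and flag degenerate bins", {
  sch <- light_schedule("LD")
  mk_mat <- function(vals) {
    structure(list(rel_min_start = c(0, 15), values = vals,
                   event = "lights_off", variable = "activity",
                   bin_minutes = 15),
              class = "response_matrix")
  }
  A <- rbind(c(1, 5), c(2, 5), c(3, 5))
  B <- rbind(c(2, 5), c(3, 5), c(4, 5))
  res <- per_bin_compare(mk_mat(A), mk_mat(B))
  expect_equal(res$t[1], -sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(res$p_raw[1], 0.2878641, tolerance = 1e-6)
  expect_true(res$degenerate[2])
  expect_true(is.na(res$p_raw[2]))
  # identical groups: p = 1 where defined
  res_same <- per_bin_compare(mk_mat(A), mk_mat(A))
  expect_equal(res_same$p_raw[1], 1)
  # symmetry: swapping groups negates t, keeps p
  res_sw <- per_bin_compare(mk_mat(B), mk_mat(A))
  expect_equal(res_sw$t[1], -res$t[1])
  expect_equal(res_sw$p_raw[1], res$p_raw[1])
})

test_that("lights-off latency hits 0 for an instant jump and the half-rise for a slow one", {
  sch <- light_schedule("LD")
  rec <- square_wave_record(days = 4, high = 9L)
  expect_equal(onset_latency(rec)$latency_min, 0)
  expect_equal(onset_latency(rec, threshold_frac = 0)$latency_min, 0)
  # deterministic relaxation rise: latency + ln(2) * rise_time reaches half of
  # full drive; with near-total light suppression the dark mean sits close to
  # the plateau, so the 50%-of-dark-mean crossing lands near the half-rise
  p <- sim_params(onset_latency = 30, rise_time = 20, baseline_rate = 0,
                  light_suppression = 0, deterministic = TRUE)
  ol <- onset_latency(simulate_animal(p, sch, days = 5), bin_minutes = 5)
  half_rise <- 30 + log(2) * 20
  expect_lt(abs(ol$latency_min - half_rise), 10)
  # all-zero dark phase is flagged undefined, not an error
  zero <- actigraphy_record("z", "g", rep(0L, 4 * 288), bin_seconds = 300L,
                            schedule = sch)
  oz <- onset_latency(zero)
  expect_true(is.na(oz$latency_min))
  expect_gt(oz$n_days_flagged, 0)
})
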