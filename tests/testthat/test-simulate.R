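test_that("deterministic zero-amplitude simulation is flat at the rounded baseline", {
  p <- sim_params(amplitude = 0, baseline_rate = 5.4, temp_amplitude = 0,
                  deterministic = TRUE)
  rec <- simulate_animal(p, light_schedule("LD"), days = 2)
  expect_true(all(rec$activity == 5L))
  expect_equal(rec$temperature, rep(p$temp_base, rec$n_bins))
})

test_that("same parameters and seed reproduce a record bit-identically", {
  p <- sim_params()
  sch <- light_schedule("LD")
  r1 <- simulate_animal(p, sch, days = 3, seed = 99)
  r2 <- simulate_animal(p, sch, days = 3, seed = 99)
  expect_identical(r1$activity, r2$activity)
  expect_identical(r1$temperature, r2$temperature)
  r3 <- simulate_animal(p, sch, days = 3, seed = 100)
  expect_false(identical(r1$activity, r3$activity))
})

test_that("flat Poisson simulation matches its rate within 3 standard errors", {
  p <- sim_params(amplitude = 0, baseline_rate = 5)
  rec <- simulate_animal(p, light_schedule("LD"), days = 42, seed = 11)
  n <- rec$n_bins
  expect_equal(n, 12096)
  expect_lt(abs(mean(rec$activity) - 5), 3 * sqrt(5 / n))
})

test_that("cohort simulation is reproducible with one record and manifest row per animal", {
  pr <- genotype_presets()
  spec <- list(list(group = "wt", n = 5, params = pr$wt_like),
               list(group = "del", n = 5, params = pr$del_like))
  sch <- light_schedule("LD")
  co <- simulate_cohort(spec, sch, days = 2, master_seed = 5)
  expect_length(co$records, 10)
  expect_equal(nrow(co$manifest), 10)
  expect_equal(co$manifest$animal_id,
               vapply(co$records, `[[`, "", "animal_id"), ignore_attr = TRUE)
  co2 <- simulate_cohort(spec, sch, days = 2, master_seed = 5)
  expect_identical(lapply(co$records, `[[`, "activity"),
                   lapply(co2$records, `[[`, "activity"))
  co3 <- simulate_cohort(spec, sch, days = 2, master_seed = 6)
  expect_false(identical(lapply(co$records, `[[`, "activity"),
                         lapply(co3$records, `[[`, "activity")))
  expect_error(simulate_cohort(list(list(group = "g", n = 1, params = pr$wt_like),
                                    list(group = "g", n = 1, params = pr$wt_like)),
                               sch, days = 1), "unique")
})

test_that("genotype presets encode the canonical period, its offset, and a faster lights-off response", {
  pr <- genotype_presets()
  expect_equal(pr$wt_like$tau, 23.7)
  expect_equal(pr$del_like$tau - pr$wt_like$tau, 5.3 / 60)
  expect_lt(pr$del_like$onset_latency, pr$wt_like$onset_latency)
  expect_lt(pr$del_like$rise_time, pr$wt_like$rise_time)
})

test_that("expected counts match the closed-form drive integral over a steady LD cycle", {
  p <- sim_params(deterministic = TRUE)
  sch <- light_schedule("LD")
  # closed form for the periodic steady state of the two-segment relaxation:
  # segment A (dark, post-latency): target 1, time constant rise_time;
  # segment B (light + latency): target sigma, time constant fall_time
  tr <- p$rise_time * 60; tf <- p$fall_time * 60; sg <- p$light_suppression
  Da <- 12 * 3600 - p$onset_latency * 60
  Db <- 12 * 3600 + p$onset_latency * 60
  ea <- exp(-Da / tr); eb <- exp(-Db / tf)
  sA <- (sg * (1 - eb) + (1 - ea) * eb) / (1 - ea * eb)  # drive at segment A start
  sB <- 1 + (sA - 1) * ea                                 # drive at segment B start
  int_s <- Da + (sA - 1) * tr * (1 - ea) + sg * Db + (sB - sg) * tf * (1 - eb)
  # simulated expected counts over the second (steady-state) cycle
  drv <- simulate_drive(p, sch, days = 3)
  mu <- p$baseline_rate + p$amplitude * drv$drive_bin[289:576]
  expected <- 288 * p$baseline_rate + p$amplitude * int_s / 300
  expect_equal(sum(mu), expected, tolerance = 1e-3)
})

test_that("dark phase carries more activity and higher temperature than light phase", {
  p <- sim_params()  # default preset: light_suppression < 1, amplitude > 0
  sch <- light_schedule("LD")
  rec <- simulate_animal(p, sch, days = 42, seed = 3)
  st <- light_state(bin_times(rec), sch)
  expect_gt(mean(rec$activity[st == "dark"]), mean(rec$activity[st == "light"]))
  nl <- simulate_animal(sim_params(deterministic = TRUE), sch, days = 7)
  stn <- light_state(bin_times(nl), sch)
  expect_gt(mean(nl$temperature[stn == "dark"]), mean(nl$temperature[stn == "light"]))
})

test_that("free-running onset advances about 0.3 h per day at tau = 23.7 h", {
  p <- sim_params(deterministic = TRUE)
  rec <- simulate_animal(p, light_schedule("DD"), days = 13)
  mk <- detect_markers(rec)
  mk <- mk[mk$valid, ]
  drift <- unname(stats::coef(stats::lm(onset_zt ~ day_index, data = mk))[2])
  expect_lt(abs(drift - (23.7 - 24)), 0.1)
})
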