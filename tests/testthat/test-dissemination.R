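growth <- gompertz_params()

test_that("a zero formation rate never produces metastases", {
  cfg <- dissemination_config(c = 0, max_days = 3000)
  err <- tryCatch(simulate_patient(growth, cfg, 1, seed = 1),
                  metadose_horizon_error = function(e) e)
  expect_s3_class(err, "metadose_horizon_error")
  expect_length(err$state$birth_days, 0)
})

test_that("fixed seeds reproduce states bit for bit", {
  cfg <- dissemination_config(c = 2.56)
  a <- simulate_patient(growth, cfg, 2, seed = 123)
  b <- simulate_patient(growth, cfg, 2, seed = 123)
  expect_identical(a$birth_days, b$birth_days)
  expect_identical(a$census_time_days, b$census_time_days)
  d <- simulate_patient(growth, cfg, 2, seed = 124)
  expect_false(identical(a$birth_days, d$birth_days))
})

test_that("census rules deliver their defining snapshots", {
  for (seed in 1:5) {
    det <- simulate_patient(growth, dissemination_config(c = 2.56, census = "at_detection"),
                            3, seed = seed)
    expect_identical(n_detectable(det), 3L)
    expect_equal(det$census_time_days, det$detection_time_days)

    win <- simulate_patient(growth, dissemination_config(c = 2.56, census = "while_detectable"),
                            3, seed = seed)
    expect_identical(n_detectable(win), 3L)
    expect_gte(win$census_time_days, win$detection_time_days)

    ev <- simulate_patient(growth, dissemination_config(c = 2.56, census = "at_formation"),
                           3, seed = seed)
    # the state always carries a metastasis disseminated on the census day
    expect_equal(min(ev$census_time_days - ev$birth_days), 0)
    expect_gte(n_detectable(ev), 3L)
  }
})

test_that("volumes, counts and burden derive from the shared growth law", {
  st <- simulate_patient(growth, dissemination_config(c = 2.56), 2, seed = 9)
  v <- tumor_volumes(st)
  expect_equal(v[1], gompertz_volume(st$census_time_days, growth))
  expect_length(v, length(st$birth_days) + 1L)
  expect_true(all(v <= growth$plateau_g))
  expect_equal(metastatic_burden(st), sum(v[-1]))
  expect_identical(tumor_volumes(st, include_primary = FALSE), v[-1])
})

test_that("formation time increases with the detectable-metastasis milestone", {
  cfg <- dissemination_config(c = 2.56)
  t1 <- mean(vapply(simulate_cohort(60, growth, cfg, 1, seed = 5),
                    `[[`, 0, "census_time_days"))
  t5 <- mean(vapply(simulate_cohort(60, growth, cfg, 5, seed = 6),
                    `[[`, 0, "census_time_days"))
  expect_gt(t5, t1)
})

test_that("low formation rates give fewer, larger metastases than high rates", {
  oligo <- summarize_cohort(simulate_cohort(60, growth,
                                            dissemination_config(c = 0.16), 5, seed = 7))
  diffuse <- summarize_cohort(simulate_cohort(60, growth,
                                              dissemination_config(c = 2.56), 5, seed = 8))
  expect_lt(oligo$n_metastases, diffuse$n_metastases)
  expect_gt(oligo$burden_cm3, 2 * diffuse$burden_cm3)
  expect_gt(oligo$median_size_cm3, diffuse$median_size_cm3)
})

test_that("halving the time step leaves cohort summaries unchanged within noise", {
  s1 <- summarize_cohort(simulate_cohort(80, growth,
                                         dissemination_config(c = 2.56, dt_days = 1), 1, seed = 11))
  s2 <- summarize_cohort(simulate_cohort(80, growth,
                                         dissemination_config(c = 2.56, dt_days = 0.5), 1, seed = 11))
  expect_equal(s2$formation_time_d / s1$formation_time_d, 1, tolerance = 0.05)
  expect_equal(s2$n_metastases / s1$n_metastases, 1, tolerance = 0.15)
})

test_that("fusion discards part of the disseminated seeds", {
  base <- summarize_cohort(simulate_cohort(40, growth,
                                           dissemination_config(c = 2.56), 1, seed = 13))
  fus <- summarize_cohort(simulate_cohort(40, growth,
                                          dissemination_config(c = 2.56, fusion_enabled = TRUE,
                                                               fusion_bed_volume_cm3 = 40),
                                          1, seed = 13))
  expect_lt(fus$n_metastases, base$n_metastases)
})

test_that("cohort summaries validate their inputs and respect the detection bound", {
  cfg <- dissemination_config(c = 2.56)
  states <- simulate_cohort(30, growth, cfg, 1, seed = 21)
  expect_error(summarize_cohort(states[1]), "at least two")
  mixed <- c(states[1:2],
             list(simulate_patient(growth, dissemination_config(c = 0.16), 1, seed = 3)))
  expect_error(summarize_cohort(mixed), "differing")
  s <- summarize_cohort(states)
  expect_gte(s$size_p2.5_cm3, sphere_volume_cm3(7))
  expect_identical(s$replicates, 30L)
})

test_that("the primary-only state is the plateau-stage baseline", {
  st <- primary_only_state(growth)
  expect_length(st$birth_days, 0)
  expect_equal(tumor_volumes(st), 0.99 * growth$plateau_g, tolerance = 1e-6)
  expect_identical(n_detectable(st), 0L)
})
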