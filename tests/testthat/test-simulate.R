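test_that("the generator is deterministic and respects the event order", {
  s1 <- simulate_study(seed = 5)
  s2 <- simulate_study(seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_study(seed = 6)
  expect_false(identical(s1$landmarks, s3$landmarks))

  ex <- s1$experiments
  ok <- !is.na(ex$courtship_start_s)
  expect_true(all(ex$courtship_start_s[ok] <= ex$copulation_start_s[ok]))
  expect_true(all(ex$copulation_start_s <= ex$settling_s))
  expect_true(all(ex$settling_s < ex$copulation_end_s))
  # copulations never shorter than the 15-second validity rule
  expect_true(all(is_valid_copulation(
    ex$copulation_end_s - ex$copulation_start_s)))
  # every measurement lies within the recording span of its experiment
  tr <- dplyr::left_join(s1$truth,
                         ex[c("experiment_id", "settling_s",
                              "copulation_end_s")],
                         by = "experiment_id")
  expect_true(all(tr$time_s >= tr$settling_s &
                    tr$time_s <= tr$copulation_end_s))
  # ground truth covers every emitted frame
  frames <- unique(s1$landmarks[c("experiment_id", "timepoint_label")])
  expect_equal(nrow(dplyr::anti_join(frames, s1$truth,
                                     by = c("experiment_id",
                                            "timepoint_label"))), 0)
  # per-species counts follow the specs
  counts <- dplyr::count(ex, species_code)
  specs <- species_sim_specs()
  expect_equal(counts$n[match(specs$species_code, counts$species_code)],
               specs$n_experiments)
})

test_that("noiseless landmarks reproduce the true angle exactly", {
  specs <- dplyr::mutate(species_sim_specs()[c(2, 3), ],
                         landmark_noise_px = 0, n_experiments = 3L)
  s <- simulate_study(specs, seed = 7)
  ang <- measure_angles(s$landmarks)
  joined <- dplyr::inner_join(
    dplyr::distinct(ang, experiment_id, timepoint_label, angle_deg),
    s$truth, by = c("experiment_id", "timepoint_label"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$angle_deg, joined$true_angle_deg, tolerance = 1e-9)

  # frontal generator closes the loop too
  sf <- simulate_frontal(n_experiments = 3, seed = 7, landmark_noise_px = 0)
  fa <- measure_angles(sf$landmarks)
  j2 <- dplyr::inner_join(fa, sf$truth, by = c("experiment_id", "time_s"))
  expect_equal(j2$angle_deg, j2$true_angle_deg, tolerance = 1e-9)
})

test_that("simulated durations track the study conditions", {
  s <- simulate_study(seed = 13)
  dur <- durations(s$experiments)
  nan <- dur$copulation_min[dur$species_code == "nan"]
  expect_equal(length(nan), 21)
  # sample mean within 3 standard errors of the 11.9-minute truth
  expect_lt(abs(mean(nan) - 11.9), 3 * 4.2 / sqrt(21))
  expect_true(all(nan >= 4.03 & nan <= 20.1))  # truncation bounds
  aca <- dur$copulation_min[dur$species_code == "aca"]
  expect_true(all(aca >= 38.85 & aca <= 144.3))
  # grid sampling reflects the per-species schedule rules: short copulators
  # only get settling + pct10
  bro_frames <- unique(s$truth$timepoint_label[s$truth$species_code == "bro"])
  expect_setequal(bro_frames, c("settling", "pct10"))
  aca_frames <- s$truth$timepoint_label[s$truth$species_code == "aca"]
  expect_true(any(grepl("^grid", aca_frames)))
})

test_that("bilateral generator hits its true index and is reproducible", {
  s <- simulate_bilateral(seed = 3)
  expect_identical(s, simulate_bilateral(seed = 3))
  scored <- asymmetry_scores(s$records)
  aca <- scored[scored$species_code == "aca", ]
  expect_equal(nrow(aca), 10)
  expect_lt(abs(mean(aca$asym_index) - (-0.2)), 3 * 0.05 / sqrt(10))
  expect_error(simulate_bilateral(
    dplyr::mutate(bilateral_sim_specs(), index_sd = -1), seed = 1),
    "non-negative")
})

test_that("discarded trials carry sampled exclusion reasons", {
  s <- simulate_study(species_sim_specs()[1:2, ], seed = 2,
                      n_discarded = 50)
  ex <- s$experiments
  expect_equal(sum(ex$exclusion_reasons != ""), 50)
  # courtship-retained = clean trials plus discards whose only reason does
  # not affect courtship (incomplete copulation recording)
  acc <- accounting(ex, "courtship")
  expect_equal(acc$n[acc$category == "retained"],
               sum(ex$exclusion_reasons == "") +
                 sum(ex$exclusion_reasons == "incomplete_copulation_recording"))
})
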