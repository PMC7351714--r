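test_that("trailing moving average matches the brute-force oracle", {
  expect_error(moving_average(1:10, 0), "width")

  # constant series is constant from index width-1 onward, NA before
  ma <- moving_average(rep(7, 50), 10)
  expect_true(all(is.na(ma[1:9])))
  expect_equal(ma[10:50], rep(7, 41))

  expect_equal(moving_average(c(1, 2, 3, 4, 5), 5)[5], 3)

  set.seed(101)
  x <- rnorm(500, 90, 5)
  x[sample.int(500, 40)] <- NA
  for (w in c(5, 60)) {
    expect_equal(moving_average(x, w), brute_ma(x, w))
  }
})

test_that("missing samples inside a partially-missing window are mean-excluded", {
  x <- c(10, NA, 20, NA, NA)
  expect_equal(moving_average(x, 3)[3], 15)   # mean of 10, 20
  expect_equal(moving_average(x, 3)[5], 20)   # only one observed value left
  expect_equal(moving_average(x, 2)[3], 20)
  expect_true(is.na(moving_average(x, 2)[5])) # window entirely missing
  expect_true(is.na(moving_average(c(NA, NA, NA), 2)[2]))
})

test_that("annotator handles the canonical drop, floor and no-drop cases", {
  # constant MAP: no episode
  expect_equal(nrow(annotate_record(flat_record(90, 180))), 0L)

  # abrupt sustained 30% drop: exactly one episode, at the oracle's onset
  rec <- vitals_record(c(rep(100, 120), rep(70, 120)),
                       rep(75, 240), rep(97, 240), "drop")
  got <- annotate_record(rec)
  want <- brute_annotate(rec)
  expect_equal(nrow(got), 1L)
  expect_equal(got$onset, want$onset)
  expect_equal(got$end, want$end)

  # drop below the 20 mmHg validity floor: rejected entirely
  rec15 <- vitals_record(c(rep(100, 120), rep(15, 120)),
                         rep(75, 240), rep(97, 240), "floor")
  expect_equal(nrow(annotate_record(rec15)), 0L)

  # record too short for the rules: empty with a warning, not an error
  short <- vitals_record(rep(80, 125), rep(70, 125), rep(95, 125), "s")
  wide <- annotation_config(long_ma_width = 120, short_ma_width = 5)
  expect_warning(out <- annotate_record(short, wide), "short")
  expect_equal(nrow(out), 0L)
})

test_that("annotator equals the naive re-implementation on seeded records", {
  # moderately noisy records with missingness and artifacts included
  coh <- generate_cohort(cohort_config(
    n_patients = 40, record_length_range = c(300L, 1000L),
    ahe_prevalence = 0.5, seed = 303))
  for (rec in coh$records) {
    got <- annotate_record(rec)
    want <- brute_annotate(rec)
    expect_equal(nrow(got), nrow(want), info = rec$patient_id)
    if (nrow(got)) {
      expect_equal(got$onset, want$onset, info = rec$patient_id)
      expect_equal(got$end, want$end, info = rec$patient_id)
    }
  }
})

test_that("episodes are non-overlapping with strictly increasing onsets", {
  # two separated drops in one record
  rec <- flat_record(100, 900)
  rec <- inject_ahe(rec, 150, 0.3, 40, precursor_lead = 0,
                    precursor_amplitude = c(hr = 0, map = 0))
  rec <- inject_ahe(rec, 600, 0.3, 40, precursor_lead = 0,
                    precursor_amplitude = c(hr = 0, map = 0))
  ev <- annotate_record(rec)
  expect_equal(nrow(ev), 2L)
  expect_true(all(diff(ev$onset) > 0))
  closed_end <- ifelse(is.na(ev$end), rec$length, ev$end)
  expect_true(all(ev$onset[-1] >= closed_end[-nrow(ev)]))

  # generated cohorts never produce overlapping or disordered episodes
  coh <- generate_cohort(cohort_config(n_patients = 30, ahe_prevalence = 0.6,
                                       seed = 77))
  for (r in coh$records) {
    e <- annotate_record(r)
    if (nrow(e) < 2) next
    expect_true(all(diff(e$onset) > 0))
    ce <- ifelse(is.na(e$end), r$length, e$end)
    expect_true(all(e$onset[-1] >= ce[-nrow(e)]))
  }
})

test_that("the MA-ratio rule is scale invariant, unlike the conventional rule", {
  coh <- generate_cohort(cohort_config(n_patients = 10, ahe_prevalence = 1,
                                       missing_rate = 0, artifact_rate = 0,
                                       seed = 55))
  cfg <- annotation_config(validity_floor = 0)  # isolate the ratio rule
  for (rec in coh$records) {
    ev1 <- annotate_record(rec, cfg)
    scaled <- vitals_record(rec$map * 3.7, rec$hr, rec$spo2, rec$patient_id)
    ev2 <- annotate_record(scaled, cfg)
    expect_equal(ev1$onset, ev2$onset)
  }

  # relative definition fires on a 25% drop from 100; conventional does not
  rec <- vitals_record(c(rep(100, 120), rep(75, 180)),
                       rep(75, 300), rep(97, 300), "fig2")
  expect_gte(nrow(annotate_record(rec)), 1L)
  expect_equal(nrow(annotate_conventional(rec)), 0L)
})

test_that("conventional threshold definition follows the 90%/30-min rule", {
  below <- vitals_record(c(rep(80, 120), rep(59, 30), rep(80, 50)),
                         rep(75, 200), rep(97, 200), "c1")
  ev <- annotate_conventional(below)
  expect_equal(nrow(ev), 1L)
  expect_lte(ev$onset, 120)
  expect_gte(ev$end, 150)

  above <- flat_record(61, 200)
  expect_equal(nrow(annotate_conventional(above)), 0L)

  # 26 of 30 readings below threshold (86.7%) does not qualify
  m <- c(rep(80, 100), rep(55, 26), rep(80, 4), rep(80, 70))
  mixed <- vitals_record(m, rep(75, 200), rep(97, 200), "c3")
  expect_equal(nrow(annotate_conventional(mixed)), 0L)
})

test_that("minimum episode duration equals the validity horizon", {
  expect_equal(minimum_event_duration(annotation_config()), 10L)
  expect_equal(minimum_event_duration(annotation_config(validity_horizon = 15)),
               15L)

  # empirical sweep: no closed episode shorter than the horizon
  coh <- generate_cohort(cohort_config(
    n_patients = 300, record_length_range = c(300L, 700L),
    ahe_prevalence = 0.6, seed = 909))
  durations <- c()
  for (rec in coh$records) {
    ev <- annotate_record(rec)
    closed <- ev[!is.na(ev$end), , drop = FALSE]
    durations <- c(durations, closed$end - closed$onset)
  }
  expect_gt(length(durations), 20)
  expect_gte(min(durations), 10)
})
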