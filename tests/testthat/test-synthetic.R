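test_that("generator configuration is validated", {
  expect_error(cohort_config(record_length_range = c(900, 500)), "min <= max")
  expect_error(cohort_config(missing_rate = 1), "probability")
  expect_error(cohort_config(missing_rate = -0.1), "probability")
})

test_that("cohort generation is a pure function of (config, seed)", {
  cfg <- cohort_config(n_patients = 6, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$events, b$events)
  c2 <- generate_cohort(cohort_config(n_patients = 6, seed = 124))
  expect_false(identical(a$records, c2$records))
})

test_that("event prevalence lands in the binomial 99% band", {
  coh <- generate_cohort(cohort_config(n_patients = 200, ahe_prevalence = 0.5,
                                       seed = 9))
  frac <- length(unique(coh$events$patient_id)) / 200
  half <- stats::qnorm(0.995) * sqrt(0.25 / 200)
  expect_gte(frac, 0.5 - half)
  expect_lte(frac, 0.5 + half)
})

test_that("no-signal cohorts yield zero annotated episodes", {
  coh <- generate_cohort(cohort_config(n_patients = 50, ahe_prevalence = 0,
                                       noise_sd = c(map = 2, hr = 3, spo2 = 0.8),
                                       missing_rate = 0, artifact_rate = 0,
                                       seed = 21))
  expect_equal(nrow(coh$events), 0L)
  for (rec in coh$records) {
    expect_equal(nrow(annotate_record(rec)), 0L)
  }
})

test_that("inject_ahe round-trips through the annotator", {
  rec <- flat_record(100, 400)
  out <- inject_ahe(rec, onset = 120, depth_fraction = 0.25, duration = 30,
                    precursor_lead = 60)
  ev <- annotate_record(out)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$onset - 120), 5)

  # identity when nothing is injected
  same <- inject_ahe(rec, 120, depth_fraction = 0, duration = 30,
                     precursor_lead = 60, precursor_amplitude = c(hr = 0, map = 0))
  expect_identical(same, rec)

  # precursor only: MAP touched solely before onset
  pre <- inject_ahe(rec, 120, depth_fraction = 0, duration = 30,
                    precursor_lead = 60, precursor_amplitude = c(hr = 10, map = 5))
  expect_identical(pre$map[122:400], rec$map[122:400])
  expect_lt(pre$map[120], rec$map[120])
  expect_gt(pre$hr[120], rec$hr[120])

  expect_error(inject_ahe(rec, onset = 30, duration = 10), "onset")
  expect_error(inject_ahe(rec, onset = 390, duration = 30), "onset")
})

test_that("a forced sub-floor MAP after detection voids the episode", {
  rec <- inject_ahe(flat_record(100, 400), onset = 120, depth_fraction = 0.25,
                    duration = 30, precursor_lead = 0,
                    precursor_amplitude = c(hr = 0, map = 0))
  det <- annotate_record(rec)$onset[1]
  bad <- rec$map
  bad[(det + 2):(det + 11)] <- 15      # violate floor in the validity horizon
  broken <- vitals_record(bad, rec$hr, rec$spo2, "violated")
  ev <- annotate_record(broken)
  expect_false(any(abs(ev$onset - det) <= 2))
})

test_that("missingness injection is Bernoulli per sample and reproducible", {
  rec <- flat_record(90, 1000)
  expect_identical(inject_missingness(rec, 0), rec)
  a <- inject_missingness(rec, 0.1, seed = 5)
  b <- inject_missingness(rec, 0.1, seed = 5)
  expect_identical(a, b)
  half <- stats::qnorm(0.995) * sqrt(1000 * 0.1 * 0.9)
  for (ch in c("map", "hr", "spo2")) {
    n_miss <- sum(is.na(a[[ch]]))
    expect_gte(n_miss, 100 - half)
    expect_lte(n_miss, 100 + half)
  }
  expect_error(inject_missingness(rec, 1), "probability")
})

test_that("planted artifacts sit outside physiological ranges", {
  coh <- generate_cohort(cohort_config(n_patients = 20, artifact_rate = 0.01,
                                       missing_rate = 0, seed = 31))
  expect_gt(nrow(coh$artifacts), 0)
  rng <- physiological_ranges()
  for (k in seq_len(nrow(coh$artifacts))) {
    a <- coh$artifacts[k, ]
    rec <- Filter(function(r) r$patient_id == a$patient_id, coh$records)[[1]]
    v <- rec[[a$channel]][a$index + 1L]
    r <- rng[[a$channel]]
    expect_true(v < r[1] || v > r[2])
  }
})

test_that("planted episodes are recovered under low-noise conditions", {
  hits <- 0L; total <- 0L; false_pos <- 0L
  for (s in 1:100) {
    cfg <- cohort_config(n_patients = 1, ahe_prevalence = 1,
                         noise_sd = c(map = 1, hr = 2, spo2 = 0.5),
                         event_duration_range = c(20L, 60L),
                         missing_rate = 0, artifact_rate = 0, seed = s)
    coh <- generate_cohort(cfg)
    if (nrow(coh$events) == 0L) next
    total <- total + 1L
    ev <- annotate_record(coh$records[[1]])
    if (nrow(ev) && any(abs(ev$onset - coh$events$onset[1]) <= 5)) {
      hits <- hits + 1L
    }
  }
  for (s in 1:100) {
    coh <- generate_cohort(cohort_config(
      n_patients = 1, ahe_prevalence = 0,
      noise_sd = c(map = 1, hr = 2, spo2 = 0.5),
      missing_rate = 0, artifact_rate = 0, seed = 5000 + s))
    false_pos <- false_pos + nrow(annotate_record(coh$records[[1]]))
  }
  expect_gte(hits / total, 0.95)
  expect_equal(false_pos, 0L)
})

test_that("cohorts round-trip through the CSV + manifest format", {
  coh <- generate_cohort(cohort_config(n_patients = 3, seed = 8))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  for (rec in coh$records) {
    back <- read_vitals(file.path(dir, paste0(rec$patient_id, ".csv")))
    expect_equal(back$map, rec$map)
    expect_equal(back$hr, rec$hr)
    expect_equal(back$spo2, rec$spo2)
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$patients, vapply(coh$records, `[[`, "", "patient_id"))
  unlink(dir, recursive = TRUE)
})
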