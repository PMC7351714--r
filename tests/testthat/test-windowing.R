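ev_row <- function(onset, end, pid = "p") {
  data.frame(patient_id = pid, onset = onset, end = end,
             drop_fraction = 0.25, definition = "patient_specific",
             stringsAsFactors = FALSE)
}

test_that("positive windows obey the interval arithmetic and boundaries", {
  rec <- flat_record(90, 500, "p")
  w <- extract_positive_windows(rec, ev_row(200, 230), 30, 10)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 160)
  expect_equal(w$start + w$obs, 190)       # ends exactly gap before onset
  expect_equal(w$label, 1L)

  # would start before the record begins
  none <- extract_positive_windows(rec, ev_row(50, 80), 30, 30)
  expect_equal(nrow(none), 0L)

  expect_error(extract_positive_windows(rec, ev_row(200, 230), 25, 10),
               "grid")
})

test_that("successive positives require 2 h from the prior episode's end", {
  rec <- flat_record(90, 800, "p")
  two <- rbind(ev_row(280, 300), ev_row(400, 430))
  w <- extract_positive_windows(rec, two, 60, 10)
  # second window [330, 390) starts before 300 + 120 = 420: suppressed
  expect_equal(nrow(w), 1L)
  expect_equal(w$event_onset, 280)

  # move the second episode far enough out and it qualifies
  two_ok <- rbind(ev_row(280, 300), ev_row(500, 530))
  w2 <- extract_positive_windows(rec, two_ok, 60, 10)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$start[2], 430)
})

test_that("negative packing is greedy with event-only guard margins", {
  rec <- flat_record(90, 500, "p")
  none <- extract_negative_windows(rec, NULL, 60)
  expect_equal(none$start, seq(0L, 420L, by = 60L))   # floor(500/60) = 8

  # an episode [240, 260) blocks the guarded middle of the record
  w <- extract_negative_windows(rec, ev_row(240, 260), 60)
  expect_equal(w$start, c(0L, 60L, 380L, 440L))
  # exhaustive check: no emitted window's guard region touches the episode
  for (s in w$start) {
    expect_false(240 < s + 60 + 120 && 260 > s - 120)
  }

  # record fully covered by one episode yields nothing
  all_ev <- extract_negative_windows(rec, ev_row(0, NA), 60)
  expect_equal(nrow(all_ev), 0L)

  # strict margins additionally require the full guard inside the record
  strict <- extract_negative_windows(rec, ev_row(240, 260), 60,
                                     strict_margin = TRUE)
  expect_true(all(strict$start - 120 >= 0 & strict$start + 180 <= 500))
})

test_that("quality filter counts missing and out-of-range jointly, strictly", {
  w <- matrix(90, 60, 3)
  expect_true(quality_filter(w))
  w19 <- w; w19[1:10, 1] <- NA; w19[1:9, 2] <- 250   # 19/180 = 10.6%
  expect_false(quality_filter(w19))
  w18 <- w; w18[1:9, 1] <- NA; w18[1:9, 2] <- 250    # exactly 10.0%
  expect_true(quality_filter(w18))
})

test_that("datasets assemble labels, provenance and gap-independent negatives", {
  coh <- generate_cohort(cohort_config(n_patients = 30, ahe_prevalence = 0.4,
                                       record_length_range = c(400L, 800L),
                                       seed = 61))
  ev <- annotate_cohort(coh)
  ds <- build_dataset(coh, ev, obs_length = 30, gap_length = 20)
  expect_s3_class(ds, "ahe_dataset")
  expect_false(anyNA(ds$x))
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_true(all(ds$mask %in% c(0, 1)))

  # positives correspond to annotated episodes that pass the margins
  pos <- which(ds$label == 1L)
  for (i in pos) {
    expect_equal(ds$start[i] + ds$obs + ds$gap, ds$event_onset[i])
  }

  # negatives do not depend on the gap
  ds2 <- build_dataset(coh, ev, obs_length = 30, gap_length = 50)
  neg1 <- paste(ds$patient_id[ds$label == 0], ds$start[ds$label == 0])
  neg2 <- paste(ds2$patient_id[ds2$label == 0], ds2$start[ds2$label == 0])
  expect_identical(neg1, neg2)

  # an event-free cohort produces only negative labels
  null_coh <- generate_cohort(cohort_config(n_patients = 10,
                                            ahe_prevalence = 0, seed = 62))
  null_ds <- build_dataset(null_coh, obs_length = 30, gap_length = 20)
  expect_true(all(null_ds$label == 0L))

  # determinism
  ds3 <- build_dataset(coh, ev, obs_length = 30, gap_length = 20)
  expect_identical(ds$x, ds3$x)
  expect_identical(ds$label, ds3$label)
})

test_that("guard regions, overlaps and positive alignment hold cohort-wide", {
  for (s in 1:25) {
    coh <- generate_cohort(cohort_config(
      n_patients = 4, record_length_range = c(300L, 700L),
      ahe_prevalence = 0.6, seed = 400 + s))
    ev <- annotate_cohort(coh)
    for (rec in coh$records) {
      e <- ev[ev$patient_id == rec$patient_id, , drop = FALSE]
      iv_end <- ifelse(is.na(e$end), rec$length, e$end)
      neg <- extract_negative_windows(rec, e, 30)
      if (nrow(neg) > 1) {
        st <- sort(neg$start)
        expect_true(all(diff(st) >= 30))
      }
      for (sdx in neg$start) {
        expect_false(any(e$onset < sdx + 30 + 120 & iv_end > sdx - 120))
      }
      pos <- extract_positive_windows(rec, e, 30, 40)
      if (nrow(pos)) {
        expect_true(all(pos$start + 30 + 40 == pos$event_onset))
      }
    }
  }
})
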