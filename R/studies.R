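# Synthetic-cohort reproduction studies.  These wrap the full pipeline into
# self-contained experiments whose conditions are fixed package choices:
# they are what the test suite and the reproduction script run.

#' Learnability study: AUROC across gap lengths with a strong precursor
#'
#' Generates a 300-patient cohort whose planted episodes carry a strong
#' 60-minute precursor (HR ramp +15 bpm, MAP drift -8 mmHg), then trains
#' one stacked-LSTM classifier per gap length (60-minute observation
#' window) over several seeds and scores each on the held-out patient test
#' set.  With the precursor confined to the hour before onset, windows at
#' short gaps overlap most of it and long gaps see none, so discrimination
#' should fall toward chance as the gap grows — the qualitative lead-time
#' trend the pipeline is designed to expose.
#'
#' @param seed Master seed (cohort, splits, fits derive from it).
#' @param gaps Gap lengths to evaluate (default [studied_grid()]).
#' @param n_seeds Training replicates per gap.
#' @param epochs LSTM training epochs (reduced-epoch regime).
#' @param n_patients Cohort size.
#' @return Data frame with columns `gap`, `seed`, `auroc`.
#' @export
study_learnability <- function(seed = 1L, gaps = studied_grid(),
                               n_seeds = 3L, epochs = 40L,
                               n_patients = 300L) {
  cfg <- cohort_config(
    n_patients = n_patients, record_length_range = c(480L, 960L),
    ahe_prevalence = 0.5, precursor_lead = 60L,
    precursor_amplitude = c(hr = 15, map = 8),
    missing_rate = 0.005, artifact_rate = 0.001,
    seed = derive_seed(seed, 99L))
  coh <- generate_cohort(cfg)
  ev <- annotate_cohort(coh)
  out <- list()
  for (gap in gaps) {
    ds <- build_dataset(coh, ev, obs_length = 60L, gap_length = gap)
    split <- split_by_patient(ds, c(0.7, 0.15, 0.15),
                              seed = derive_seed(seed, 5L))
    for (r in seq_len(n_seeds)) {
      bal <- balance_training_sets(split, seed = derive_seed(seed, 10L * gap + r))
      fit <- ahe_fit(bal$train, "lstm", val_data = bal$val,
                     spec = lstm_spec(epochs = epochs),
                     seed = derive_seed(seed, 100L * gap + r))
      out[[length(out) + 1L]] <- data.frame(
        gap = gap, seed = r,
        auroc = auroc(predict(fit, bal$test), bal$test$label))
    }
  }
  do.call(rbind, out)
}

#' Null-calibration study: shuffled-label training
#'
#' Trains the LSTM on the gap-10 dataset after randomly permuting the
#' training and validation labels, repeating over seeds.  Test AUROC should
#' sit at chance: any systematic departure indicates leakage between the
#' pipeline stages.
#'
#' @param seed Master seed.
#' @param n_seeds Number of shuffled replicates.
#' @param epochs Training epochs per replicate.
#' @param n_patients Cohort size.
#' @return Numeric vector of test AUROCs, one per replicate.
#' @export
study_null_calibration <- function(seed = 1L, n_seeds = 5L, epochs = 12L,
                                   n_patients = 300L) {
  cfg <- cohort_config(
    n_patients = n_patients, record_length_range = c(480L, 960L),
    ahe_prevalence = 0.5, precursor_lead = 60L,
    precursor_amplitude = c(hr = 15, map = 8),
    missing_rate = 0.005, artifact_rate = 0.001,
    seed = derive_seed(seed, 99L))
  coh <- generate_cohort(cfg)
  ds <- build_dataset(coh, obs_length = 60L, gap_length = 10L)
  split <- split_by_patient(ds, c(0.7, 0.15, 0.15),
                            seed = derive_seed(seed, 5L))
  vapply(seq_len(n_seeds), function(r) {
    bal <- balance_training_sets(split, seed = derive_seed(seed, 600L + r))
    sh <- bal
    sh$train$label <- with_seed(derive_seed(seed, 700L + r),
                                resample(bal$train$label))
    sh$val$label <- with_seed(derive_seed(seed, 800L + r),
                              resample(bal$val$label))
    fit <- ahe_fit(sh$train, "lstm", val_data = sh$val,
                   spec = lstm_spec(epochs = epochs),
                   seed = derive_seed(seed, 900L + r))
    auroc(predict(fit, bal$test), bal$test$label)
  }, 0)
}

#' Planted-event recovery study
#'
#' Low-noise round trip between the generator and the annotator: single
#' planted episodes (depth 25%, duration 20-60 min, MAP noise SD 1 mmHg, no
#' missingness or artifacts) must be re-detected within 5 minutes of their
#' planted onset, and matching event-free cohorts must produce no episodes.
#'
#' @param seed Master seed.
#' @param n_records Records per arm.
#' @return List with `recovery` (fraction re-detected within 5 min) and
#'   `false_positives` (episode count over the null arm).
#' @export
study_event_recovery <- function(seed = 1L, n_records = 100L) {
  hits <- 0L; total <- 0L; fp <- 0L
  for (i in seq_len(n_records)) {
    coh <- generate_cohort(cohort_config(
      n_patients = 1L, ahe_prevalence = 1,
      noise_sd = c(map = 1, hr = 2, spo2 = 0.5),
      event_duration_range = c(20L, 60L),
      missing_rate = 0, artifact_rate = 0,
      seed = derive_seed(seed, i)))
    if (nrow(coh$events) == 0L) next
    total <- total + 1L
    ev <- annotate_record(coh$records[[1L]])
    if (nrow(ev) && any(abs(ev$onset - coh$events$onset[1L]) <= 5)) {
      hits <- hits + 1L
    }
  }
  for (i in seq_len(n_records)) {
    coh <- generate_cohort(cohort_config(
      n_patients = 1L, ahe_prevalence = 0,
      noise_sd = c(map = 1, hr = 2, spo2 = 0.5),
      missing_rate = 0, artifact_rate = 0,
      seed = derive_seed(seed, 100000L + i)))
    fp <- fp + nrow(annotate_record(coh$records[[1L]]))
  }
  list(recovery = hits / total, false_positives = fp, n = total)
}

#' Bootstrap coverage study
#'
#' Simulates score sets with a known true AUROC (binormal model: negatives
#' N(0,1), positives N(mu,1) with `mu = sqrt(2) * qnorm(true_auroc)`),
#' computes the percentile bootstrap 95% interval on each, and reports how
#' often the interval covers the truth.
#'
#' @param seed Master seed.
#' @param n_datasets Simulated datasets.
#' @param n_pos,n_neg Class sizes per dataset.
#' @param true_auroc Target true AUROC.
#' @param n_boot Bootstrap resamples per dataset.
#' @return List with `coverage` and the per-dataset `covered` logical.
#' @export
study_bootstrap_coverage <- function(seed = 1L, n_datasets = 200L,
                                     n_pos = 40L, n_neg = 60L,
                                     true_auroc = 0.8, n_boot = 1000L) {
  mu <- sqrt(2) * stats::qnorm(true_auroc)
  covered <- with_seed(seed, {
    vapply(seq_len(n_datasets), function(i) {
      s <- c(stats::rnorm(n_pos, mu), stats::rnorm(n_neg))
      y <- c(rep(1L, n_pos), rep(0L, n_neg))
      ci <- bootstrap_ci(s, y, n_boot = n_boot,
                         seed = derive_seed(seed, 3000L + i))
      ci[["lo"]] <= true_auroc && true_auroc <= ci[["hi"]]
    }, NA)
  })
  list(coverage = mean(covered), covered = covered)
}
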