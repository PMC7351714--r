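#' Configuration for the synthetic vital-signs cohort generator
#'
#' The generator emulates the statistical structure of per-minute ICU
#' bedside-monitor extracts: records of several hours to a day, wide
#' inter-patient variation in baseline MAP, slow autocorrelated
#' within-patient fluctuation, sporadic missing samples and isolated
#' non-physiological artifact spikes.  A configurable fraction of records
#' carries one planted hypotensive episode: a smooth 2–3 minute sigmoid
#' descent into a depressed MAP plateau (default 25% below the local
#' baseline, comfortably past the 20% annotation threshold), preceded by a
#' learnable precursor — a linear heart-rate ramp and gentle MAP down-drift
#' starting `precursor_lead` minutes before onset — so that predictive skill
#' at a given gap length is verifiable against ground truth.
#'
#' @param n_patients Number of records to generate.
#' @param record_length_range Min/max record length in minutes.
#' @param baseline_map_mean_range Per-patient baseline MAP draw range (mmHg).
#' @param baseline_hr_mean_range Per-patient baseline HR draw range (bpm).
#' @param baseline_spo2_mean_range Per-patient baseline SpO2 range (percent).
#' @param noise_sd Named vector of within-patient stationary noise SDs for
#'   `map`, `hr`, `spo2`.
#' @param ahe_prevalence Probability a record carries a planted episode.
#' @param event_depth_fraction Relative MAP drop of planted episodes; keep
#'   above 0.20 for events meant to be detectable.
#' @param event_duration_range Min/max planted episode duration (minutes).
#' @param precursor_lead Minutes before onset the precursor begins.
#' @param precursor_amplitude Named vector: `hr` ramp height (bpm) and `map`
#'   down-drift (mmHg) reached at onset.
#' @param missing_rate Per-sample, per-channel missingness probability
#'   (missing completely at random).
#' @param artifact_rate Per-sample, per-channel probability of an isolated
#'   out-of-physiological-range spike.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit-for-bit.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          record_length_range = c(480L, 1440L),
                          baseline_map_mean_range = c(70, 110),
                          baseline_hr_mean_range = c(60, 100),
                          baseline_spo2_mean_range = c(94, 99),
                          noise_sd = c(map = 2, hr = 3, spo2 = 0.8),
                          ahe_prevalence = 0.35,
                          event_depth_fraction = 0.25,
                          event_duration_range = c(20L, 60L),
                          precursor_lead = 60L,
                          precursor_amplitude = c(hr = 10, map = 5),
                          missing_rate = 0.02,
                          artifact_rate = 0.002,
                          seed = 1L) {
  chk_range <- function(r, name) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be c(min, max) with min <= max", name),
           call. = FALSE)
    }
  }
  chk_range(record_length_range, "record_length_range")
  chk_range(baseline_map_mean_range, "baseline_map_mean_range")
  chk_range(baseline_hr_mean_range, "baseline_hr_mean_range")
  chk_range(baseline_spo2_mean_range, "baseline_spo2_mean_range")
  chk_range(event_duration_range, "event_duration_range")
  stopifnot_prob(missing_rate, "missing_rate")
  stopifnot_prob(artifact_rate, "artifact_rate")
  if (ahe_prevalence < 0 || ahe_prevalence > 1) {
    stop("ahe_prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (record_length_range[1] < 240L) {
    stop("records shorter than 240 min leave no room for episode placement",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    record_length_range = as.integer(record_length_range),
    baseline_map_mean_range = baseline_map_mean_range,
    baseline_hr_mean_range = baseline_hr_mean_range,
    baseline_spo2_mean_range = baseline_spo2_mean_range,
    noise_sd = noise_sd,
    ahe_prevalence = ahe_prevalence,
    event_depth_fraction = event_depth_fraction,
    event_duration_range = as.integer(event_duration_range),
    precursor_lead = as.integer(precursor_lead),
    precursor_amplitude = precursor_amplitude,
    missing_rate = missing_rate,
    artifact_rate = artifact_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Stationary AR(1) noise: slow physiological fluctuation without drifts
# large enough to open a 20% gap between the 5- and 60-min moving averages.
ar1_noise <- function(n, sd, phi = 0.9) {
  if (sd == 0) return(rep(0, n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  stats::filter(e, phi, method = "recursive") +
    stats::rnorm(1, 0, sd) * phi^(seq_len(n))  # warm start from stationarity
}

#' Plant a hypotensive episode (with precursor) into a record
#'
#' MAP is depressed multiplicatively by `depth_fraction` relative to the
#' pre-onset baseline (the mean MAP over the hour before the precursor
#' begins) over `[onset, onset + duration)`, entering and leaving the
#' plateau through a ~3-minute sigmoid so the short moving average descends
#' gradually.  A precursor — linear HR ramp up and linear MAP drift down,
#' reaching `precursor_amplitude` at onset — occupies
#' `[onset - precursor_lead, onset)`.  Modified MAP samples are floored at
#' `map_floor` so planted episodes respect the annotator's validity floor.
#'
#' This is a deterministic transformation; all randomness lives in
#' [generate_cohort()].
#'
#' @param record A [vitals_record()].
#' @param onset 0-based minute index of episode onset; must be `>= 60` (the
#'   annotator needs an hour of history) and leave room for `duration`.
#' @param depth_fraction Relative MAP drop (0 disables the drop).
#' @param duration Episode duration in minutes.
#' @param precursor_lead Precursor length in minutes (0 disables it).
#' @param precursor_amplitude Named vector `c(hr = , map = )`.
#' @param map_floor Lower clamp (mmHg) applied to modified samples.
#' @return The modified `vitals_record`.
#' @export
inject_ahe <- function(record, onset, depth_fraction = 0.25, duration = 30L,
                       precursor_lead = 60L,
                       precursor_amplitude = c(hr = 10, map = 5),
                       map_floor = 25) {
  stopifnot(inherits(record, "vitals_record"))
  onset <- as.integer(onset); duration <- as.integer(duration)
  n <- record$length
  if (onset < 60L || onset + duration > n) {
    stop("onset must be >= 60 and onset + duration <= record length",
         call. = FALSE)
  }
  if (onset - precursor_lead < 0L) {
    stop("precursor would start before the record begins", call. = FALSE)
  }
  amp_hr <- precursor_amplitude[["hr"]] %||% 0
  amp_map <- precursor_amplitude[["map"]] %||% 0
  if (depth_fraction == 0 && amp_hr == 0 && amp_map == 0) return(record)

  map <- record$map; hr <- record$hr
  base_lo <- max(1L, onset - precursor_lead - 60L) ; base_hi <- onset - precursor_lead
  baseline <- mean(map[base_lo:max(base_lo, base_hi)], na.rm = TRUE)

  touched <- integer(0)
  if (precursor_lead > 0L && (amp_hr != 0 || amp_map != 0)) {
    pre <- (onset - precursor_lead + 1L):onset          # 1-based indices
    q <- seq_along(pre) / precursor_lead                # 0 -> 1 progression
    hr[pre] <- hr[pre] + amp_hr * q
    map[pre] <- map[pre] - amp_map * q
    touched <- c(touched, pre)
  }
  if (depth_fraction > 0) {
    ev <- (onset + 1L):(onset + duration)
    i <- seq_along(ev) - 1L
    # sigmoid descent centred on the onset sample: the continuous curve
    # spans ~2-3 min but the plateau is reached by the second sample, so
    # the trailing 5-min average registers the drop ~5 min after onset
    win <- stats::plogis(i / 0.35)
    rec_len <- min(5L, n - (onset + duration))
    drift <- if (precursor_lead > 0L) amp_map else 0    # continue the drift
    map[ev] <- (map[ev] - drift) * (1 - depth_fraction * win)
    touched <- c(touched, ev)
    if (rec_len > 0L) {                                 # sigmoid recovery
      po <- (onset + duration + 1L):(onset + duration + rec_len)
      j <- seq_along(po) - 1L
      wrec <- 1 - stats::plogis(j / 0.35)
      map[po] <- map[po] * (1 - depth_fraction * wrec)
      touched <- c(touched, po)
    }
  }
  map[touched] <- pmax(map[touched], map_floor)
  vitals_record(map, hr, record$spo2, record$patient_id)
}

#' Replace samples with missing values completely at random
#'
#' Each sample of each channel is independently replaced by `NA` with
#' probability `missing_rate`.
#'
#' @param record A [vitals_record()].
#' @param missing_rate Probability in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the same pattern.
#' @return The degraded `vitals_record`.
#' @export
inject_missingness <- function(record, missing_rate, seed = 1L) {
  stopifnot(inherits(record, "vitals_record"))
  stopifnot_prob(missing_rate, "missing_rate")
  if (missing_rate == 0) return(record)
  with_seed(seed, {
    n <- record$length
    map <- record$map; hr <- record$hr; spo2 <- record$spo2
    map[stats::runif(n) < missing_rate] <- NA_real_
    hr[stats::runif(n) < missing_rate] <- NA_real_
    spo2[stats::runif(n) < missing_rate] <- NA_real_
    vitals_record(map, hr, spo2, record$patient_id)
  })
}

# Isolated out-of-physiological-range spikes (monitor artifacts).
inject_artifacts <- function(record, artifact_rate) {
  if (artifact_rate == 0) {
    return(list(record = record,
                artifacts = data.frame(channel = character(0),
                                       index = integer(0))))
  }
  n <- record$length
  spike_vals <- list(map = c(0, 250), hr = c(0, 300), spo2 = c(0, 20))
  chans <- list(map = record$map, hr = record$hr, spo2 = record$spo2)
  art_chan <- character(0); art_idx <- integer(0)
  for (ch in names(chans)) {
    hit <- which(stats::runif(n) < artifact_rate)
    if (length(hit)) {
      chans[[ch]][hit] <- resample(spike_vals[[ch]], length(hit),
                                   replace = TRUE)
      art_chan <- c(art_chan, rep(ch, length(hit)))
      art_idx <- c(art_idx, hit - 1L)
    }
  }
  list(record = vitals_record(chans$map, chans$hr, chans$spo2,
                              record$patient_id),
       artifacts = data.frame(channel = art_chan, index = art_idx,
                              stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws `n_patients` records under a [cohort_config()]: per-patient
#' baselines uniform in the configured ranges, AR(1) within-patient noise,
#' a planted episode (with precursor) in a `ahe_prevalence` fraction of
#' records, then artifact spikes and missingness.  Episode onsets are placed
#' uniformly at least 2 h into the record and at least an hour before its
#' end, so every planted event has full moving-average history and room for
#' observation windows.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ahe_cohort`: list with `records` (list of
#'   [vitals_record()]), `events` (ground-truth log: `patient_id`, `onset`,
#'   `duration`, `depth`, `precursor_lead`), `artifacts` (planted spike
#'   positions) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 4, seed = 7))
#' coh$events
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    records <- vector("list", config$n_patients)
    ev_rows <- list(); art_rows <- list()
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", i)
      len <- resample(config$record_length_range[1]:config$record_length_range[2], 1L)
      b_map <- stats::runif(1, config$baseline_map_mean_range[1],
                            config$baseline_map_mean_range[2])
      b_hr <- stats::runif(1, config$baseline_hr_mean_range[1],
                           config$baseline_hr_mean_range[2])
      b_spo2 <- stats::runif(1, config$baseline_spo2_mean_range[1],
                             config$baseline_spo2_mean_range[2])
      rec <- vitals_record(
        b_map + ar1_noise(len, config$noise_sd[["map"]]),
        b_hr + ar1_noise(len, config$noise_sd[["hr"]]),
        pmin(100, b_spo2 + ar1_noise(len, config$noise_sd[["spo2"]])),
        pid
      )
      if (stats::runif(1) < config$ahe_prevalence) {
        dur <- resample(config$event_duration_range[1]:config$event_duration_range[2], 1L)
        lo <- max(120L, config$precursor_lead)
        hi <- len - dur - 60L
        if (hi >= lo) {
          onset <- resample(lo:hi, 1L)
          rec <- inject_ahe(rec, onset,
                            depth_fraction = config$event_depth_fraction,
                            duration = dur,
                            precursor_lead = config$precursor_lead,
                            precursor_amplitude = config$precursor_amplitude)
          ev_rows[[length(ev_rows) + 1L]] <-
            data.frame(patient_id = pid, onset = onset, duration = dur,
                       depth = config$event_depth_fraction,
                       precursor_lead = config$precursor_lead,
                       stringsAsFactors = FALSE)
        }
      }
      art <- inject_artifacts(rec, config$artifact_rate)
      rec <- art$record
      if (nrow(art$artifacts)) {
        art$artifacts$patient_id <- pid
        art_rows[[length(art_rows) + 1L]] <- art$artifacts
      }
      if (config$missing_rate > 0) {
        rec <- inject_missingness(rec, config$missing_rate,
                                  seed = derive_seed(config$seed, i))
      }
      records[[i]] <- rec
    }
    structure(list(
      records = records,
      events = if (length(ev_rows)) do.call(rbind, ev_rows) else
        data.frame(patient_id = character(0), onset = integer(0),
                   duration = integer(0), depth = numeric(0),
                   precursor_lead = integer(0)),
      artifacts = if (length(art_rows)) do.call(rbind, art_rows) else
        data.frame(channel = character(0), index = integer(0),
                   patient_id = character(0)),
      config = config
    ), class = "ahe_cohort")
  })
}

#' @export
print.ahe_cohort <- function(x, ...) {
  cat(sprintf("<ahe_cohort> %d patients, %d planted episodes (seed %d)\n",
              length(x$records), nrow(x$events), x$config$seed))
  invisible(x)
}

#' Annotate every record of a cohort
#'
#' Convenience wrapper running [annotate_record()] across a cohort and
#' row-binding the episode tables.
#'
#' @param cohort An `ahe_cohort` (or plain list of records).
#' @param config An [annotation_config()].
#' @return Data frame of episodes across patients.
#' @export
annotate_cohort <- function(cohort, config = annotation_config()) {
  recs <- if (inherits(cohort, "ahe_cohort")) cohort$records else cohort
  do.call(rbind, lapply(recs, annotate_record, config = config))
}

#' Write a cohort to disk as per-patient CSVs plus a JSON manifest
#'
#' @param cohort An `ahe_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$records, function(r) {
    p <- file.path(dir, paste0(r$patient_id, ".csv"))
    write_vitals(r, p)
    p
  }, character(1))
  manifest <- list(
    patients = vapply(cohort$records, `[[`, character(1), "patient_id"),
    files = basename(paths),
    events = cohort$events,
    seed = cohort$config$seed
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(mpath)
}
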