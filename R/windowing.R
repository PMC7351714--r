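#' Studied observation-window and gap-length grid
#'
#' Both the observation length (data seen by the model) and the gap length
#' (lead time between window end and episode onset) span 10 to 60 minutes in
#' 10-minute increments.
#' @return Integer vector `c(10, 20, 30, 40, 50, 60)`.
#' @export
studied_grid <- function() seq(10L, 60L, by = 10L)

check_grid <- function(x, name, grid) {
  if (!x %in% grid) {
    stop(sprintf("`%s` = %d is not in the studied grid (%s)", name, x,
                 paste(grid, collapse = ", ")), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Event intervals as [onset, end) with open events running to record end.
event_intervals <- function(events, record_length) {
  if (is.null(events) || nrow(events) == 0L) {
    return(cbind(onset = integer(0), end = integer(0)))
  }
  end <- ifelse(is.na(events$end), record_length, events$end)
  cbind(onset = events$onset, end = end)[order(events$onset), , drop = FALSE]
}

#' Extract positive observation windows for one record
#'
#' For each annotated episode with onset `o`, the positive window occupies
#' `[o - gap_length - obs_length, o - gap_length)` (0-based, half-open): it
#' ends exactly `gap_length` minutes before onset.  One window is emitted
#' per episode, and only when it lies fully inside the record and — when a
#' prior episode exists — starts at least 120 minutes after that episode's
#' end, enforcing independence between successive positives.
#'
#' @param record A [vitals_record()].
#' @param events Episode table from [annotate_record()] on the same record.
#' @param obs_length,gap_length Minutes; must belong to `grid`.
#' @param grid Allowed lengths (default [studied_grid()]).
#' @param min_event_separation Required minutes from a prior episode's end
#'   to the next positive window's start (default 120).
#' @return Data frame: `patient_id`, `start`, `obs`, `gap`, `label` (1),
#'   `event_onset`.
#' @export
extract_positive_windows <- function(record, events, obs_length, gap_length,
                                     grid = studied_grid(),
                                     min_event_separation = 120L) {
  obs_length <- check_grid(obs_length, "obs_length", grid)
  gap_length <- check_grid(gap_length, "gap_length", grid)
  empty <- data.frame(patient_id = character(0), start = integer(0),
                      obs = integer(0), gap = integer(0), label = integer(0),
                      event_onset = integer(0), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0L) return(empty)
  ev <- events[order(events$onset), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ev))) {
    o <- ev$onset[i]
    start <- o - gap_length - obs_length
    if (start < 0L) next
    if (i > 1L) {
      prior_end <- ev$end[i - 1L]
      if (is.na(prior_end)) next                       # prior episode open
      if (start < prior_end + min_event_separation) next
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = record$patient_id, start = as.integer(start),
      obs = obs_length, gap = gap_length, label = 1L,
      event_onset = as.integer(o), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Extract negative observation windows for one record
#'
#' Emits non-overlapping windows `[s, s + obs_length)` such that no
#' annotated episode intersects the guarded region
#' `[s - 120, s + obs_length + 120)`: no episode within two hours before
#' the window or after its end.  Packing is greedy left-to-right — after a
#' placement the scan advances by `obs_length`, otherwise by one minute —
#' which is deterministic and maximal for the fixed stride.  The guard
#' constrains episodes only: near the record edges the out-of-record part
#' of the margin is vacuously episode-free (set `strict_margin = TRUE` to
#' require the full margin inside the record instead).  Records with no
#' episodes at all still yield negatives.
#'
#' @inheritParams extract_positive_windows
#' @param margin Guard half-width in minutes (default 120).
#' @param strict_margin Require the whole guard region inside the record.
#' @return Data frame like [extract_positive_windows()] with `label = 0`
#'   and `event_onset = NA`.
#' @export
extract_negative_windows <- function(record, events, obs_length,
                                     grid = studied_grid(), margin = 120L,
                                     strict_margin = FALSE) {
  obs_length <- check_grid(obs_length, "obs_length", grid)
  n <- record$length
  iv <- event_intervals(events, n)
  starts <- integer(0)
  s <- 0L
  while (s + obs_length <= n) {
    g_lo <- s - margin
    g_hi <- s + obs_length + margin
    ok <- !(strict_margin && (g_lo < 0L || g_hi > n))
    if (ok && nrow(iv)) {
      ok <- !any(iv[, "onset"] < g_hi & iv[, "end"] > g_lo)
    }
    if (ok) {
      starts <- c(starts, s)
      s <- s + obs_length
    } else {
      s <- s + 1L
    }
  }
  data.frame(patient_id = rep(record$patient_id, length(starts)),
             start = starts, obs = rep(obs_length, length(starts)),
             gap = rep(NA_integer_, length(starts)),
             label = rep(0L, length(starts)),
             event_onset = rep(NA_integer_, length(starts)),
             stringsAsFactors = FALSE)
}

#' Quality filter: reject windows with too many erroneous samples
#'
#' Erroneous samples are those missing or outside normal physiological
#' ranges, counted jointly over all channels of the raw (pre-imputation)
#' window.  A window is rejected when the erroneous fraction strictly
#' exceeds `max_erroneous_fraction` (more than 10% by default).
#'
#' @param window Numeric matrix `[timesteps x 3]` (`map`, `hr`, `spo2`),
#'   `NA` for missing.
#' @param max_erroneous_fraction Rejection threshold (default 0.10).
#' @param ranges A [physiological_ranges()].
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
quality_filter <- function(window, max_erroneous_fraction = 0.10,
                           ranges = physiological_ranges()) {
  bad <- erroneous_mask(window, ranges)
  mean(bad) <= max_erroneous_fraction
}

# TRUE where a sample is missing or out of physiological range.
erroneous_mask <- function(window, ranges = physiological_ranges()) {
  lo <- c(ranges$map[1], ranges$hr[1], ranges$spo2[1])
  hi <- c(ranges$map[2], ranges$hr[2], ranges$spo2[2])
  bad <- is.na(window)
  for (j in 1:3) {
    bad[, j] <- bad[, j] | (!is.na(window[, j]) &
                            (window[, j] < lo[j] | window[, j] > hi[j]))
  }
  bad
}

#' Build a labeled window dataset from an annotated cohort
#'
#' Runs positive and negative extraction over every record, applies the
#' quality filter, and materialises the model-ready representations:
#' imputed + normalised features for the dense-input models, and the raw
#' (unfilled, normalised) values with observation mask and per-channel
#' time-since-last-observation for the decay model.  Windows whose raw MAP,
#' HR or SpO2 channel is entirely erroneous are dropped (imputation is
#' impossible within the window).
#'
#' @param cohort An `ahe_cohort` or list of [vitals_record()]s.
#' @param events Episode table across patients (e.g. [annotate_cohort()]);
#'   `NULL` annotates the cohort with default settings.
#' @param obs_length,gap_length Window geometry in minutes.
#' @param grid Allowed lengths (default [studied_grid()]).
#' @param phys_ranges A [physiological_ranges()] for erroneous-value
#'   detection.
#' @param norm_ranges A [normalization_ranges()] for the `[0, 1]` scaling.
#' @param max_erroneous_fraction Quality-filter threshold.
#' @return An object of class `ahe_dataset`: list with arrays
#'   `x` (`n x obs x 3`, imputed + normalised), `x_raw` (normalised, `NA`
#'   at unobserved), `mask`, `delta` (minutes since last observation),
#'   `summary_features` (`n x 3` per-window channel means in raw units),
#'   vectors `label`, `patient_id`, `start`, and scalars `obs`, `gap`,
#'   plus filtering counts in `dropped`.
#' @export
build_dataset <- function(cohort, events = NULL, obs_length, gap_length,
                          grid = studied_grid(),
                          phys_ranges = physiological_ranges(),
                          norm_ranges = normalization_ranges(),
                          max_erroneous_fraction = 0.10) {
  recs <- if (inherits(cohort, "ahe_cohort")) cohort$records else cohort
  if (length(recs) == 0L) {
    warning("empty cohort: returning empty dataset")
  }
  if (is.null(events)) events <- annotate_cohort(recs)
  obs_length <- check_grid(obs_length, "obs_length", grid)
  gap_length <- check_grid(gap_length, "gap_length", grid)

  meta <- list(); n_rej_quality <- 0L; n_rej_channel <- 0L
  xs <- list(); raws <- list(); masks <- list(); deltas <- list()
  sfs <- list()
  for (rec in recs) {
    ev <- events[events$patient_id == rec$patient_id, , drop = FALSE]
    wins <- rbind(
      extract_positive_windows(rec, ev, obs_length, gap_length, grid = grid),
      extract_negative_windows(rec, ev, obs_length, grid = grid)
    )
    if (nrow(wins) == 0L) next
    for (k in seq_len(nrow(wins))) {
      s <- wins$start[k]
      raw <- record_matrix(rec, from = s, to = s + obs_length)
      bad <- erroneous_mask(raw, phys_ranges)
      if (mean(bad) > max_erroneous_fraction) {
        n_rej_quality <- n_rej_quality + 1L
        next
      }
      clean <- raw
      clean[bad] <- NA_real_                     # out-of-range -> missing
      if (any(colSums(!is.na(clean)) == 0L)) {
        n_rej_channel <- n_rej_channel + 1L
        next
      }
      filled <- normalize_window(impute_window(clean), norm_ranges)
      raw_norm <- normalize_window(clean, norm_ranges)
      dec <- prepare_decay_inputs(raw_norm)
      meta[[length(meta) + 1L]] <- wins[k, , drop = FALSE]
      xs[[length(xs) + 1L]] <- filled
      raws[[length(raws) + 1L]] <- raw_norm
      masks[[length(masks) + 1L]] <- dec$mask
      deltas[[length(deltas) + 1L]] <- dec$time_delta
      sfs[[length(sfs) + 1L]] <- colMeans(clean, na.rm = TRUE)
    }
  }
  n <- length(xs)
  dims <- c(n, obs_length, 3L)
  to_array <- function(lst) {
    a <- array(NA_real_, dims)
    for (i in seq_len(n)) a[i, , ] <- lst[[i]]
    a
  }
  md <- if (n) do.call(rbind, meta) else
    data.frame(patient_id = character(0), start = integer(0),
               obs = integer(0), gap = integer(0), label = integer(0),
               event_onset = integer(0))
  structure(list(
    x = to_array(xs), x_raw = to_array(raws), mask = to_array(masks),
    delta = to_array(deltas),
    summary_features = if (n) do.call(rbind, sfs) else
      matrix(numeric(0), 0, 3, dimnames = list(NULL, c("map", "hr", "spo2"))),
    label = md$label, patient_id = md$patient_id, start = md$start,
    event_onset = md$event_onset,
    obs = obs_length, gap = gap_length,
    norm_ranges = norm_ranges,
    dropped = c(quality = n_rej_quality, empty_channel = n_rej_channel)
  ), class = "ahe_dataset")
}

#' @export
print.ahe_dataset <- function(x, ...) {
  cat(sprintf(
    "<ahe_dataset> %d windows (%d positive / %d negative), obs %d min, gap %d min\n",
    length(x$label), sum(x$label == 1L), sum(x$label == 0L), x$obs, x$gap))
  if (any(x$dropped > 0)) {
    cat(sprintf("  dropped: %d quality-filtered, %d empty-channel\n",
                x$dropped[["quality"]], x$dropped[["empty_channel"]]))
  }
  invisible(x)
}

#' Subset an `ahe_dataset` by window index or patient ids
#'
#' @param data An `ahe_dataset`.
#' @param i Integer window indices, or a character vector of patient ids.
#' @return The subsetted `ahe_dataset`.
#' @export
dataset_subset <- function(data, i) {
  if (is.character(i)) i <- which(data$patient_id %in% i)
  out <- data
  for (f in c("x", "x_raw", "mask", "delta")) {
    out[[f]] <- data[[f]][i, , , drop = FALSE]
  }
  out$summary_features <- data$summary_features[i, , drop = FALSE]
  for (f in c("label", "patient_id", "start", "event_onset")) {
    out[[f]] <- data[[f]][i]
  }
  out
}

n_windows <- function(data) length(data$label)
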