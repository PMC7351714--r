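#' Annotation configuration for the patient-specific AHE definition
#'
#' The relative definition flags an acute hypotensive episode (AHE) when the
#' trailing 5-minute moving average of MAP falls 20% or more below the
#' trailing 60-minute moving average.  A detection is only valid when every
#' MAP sample in the 10 minutes after it is observed (non-missing) and above
#' 20 mmHg, which guards against sensor drop-offs; the same 10-minute
#' horizon is the definitional minimum episode duration.
#'
#' @param long_ma_width Long moving-average width in minutes (default 60).
#' @param short_ma_width Short moving-average width in minutes (default 5).
#' @param drop_threshold Relative drop defining an episode (default 0.20).
#' @param validity_horizon Post-detection check horizon, minutes (default 10).
#' @param validity_floor MAP floor (mmHg) the horizon must stay above
#'   (default 20).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(long_ma_width = 60L, short_ma_width = 5L,
                              drop_threshold = 0.20, validity_horizon = 10L,
                              validity_floor = 20) {
  if (!(long_ma_width > short_ma_width && short_ma_width > 0)) {
    stop("need long_ma_width > short_ma_width > 0", call. = FALSE)
  }
  if (!(drop_threshold > 0 && drop_threshold < 1)) {
    stop("drop_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(long_ma_width = as.integer(long_ma_width),
                 short_ma_width = as.integer(short_ma_width),
                 drop_threshold = drop_threshold,
                 validity_horizon = as.integer(validity_horizon),
                 validity_floor = validity_floor),
            class = "annotation_config")
}

#' Trailing moving average with missing-value exclusion
#'
#' Right-aligned (causal) moving mean: the value at index `t` averages the
#' most recent `width` samples ending at `t`.  Indices with fewer than
#' `width` prior samples yield `NA`, as do windows whose samples are all
#' missing; partially missing windows average the available values.
#'
#' @param x Numeric vector, `NA` for missing.
#' @param width Window width in samples (minutes), `>= 1`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 5)
#' @export
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1", call. = FALSE)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  obs <- !is.na(x)
  xz <- ifelse(obs, x, 0)
  csum <- cumsum(xz)
  ccnt <- cumsum(as.numeric(obs))
  out <- rep(NA_real_, n)
  if (n >= width) {
    idx <- width:n
    s <- csum[idx] - c(0, csum)[idx - width + 1L]
    k <- ccnt[idx] - c(0, ccnt)[idx - width + 1L]
    out[idx] <- ifelse(k > 0, s / k, NA_real_)
  }
  out
}

#' Annotate patient-specific acute hypotensive episodes
#'
#' Scans a record sequentially for onsets where the short trailing MAP
#' moving average has dropped by at least `drop_threshold` relative to the
#' long one (`short_MA <= (1 - drop_threshold) * long_MA`, ties included;
#' both averages evaluated at the same index).  A candidate is confirmed
#' only if every MAP sample in the `validity_horizon` minutes after the
#' detection is non-missing and above `validity_floor`.  The episode ends at
#' the first later index where the moving-average gap closes below the
#' threshold; an episode still open at the end of the record has `end = NA`.
#' Closed episodes shorter than the validity horizon are discarded entirely,
#' so the minimum emitted duration equals [minimum_event_duration()].
#' Events never overlap; scanning resumes at an event's end.
#'
#' @param record A [vitals_record()].
#' @param config An [annotation_config()].
#' @return A data frame with one row per episode: `patient_id`,
#'   `onset` and `end` (0-based minute indices, `[onset, end)`, `end = NA`
#'   when open), `drop_fraction` (relative MA drop at onset) and
#'   `definition = "patient_specific"`.  Records too short to evaluate
#'   (`< long_ma_width + validity_horizon`) yield zero rows with a warning.
#' @examples
#' rec <- vitals_record(c(rep(100, 120), rep(70, 80)),
#'                      rep(75, 200), rep(97, 200), "p1")
#' annotate_record(rec)
#' @export
annotate_record <- function(record, config = annotation_config()) {
  stopifnot(inherits(record, "vitals_record"))
  empty <- data.frame(patient_id = character(0), onset = integer(0),
                      end = integer(0), drop_fraction = numeric(0),
                      definition = character(0), stringsAsFactors = FALSE)
  n <- record$length
  if (n < config$long_ma_width + config$validity_horizon) {
    warning(sprintf("record %s shorter than %d min: no annotation attempted",
                    record$patient_id,
                    config$long_ma_width + config$validity_horizon))
    return(empty)
  }
  map <- record$map
  sma <- moving_average(map, config$short_ma_width)
  lma <- moving_average(map, config$long_ma_width)
  keep <- 1 - config$drop_threshold
  H <- config$validity_horizon
  floor_ <- config$validity_floor

  onsets <- integer(0); ends <- integer(0); drops <- numeric(0)
  t <- 1L
  while (t <= n) {
    if (!is.na(sma[t]) && !is.na(lma[t]) && sma[t] <= keep * lma[t]) {
      # candidate detection at t (1-based); validity over (t, t + H]
      hi <- t + H
      if (hi > n) { t <- t + 1L; next }  # horizon not observable: reject
      seg <- map[(t + 1L):hi]
      if (all(!is.na(seg) & seg > floor_)) {
        # end = first later index where the MA gap has re-closed; an index
        # where either MA is undefined cannot close the episode
        e <- NA_integer_
        for (u in (t + 1L):n) {
          if (!is.na(sma[u]) && !is.na(lma[u]) && sma[u] > keep * lma[u]) {
            e <- u; break
          }
        }
        if (is.na(e)) {            # open episode: record consumed
          onsets <- c(onsets, t); ends <- c(ends, NA_integer_)
          drops <- c(drops, 1 - sma[t] / lma[t])
          break
        }
        if (e - t >= H) {          # meets the definitional minimum duration
          onsets <- c(onsets, t); ends <- c(ends, e)
          drops <- c(drops, 1 - sma[t] / lma[t])
        }
        t <- e                     # resume after the episode interval
      } else {
        t <- t + 1L                # validity rejection: move on
      }
    } else {
      t <- t + 1L
    }
  }
  if (length(onsets) == 0L) return(empty)
  data.frame(patient_id = record$patient_id,
             onset = onsets - 1L, end = ends - 1L,
             drop_fraction = drops, definition = "patient_specific",
             stringsAsFactors = FALSE)
}

#' Annotate episodes under the conventional fixed-threshold definition
#'
#' The conventional definition flags a period of at least `window` minutes
#' in which at least `fraction` of the non-missing MAP readings lie below
#' `threshold` mmHg.  Qualifying 30-minute windows are merged into maximal
#' intervals.  Provided for comparison with the relative definition; a
#' patient whose baseline drops 25% but stays above the threshold is
#' invisible to this rule.
#'
#' @param record A [vitals_record()].
#' @param window Minimum episode duration in minutes (default 30).
#' @param fraction Required fraction of sub-threshold readings (default 0.9).
#' @param threshold MAP threshold in mmHg (default 60).
#' @return A data frame in the same layout as [annotate_record()], with
#'   `definition = "conventional_physionet"`.
#' @export
annotate_conventional <- function(record, window = 30L, fraction = 0.9,
                                  threshold = 60) {
  stopifnot(inherits(record, "vitals_record"))
  window <- as.integer(window)
  n <- record$length
  empty <- data.frame(patient_id = character(0), onset = integer(0),
                      end = integer(0), drop_fraction = numeric(0),
                      definition = character(0), stringsAsFactors = FALSE)
  if (n < window) return(empty)
  map <- record$map
  below <- !is.na(map) & map < threshold
  avail <- !is.na(map)
  cb <- cumsum(as.numeric(below)); ca <- cumsum(as.numeric(avail))
  starts <- 1:(n - window + 1L)
  nb <- cb[starts + window - 1L] - c(0, cb)[starts]
  na_ <- ca[starts + window - 1L] - c(0, ca)[starts]
  ok <- na_ > 0 & nb >= fraction * na_
  if (!any(ok)) return(empty)
  # union of qualifying windows, merged into maximal intervals
  covered <- rep(FALSE, n)
  for (s in starts[ok]) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  on <- lo[r$values]; off <- hi[r$values]
  data.frame(patient_id = record$patient_id,
             onset = on - 1L, end = off,  # half-open [onset, end)
             drop_fraction = NA_real_,
             definition = "conventional_physionet",
             stringsAsFactors = FALSE)
}

#' Minimum episode duration implied by the annotation rules
#'
#' The post-detection validity horizon doubles as the definitional lower
#' bound on episode duration: the annotator never emits a closed episode
#' shorter than this.
#'
#' @param config An [annotation_config()].
#' @return Minutes (integer).
#' @export
minimum_event_duration <- function(config = annotation_config()) {
  config$validity_horizon
}

#' Write an event table to CSV
#'
#' @param events Data frame from [annotate_record()] /
#'   [annotate_conventional()] (possibly row-bound across patients).
#' @param path Output file path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    events[, c("patient_id", "onset", "end", "definition")],
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}
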