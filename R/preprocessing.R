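#' Physiological plausibility ranges
#'
#' Samples outside these per-channel bounds are treated as erroneous
#' (monitor artifacts) and removed before imputation.  Defaults coincide
#' with the static normalisation ranges — the only ranges the analysis
#' pins down numerically — and are configurable.
#'
#' @param map,hr,spo2 Length-2 `c(low, high)` per channel.
#' @return A list of class `physiological_ranges`.
#' @export
physiological_ranges <- function(map = c(40, 160), hr = c(40, 160),
                                 spo2 = c(60, 100)) {
  for (r in list(map, hr, spo2)) {
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("each range must be c(low, high) with low < high", call. = FALSE)
    }
  }
  structure(list(map = map, hr = hr, spo2 = spo2),
            class = "physiological_ranges")
}

#' Static normalisation ranges
#'
#' Features are scaled to `[0, 1]` with fixed per-feature ranges: 40–160
#' for MAP and HR, 60–100 for SpO2.
#'
#' @inheritParams physiological_ranges
#' @return A list of class `normalization_ranges`.
#' @export
normalization_ranges <- function(map = c(40, 160), hr = c(40, 160),
                                 spo2 = c(60, 100)) {
  r <- physiological_ranges(map, hr, spo2)
  class(r) <- "normalization_ranges"
  r
}

#' Down-sample a higher-frequency series to per-minute means
#'
#' Each output minute is the mean of the available (non-missing) source
#' samples falling in that minute; a minute with no available samples is
#' missing.  Sample `i` (0-based) is assumed to occur at time `i /
#' source_rate` seconds.
#'
#' @param series Numeric vector at `source_rate` Hz, `NA` for missing.
#' @param source_rate Sampling rate in Hz (`>= 1/60`).
#' @return Per-minute numeric vector.
#' @examples
#' resample_to_per_minute(rep(90, 120), source_rate = 0.5)  # 60 minutes
#' @export
resample_to_per_minute <- function(series, source_rate) {
  if (source_rate < 1 / 60) stop("source_rate must be >= 1/60 Hz", call. = FALSE)
  idx <- seq_along(series) - 1L
  minute <- floor(idx / (source_rate * 60))
  out <- tapply(series, minute, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  as.numeric(out)
}

#' Remove non-physiological samples from a window
#'
#' Samples outside the physiological ranges are set to missing; the number
#' of replacements feeds the quality filter.
#'
#' @param window Matrix `[timesteps x 3]` (`map`, `hr`, `spo2`).
#' @param ranges A [physiological_ranges()].
#' @return The window with offending samples `NA`; attribute
#'   `"n_replaced"` counts the replacements.
#' @export
remove_nonphysiological <- function(window, ranges = physiological_ranges()) {
  bad <- erroneous_mask(window, ranges) & !is.na(window)
  window[bad] <- NA_real_
  attr(window, "n_replaced") <- sum(bad)
  window
}

#' Impute missing values within a window (backfill, then forward-fill)
#'
#' Missing values take the next observed value in the window (backfilling);
#' any trailing missing run left over takes the last observed value
#' (forward-filling).  No value outside the window is ever used, so no
#' information leaks across window boundaries.
#'
#' @param window Numeric vector or `[timesteps x channels]` matrix.
#' @return Same shape with no missing values.
#' @examples
#' impute_window(c(NA, 5, NA, 7))   # 5 5 7 7
#' impute_window(c(3, NA, NA))      # 3 3 3
#' @export
impute_window <- function(window) {
  fill1 <- function(v) {
    if (!anyNA(v)) return(v)
    obs <- which(!is.na(v))
    if (length(obs) == 0L) {
      stop("cannot impute a fully-missing channel", call. = FALSE)
    }
    n <- length(v)
    out <- v
    nxt <- 0L                 # index of the next observed value to the right
    for (t in n:1) {
      if (!is.na(v[t])) nxt <- t else if (nxt > 0L) out[t] <- v[nxt]
    }
    last <- max(obs)          # forward-fill the trailing remainder
    if (last < n) out[(last + 1L):n] <- v[last]
    out
  }
  if (is.matrix(window)) {
    apply(window, 2L, fill1)
  } else {
    fill1(window)
  }
}

#' Scale a window to `[0, 1]` with static per-feature ranges
#'
#' `x' = (x - low) / (high - low)` per channel, clipped to `[0, 1]`.
#' Clipping only matters when the physiological and normalisation ranges
#' are configured to differ; under the defaults they coincide.
#'
#' @param window Matrix `[timesteps x 3]` (`map`, `hr`, `spo2`).
#' @param ranges A [normalization_ranges()].
#' @return The normalised window (missing values pass through as `NA`).
#' @export
normalize_window <- function(window, ranges = normalization_ranges()) {
  lo <- c(ranges$map[1], ranges$hr[1], ranges$spo2[1])
  hi <- c(ranges$map[2], ranges$hr[2], ranges$spo2[2])
  out <- window
  for (j in 1:3) {
    out[, j] <- pmin(1, pmax(0, (window[, j] - lo[j]) / (hi[j] - lo[j])))
  }
  out
}

#' @rdname normalize_window
#' @export
denormalize_window <- function(window, ranges = normalization_ranges()) {
  lo <- c(ranges$map[1], ranges$hr[1], ranges$spo2[1])
  hi <- c(ranges$map[2], ranges$hr[2], ranges$spo2[2])
  out <- window
  for (j in 1:3) out[, j] <- window[, j] * (hi[j] - lo[j]) + lo[j]
  out
}

#' Prepare the triple inputs for the decay (missing-data-tolerant) model
#'
#' From a raw, unfilled window the decay model receives three aligned
#' pieces: the values (with a fill at unobserved positions — by default the
#' within-window channel mean; at fit time the training-set channel mean is
#' substituted), a binary observation mask, and per-channel time deltas
#' `delta[t]` = minutes since the last observed sample: `delta[1] = 0` and
#' `delta[t] = 1` after an observed step, accumulating `+1` across
#' consecutive unobserved steps.
#'
#' @param window Raw (unfilled) matrix `[timesteps x 3]`, `NA` at
#'   unobserved positions.
#' @param fill Optional length-3 vector of per-channel fill values for
#'   unobserved positions (defaults to the within-window observed mean).
#' @return List with `values`, `mask`, `time_delta` (all
#'   `[timesteps x 3]`).
#' @examples
#' w <- matrix(c(1, NA, NA, 4), 4, 3)
#' prepare_decay_inputs(w)$time_delta[, 1]  # 0 1 2 3
#' @export
prepare_decay_inputs <- function(window, fill = NULL) {
  m <- (!is.na(window)) * 1
  tt <- nrow(window)
  delta <- matrix(0, tt, ncol(window))
  if (tt > 1L) {
    for (t in 2:tt) {
      delta[t, ] <- ifelse(m[t - 1L, ] == 1, 1, delta[t - 1L, ] + 1)
    }
  }
  vals <- window
  if (is.null(fill)) fill <- colMeans(window, na.rm = TRUE)
  for (j in seq_len(ncol(window))) {
    vals[is.na(vals[, j]), j] <- fill[j]
  }
  list(values = vals, mask = m, time_delta = delta)
}
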