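#' Construct a per-minute vital-signs record
#'
#' A `vitals_record` holds one patient's per-minute mean arterial pressure
#' (MAP, mmHg), heart rate (HR, bpm) and peripheral oxygen saturation
#' (SpO2, %) series.  Missing samples are `NA`.  The sampling period is
#' fixed at one minute; minute indices are 0-based throughout the package.
#'
#' @param map Numeric vector of MAP values (mmHg), `NA` for missing.
#' @param hr Numeric vector of heart-rate values (bpm), same length.
#' @param spo2 Numeric vector of SpO2 values (percent), same length.
#' @param patient_id Character scalar identifying the patient.
#'
#' @return An object of class `vitals_record`: a list with elements
#'   `patient_id`, `map`, `hr`, `spo2` and `length` (minutes).
#'
#' @details Records shorter than 120 minutes are refused: two hours of MAP
#'   history is the minimum for the relative episode definition to be
#'   evaluable (the long moving average spans one hour) and mirrors the
#'   usual cohort inclusion rule for this analysis.
#'
#' @examples
#' rec <- vitals_record(rep(90, 180), rep(75, 180), rep(97, 180), "p1")
#' rec
#' @export
vitals_record <- function(map, hr, spo2, patient_id = "patient") {
  map <- as.numeric(map); hr <- as.numeric(hr); spo2 <- as.numeric(spo2)
  n <- length(map)
  if (length(hr) != n || length(spo2) != n) {
    stop("map, hr and spo2 must have identical length", call. = FALSE)
  }
  if (n < 120L) {
    stop("a vitals record requires at least 120 minutes of data", call. = FALSE)
  }
  for (s in list(map, hr, spo2)) {
    if (any(!is.finite(s) & !is.na(s))) {
      stop("non-missing vital-sign values must be finite", call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         map = map, hr = hr, spo2 = spo2, length = n),
    class = "vitals_record"
  )
}

#' @export
print.vitals_record <- function(x, ...) {
  miss <- vapply(list(x$map, x$hr, x$spo2), function(s) mean(is.na(s)), 0)
  cat(sprintf("<vitals_record> patient %s: %d min", x$patient_id, x$length),
      sprintf("(missing: MAP %.1f%%, HR %.1f%%, SpO2 %.1f%%)\n",
              100 * miss[1], 100 * miss[2], 100 * miss[3]))
  invisible(x)
}

#' @export
length.vitals_record <- function(x) x$length

#' Read and write per-minute vitals files
#'
#' Vitals files are plain CSV with columns `minute,map,hr,spo2`; an empty
#' field encodes a missing sample.  One file holds one patient record.
#'
#' @param path File path.
#' @param record A [vitals_record()].
#' @param patient_id Patient id to attach on read; defaults to the file
#'   name without extension.
#' @return `read_vitals()` returns a `vitals_record`; `write_vitals()`
#'   returns `path` invisibly.
#' @export
read_vitals <- function(path, patient_id = NULL) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("minute", "map", "hr", "spo2") %in% names(df))) {
    stop("vitals file must have columns minute,map,hr,spo2", call. = FALSE)
  }
  df <- df[order(df$minute), ]
  vitals_record(df$map, df$hr, df$spo2,
                patient_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_vitals
#' @export
write_vitals <- function(record, path) {
  stopifnot(inherits(record, "vitals_record"))
  df <- data.frame(minute = seq_len(record$length) - 1L,
                   map = record$map, hr = record$hr, spo2 = record$spo2)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Internal: 3-column matrix view (timesteps x channels) of a record slice.
record_matrix <- function(record, from = 0L, to = record$length) {
  idx <- (from + 1L):to
  cbind(map = record$map[idx], hr = record$hr[idx], spo2 = record$spo2[idx])
}
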