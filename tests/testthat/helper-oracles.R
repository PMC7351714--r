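# Independent brute-force oracles.  These deliberately re-derive each
# quantity with plain loops and stats::mean / all-pairs counting, sharing no
# code with the package internals they check.

# Trailing moving average: recompute the mean of the last `width` samples
# from scratch at every index.
brute_ma <- function(x, width) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t < width) next
    w <- x[(t - width + 1):t]
    if (all(is.na(w))) next
    out[t] <- mean(w, na.rm = TRUE)
  }
  out
}

# Naive sequential annotator: at every index recompute both moving averages
# from scratch, then apply the detection / validity / end / minimum-duration
# rules as a plain state machine.
brute_annotate <- function(record, config = annotation_config()) {
  map <- record$map
  n <- length(map)
  keep <- 1 - config$drop_threshold
  H <- config$validity_horizon
  W_s <- config$short_ma_width; W_l <- config$long_ma_width
  ma_at <- function(t, width) {
    if (t < width) return(NA_real_)
    w <- map[(t - width + 1):t]
    if (all(is.na(w))) return(NA_real_)
    mean(w, na.rm = TRUE)
  }
  res <- list()
  t <- 1
  while (t <= n) {
    s <- ma_at(t, W_s); l <- ma_at(t, W_l)
    if (!is.na(s) && !is.na(l) && s <= keep * l) {
      if (t + H > n) { t <- t + 1; next }
      seg <- map[(t + 1):(t + H)]
      if (all(!is.na(seg) & seg > config$validity_floor)) {
        e <- NA
        for (u in (t + 1):n) {
          su <- ma_at(u, W_s); lu <- ma_at(u, W_l)
          if (!is.na(su) && !is.na(lu) && su > keep * lu) { e <- u; break }
        }
        if (is.na(e)) {
          res[[length(res) + 1]] <- c(onset = t - 1, end = NA)
          break
        }
        if (e - t >= H) res[[length(res) + 1]] <- c(onset = t - 1, end = e - 1)
        t <- e
      } else t <- t + 1
    } else t <- t + 1
  }
  if (!length(res)) {
    return(data.frame(onset = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, res))
}

# All-pairs concordance AUROC.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Reference single-layer GRU (standard gating, no decay, no mask input),
# written as an explicit per-unit loop over time.
reference_gru <- function(xt, W_r, U_r, b_r, W_z, U_z, b_z, W_h, U_h, b_h) {
  sig <- function(v) 1 / (1 + exp(-v))
  n <- nrow(xt[[1]]); H <- ncol(U_r)
  h <- matrix(0, n, H)
  hs <- vector("list", length(xt))
  for (t in seq_along(xt)) {
    x <- xt[[t]]
    r <- sig(x %*% W_r + h %*% U_r + matrix(b_r, n, H, byrow = TRUE))
    z <- sig(x %*% W_z + h %*% U_z + matrix(b_z, n, H, byrow = TRUE))
    hc <- tanh(x %*% W_h + (r * h) %*% U_h + matrix(b_h, n, H, byrow = TRUE))
    h <- (1 - z) * h + z * hc
    hs[[t]] <- h
  }
  hs
}

# Central finite-difference gradient of a scalar loss over a parameter list.
numeric_gradient <- function(loss_fn, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in seq_along(p)) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      pm <- params; pm[[nm]][i] <- p[i] - eps
      g[[nm]][i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
  }
  g
}

flat_record <- function(map_value = 100, n = 200, patient_id = "flat",
                        hr = 75, spo2 = 97) {
  vitals_record(rep(map_value, n), rep(hr, n), rep(spo2, n), patient_id)
}

# A minimal in-memory dataset for model-level tests: positives carry a
# downward MAP trend (and HR rise) over the window, negatives are flat.
make_toy_dataset <- function(n_per_class = 40, tt = 20, signal = 0.2,
                             noise = 0.03, seed = 1, miss = 0) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, c(n, tt, 3))
  y <- rep(c(1L, 0L), each = n_per_class)
  ramp <- seq(0, 1, length.out = tt)
  for (i in seq_len(n)) {
    base <- c(0.5, 0.5, 0.9)
    for (j in 1:3) x[i, , j] <- base[j] + rnorm(tt, 0, noise)
    if (y[i] == 1L) {
      x[i, , 1] <- x[i, , 1] - signal * ramp
      x[i, , 2] <- x[i, , 2] + signal * ramp
    }
  }
  x[] <- pmin(1, pmax(0, x))
  x_raw <- x
  if (miss > 0) x_raw[array(runif(length(x_raw)) < miss, dim(x_raw))] <- NA
  mask <- array(as.numeric(!is.na(x_raw)), dim(x_raw))
  delta <- array(0, dim(x_raw))
  for (i in seq_len(n)) for (j in 1:3) {
    d <- ahepredict::prepare_decay_inputs(
      matrix(x_raw[i, , ], tt, 3))$time_delta
    delta[i, , ] <- d
  }
  filled <- x_raw
  for (i in seq_len(n)) {
    filled[i, , ] <- ahepredict::impute_window(matrix(x_raw[i, , ], tt, 3))
  }
  sf <- t(apply(filled, 1, colMeans))
  colnames(sf) <- c("map", "hr", "spo2")
  structure(list(x = filled, x_raw = x_raw, mask = mask, delta = delta,
                 summary_features = sf, label = y,
                 patient_id = sprintf("T%03d", seq_len(n)),
                 start = rep(0L, n), event_onset = rep(NA_integer_, n),
                 obs = tt, gap = 10L,
                 norm_ranges = ahepredict::normalization_ranges(),
                 dropped = c(quality = 0L, empty_channel = 0L)),
            class = "ahe_dataset")
}
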