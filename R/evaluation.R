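#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive window outscores a
#' randomly chosen negative one, with ties counted one half — computed from
#' midranks, equivalent to the normalised concordant-pair count.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return Data frame of `(fpr, tpr, threshold)` sorted so both
#'   coordinates are non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  keep <- c(s[-length(s)] != s[-1L], TRUE)   # one point per distinct score
  data.frame(
    fpr = c(0, fp[keep] / max(1L, sum(y == 0L))),
    tpr = c(0, tp[keep] / max(1L, sum(y == 1L))),
    threshold = c(Inf, s[keep])
  )
}

#' Percentile bootstrap confidence interval for a discrimination metric
#'
#' Resamples windows with replacement (`n_boot` times), recomputes the
#' metric, and reports the percentile interval.  Resamples missing a class
#' are redrawn.  A cluster variant resampling whole patients is available
#' since windows within a patient are dependent.
#'
#' @inheritParams auroc
#' @param metric Function `(scores, labels) -> numeric` (default [auroc()]).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param cluster Optional vector of patient ids: resample patients rather
#'   than windows.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auroc, n_boot = 1000L,
                         alpha = 0.05, seed = 1L, cluster = NULL) {
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  labels <- as.integer(labels)
  n <- length(scores)
  with_seed(seed, {
    stat <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      for (attempt in 1:100) {
        if (is.null(cluster)) {
          idx <- sample.int(n, n, replace = TRUE)
        } else {
          ids <- unique(cluster)
          pick <- resample(ids, length(ids), replace = TRUE)
          idx <- unlist(lapply(pick, function(p) which(cluster == p)),
                        use.names = FALSE)
        }
        if (length(unique(labels[idx])) == 2L) break
        if (attempt == 100L) {
          stop("could not draw a two-class resample", call. = FALSE)
        }
      }
      stat[b] <- metric(scores[idx], labels[idx])
    }
    ci <- stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 7)
    c(lo = ci[1], hi = ci[2])
  })
}

#' Sensitivity, specificity and PPV at an operating threshold
#'
#' Standard 2x2-table metrics with predictions `score >= threshold`.  When
#' no window is predicted positive the PPV is undefined and reported as
#' `NA` rather than zero.
#'
#' @inheritParams auroc
#' @param threshold Operating threshold (default 0.5).
#' @return List with `sensitivity`, `specificity`, `ppv` and the table
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Per-patient classification rates
#'
#' The fraction of each patient's windows correctly classified at the
#' operating threshold, with summary counts of patients at or above the
#' given rate cutoffs (0.85 and 0.90 by default).
#'
#' @inheritParams confusion_metrics
#' @param patient_ids Patient id per window.
#' @param cutoffs Rate cutoffs for the summary counts.
#' @return List with `rates` (named per patient) and `n_at_cutoff` (named
#'   count of patients with rate >= each cutoff).
#' @export
per_patient_rates <- function(scores, labels, patient_ids, threshold = 0.5,
                              cutoffs = c(0.85, 0.90)) {
  labels <- as.integer(labels)
  correct <- as.integer(scores >= threshold) == labels
  rates <- tapply(correct, patient_ids, mean)
  n_at <- vapply(cutoffs, function(ct) sum(rates >= ct), 0L)
  list(rates = rates,
       n_at_cutoff = stats::setNames(n_at, sprintf("%.2f", cutoffs)))
}

#' Evaluate a fitted model on a test dataset
#'
#' Combines discrimination (AUROC with bootstrap 95% CI, ROC points),
#' threshold metrics and per-patient classification rates into one report.
#'
#' @param model An `ahe_model`.
#' @param data Test `ahe_dataset`.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @param threshold Operating threshold.
#' @param cluster_by_patient Resample patients instead of windows in the
#'   bootstrap.
#' @return An object of class `ahe_eval`.
#' @export
evaluate_model <- function(model, data, n_boot = 1000L, seed = 1L,
                           threshold = NULL, cluster_by_patient = FALSE) {
  threshold <- threshold %||% model$threshold %||% 0.5
  sc <- predict(model, data)
  y <- data$label
  cm <- confusion_metrics(sc, y, threshold)
  structure(list(
    model = model$model, obs = data$obs, gap = data$gap,
    auroc = auroc(sc, y),
    ci95 = bootstrap_ci(sc, y, n_boot = n_boot, seed = seed,
                        cluster = if (cluster_by_patient) data$patient_id),
    roc = roc_points(sc, y),
    threshold = threshold,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv,
    per_patient = per_patient_rates(sc, y, data$patient_id, threshold),
    n_pos = sum(y == 1L), n_neg = sum(y == 0L)
  ), class = "ahe_eval")
}

#' @export
print.ahe_eval <- function(x, ...) {
  cat(sprintf("<ahe_eval: %s> obs %d / gap %d min, %d pos / %d neg windows\n",
              x$model, x$obs, x$gap, x$n_pos, x$n_neg))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$auroc, x$ci95[["lo"]], x$ci95[["hi"]]))
  cat(sprintf("  at threshold %.2f: sensitivity %.3f, specificity %.3f, PPV %s\n",
              x$threshold, x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "undefined", sprintf("%.3f", x$ppv))))
  np <- x$per_patient$n_at_cutoff
  cat(sprintf("  patients at classification rate >= %s: %s\n",
              paste(names(np), collapse = "/"),
              paste(np, collapse = "/")))
  invisible(x)
}

#' @export
plot.ahe_eval <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2, col = "firebrick",
       xlab = "false positive rate", ylab = "true positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright",
                   sprintf("%s AUROC %.3f", x$model, x$auroc), bty = "n")
  invisible(x)
}

#' Heatmap of grid AUROC results
#'
#' @param results Data frame from [run_grid()] (one family).
#' @param family Family to plot when several are present.
#' @export
plot_grid_auroc <- function(results, family = results$family[1]) {
  res <- results[results$family == family, ]
  obs <- sort(unique(res$obs)); gap <- sort(unique(res$gap))
  m <- matrix(NA_real_, length(obs), length(gap),
              dimnames = list(obs, gap))
  for (i in seq_len(nrow(res))) {
    m[as.character(res$obs[i]), as.character(res$gap[i])] <- res$auroc[i]
  }
  graphics::image(seq_along(obs), seq_along(gap), m, axes = FALSE,
                  xlab = "observation length (min)", ylab = "gap length (min)",
                  main = sprintf("AUROC: %s", family),
                  col = grDevices::hcl.colors(25, "viridis"))
  graphics::axis(1, seq_along(obs), obs)
  graphics::axis(2, seq_along(gap), gap)
  for (i in seq_along(obs)) for (j in seq_along(gap)) {
    if (!is.na(m[i, j])) graphics::text(i, j, sprintf("%.2f", m[i, j]),
                                        col = "white", cex = 0.8)
  }
  invisible(m)
}
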