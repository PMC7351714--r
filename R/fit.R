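#' Model specifications
#'
#' `lstm_spec()` describes the stacked-LSTM classifier: two LSTM layers of
#' 60 units, dropout 0.4 between the recurrent output and the dense sigmoid
#' head, L2 penalty 1e-3 on all parameters, Adam with cosine-annealed
#' learning rate and warm restarts.  `grud_spec()` describes the
#' decay-gated recurrent classifier for unfilled inputs: a single layer of
#' 100 units with trainable input and hidden-state decay, dropout 0.3 and a
#' fixed learning rate of 1e-4; remaining hyperparameters match the LSTM.
#' Epoch count, batch size and restart period are not pinned by the
#' analysis design and default to standard values.
#'
#' @param units Recurrent units per layer.
#' @param layers Number of recurrent layers.
#' @param dropout Dropout rate before the dense head.
#' @param l2 L2 penalty applied to every parameter.
#' @param lr,lr_min Learning-rate bounds (for the LSTM, the cosine schedule
#'   anneals from `lr` to `lr_min`; the decay model uses `lr` fixed).
#' @param restart_period Warm-restart period in epochs (LSTM only).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @return A list of class `ahe_spec`.
#' @export
lstm_spec <- function(units = 60L, layers = 2L, dropout = 0.4, l2 = 1e-3,
                      lr = 1e-3, lr_min = 1e-5, restart_period = 10L,
                      epochs = 100L, batch_size = 64L) {
  structure(list(model = "lstm", units = as.integer(units),
                 layers = as.integer(layers), dropout = dropout, l2 = l2,
                 lr = lr, lr_min = lr_min,
                 restart_period = as.integer(restart_period),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "ahe_spec")
}

#' @rdname lstm_spec
#' @export
grud_spec <- function(units = 100L, dropout = 0.3, l2 = 1e-3, lr = 1e-4,
                      epochs = 100L, batch_size = 64L) {
  structure(list(model = "grud", units = as.integer(units), layers = 1L,
                 dropout = dropout, l2 = l2, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "ahe_spec")
}

#' Fit an AHE-forecasting classifier
#'
#' Single fitting front-end for the four model families studied: the
#' stacked LSTM (`"lstm"`, on imputed + normalised windows), the
#' decay-gated recurrent model (`"grud"`, on raw unfilled windows with mask
#' and time-delta inputs), a single-feature logistic regression on the
#' window-mean MAP (`"logreg"`, raw mmHg units), and an RBF-kernel SVM on
#' the window means of all three channels (`"svm"`).  Deep models minimise
#' binary cross-entropy with Adam and keep the parameters from the epoch
#' with the best validation loss.
#'
#' @param data Training `ahe_dataset` from [build_dataset()] (class
#'   balancing, when wanted, is done beforehand with
#'   [balance_training_sets()]).
#' @param model One of `"lstm"`, `"grud"`, `"logreg"`, `"svm"`.
#' @param val_data Validation `ahe_dataset` (deep models; defaults to the
#'   training data with a warning).
#' @param spec An `ahe_spec` ([lstm_spec()] / [grud_spec()]); ignored by
#'   the baselines.
#' @param seed Integer seed controlling initialisation, dropout and
#'   shuffling; fits are reproducible given (data, spec, seed).
#' @param init Optional parameter list to start from (used by
#'   [transfer_finetune()]).
#' @param verbose Print per-epoch losses.
#' @return An object of class `ahe_model` with fields `model`, `spec`,
#'   `params`/`fit`, `log` (per-epoch losses), `obs`, `gap`,
#'   `channel_means` (decay model), `threshold` (default 0.5).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_patients = 30, seed = 2))
#' ds <- build_dataset(coh, obs_length = 30, gap_length = 10)
#' split <- split_by_patient(ds, c(0.6, 0.2, 0.2), seed = 1)
#' m <- ahe_fit(split$train, "logreg")
#' summary(m)
#' }
#' @export
ahe_fit <- function(data, model = c("lstm", "grud", "logreg", "svm"),
                    val_data = NULL, spec = NULL, seed = 1L, init = NULL,
                    channel_means = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "ahe_dataset"))
  y <- data$label
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (model %in% c("logreg", "svm")) {
    return(fit_baseline(data, model))
  }
  spec <- spec %||% if (model == "lstm") lstm_spec() else grud_spec()
  if (is.null(val_data)) {
    warning("no validation set supplied; selecting on training loss")
    val_data <- data
  }
  fit_deep(data, val_data, model, spec, seed, init, verbose, channel_means)
}

fit_baseline <- function(data, model) {
  sf <- as.data.frame(data$summary_features)
  names(sf) <- c("map", "hr", "spo2")
  sf$y <- data$label
  if (model == "logreg") {
    fit <- stats::glm(y ~ map, data = sf, family = stats::binomial())
  } else {
    fit <- e1071::svm(y ~ map + hr + spo2,
                      data = transform(sf, y = factor(y, levels = c(0, 1))),
                      kernel = "radial", cost = 1, scale = TRUE)
  }
  structure(list(model = model, fit = fit, obs = data$obs, gap = data$gap,
                 threshold = 0.5),
            class = c(paste0("ahe_", model), "ahe_model"))
}

deep_inputs <- function(data, model) {
  if (model == "lstm") {
    list(x = slice_timesteps(data$x))
  } else {
    vals <- data$x_raw
    vals[is.na(vals)] <- 0          # placeholder; mean substituted per fit
    list(x = slice_timesteps(vals),
         m = slice_timesteps(data$mask),
         d = slice_timesteps(data$delta))
  }
}

# Substitute the per-channel training mean at unobserved positions.
apply_mean_fill <- function(inp, means) {
  for (t in seq_along(inp$x)) {
    mm <- matrix(means, nrow(inp$x[[t]]), length(means), byrow = TRUE)
    inp$x[[t]] <- inp$m[[t]] * inp$x[[t]] + (1 - inp$m[[t]]) * mm
  }
  inp
}

forward_any <- function(model, params, inp, means = NULL, drop_mask = NULL,
                        layers = 2L) {
  if (model == "lstm") {
    lstm_forward(params, inp$x, layers = layers, drop_mask = drop_mask)
  } else {
    grud_forward(params, inp$x, inp$m, inp$d, means, drop_mask = drop_mask)
  }
}

fit_deep <- function(data, val_data, model, spec, seed, init, verbose,
                     channel_means = NULL) {
  y <- data$label
  n <- length(y)
  inp <- deep_inputs(data, model)
  vinp <- deep_inputs(val_data, model)
  means <- NULL
  if (model == "grud") {
    means <- channel_means %||% vapply(1:3, function(j) {
      v <- data$x_raw[, , j]
      mean(v[!is.na(v)])
    }, 0)
    inp <- apply_mean_fill(inp, means)
    vinp <- apply_mean_fill(vinp, means)
  }
  with_seed(seed, {
    params <- init %||% if (model == "lstm") {
      lstm_init(3L, spec$units, spec$layers)
    } else {
      grud_init(3L, spec$units)
    }
    state <- adam_init(params)
    best <- list(loss = Inf, params = params)
    log <- data.frame(epoch = integer(0), lr = numeric(0),
                      train_loss = numeric(0), val_loss = numeric(0))
    keep <- 1 - spec$dropout
    for (e in seq_len(spec$epochs)) {
      lr <- if (model == "lstm") {
        cosine_lr(e, spec$lr, spec$lr_min, spec$restart_period)
      } else {
        spec$lr
      }
      ord <- sample.int(n)
      nb <- ceiling(n / spec$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[(((b - 1L) * spec$batch_size) + 1L):min(b * spec$batch_size, n)]
        bi <- lapply(inp, subset_steps, idx = idx)
        yb <- y[idx]
        dmask <- if (spec$dropout > 0) {
          matrix(stats::rbinom(length(idx) * spec$units, 1L, keep) / keep,
                 length(idx), spec$units)
        } else {
          NULL
        }
        fw <- forward_any(model, params, bi, means, dmask, spec$layers)
        grads <- if (model == "lstm") {
          lstm_backward(params, fw, yb, spec$layers, spec$l2)
        } else {
          grud_backward(params, fw, yb, spec$l2)
        }
        up <- adam_step(params, grads, state, lr)
        params <- up$params; state <- up$state
        tr_loss <- tr_loss + bce_loss(fw$prob, yb) * length(idx)
      }
      tr_loss <- tr_loss / n
      vfw <- forward_any(model, params, vinp, means, NULL, spec$layers)
      vl <- bce_loss(vfw$prob, val_data$label)
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = e)
      log <- rbind(log, data.frame(epoch = e, lr = lr, train_loss = tr_loss,
                                   val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        e, lr, tr_loss, vl))
      }
    }
    structure(list(model = model, spec = spec, params = best$params,
                   best_epoch = best$epoch %||% NA_integer_,
                   val_loss = best$loss, log = log,
                   channel_means = means, obs = data$obs, gap = data$gap,
                   threshold = 0.5, seed = seed),
              class = c(paste0("ahe_", model), "ahe_model"))
  })
}

#' Predict AHE probabilities for new windows
#'
#' @param object An `ahe_model` from [ahe_fit()].
#' @param newdata An `ahe_dataset` preprocessed identically to training.
#' @param type `"prob"` for probabilities (decision scores for the SVM are
#'   mapped through no calibration; `"score"` returns the raw SVM decision
#'   value), `"class"` for thresholded 0/1 labels.
#' @param ... Unused.
#' @return Numeric vector, one value per window, order-preserving.
#' @export
predict.ahe_model <- function(object, newdata, type = c("prob", "class",
                                                        "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "ahe_dataset"))
  p <- switch(object$model,
    lstm = ,
    grud = {
      inp <- deep_inputs(newdata, object$model)
      if (object$model == "grud") {
        inp <- apply_mean_fill(inp, object$channel_means)
      }
      as.numeric(forward_any(object$model, object$params, inp,
                             object$channel_means, NULL,
                             object$spec$layers)$prob)
    },
    logreg = {
      sf <- as.data.frame(newdata$summary_features)
      names(sf) <- c("map", "hr", "spo2")
      as.numeric(stats::predict(object$fit, newdata = sf, type = "response"))
    },
    svm = {
      sf <- as.data.frame(newdata$summary_features)
      names(sf) <- c("map", "hr", "spo2")
      dv <- attr(stats::predict(object$fit, newdata = sf,
                                decision.values = TRUE), "decision.values")
      sc <- as.numeric(dv)
      # orient scores so larger = more likely positive
      if (colnames(dv)[1L] == "0/1") sc <- -sc
      if (type == "score") sc else sigmoid(sc)
    }
  )
  if (type == "class") as.integer(p >= object$threshold) else p
}

#' @export
print.ahe_model <- function(x, ...) {
  cat(sprintf("<ahe_model: %s> obs %s min, gap %s min\n", x$model,
              x$obs %||% "?", x$gap %||% "?"))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epochs; best val loss %.4f (epoch %d)\n",
                nrow(x$log), x$val_loss, x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.ahe_model <- function(object, ...) {
  print(object)
  if (object$model == "logreg") {
    print(summary(object$fit)$coefficients)
  } else if (object$model %in% c("lstm", "grud")) {
    np <- sum(vapply(object$params, length, 0L))
    cat(sprintf("  %d trainable parameters (%d units x %d layer(s))\n",
                np, object$spec$units, object$spec$layers))
  }
  invisible(object)
}

#' @export
coef.ahe_model <- function(object, ...) {
  if (object$model == "logreg") return(stats::coef(object$fit))
  object$params
}

#' @export
plot.ahe_model <- function(x, ...) {
  if (is.null(x$log)) {
    stop("no training log to plot for baseline models", call. = FALSE)
  }
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# Closed-form trainable parameter count for the stacked LSTM head.
lstm_param_count <- function(input_dim = 3L, hidden = 60L, layers = 2L) {
  total <- 0L
  din <- input_dim
  for (l in seq_len(layers)) {
    total <- total + 4L * hidden * (din + hidden + 1L)
    din <- hidden
  }
  total + hidden + 1L
}
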