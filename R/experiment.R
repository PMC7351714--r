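#' Partition windows into train/validation/test sets by patient
#'
#' Patients — not windows — are shuffled and allocated, so no patient
#' contributes windows to more than one set and evaluation reflects
#' between-patient generalisation.
#'
#' @param data An `ahe_dataset` (or a character vector of patient ids, in
#'   which case only the id sets are returned).
#' @param fractions Length-3 proportions `(train, val, test)` summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return For a dataset: list with `train`, `val`, `test`
#'   (`ahe_dataset`s) and `patients` (list of id vectors).  For an id
#'   vector: just the `patients` list.
#' @export
split_by_patient <- function(data, fractions = c(0.7, 0.15, 0.15),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    stop("fractions must be three proportions summing to 1", call. = FALSE)
  }
  ids <- if (inherits(data, "ahe_dataset")) unique(data$patient_id) else
    unique(as.character(data))
  if (length(ids) == 0L) stop("no patients to split", call. = FALSE)
  with_seed(seed, {
    ids <- resample(ids)
    n <- length(ids)
    n_train <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    n_val <- min(n_val, n - n_train)
    sets <- list(train = ids[seq_len(n_train)],
                 val = ids[n_train + seq_len(n_val)],
                 test = ids[setdiff(seq_len(n), seq_len(n_train + n_val))])
    if (!inherits(data, "ahe_dataset")) return(list(patients = sets))
    out <- list(train = dataset_subset(data, sets$train),
                val = dataset_subset(data, sets$val),
                test = dataset_subset(data, sets$test),
                patients = sets)
    assert_no_leakage(out)
    out
  })
}

# Patient-level leakage guard: any id in two sets aborts the run.
assert_no_leakage <- function(split) {
  p <- split$patients
  pairs <- list(c("train", "val"), c("train", "test"), c("val", "test"))
  for (pr in pairs) {
    shared <- intersect(p[[pr[1]]], p[[pr[2]]])
    if (length(shared)) {
      stop(sprintf("patient-level leakage between %s and %s: %s",
                   pr[1], pr[2], paste(shared, collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(split)
}

#' Balance classes in the training and validation sets
#'
#' Randomly down-samples negative windows in the train and validation sets
#' to `neg_per_pos` times the positive count (1 gives the evenly balanced
#' sets used by default; 2 gives the 66%/33% composition also explored).
#' The test set always keeps every negative so that reported performance
#' reflects the deployment class imbalance.
#'
#' @param split List from [split_by_patient()].
#' @param seed Integer seed for the down-sampling draw.
#' @param neg_per_pos Negatives retained per positive (default 1).
#' @return The split with balanced `train` and `val`, untouched `test`.
#' @export
balance_training_sets <- function(split, seed = 1L, neg_per_pos = 1) {
  with_seed(seed, {
    for (s in c("train", "val")) {
      ds <- split[[s]]
      pos <- which(ds$label == 1L); neg <- which(ds$label == 0L)
      if (length(pos) == 0L) {
        stop(sprintf("no positive windows in the %s set", s), call. = FALSE)
      }
      if (length(neg) < length(pos)) {
        stop("fewer negatives than positives; balancing assumes the reverse",
             call. = FALSE)
      }
      keep_neg <- resample(neg, min(length(neg),
                                    round(neg_per_pos * length(pos))))
      split[[s]] <- dataset_subset(ds, sort(c(pos, keep_neg)))
    }
  })
  split
}

#' Enumerate the experiment grid
#'
#' The full cross-product of observation lengths, gap lengths and model
#' families: one model configuration per cell per family.
#'
#' @param obs_lengths,gap_lengths Minutes (default [studied_grid()]).
#' @param families Model families.
#' @return Data frame with columns `family`, `obs`, `gap`.
#' @examples
#' nrow(grid_plan(families = "lstm"))                  # 36
#' nrow(grid_plan(families = c("lstm", "grud")))       # 72
#' @export
grid_plan <- function(obs_lengths = studied_grid(),
                      gap_lengths = studied_grid(),
                      families = c("lstm", "grud")) {
  expand.grid(family = families, obs = obs_lengths, gap = gap_lengths,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Fit and evaluate models over the (observation, gap) grid
#'
#' For every cell of [grid_plan()] and every family, builds the window
#' dataset, applies the patient-level split and class balancing, fits the
#' model and evaluates discrimination on the untouched test set.  Negative
#' windows do not depend on the gap, so datasets are rebuilt per
#' (obs, gap) from the shared annotation.
#'
#' @param cohort An `ahe_cohort`.
#' @param events Episode table (default: annotate the cohort).
#' @param obs_lengths,gap_lengths Grid axes in minutes.
#' @param families Subset of `c("lstm", "grud", "logreg", "svm")`.
#' @param fractions Patient-split proportions.
#' @param seed Master seed: split, balancing and fits derive from it.
#' @param specs Optional named list of `ahe_spec` overrides per family.
#' @param threshold Operating threshold for the confusion metrics.
#' @return Data frame: `family`, `obs`, `gap`, `auroc`, `sens`, `spec`,
#'   `ppv`, `n_pos`, `n_neg`.
#' @export
run_grid <- function(cohort, events = NULL, obs_lengths = studied_grid(),
                     gap_lengths = studied_grid(),
                     families = c("lstm", "grud", "logreg", "svm"),
                     fractions = c(0.7, 0.15, 0.15), seed = 1L,
                     specs = list(), threshold = 0.5) {
  if (is.null(events)) events <- annotate_cohort(cohort)
  plan <- grid_plan(obs_lengths, gap_lengths, families)
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    fam <- plan$family[k]; obs <- plan$obs[k]; gap <- plan$gap[k]
    ds <- build_dataset(cohort, events, obs_length = obs, gap_length = gap)
    split <- split_by_patient(ds, fractions, seed = seed)
    split <- balance_training_sets(split, seed = derive_seed(seed, k))
    fit <- ahe_fit(split$train, fam, val_data = split$val,
                   spec = specs[[fam]], seed = derive_seed(seed, 1000L + k))
    sc <- predict(fit, split$test)
    cm <- confusion_metrics(sc, split$test$label, threshold)
    rows[[k]] <- data.frame(
      family = fam, obs = obs, gap = gap,
      auroc = auroc(sc, split$test$label),
      sens = cm$sensitivity, spec = cm$specificity, ppv = cm$ppv,
      n_pos = sum(split$test$label == 1L),
      n_neg = sum(split$test$label == 0L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Adapt a trained model to a new cohort by fine-tuning
#'
#' Transfers the source model's weights into an identical architecture and
#' fine-tunes on small class-balanced tuning sets of increasing size (10 to
#' 50 windows by default), at a reduced fixed learning rate of 1e-4,
#' selecting the adapted model with the best target-domain validation loss.
#' The source model is never mutated.
#'
#' @param source_model A deep `ahe_model` (`"lstm"` or `"grud"`).
#' @param tune_data Target-domain `ahe_dataset` to draw tuning windows from.
#' @param val_data Target-domain validation `ahe_dataset`.
#' @param tune_sizes Total tuning-set sizes (balanced: half positive).
#' @param epochs Fine-tuning epochs per size.
#' @param lr Reduced fine-tuning learning rate.
#' @param seed Integer seed for the tuning draws and fine-tune fits.
#' @return List with `models` (one adapted `ahe_model` per size), `best`
#'   (lowest target validation loss) and `val_loss` per size.
#' @export
transfer_finetune <- function(source_model, tune_data, val_data,
                              tune_sizes = seq(10L, 50L, by = 10L),
                              epochs = 30L, lr = 1e-4, seed = 1L) {
  if (!source_model$model %in% c("lstm", "grud")) {
    stop("transfer fine-tuning applies to the deep models", call. = FALSE)
  }
  pos <- which(tune_data$label == 1L); neg <- which(tune_data$label == 0L)
  models <- list(); vls <- numeric(0)
  for (sz in tune_sizes) {
    half <- sz %/% 2L
    if (length(pos) < half || length(neg) < sz - half) {
      stop(sprintf("tune size %d exceeds available balanced windows", sz),
           call. = FALSE)
    }
    sub <- with_seed(derive_seed(seed, sz), {
      sort(c(resample(pos, half), resample(neg, sz - half)))
    })
    tset <- dataset_subset(tune_data, sub)
    spec <- source_model$spec
    spec$lr <- lr
    spec$epochs <- as.integer(epochs)
    if (source_model$model == "lstm") spec$lr_min <- lr / 100
    m <- ahe_fit(tset, source_model$model, val_data = val_data, spec = spec,
                 seed = derive_seed(seed, 7000L + sz),
                 init = source_model$params,
                 channel_means = source_model$channel_means)
    models[[as.character(sz)]] <- m
    vls <- c(vls, m$val_loss)
  }
  list(models = models, val_loss = stats::setNames(vls, tune_sizes),
       best = models[[which.min(vls)]])
}
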