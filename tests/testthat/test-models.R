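ns <- asNamespace("ahepredict")

test_that("LSTM backpropagation matches finite differences", {
  set.seed(11)
  n <- 5; tt <- 4; d <- 3; H <- 4; l2 <- 1e-3
  xt <- lapply(seq_len(tt), function(t) matrix(rnorm(n * d), n, d))
  y <- rbinom(n, 1, 0.5)
  params <- ns$lstm_init(d, H, 2L)
  fw <- ns$lstm_forward(params, xt, layers = 2L)
  g <- ns$lstm_backward(params, fw, y, 2L, l2)
  ng <- numeric_gradient(function(p) {
    ns$bce_loss(ns$lstm_forward(p, xt, layers = 2L)$prob, y, p, l2)
  }, params)
  for (nm in names(params)) {
    denom <- max(abs(ng[[nm]])) + 1e-8
    expect_lt(max(abs(g[[nm]] - ng[[nm]])) / denom, 1e-5)
  }
})

test_that("decay-cell backpropagation matches finite differences", {
  set.seed(12)
  n <- 5; tt <- 4; d <- 3; H <- 4; l2 <- 1e-3
  m <- lapply(seq_len(tt), function(t) matrix(rbinom(n * d, 1, 0.7), n, d))
  dl <- list(matrix(0, n, d))
  for (t in 2:tt) dl[[t]] <- ifelse(m[[t - 1]] == 1, 1, dl[[t - 1]] + 1)
  means <- rnorm(d)
  xt <- lapply(seq_len(tt), function(t) {
    matrix(rnorm(n * d), n, d) * m[[t]] +
      (1 - m[[t]]) * matrix(means, n, d, byrow = TRUE)
  })
  params <- ns$grud_init(d, H)
  params$w_gx <- rnorm(d, 0.5, 0.2); params$b_gx <- rnorm(d, 0.1, 0.1)
  params$W_gh <- matrix(rnorm(d * H, 0, 0.3), d, H)
  params$b_gh <- rnorm(H, 0.1, 0.1)
  y <- rbinom(n, 1, 0.5)
  fw <- ns$grud_forward(params, xt, m, dl, means)
  g <- ns$grud_backward(params, fw, y, l2)
  ng <- numeric_gradient(function(p) {
    ns$bce_loss(ns$grud_forward(p, xt, m, dl, means)$prob, y, p, l2)
  }, params)
  for (nm in names(params)) {
    denom <- max(abs(ng[[nm]])) + 1e-8
    expect_lt(max(abs(g[[nm]] - ng[[nm]])) / denom, 1e-5)
  }
})

test_that("the decay cell reduces to a standard gated unit", {
  # fully observed input, decay parameters and mask weights at zero:
  # the hidden trajectory must equal an independently coded GRU
  set.seed(13)
  n <- 6; tt <- 8; d <- 3; H <- 5
  xt <- lapply(seq_len(tt), function(t) matrix(rnorm(n * d), n, d))
  ones <- lapply(seq_len(tt), function(t) matrix(1, n, d))
  dl <- c(list(matrix(0, n, d)), lapply(seq_len(tt - 1), function(t) {
    matrix(1, n, d)
  }))
  params <- ns$grud_init(d, H)
  params$V_r <- params$V_r * 0
  params$V_z <- params$V_z * 0
  params$V_h <- params$V_h * 0
  means <- rnorm(d)
  fw <- ns$grud_forward(params, xt, ones, dl, means)
  ref <- reference_gru(xt, params$W_r, params$U_r, params$b_r,
                       params$W_z, params$U_z, params$b_z,
                       params$W_h, params$U_h, params$b_h)
  expect_lt(max(abs(fw$hT - ref[[tt]])), 1e-12)
})

test_that("input decay relaxes a silent channel monotonically toward the mean", {
  set.seed(14)
  n <- 2; tt <- 12; d <- 3; H <- 4
  params <- ns$grud_init(d, H)
  params$w_gx <- rep(0.3, d)           # positive decay weights
  means <- c(0.5, 0.5, 0.9)
  m <- lapply(seq_len(tt), function(t) {
    mm <- matrix(1, n, d)
    if (t > 3) mm[, 1] <- 0            # channel 1 silent from step 4
    mm
  })
  dl <- list(matrix(0, n, d))
  for (t in 2:tt) dl[[t]] <- ifelse(m[[t - 1]] == 1, 1, dl[[t - 1]] + 1)
  xt <- lapply(seq_len(tt), function(t) matrix(0.9, n, d))
  fw <- ns$grud_forward(params, xt, m, dl, means)
  xhat1 <- vapply(4:tt, function(t) fw$cache[[t]]$xhat[1, 1], 0)
  expect_true(all(diff(xhat1) < 0))            # decaying from 0.9 ...
  expect_true(all(xhat1 > means[1]))           # ... toward the mean, never past
})

test_that("model builds are deterministic and sized by the closed form", {
  toy <- make_toy_dataset(n_per_class = 10, tt = 10)
  spec <- lstm_spec(units = 8, epochs = 2, batch_size = 10)
  m1 <- ahe_fit(toy, "lstm", val_data = toy, spec = spec, seed = 3)
  m2 <- ahe_fit(toy, "lstm", val_data = toy, spec = spec, seed = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log$val_loss, m2$log$val_loss)

  p <- predict(m1, toy)
  expect_true(all(p > 0 & p < 1))
  expect_equal(sum(vapply(m1$params, length, 0L)),
               ns$lstm_param_count(3L, 8L, 2L))
  # the architecture in its published configuration
  full <- ns$lstm_init(3L, 60L, 2L)
  expect_equal(sum(vapply(full, length, 0L)),
               ns$lstm_param_count(3L, 60L, 2L))
  expect_equal(ns$lstm_param_count(3L, 60L, 2L),
               4 * 60 * (3 + 60 + 1) + 4 * 60 * (60 + 60 + 1) + 60 + 1)
})

test_that("prediction is order-preserving and batch-size invariant", {
  toy <- make_toy_dataset(n_per_class = 8, tt = 10, miss = 0.1)
  for (fam in c("lstm", "grud")) {
    spec <- if (fam == "lstm") lstm_spec(units = 6, epochs = 2, batch_size = 8)
            else grud_spec(units = 6, epochs = 2, batch_size = 8)
    m <- ahe_fit(toy, fam, val_data = toy, spec = spec, seed = 4)
    whole <- predict(m, toy)
    single <- vapply(seq_along(toy$label), function(i) {
      predict(m, dataset_subset(toy, i))
    }, 0)
    expect_equal(whole, single, tolerance = 1e-12)
    dup <- dataset_subset(toy, c(1L, 1L))
    expect_equal(predict(m, dup)[1], predict(m, dup)[2])
  }
})

test_that("deep models learn a separable toy and refuse one-class data", {
  toy <- make_toy_dataset(n_per_class = 30, tt = 10, signal = 0.3, seed = 6)
  m <- ahe_fit(toy, "lstm", val_data = toy,
               spec = lstm_spec(units = 16, epochs = 50, batch_size = 20),
               seed = 7)
  expect_gt(auroc(predict(m, toy), toy$label), 0.95)

  toy_m <- make_toy_dataset(n_per_class = 30, tt = 10, signal = 0.3,
                            seed = 8, miss = 0.1)
  g <- ahe_fit(toy_m, "grud", val_data = toy_m,
               spec = grud_spec(units = 16, epochs = 50, batch_size = 20,
                                lr = 1e-2),
               seed = 9)
  expect_gt(auroc(predict(g, toy_m), toy_m$label), 0.95)

  ones <- dataset_subset(toy, which(toy$label == 1L))
  expect_error(ahe_fit(ones, "lstm"), "both classes")
})

test_that("mean-feature baselines behave on separable and degenerate toys", {
  toy <- make_toy_dataset(n_per_class = 40, tt = 10, signal = 0.4, seed = 10)
  m <- suppressWarnings(ahe_fit(toy, "logreg"))  # separation is intended
  p <- predict(m, toy)
  expect_gt(auroc(p, toy$label), 0.99)
  # positives drift to lower MAP, so the MAP coefficient is negative
  expect_lt(coef(m)[["map"]], 0)

  s <- ahe_fit(toy, "svm")
  expect_gt(auroc(predict(s, toy, type = "score"), toy$label), 0.99)

  # constant feature: no discrimination
  flat <- toy
  flat$summary_features[, ] <- 70
  mf <- suppressWarnings(ahe_fit(flat, "logreg"))
  expect_equal(auroc(predict(mf, flat), flat$label), 0.5)
})

test_that("cosine annealing restarts and bounds the learning rate", {
  lr <- vapply(1:25, cosine_lr, 0, lr_max = 1e-3, lr_min = 1e-5, period = 10L)
  expect_equal(lr[1], 1e-3)
  expect_equal(lr[11], 1e-3)          # warm restart
  expect_equal(lr[21], 1e-3)
  expect_true(all(lr >= 1e-5 & lr <= 1e-3))
  expect_true(all(diff(lr[1:10]) < 0))
})
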