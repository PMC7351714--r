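# Recurrent network internals: stacked LSTM and decay-gated (GRU-D style)
# classifiers, implemented directly with base matrix algebra.  Sequences are
# short (10-60 timesteps) and batches small, so vectorised BPTT over the
# batch dimension is fast without compiled code.  Parameters live in flat
# named lists of matrices/vectors; gradients mirror that layout, which keeps
# the Adam update and finite-difference verification trivial.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# ---- parameter initialisation -------------------------------------------

lstm_init <- function(input_dim, hidden, layers = 2L) {
  p <- list()
  din <- input_dim
  for (l in seq_len(layers)) {
    W <- glorot(din, 4L * hidden)
    U <- glorot(hidden, 4L * hidden)
    b <- rep(0, 4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1        # forget-gate bias
    p[[paste0("W", l)]] <- W
    p[[paste0("U", l)]] <- U
    p[[paste0("b", l)]] <- b
    din <- hidden
  }
  p$wd <- glorot(hidden, 1L)
  p$bd <- 0
  p
}

grud_init <- function(input_dim, hidden) {
  p <- list(
    w_gx = rep(0, input_dim), b_gx = rep(0, input_dim),
    W_gh = matrix(0, input_dim, hidden), b_gh = rep(0, hidden)
  )
  for (g in c("r", "z", "h")) {
    p[[paste0("W_", g)]] <- glorot(input_dim, hidden)
    p[[paste0("U_", g)]] <- glorot(hidden, hidden)
    p[[paste0("V_", g)]] <- glorot(input_dim, hidden)
    p[[paste0("b_", g)]] <- rep(0, hidden)
  }
  p$wd <- glorot(hidden, 1L)
  p$bd <- 0
  p
}

# ---- LSTM forward / backward --------------------------------------------

# xt: list over timesteps of [n x d] matrices.
lstm_layer_forward <- function(xt, W, U, b) {
  tt <- length(xt); n <- nrow(xt[[1L]]); H <- nrow(U)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", tt); hs <- vector("list", tt)
  bi <- 1:H; bf <- (H + 1L):(2L * H); bg <- (2L * H + 1L):(3L * H)
  bo <- (3L * H + 1L):(4L * H)
  for (t in seq_len(tt)) {
    z <- xt[[t]] %*% W + h %*% U + matrix(b, n, 4L * H, byrow = TRUE)
    i <- sigmoid(z[, bi, drop = FALSE]); f <- sigmoid(z[, bf, drop = FALSE])
    g <- tanh(z[, bg, drop = FALSE]);    o <- sigmoid(z[, bo, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(x = xt[[t]], h_prev = h, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, c = cc, tc = tc)
    h <- o * tc
    hs[[t]] <- h
  }
  list(h = hs, cache = cache)
}

# dh_ext: list over timesteps of external gradients into h_t (or NULL).
lstm_layer_backward <- function(cache, dh_ext, W, U) {
  tt <- length(cache); n <- nrow(cache[[1L]]$x); H <- nrow(U)
  dW <- W * 0; dU <- U * 0; db <- rep(0, 4L * H)
  dx <- vector("list", tt)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(tt))) {
    cc <- cache[[t]]
    dh <- dh_next + (dh_ext[[t]] %||% 0)
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dx[[t]] <- dz %*% t(W)
    dh_next <- dz %*% t(U)
  }
  list(dW = dW, dU = dU, db = db, dx = dx)
}

lstm_forward <- function(params, xt, layers = 2L, drop_mask = NULL) {
  caches <- vector("list", layers)
  inp <- xt
  for (l in seq_len(layers)) {
    fw <- lstm_layer_forward(inp, params[[paste0("W", l)]],
                             params[[paste0("U", l)]],
                             params[[paste0("b", l)]])
    caches[[l]] <- fw$cache
    inp <- fw$h
  }
  hT <- inp[[length(inp)]]
  hd <- if (is.null(drop_mask)) hT else hT * drop_mask
  logit <- hd %*% params$wd + params$bd
  list(prob = sigmoid(logit), hT = hT, hd = hd, caches = caches,
       drop_mask = drop_mask)
}

lstm_backward <- function(params, fw, y, layers = 2L, l2 = 0) {
  n <- length(y)
  dlogit <- (fw$prob - y) / n                 # BCE + sigmoid
  g <- list()
  g$wd <- crossprod(fw$hd, dlogit)
  g$bd <- sum(dlogit)
  dhd <- dlogit %*% t(params$wd)
  dhT <- if (is.null(fw$drop_mask)) dhd else dhd * fw$drop_mask
  tt <- length(fw$caches[[1L]])
  dh_ext <- vector("list", tt)
  dh_ext[[tt]] <- dhT
  for (l in rev(seq_len(layers))) {
    bk <- lstm_layer_backward(fw$caches[[l]], dh_ext,
                              params[[paste0("W", l)]],
                              params[[paste0("U", l)]])
    g[[paste0("W", l)]] <- bk$dW
    g[[paste0("U", l)]] <- bk$dU
    g[[paste0("b", l)]] <- bk$db
    dh_ext <- bk$dx
  }
  add_l2(g, params, l2)
}

# ---- GRU-D forward / backward -------------------------------------------

# xt, mt, dt: lists over timesteps of [n x d] matrices (values, mask,
# time-since-observation); means: length-d channel means used as the decay
# target and as the pre-first-observation carry value.
grud_forward <- function(params, xt, mt, dt, means, drop_mask = NULL) {
  tt <- length(xt); n <- nrow(xt[[1L]]); H <- ncol(params$U_r)
  d <- ncol(xt[[1L]])
  mean_mat <- matrix(means, n, d, byrow = TRUE)
  h <- matrix(0, n, H)
  xlast <- mean_mat
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    x <- xt[[t]]; m <- mt[[t]]; dl <- dt[[t]]
    sx <- sweep(dl, 2L, params$w_gx, `*`) +
      matrix(params$b_gx, n, d, byrow = TRUE)
    gx <- exp(-pmax(sx, 0))
    xhat <- m * x + (1 - m) * (gx * xlast + (1 - gx) * mean_mat)
    sh <- dl %*% params$W_gh + matrix(params$b_gh, n, H, byrow = TRUE)
    gh <- exp(-pmax(sh, 0))
    hdec <- gh * h
    r <- sigmoid(xhat %*% params$W_r + hdec %*% params$U_r +
                   m %*% params$V_r + matrix(params$b_r, n, H, byrow = TRUE))
    z <- sigmoid(xhat %*% params$W_z + hdec %*% params$U_z +
                   m %*% params$V_z + matrix(params$b_z, n, H, byrow = TRUE))
    hc <- tanh(xhat %*% params$W_h + (r * hdec) %*% params$U_h +
                 m %*% params$V_h + matrix(params$b_h, n, H, byrow = TRUE))
    h_new <- (1 - z) * hdec + z * hc
    cache[[t]] <- list(x = x, m = m, dl = dl, sx = sx, gx = gx, xhat = xhat,
                       sh = sh, gh = gh, h_prev = h, hdec = hdec,
                       xlast = xlast, r = r, z = z, hc = hc)
    h <- h_new
    xlast <- m * x + (1 - m) * xlast
  }
  hd <- if (is.null(drop_mask)) h else h * drop_mask
  logit <- hd %*% params$wd + params$bd
  list(prob = sigmoid(logit), hT = h, hd = hd, cache = cache,
       drop_mask = drop_mask, mean_mat = mean_mat)
}

grud_backward <- function(params, fw, y, l2 = 0) {
  n <- length(y)
  cache <- fw$cache; tt <- length(cache)
  H <- ncol(params$U_r); d <- length(params$w_gx)
  g <- lapply(params, function(p) p * 0)
  dlogit <- (fw$prob - y) / n
  g$wd <- crossprod(fw$hd, dlogit)
  g$bd <- sum(dlogit)
  dhd <- dlogit %*% t(params$wd)
  dh <- if (is.null(fw$drop_mask)) dhd else dhd * fw$drop_mask
  for (t in rev(seq_len(tt))) {
    cc <- cache[[t]]
    dz <- dh * (cc$hc - cc$hdec)
    dhc <- dh * cc$z
    dhdec <- dh * (1 - cc$z)
    # candidate
    da <- dhc * (1 - cc$hc^2)
    g$W_h <- g$W_h + crossprod(cc$xhat, da)
    g$U_h <- g$U_h + crossprod(cc$r * cc$hdec, da)
    g$V_h <- g$V_h + crossprod(cc$m, da)
    g$b_h <- g$b_h + colSums(da)
    drh <- da %*% t(params$U_h)
    dr <- drh * cc$hdec
    dhdec <- dhdec + drh * cc$r
    dxhat <- da %*% t(params$W_h)
    # update gate
    dzp <- dz * cc$z * (1 - cc$z)
    g$W_z <- g$W_z + crossprod(cc$xhat, dzp)
    g$U_z <- g$U_z + crossprod(cc$hdec, dzp)
    g$V_z <- g$V_z + crossprod(cc$m, dzp)
    g$b_z <- g$b_z + colSums(dzp)
    dxhat <- dxhat + dzp %*% t(params$W_z)
    dhdec <- dhdec + dzp %*% t(params$U_z)
    # reset gate
    drp <- dr * cc$r * (1 - cc$r)
    g$W_r <- g$W_r + crossprod(cc$xhat, drp)
    g$U_r <- g$U_r + crossprod(cc$hdec, drp)
    g$V_r <- g$V_r + crossprod(cc$m, drp)
    g$b_r <- g$b_r + colSums(drp)
    dxhat <- dxhat + drp %*% t(params$W_r)
    dhdec <- dhdec + drp %*% t(params$U_r)
    # hidden decay: hdec = gh * h_prev, gh = exp(-relu(sh))
    dgh <- dhdec * cc$h_prev
    dh_prev <- dhdec * cc$gh
    dsh <- -dgh * cc$gh * (cc$sh > 0)
    g$W_gh <- g$W_gh + crossprod(cc$dl, dsh)
    g$b_gh <- g$b_gh + colSums(dsh)
    # input decay: xhat = m x + (1-m)(gx xlast + (1-gx) mean)
    dgx <- dxhat * (1 - cc$m) * (cc$xlast - fw$mean_mat)
    dsx <- -dgx * cc$gx * (cc$sx > 0)
    g$w_gx <- g$w_gx + colSums(dsx * cc$dl)
    g$b_gx <- g$b_gx + colSums(dsx)
    dh <- dh_prev
  }
  add_l2(g, params, l2)
}

# ---- loss, regularisation, optimiser ------------------------------------

bce_loss <- function(prob, y, params = NULL, l2 = 0) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (l2 > 0 && !is.null(params)) {
    loss <- loss + l2 * sum(vapply(params, function(q) sum(q^2), 0))
  }
  loss
}

add_l2 <- function(grads, params, l2) {
  if (l2 > 0) {
    for (nm in names(params)) grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Within each restart period of `period` epochs the rate decays from
#' `lr_max` to `lr_min` along a half cosine, then resets.
#'
#' @param epoch 1-based epoch number.
#' @param lr_max,lr_min Rate bounds.
#' @param period Restart period in epochs.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, lr_max = 1e-3, lr_min = 1e-5, period = 10L) {
  tcur <- (epoch - 1L) %% period
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * tcur / period))
}

# ---- shared data plumbing ------------------------------------------------

# Convert [n x T x d] array into a list of per-timestep [n x d] matrices.
slice_timesteps <- function(a) {
  n <- dim(a)[1L]; tt <- dim(a)[2L]; d <- dim(a)[3L]
  lapply(seq_len(tt), function(t) matrix(a[, t, ], n, d))
}

subset_steps <- function(xt, idx) {
  lapply(xt, function(m) m[idx, , drop = FALSE])
}
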