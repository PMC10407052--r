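# Minimal fully connected regressor: input -> ReLU hidden -> linear
# output, trained by full-batch Adam on mean squared error. Small enough
# that plain matrix algebra (BLAS) is the right tool; seeded and
# serializable as a plain list.

mlp_init <- function(n_in, n_hidden, seed, y_mean = 0) {
  with_seed(seed, {
    list(W1 = matrix(stats::rnorm(n_in * n_hidden, sd = sqrt(2 / n_in)), n_in),
         b1 = rep(0, n_hidden),
         W2 = matrix(stats::rnorm(n_hidden, sd = sqrt(2 / n_hidden)), n_hidden, 1L),
         b2 = y_mean)
  })
}

mlp_forward <- function(par, X) {
  H <- X %*% par$W1
  H <- pmax(sweep(H, 2L, par$b1, `+`), 0)
  list(H = H, yhat = as.vector(H %*% par$W2) + par$b2)
}

#' Train a small fully connected regressor
#'
#' @param X Numeric input matrix (rows = samples).
#' @param y Numeric targets.
#' @param hidden Hidden-layer width.
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed (initialization and validation split).
#' @param val_frac Fraction held out for the early-stopping split.
#' @param patience Epochs without validation improvement before stopping.
#' @return A `numsense_mlp`: weights, training `history` (train and
#'   validation MSE per epoch) and configuration.
#' @keywords internal
mlp_train <- function(X, y, hidden = 2000L, epochs = 300L, lr = 0.01,
                      seed = 1L, val_frac = 0.1, patience = 25L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 4L)
  n <- nrow(X)
  idx_val <- with_seed(derive_seed(seed, "valsplit"), {
    sample.int(n, max(1L, round(val_frac * n)))
  })
  Xt <- X[-idx_val, , drop = FALSE]; yt <- y[-idx_val]
  Xv <- X[idx_val, , drop = FALSE]; yv <- y[idx_val]
  par <- mlp_init(ncol(X), hidden, derive_seed(seed, "init"), y_mean = mean(yt))
  m <- v <- lapply(par, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  hist_tr <- hist_va <- numeric(epochs)
  best <- list(par = par, loss = Inf, epoch = 0L)
  for (t in seq_len(epochs)) {
    fw <- mlp_forward(par, Xt)
    err <- fw$yhat - yt
    hist_tr[t] <- mean(err^2)
    dY <- matrix(2 * err / length(err), ncol = 1L)
    g <- list(W2 = crossprod(fw$H, dY), b2 = sum(dY))
    dH <- (dY %*% t(par$W2)) * (fw$H > 0)
    g$W1 <- crossprod(Xt, dH)
    g$b1 <- colSums(dH)
    for (nm in names(par)) {
      m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * g[[nm]]
      v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * g[[nm]]^2
      par[[nm]] <- par[[nm]] - lr * (m[[nm]] / (1 - b1m^t)) /
        (sqrt(v[[nm]] / (1 - b2m^t)) + eps)
    }
    hist_va[t] <- mean((mlp_forward(par, Xv)$yhat - yv)^2)
    if (hist_va[t] < best$loss - 1e-7) best <- list(par = par, loss = hist_va[t], epoch = t)
    if (t - best$epoch >= patience) { hist_tr <- hist_tr[1:t]; hist_va <- hist_va[1:t]; break }
  }
  structure(list(par = best$par, hidden = hidden,
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_mse = hist_tr, val_mse = hist_va),
                 config = list(epochs = epochs, lr = lr, seed = seed,
                               val_frac = val_frac, patience = patience,
                               stopped_at = length(hist_tr),
                               best_epoch = best$epoch)),
            class = "numsense_mlp")
}

mlp_predict <- function(model, X) mlp_forward(model$par, as.matrix(X))$yhat
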