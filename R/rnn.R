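# Lightweight Elman recurrent classifier. The univariate lag window is fed
# one value per time step through stacked tanh recurrent layers
# (a_t = b + W h_{t-1} + U x_t, h_t = tanh(a_t)); the final hidden state of
# the top layer drives a single sigmoid output unit. Training is full
# backpropagation through time with Adam, inverted dropout on each recurrent
# layer's output, and early stopping on validation loss.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained recurrent classifier
#'
#' The network has `lags` scalar inputs consumed sequentially,
#' `hp$num_layers` stacked recurrent tanh layers with `hp$neurons` units,
#' dropout after each recurrent layer, and one sigmoid output unit. Weight
#' initialization (Glorot uniform) is seed-deterministic.
#'
#' @param hp A `hyperparameter_set`.
#' @param lags Input window length (default 15).
#' @param seed Optional integer seed for the initialization.
#' @return An `rnn_model` object.
#' @export
build_rnn <- function(hp, lags = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- hp$neurons
  in_sizes <- c(1L, sizes[-length(sizes)])
  layers <- lapply(seq_along(sizes), function(l) {
    list(U = glorot(in_sizes[l], sizes[l]),
         W = glorot(sizes[l], sizes[l]),
         b = numeric(sizes[l]))
  })
  structure(list(lags = as.integer(lags),
                 layers = layers,
                 V = glorot(sizes[length(sizes)], 1L),
                 c = 0,
                 dropout = hp$dropout,
                 norm = list(mean = 0, sd = 1),
                 hp = hp),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("recurrent classifier: %d lags -> [%s] tanh units -> sigmoid\n",
              x$lags, paste(x$hp$neurons, collapse = ", ")))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# Forward pass over a batch of raw windows. With cache = TRUE, returns the
# intermediates needed by backprop; `training` draws dropout masks.
rnn_forward_pass <- function(model, X, training = FALSE, cache = FALSE) {
  B <- nrow(X)
  Tt <- ncol(X)
  L <- length(model$layers)
  Xs <- (X - model$norm$mean) / model$norm$sd
  p_drop <- if (training) model$dropout else 0
  h_prev <- lapply(model$layers, function(ly) {
    matrix(0, B, ncol(ly$U))
  })
  H <- if (cache) lapply(seq_len(L), function(l) vector("list", Tt))
  IN <- if (cache) lapply(seq_len(L), function(l) vector("list", Tt))
  M <- if (cache) lapply(seq_len(L), function(l) vector("list", Tt))
  out <- NULL
  for (t in seq_len(Tt)) {
    inp <- Xs[, t, drop = FALSE]
    for (l in seq_len(L)) {
      ly <- model$layers[[l]]
      A <- add_bias(inp %*% ly$U + h_prev[[l]] %*% ly$W, ly$b)
      Hlt <- tanh(A)
      h_prev[[l]] <- Hlt
      if (p_drop > 0) {
        mask <- matrix(stats::rbinom(length(Hlt), 1, 1 - p_drop) / (1 - p_drop),
                       nrow(Hlt), ncol(Hlt))
      } else {
        mask <- NULL
      }
      dropped <- if (is.null(mask)) Hlt else Hlt * mask
      if (cache) {
        H[[l]][[t]] <- Hlt
        IN[[l]][[t]] <- inp
        M[[l]][[t]] <- mask
      }
      inp <- dropped
      if (l == L && t == Tt) out <- dropped
    }
  }
  z <- out %*% model$V + model$c
  prob <- sigmoid(z)
  if (!cache) return(as.numeric(prob))
  list(prob = prob, out_final = out, H = H, IN = IN, M = M, B = B, Tt = Tt)
}

#' Forward pass: class-1 (anomalous) probabilities
#'
#' Applies the stored training standardization, runs the recurrence over the
#' window, and returns the sigmoid output.
#'
#' @param model An `rnn_model`.
#' @param windows A numeric vector of length `model$lags` or a matrix with
#'   `model$lags` columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
rnn_forward <- function(model, windows) {
  if (is.vector(windows)) windows <- matrix(windows, nrow = 1)
  if (ncol(windows) != model$lags) {
    stop(sprintf("windows have %d columns; model expects %d lags",
                 ncol(windows), model$lags))
  }
  rnn_forward_pass(model, windows, training = FALSE, cache = FALSE)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradients of mean BCE wrt every parameter, by backpropagation through time.
rnn_backward <- function(model, fwd, y) {
  L <- length(model$layers)
  B <- fwd$B
  Tt <- fwd$Tt
  dz <- (fwd$prob - y) / B
  g <- list(V = t(fwd$out_final) %*% dz, c = sum(dz),
            layers = lapply(model$layers, function(ly) {
              list(U = ly$U * 0, W = ly$W * 0, b = ly$b * 0)
            }))
  d_out_final <- dz %*% t(model$V)
  dh_rec <- lapply(model$layers, function(ly) matrix(0, B, ncol(ly$U)))
  dA_t <- vector("list", L)
  for (t in rev(seq_len(Tt))) {
    for (l in rev(seq_len(L))) {
      dh <- dh_rec[[l]]
      if (l == L && t == Tt) {
        dh <- dh + if (is.null(fwd$M[[l]][[t]])) d_out_final else
          d_out_final * fwd$M[[l]][[t]]
      }
      if (l < L) {
        from_above <- dA_t[[l + 1]] %*% t(model$layers[[l + 1]]$U)
        if (!is.null(fwd$M[[l]][[t]])) from_above <- from_above * fwd$M[[l]][[t]]
        dh <- dh + from_above
      }
      dA <- dh * (1 - fwd$H[[l]][[t]]^2)
      dA_t[[l]] <- dA
      g$layers[[l]]$U <- g$layers[[l]]$U + t(fwd$IN[[l]][[t]]) %*% dA
      if (t > 1) {
        g$layers[[l]]$W <- g$layers[[l]]$W + t(fwd$H[[l]][[t - 1]]) %*% dA
      }
      g$layers[[l]]$b <- g$layers[[l]]$b + colSums(dA)
      dh_rec[[l]] <- dA %*% t(model$layers[[l]]$W)
    }
  }
  g
}

get_params <- function(model) {
  c(list(V = model$V, c = model$c),
    unlist(lapply(model$layers, function(ly) ly[c("U", "W", "b")]),
           recursive = FALSE))
}

flatten_grads <- function(g) {
  c(list(V = g$V, c = g$c),
    unlist(lapply(g$layers, function(ly) ly[c("U", "W", "b")]),
           recursive = FALSE))
}

set_params <- function(model, params) {
  model$V <- params$V
  model$c <- params$c
  L <- length(model$layers)
  for (l in seq_len(L)) {
    base <- 2 + (l - 1) * 3
    model$layers[[l]]$U <- params[[base + 1]]
    model$layers[[l]]$W <- params[[base + 2]]
    model$layers[[l]]$b <- params[[base + 3]]
  }
  model
}

#' Train the recurrent classifier with early stopping
#'
#' Minimizes binary cross-entropy with Adam at `hp$learning_rate` (batch
#' size `batch_size`) for at most `hp$epochs` epochs over the chronological
#' training split. Training stops early when validation loss fails to
#' improve for `ceiling(epochs / 3)` consecutive epochs, and the returned
#' model carries the weights of the best-validation epoch.
#'
#' @param model An `rnn_model` from [build_rnn()].
#' @param train_set,val_set `windowed_dataset` splits (chronologically
#'   disjoint).
#' @param hp Hyperparameters; defaults to those stored in the model.
#' @param seed Optional integer seed controlling shuffling and dropout.
#' @param batch_size Minibatch size (default 32).
#' @return A `training_run` list: trained `model`, `history` data frame
#'   (epoch, train_loss, val_loss), `epochs_requested`, `epochs_executed`,
#'   `patience`, `best_epoch`.
#' @export
rnn_train <- function(model, train_set, val_set, hp = model$hp, seed = NULL,
                      batch_size = 32L) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(train_set$X) == 0 || nrow(val_set$X) == 0) {
    stop("training and validation sets must be non-empty")
  }
  model$norm <- list(mean = mean(train_set$X), sd = max(stats::sd(train_set$X), 1e-8))
  patience <- ceiling(hp$epochs / 3)
  n <- nrow(train_set$X)
  params <- get_params(model)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L
  epochs_executed <- 0L
  for (epoch in seq_len(hp$epochs)) {
    idx <- sample.int(n)
    batch_losses <- numeric()
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      fwd <- rnn_forward_pass(model, train_set$X[bi, , drop = FALSE],
                              training = TRUE, cache = TRUE)
      yb <- matrix(train_set$y[bi], ncol = 1)
      batch_losses <- c(batch_losses, bce_loss(as.numeric(fwd$prob), train_set$y[bi]))
      g <- flatten_grads(rnn_backward(model, fwd, yb))
      step <- step + 1L
      for (k in seq_along(params)) {
        mstate[[k]] <- beta1 * mstate[[k]] + (1 - beta1) * g[[k]]
        vstate[[k]] <- beta2 * vstate[[k]] + (1 - beta2) * g[[k]]^2
        mhat <- mstate[[k]] / (1 - beta1^step)
        vhat <- vstate[[k]] / (1 - beta2^step)
        params[[k]] <- params[[k]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      model <- set_params(model, params)
    }
    val_prob <- rnn_forward_pass(model, val_set$X)
    val_loss <- bce_loss(val_prob, val_set$y)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    epochs_executed <- epoch
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model <- set_params(model, best_params)
  structure(list(model = model, history = history,
                 epochs_requested = hp$epochs,
                 epochs_executed = epochs_executed,
                 patience = patience, best_epoch = best_epoch,
                 best_val_loss = best_val),
            class = "training_run")
}

#' Early-stopping patience for a requested epoch budget
#'
#' One-third of the requested epochs, rounded up.
#'
#' @param epochs Requested epochs.
#' @return Integer patience.
#' @export
early_stopping_patience <- function(epochs) as.integer(ceiling(epochs / 3))

#' Predict binary anomaly labels
#'
#' @param object A trained `rnn_model`.
#' @param windows Window matrix or single window vector.
#' @param threshold Decision threshold; label 1 (anomalous) iff probability
#'   `>= threshold`.
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.rnn_model <- function(object, windows, threshold = 0.5, ...) {
  as.integer(rnn_forward(object, windows) >= threshold)
}
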