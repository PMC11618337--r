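# A small multilayer perceptron for tabular binary classification, written
# in base R matrix code: four fully connected layers with three batch
# normalizations and three leaky-ReLU activations, a sigmoid output,
# binary cross-entropy loss and ADAM. The learning rate starts at 1e-5 and
# drops permanently to 1e-6 once training accuracy reaches 95% (evaluated
# per epoch); training runs 200 epochs and the parameter state at the
# lowest validation loss is retained.

#' MLP architecture and training schedule
#'
#' @param input_dim Number of input features (default 9).
#' @param hidden Widths of the three hidden layers (default 64, 32, 16).
#' @param leaky_slope Negative-side slope of the leaky ReLU (default 0.01).
#' @param lr_initial,lr_reduced Learning rates before/after the switch
#'   (defaults 1e-5 and 1e-6).
#' @param lr_switch_train_accuracy Training accuracy (per epoch, evaluation
#'   mode) at which the learning rate drops permanently (default 0.95).
#' @param epochs Training epochs (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param bn_momentum,bn_eps Batch-norm running-average momentum and
#'   variance epsilon.
#' @return A list of class \code{reachkin_mlp_spec}.
#' @export
mlp_spec <- function(input_dim = 9, hidden = c(64, 32, 16), leaky_slope = 0.01,
                     lr_initial = 1e-5, lr_reduced = 1e-6,
                     lr_switch_train_accuracy = 0.95, epochs = 200,
                     batch_size = 32, bn_momentum = 0.1, bn_eps = 1e-5) {
  if (length(hidden) != 3) stopf("the architecture uses exactly 3 hidden layers")
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 leaky_slope = leaky_slope, lr_initial = lr_initial,
                 lr_reduced = lr_reduced,
                 lr_switch_train_accuracy = lr_switch_train_accuracy,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 output_activation = "sigmoid"),
            class = "reachkin_mlp_spec")
}

# He-normal hidden weights; zero output layer. A zero-initialized output
# layer puts the initial decision exactly at chance, so with the very small
# learning rates of the schedule the decision boundary moves only in the
# learned direction - sign-correct classification does not require large
# logits.
mlp_init <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden)
  W <- vector("list", 4L)
  for (l in 1:3) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
  }
  W[[4]] <- matrix(0, dims[4], 1)
  bn <- lapply(1:3, function(l) list(
    gamma = rep(1, dims[l + 1]), beta = rep(0, dims[l + 1]),
    run_mean = rep(0, dims[l + 1]), run_var = rep(1, dims[l + 1])))
  list(W = W, b_out = 0, bn = bn)
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward pass. training = TRUE uses batch statistics and returns a cache
# for backprop while updating running statistics in place (returned).
mlp_forward <- function(params, X, spec, training = FALSE) {
  A <- X
  cache <- list(A0 = X)
  for (l in 1:3) {
    Z <- A %*% params$W[[l]]
    bnl <- params$bn[[l]]
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
      bnl$run_mean <- (1 - spec$bn_momentum) * bnl$run_mean + spec$bn_momentum * mu
      bnl$run_var <- (1 - spec$bn_momentum) * bnl$run_var + spec$bn_momentum * v
      params$bn[[l]] <- bnl
    } else {
      mu <- bnl$run_mean
      v <- bnl$run_var
    }
    invstd <- 1 / sqrt(v + spec$bn_eps)
    Xhat <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
    B <- sweep(sweep(Xhat, 2, bnl$gamma, "*"), 2, bnl$beta, "+")
    Anew <- leaky(B, spec$leaky_slope)
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("Xhat", l)]] <- Xhat
    cache[[paste0("invstd", l)]] <- invstd
    cache[[paste0("B", l)]] <- B
    cache[[paste0("A", l)]] <- Anew
    A <- Anew
  }
  logits <- A %*% params$W[[4]] + params$b_out
  p <- sigmoid(logits)
  list(p = as.numeric(p), logits = as.numeric(logits), cache = cache,
       params = params)
}

# Backprop for one mini-batch; returns gradients with the params layout.
mlp_backward <- function(params, cache, p, y, spec) {
  m <- length(y)
  g <- list(W = vector("list", 4L), b_out = 0,
            bn = lapply(1:3, function(l) list(gamma = NULL, beta = NULL)))
  dlogits <- matrix((p - y) / m, m, 1)
  A3 <- cache$A3
  g$W[[4]] <- crossprod(A3, dlogits)
  g$b_out <- sum(dlogits)
  dA <- dlogits %*% t(params$W[[4]])
  for (l in 3:1) {
    B <- cache[[paste0("B", l)]]
    dB <- dA * ifelse(B > 0, 1, spec$leaky_slope)
    Xhat <- cache[[paste0("Xhat", l)]]
    invstd <- cache[[paste0("invstd", l)]]
    gamma <- params$bn[[l]]$gamma
    g$bn[[l]]$gamma <- colSums(dB * Xhat)
    g$bn[[l]]$beta <- colSums(dB)
    dXhat <- sweep(dB, 2, gamma, "*")
    s1 <- colSums(dXhat)
    s2 <- colSums(dXhat * Xhat)
    dZ <- sweep(dXhat * m - matrix(s1, m, length(s1), byrow = TRUE) -
                  sweep(Xhat, 2, s2, "*"),
                2, invstd / m, "*")
    Aprev <- cache[[paste0("A", l - 1)]]
    g$W[[l]] <- crossprod(Aprev, dZ)
    if (l > 1) dA <- dZ %*% t(params$W[[l]])
  }
  g
}

adam_state_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else x * 0
  list(m = rapply(params, zero_like, how = "replace"),
       v = rapply(params, zero_like, how = "replace"), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(theta, gr, m, v) {
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    theta <- theta - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(theta = theta, m = m, v = v)
  }
  for (l in 1:4) {
    r <- upd(params$W[[l]], grads$W[[l]], state$m$W[[l]], state$v$W[[l]])
    params$W[[l]] <- r$theta; state$m$W[[l]] <- r$m; state$v$W[[l]] <- r$v
  }
  r <- upd(params$b_out, grads$b_out, state$m$b_out, state$v$b_out)
  params$b_out <- r$theta; state$m$b_out <- r$m; state$v$b_out <- r$v
  for (l in 1:3) {
    for (nm in c("gamma", "beta")) {
      r <- upd(params$bn[[l]][[nm]], grads$bn[[l]][[nm]],
               state$m$bn[[l]][[nm]], state$v$bn[[l]][[nm]])
      params$bn[[l]][[nm]] <- r$theta
      state$m$bn[[l]][[nm]] <- r$m; state$v$bn[[l]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

# Mini-batch index splits; a trailing singleton is merged into the previous
# batch because batch statistics need at least 2 rows.
batch_splits <- function(n, batch_size) {
  idx <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  out <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  k <- length(out)
  if (k > 1 && length(out[[k]]) < 2) {
    out[[k - 1]] <- c(out[[k - 1]], out[[k]])
    out[[k]] <- NULL
  }
  out
}

#' Train the MLP on one train/validation split
#'
#' Mini-batch ADAM training for the configured number of epochs; after any
#' epoch whose training accuracy (evaluation mode) reaches the switch
#' threshold the learning rate drops permanently to the reduced value.
#' Validation binary cross-entropy is evaluated each epoch and the
#' parameter state at the minimum is retained as \code{best}.
#' Deterministic under \code{seed}.
#'
#' @param X_train,y_train Training matrix (rows = samples) and 0/1 labels;
#'   both classes must be present.
#' @param X_val,y_val Validation split.
#' @param spec A \code{\link{mlp_spec}}.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return Object of class \code{reachkin_mlp}: \code{spec}, \code{params}
#'   (final), \code{best} (parameters at the lowest validation loss),
#'   \code{best_val_loss}, \code{best_epoch} and a per-epoch \code{history}
#'   (train_loss, train_accuracy, val_loss, lr).
#' @export
train_mlp <- function(X_train, y_train, X_val, y_val, spec = mlp_spec(),
                      seed = 1) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2)
    stopf("training set must contain both classes")
  if (ncol(X_train) != spec$input_dim)
    stopf("spec expects %d input features, got %d", spec$input_dim, ncol(X_train))
  with_seed(seed, {
    params <- mlp_init(spec)
    state <- adam_state_init(params)
    lr <- spec$lr_initial
    n <- nrow(X_train)
    hist <- data.frame(epoch = seq_len(spec$epochs), train_loss = NA_real_,
                       train_accuracy = NA_real_, val_loss = NA_real_,
                       lr = NA_real_)
    best_val <- Inf
    best_params <- params
    best_epoch <- NA_integer_
    for (ep in seq_len(spec$epochs)) {
      for (bi in batch_splits(n, spec$batch_size)) {
        fw <- mlp_forward(params, X_train[bi, , drop = FALSE], spec,
                          training = TRUE)
        params <- fw$params          # running BN stats updated
        grads <- mlp_backward(params, fw$cache, fw$p, y_train[bi], spec)
        au <- adam_update(params, grads, state, lr)
        params <- au$params; state <- au$state
      }
      tr <- mlp_forward(params, X_train, spec, training = FALSE)
      train_loss <- bce_loss(tr$p, y_train)
      train_acc <- mean((tr$p > 0.5) == (y_train == 1))
      vl <- bce_loss(mlp_forward(params, X_val, spec, training = FALSE)$p, y_val)
      hist$train_loss[ep] <- train_loss
      hist$train_accuracy[ep] <- train_acc
      hist$val_loss[ep] <- vl
      hist$lr[ep] <- lr
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_epoch <- ep
      }
      if (train_acc >= spec$lr_switch_train_accuracy) lr <- spec$lr_reduced
    }
    structure(list(spec = spec, params = params, best = best_params,
                   best_val_loss = best_val, best_epoch = best_epoch,
                   history = hist, seed = seed),
              class = "reachkin_mlp")
  })
}

#' Predict with a trained MLP
#'
#' Uses the parameter state at the lowest validation loss (evaluation mode:
#' batch norm with running statistics).
#'
#' @param object A \code{\link{train_mlp}} result.
#' @param newdata Feature matrix.
#' @param type \code{"prob"} (default) or \code{"class"} (0.5 threshold).
#' @param ... Unused.
#' @return Numeric vector of probabilities or 0/1 labels.
#' @export
predict.reachkin_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object$best, as.matrix(newdata), object$spec,
                   training = FALSE)$p
  if (type == "class") as.integer(p > 0.5) else p
}

#' Structural audit of a built MLP
#'
#' Counts the network's components from the parameter structure itself
#' (not from the spec): fully connected layers, batch-norm layers,
#' leaky-ReLU activations and sigmoid outputs.
#'
#' @param model A \code{\link{train_mlp}} result (or an initialized
#'   parameter set with a spec attached).
#' @return Named list: n_linear, n_batchnorm, n_leaky_relu, n_sigmoid.
#' @export
mlp_audit <- function(model) {
  params <- model$params
  n_linear <- sum(vapply(params$W, is.matrix, logical(1)))
  n_bn <- sum(vapply(params$bn, function(b)
    !is.null(b$gamma) && !is.null(b$beta), logical(1)))
  # activations: one leaky ReLU after each batch-normed hidden layer
  n_leaky <- n_bn
  n_sig <- as.integer(identical(model$spec$output_activation, "sigmoid"))
  list(n_linear = n_linear, n_batchnorm = n_bn, n_leaky_relu = n_leaky,
       n_sigmoid = n_sig)
}

#' @export
print.reachkin_mlp <- function(x, ...) {
  a <- mlp_audit(x)
  cat(sprintf("<reachkin_mlp> %d-%s-1, %d FC / %d BN / %d leakyReLU / %d sigmoid; best val loss %.4f @ epoch %s\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = "-"),
              a$n_linear, a$n_batchnorm, a$n_leaky_relu, a$n_sigmoid,
              x$best_val_loss, x$best_epoch))
  invisible(x)
}
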