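## Fixed-architecture feed-forward classifier: 3 hidden layers of 300 ReLU
## units, 2-unit softmax output, trained with AdamW and early stopping.
## Written directly in base R matrix code.

#' Network architecture specification
#'
#' @param input_dim number of input features.
#' @param width hidden-layer width (default 300).
#' @param depth number of hidden layers (default 3).
#' @param classes output classes (default 2, softmax).
#' @return list of class `"network_spec"`.
#' @export
network_spec <- function(input_dim, width = 300L, depth = 3L, classes = 2L) {
  stopifnot(input_dim >= 1, width >= 1, depth >= 1, classes >= 2)
  structure(list(input_dim = as.integer(input_dim), width = as.integer(width),
                 depth = as.integer(depth), classes = as.integer(classes)),
            class = "network_spec")
}

#' Trainable parameter count of the network
#'
#' Weights plus biases: `d*w + w` for the input layer, `(depth-1)*(w^2 + w)`
#' for the hidden-to-hidden layers, and `w*classes + classes` for the output
#' layer. For the default architecture and `d = 10` this is 184,502.
#'
#' @param input_dim input dimension `d`.
#' @param width,depth,classes architecture (defaults 300/3/2).
#' @return integer parameter count.
#' @export
mlp_param_count <- function(input_dim, width = 300L, depth = 3L,
                            classes = 2L) {
  input_dim * width + width +
    (depth - 1L) * (width * width + width) +
    width * classes + classes
}

#' Training configuration for the network
#'
#' @param max_epochs maximum epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param patience early-stopping patience on validation loss (default 3).
#' @param weight_decay decoupled AdamW weight decay (default 0.01; weights
#'   only, biases undecayed).
#' @param epsilon Adam denominator stabilizer.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(max_epochs = 100L, batch_size = 32L, patience = 3L,
                         weight_decay = 0.01, epsilon = 1e-8) {
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, epsilon = epsilon),
            class = "train_config")
}

mlp_init <- function(spec) {
  dims <- c(spec$input_dim, rep(spec$width, spec$depth), spec$classes)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L]) *
                       sqrt(2 / dims[l]), dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(params, X, keep_hidden = FALSE) {
  L <- length(params$W)
  A <- X
  hidden <- if (keep_hidden) vector("list", L - 1L) else NULL
  for (l in seq_len(L - 1L)) {
    A <- pmax(sweep(A %*% params$W[[l]], 2, params$b[[l]], "+"), 0)
    if (keep_hidden) hidden[[l]] <- A
  }
  Z <- sweep(A %*% params$W[[L]], 2, params$b[[L]], "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(probs = P, hidden = hidden)
}

mlp_loss <- function(P, y, eps = 1e-12) {
  # y in {0,1}; column 2 of P is the class-1 probability
  p_true <- ifelse(y == 1L, P[, 2], P[, 1])
  -mean(log(pmax(p_true, eps)))
}

mlp_backward <- function(params, X, y, fw) {
  L <- length(params$W)
  n <- nrow(X)
  Y <- cbind(1 - y, y)
  dZ <- (fw$probs - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- if (l == 1L) X else fw$hidden[[l - 1L]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, params$W[[l]])
      dZ <- dA * (fw$hidden[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adamw_step <- function(params, grads, state, lr, beta1, beta2, wd, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * ((state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps) +
              wd * params$W[[l]])
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the network with AdamW and early stopping
#'
#' Minibatch training of the fixed-architecture feed-forward classifier with
#' the AdamW optimizer (decoupled weight decay); training stops when the
#' validation loss fails to improve for `patience` consecutive epochs or at
#' `max_epochs`, and the weights from the best-validation epoch are returned.
#'
#' @param x_train,y_train training rows (features scaled to `[0, 1]`, labels
#'   0/1).
#' @param x_val,y_val validation rows monitored for early stopping.
#' @param hyper named vector with `learning_rate`, `beta1`, `beta2`.
#' @param spec a [network_spec()]; defaults to 3x300 on `ncol(x_train)`.
#' @param config a [train_config()].
#' @param seed integer seed for initialization and batch shuffling.
#' @return list of class `"mlp_model"`: `params`, `spec`, `features`,
#'   `val_loss`, `val_loglik`, `epochs_run`, `best_epoch`.
#' @export
train_network <- function(x_train, y_train, x_val, y_val, hyper,
                          spec = NULL, config = train_config(), seed = 1L) {
  stopifnot(is.matrix(x_train), is.matrix(x_val))
  if (is.null(spec)) spec <- network_spec(ncol(x_train))
  lr <- hyper[["learning_rate"]]; b1 <- hyper[["beta1"]]; b2 <- hyper[["beta2"]]
  set.seed(seed)
  params <- mlp_init(spec)
  zeros <- function(tmpl) lapply(tmpl, function(m) m * 0)
  state <- list(mW = zeros(params$W), vW = zeros(params$W),
                mb = zeros(params$b), vb = zeros(params$b), t = 0L)
  n <- nrow(x_train)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + config$batch_size - 1L, n)]
      Xb <- x_train[rows, , drop = FALSE]
      yb <- y_train[rows]
      fw <- mlp_forward(params, Xb, keep_hidden = TRUE)
      gr <- mlp_backward(params, Xb, yb, fw)
      upd <- adamw_step(params, gr, state, lr, b1, b2,
                        config$weight_decay, config$epsilon)
      params <- upd$params; state <- upd$state
    }
    val_probs <- mlp_forward(params, x_val)$probs
    vl <- mlp_loss(val_probs, y_val)
    if (!is.finite(vl))
      stopf("non-finite validation loss (lr=%.3g, beta1=%.4g, beta2=%.4g)",
            lr, b1, b2)
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  P <- mlp_forward(best$params, x_val)$probs
  p_true <- ifelse(y_val == 1L, P[, 2], P[, 1])
  structure(list(params = best$params, spec = spec,
                 features = colnames(x_train),
                 val_loss = best$loss,
                 val_loglik = sum(log(pmax(p_true, 1e-12))),
                 epochs_run = epoch, best_epoch = best$epoch),
            class = "mlp_model")
}

#' Predicted class-1 probabilities
#'
#' @param model an `"mlp_model"`.
#' @param x matrix containing (at least) the model's features by name.
#' @return numeric vector of class-1 probabilities.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.null(model$features)) {
    missing <- setdiff(model$features, colnames(x))
    if (length(missing))
      stopf("input lacks model features: %s", paste(missing, collapse = ", "))
    x <- x[, model$features, drop = FALSE]
  }
  mlp_forward(model$params, x)$probs[, 2]
}

#' Threshold probabilities into class labels
#'
#' @param probs class-1 probabilities.
#' @param threshold decision threshold; label 1 iff probability `>=`
#'   threshold (default 0.5).
#' @return integer 0/1 labels.
#' @export
classify <- function(probs, threshold = 0.5) as.integer(probs >= threshold)

#' @export
predict.mlp_model <- function(object, newdata,
                              type = c("prob", "class"), threshold = 0.5,
                              ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else classify(p, threshold)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Feed-forward classifier: %d-%s-%d (ReLU, softmax), %s parameters\n",
              x$spec$input_dim,
              paste(rep(x$spec$width, x$spec$depth), collapse = "-"),
              x$spec$classes,
              format(mlp_param_count(x$spec$input_dim, x$spec$width,
                                     x$spec$depth, x$spec$classes),
                     big.mark = ",")))
  cat(sprintf("  validation loss %.4f at epoch %d (of %d run)\n",
              x$val_loss, x$best_epoch, x$epochs_run))
  invisible(x)
}
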