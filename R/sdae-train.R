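#' Training configuration for the stacked denoising autoencoder
#'
#' Defaults reflect the study protocol for 28x28 ROIs: two encoding layers
#' of 256 and 64 units, full-batch gradient descent at rate 0.5 for 3000
#' pretraining epochs per layer and 4000 fine-tuning epochs, masking
#' corruption at level 0.3, and a cross-entropy fine-tuning loss (squared
#' error available as an option). Full-batch descent performs one update
#' per epoch, so these epoch counts are necessarily much larger than
#' minibatch practice would suggest (3000 full-batch updates per layer is
#' an order of magnitude fewer parameter updates than common minibatch
#' SDAE schedules); with substantially fewer updates the features carry
#' too little between-sample variance for the zero-initialized head to
#' exploit, and training stalls at the majority class.
#'
#' @param hidden_sizes Integer vector of layer widths, length `L >= 1`.
#' @param alpha Learning rate `> 0` for both phases.
#' @param epochs_pretrain,epochs_finetune Nonnegative epoch counts.
#' @param corruption A [corruption_spec()].
#' @param finetune_loss `"cross_entropy"` or `"squared_error"`.
#' @param seed Integer seed; all randomness (weight initialization and
#'   per-epoch corruption resampling) flows through one stream seeded here.
#' @return A list of class `sdae_config`.
#' @export
sdae_config <- function(hidden_sizes = c(256, 64), alpha = 0.5,
                        epochs_pretrain = 3000, epochs_finetune = 4000,
                        corruption = corruption_spec("masking", 0.3),
                        finetune_loss = c("cross_entropy", "squared_error"),
                        seed = 1L) {
  finetune_loss <- match.arg(finetune_loss)
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            alpha > 0, epochs_pretrain >= 0, epochs_finetune >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes), alpha = alpha,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 corruption = corruption, finetune_loss = finetune_loss,
                 seed = as.integer(seed)),
            class = "sdae_config")
}

# Glorot-style uniform init keeps sigmoid pre-activations in the linear
# regime at the start of training.
init_dae_layer <- function(n_visible, n_hidden) {
  r <- sqrt(6 / (n_visible + n_hidden))
  dae_layer(matrix(stats::runif(n_hidden * n_visible, -r, r),
                   n_hidden, n_visible),
            rep(0, n_hidden), rep(0, n_visible))
}

#' Pretrain one DAE layer by full-batch gradient descent
#'
#' Initializes `W ~ Uniform(-r, r)` with `r = sqrt(6/(n_visible +
#' n_hidden))` and zero biases, then for each epoch corrupts the batch
#' afresh, reconstructs, and applies one full-batch update
#' `w <- w - alpha * dE/dw`. The reconstruction error recorded at each
#' epoch is evaluated before that epoch's update; the post-training error
#' is appended as the final trace entry.
#'
#' @param data Batch matrix, `n x n_visible` (rows are samples).
#' @param n_hidden Hidden width.
#' @param config An [sdae_config()]; uses `alpha`, `epochs_pretrain`,
#'   `corruption`.
#' @param seed If non-`NULL`, `set.seed(seed)` first. [pretrain_stack()]
#'   passes `NULL` so all layers share one stream.
#' @return A `dae_layer` with attribute `"trace"` (numeric vector of
#'   length `epochs_pretrain + 1`).
#' @export
pretrain_layer <- function(data, n_hidden, config, seed = config$seed) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty training batch", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  layer <- init_dae_layer(ncol(data), n_hidden)
  init_sum <- sum(layer$W)
  trace <- numeric(config$epochs_pretrain + 1)
  for (ep in seq_len(config$epochs_pretrain)) {
    xt <- corrupt(data, config$corruption)
    g <- dae_gradients(layer, data, xt)
    if (!is.finite(g$loss))
      stop(sprintf("pretraining diverged at epoch %d (non-finite loss); reduce alpha",
                   ep), call. = FALSE)
    trace[ep] <- g$loss
    layer$W <- layer$W - config$alpha * g$dW
    layer$b <- layer$b - config$alpha * g$db
    layer$b_prime <- layer$b_prime - config$alpha * g$db_prime
  }
  xr <- decode(layer, encode(layer, data))
  if (is.null(dim(xr))) xr <- matrix(xr, 1)
  trace[config$epochs_pretrain + 1] <- mean(0.5 * rowSums((data - xr)^2))
  attr(layer, "trace") <- trace
  attr(layer, "init_sum") <- init_sum
  layer
}

#' Greedy layer-wise pretraining of the encoder stack
#'
#' Trains the first DAE on the data, then propagates the *clean* (never
#' corrupted) encodings through the trained layer and trains the next DAE
#' on them, and so on. The returned model keeps only the encoders — the
#' decoder biases are used during pretraining and then dropped — plus an
#' all-zero logistic-regression head awaiting [finetune()].
#'
#' @param data Batch matrix, `n x n_visible`.
#' @param config An [sdae_config()].
#' @return An object of class `sdae`: `layers` (encoder `W`, `b` per
#'   layer), `v`/`c` (zero head), `n_visible`, `hidden_sizes`, `config`,
#'   `pretrain_traces`, and `init_checksum` (sum of all initial weights,
#'   for verifying that two runs started identically).
#' @export
pretrain_stack <- function(data, config) {
  data <- as.matrix(data)
  set.seed(config$seed)
  layers <- vector("list", length(config$hidden_sizes))
  traces <- vector("list", length(config$hidden_sizes))
  z <- data
  checksum <- 0
  for (k in seq_along(config$hidden_sizes)) {
    layer <- pretrain_layer(z, config$hidden_sizes[k], config, seed = NULL)
    checksum <- checksum + attr(layer, "init_sum")
    traces[[k]] <- attr(layer, "trace")
    layers[[k]] <- layer
    z <- encode(layer, z)
    if (is.null(dim(z))) z <- matrix(z, 1)
  }
  top <- config$hidden_sizes[length(config$hidden_sizes)]
  structure(list(layers = lapply(layers, function(l) list(W = l$W, b = l$b)),
                 v = rep(0, top), c = 0,
                 n_visible = ncol(data),
                 hidden_sizes = config$hidden_sizes,
                 config = config,
                 pretrain_traces = traces,
                 finetune_trace = numeric(0),
                 init_checksum = checksum),
            class = "sdae")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 17 significant digits round-trip IEEE doubles exactly through text.
num_encode <- function(x) sprintf("%.17g", as.vector(x))

# Forward pass through all encoder layers; returns list of activations
# Z^0 .. Z^L (each n x width).
sdae_forward <- function(model, x) {
  x <- rbind_batch(x, model$n_visible, "sdae forward")
  acts <- vector("list", length(model$layers) + 1)
  acts[[1]] <- x
  for (k in seq_along(model$layers)) {
    l <- model$layers[[k]]
    acts[[k + 1]] <- sigmoid(sweep(acts[[k]] %*% t(l$W), 2, l$b, `+`))
  }
  acts
}

# Loss and gradients of the full network (encoders + sigmoid LR head) on a
# batch; reduction is the batch mean.
sdae_head_gradients <- function(model, x, labels, loss) {
  acts <- sdae_forward(model, x)
  n <- nrow(acts[[1]])
  zl <- acts[[length(acts)]]
  logits <- drop(zl %*% model$v) + model$c
  y <- sigmoid(logits)
  if (loss == "cross_entropy") {
    yc <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    loss_val <- -mean(labels * log(yc) + (1 - labels) * log(1 - yc))
    dlogit <- (y - labels) / n
  } else {
    loss_val <- mean(0.5 * (labels - y)^2)
    dlogit <- (y - labels) * y * (1 - y) / n
  }
  grads <- list(v = drop(t(zl) %*% dlogit), c = sum(dlogit),
                layers = vector("list", length(model$layers)))
  delta <- (dlogit %*% t(model$v)) * zl * (1 - zl)
  for (k in rev(seq_along(model$layers))) {
    grads$layers[[k]] <- list(dW = t(delta) %*% acts[[k]],
                              db = colSums(delta))
    if (k > 1) {
      zk <- acts[[k]]
      delta <- (delta %*% model$layers[[k]]$W) * zk * (1 - zk)
    }
  }
  list(loss = loss_val, grads = grads, prob = y)
}

#' Supervised fine-tuning of the pretrained stack
#'
#' Adds label information: the sigmoid head probability
#' `S(v . Z^L + c)` is trained against binary labels (1 = malignant) by
#' full-batch backpropagation through the head and every encoder layer,
#' `epochs_finetune` steps starting at rate `alpha`. The head starts at
#' zero, so with `epochs_finetune = 0` every prediction is exactly 0.5.
#'
#' The step size follows the classic bold-driver schedule for full-batch
#' descent: after an epoch whose loss decreased the rate grows by 5%
#' (capped at 10x the initial rate); after an epoch whose loss increased
#' the update is rolled back and the rate halved. A fixed rate large
#' enough to make progress in a reasonable number of full-batch updates
#' otherwise destabilizes late in training, once the growing weights
#' sharpen the loss surface: runs can descend to a small loss and then
#' oscillate back to an untrained state. The schedule is deterministic,
#' so seeded reproducibility is unaffected.
#'
#' @param model An `sdae` from [pretrain_stack()].
#' @param data Batch matrix, `n x n_visible`.
#' @param labels Numeric/integer vector in `{0, 1}` (1 = malignant).
#' @param config An [sdae_config()]; uses `alpha`, `epochs_finetune`,
#'   `finetune_loss`.
#' @return The fine-tuned `sdae`, with `finetune_trace` holding the
#'   per-epoch loss (evaluated before each update).
#' @export
finetune <- function(model, data, labels, config = model$config) {
  data <- rbind_batch(as.matrix(data), model$n_visible, "finetune")
  labels <- as.numeric(labels)
  if (length(labels) != nrow(data))
    stop("labels length must match batch size", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 (benign) or 1 (malignant)", call. = FALSE)
  trace <- numeric(config$epochs_finetune)
  alpha <- config$alpha
  prev <- NULL  # last accepted state: list(model, loss, grads)
  for (ep in seq_len(config$epochs_finetune)) {
    hg <- sdae_head_gradients(model, data, labels, config$finetune_loss)
    if (!is.finite(hg$loss))
      stop(sprintf("fine-tuning diverged at epoch %d (non-finite loss); reduce alpha",
                   ep), call. = FALSE)
    if (!is.null(prev) && hg$loss > prev$loss) {
      # bold driver: roll back the oversized step and halve the rate
      model <- prev$model
      hg <- prev$grads
      alpha <- alpha / 2
    } else {
      prev <- list(model = model, loss = hg$loss, grads = hg)
      alpha <- min(alpha * 1.05, 10 * config$alpha)
    }
    trace[ep] <- prev$loss
    model$v <- model$v - alpha * hg$grads$v
    model$c <- model$c - alpha * hg$grads$c
    for (k in seq_along(model$layers)) {
      model$layers[[k]]$W <- model$layers[[k]]$W -
        alpha * hg$grads$layers[[k]]$dW
      model$layers[[k]]$b <- model$layers[[k]]$b -
        alpha * hg$grads$layers[[k]]$db
    }
  }
  if (!is.null(prev)) {
    # end on the last accepted state, not a trial step
    hg_final <- sdae_head_gradients(model, data, labels,
                                    config$finetune_loss)
    if (!is.finite(hg_final$loss) || hg_final$loss > prev$loss)
      model <- prev$model
  }
  model$finetune_trace <- trace
  model
}

#' Train an SDAE classifier end to end
#'
#' Convenience wrapper: seeds the stream, pretrains the stack greedily,
#' then fine-tunes with the labels.
#'
#' @inheritParams finetune
#' @param config An [sdae_config()].
#' @return A trained `sdae`.
#' @export
train_sdae <- function(data, labels, config) {
  model <- pretrain_stack(data, config)
  finetune(model, data, labels, config)
}

#' Predict malignancy probability and hard label
#'
#' @param object A trained `sdae`.
#' @param x Input vector (length `n_visible`) or batch matrix.
#' @param ... Unused.
#' @return A data.frame with columns `prob` (in (0, 1)) and `label`
#'   (1 = malignant iff `prob >= 0.5`; ties go to malignant).
#' @export
predict.sdae <- function(object, x, ...) {
  acts <- sdae_forward(object, x)
  prob <- drop(sigmoid(drop(acts[[length(acts)]] %*% object$v) + object$c))
  data.frame(prob = prob, label = as.integer(prob >= 0.5))
}

#' @export
print.sdae <- function(x, ...) {
  cat(sprintf("<sdae %s head %s; %s>\n",
              paste(c(x$n_visible, x$hidden_sizes), collapse = "-"),
              if (all(x$v == 0) && x$c == 0) "untrained" else "trained",
              if (length(x$finetune_trace))
                sprintf("final finetune loss %.4g",
                        x$finetune_trace[length(x$finetune_trace)])
              else "not fine-tuned"))
  invisible(x)
}

#' Save / load an SDAE model archive
#'
#' One JSON file holding every numeric array (`W`, `b` per layer, head `v`
#' and `c`) plus a metadata block (sizes, training configuration, format
#' version). Array values are written as decimal strings with 17
#' significant digits, so the round trip reproduces every IEEE double
#' bit for bit.
#'
#' @param model A trained or pretrained `sdae`.
#' @param path Destination file.
#' @return `save_sdae`: `path` invisibly. `load_sdae`: the restored `sdae`.
#' @export
save_sdae <- function(model, path) {
  cfg <- unclass(model$config)
  cfg$corruption <- unclass(cfg$corruption)
  payload <- list(
    format = "sonodae-sdae/1",
    n_visible = model$n_visible,
    hidden_sizes = model$hidden_sizes,
    config = cfg,
    layers = stats::setNames(
      lapply(model$layers, function(l)
        list(W = num_encode(l$W), n_hidden = nrow(l$W),
             n_visible = ncol(l$W), b = num_encode(l$b))),
      paste0("layer_", seq_along(model$layers))),
    v = num_encode(model$v), c = num_encode(model$c),
    finetune_trace = num_encode(model$finetune_trace))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_sdae
#' @export
load_sdae <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sonodae-sdae/1"))
    stop("not a recognized model archive: ", path, call. = FALSE)
  cfg <- p$config
  config <- sdae_config(hidden_sizes = cfg$hidden_sizes, alpha = cfg$alpha,
                        epochs_pretrain = cfg$epochs_pretrain,
                        epochs_finetune = cfg$epochs_finetune,
                        corruption = corruption_spec(cfg$corruption$kind,
                                                     cfg$corruption$level),
                        finetune_loss = cfg$finetune_loss, seed = cfg$seed)
  layers <- lapply(p$layers, function(l)
    list(W = matrix(as.numeric(l$W), l$n_hidden, l$n_visible),
         b = as.numeric(l$b)))
  names(layers) <- NULL
  structure(list(layers = layers, v = as.numeric(p$v), c = as.numeric(p$c),
                 n_visible = p$n_visible, hidden_sizes = p$hidden_sizes,
                 config = config, pretrain_traces = NULL,
                 finetune_trace = as.numeric(p$finetune_trace %||%
                                               character(0))),
            class = "sdae")
}
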