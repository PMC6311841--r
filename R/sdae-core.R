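#' Numerically stable logistic sigmoid
#'
#' `S(t) = 1 / (1 + exp(-t))`, evaluated branch-wise so that no
#' intermediate overflows even for |t| in the hundreds; satisfies
#' `S(-t) = 1 - S(t)` to machine precision.
#'
#' @param t Numeric vector or matrix of finite values.
#' @return Values in (0, 1), same shape as `t`.
#' @examples
#' sigmoid(0)   # 0.5
#' sigmoid(2)   # 0.8807971
#' @export
sigmoid <- function(t) {
  out <- t
  pos <- t >= 0
  out[pos] <- 1 / (1 + exp(-t[pos]))
  et <- exp(t[!pos])
  out[!pos] <- et / (1 + et)
  out
}

#' Corruption specification for denoising training
#'
#' @param kind `"masking"` (inputs independently set to 0) or `"gaussian"`
#'   (i.i.d. additive noise).
#' @param level Masking probability in \[0, 1\], or Gaussian standard
#'   deviation `>= 0`.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(kind = c("masking", "gaussian"), level = 0.3) {
  kind <- match.arg(kind)
  if (kind == "masking" && (level < 0 || level > 1))
    stop("masking level must lie in [0, 1]", call. = FALSE)
  if (kind == "gaussian" && level < 0)
    stop("gaussian level (sd) must be >= 0", call. = FALSE)
  structure(list(kind = kind, level = level), class = "corruption_spec")
}

#' Corrupt a batch of inputs
#'
#' Masking zeroes each entry independently with probability `level`;
#' Gaussian adds i.i.d. `N(0, level^2)` noise. Draws come from R's global
#' RNG stream, so results are deterministic after `set.seed()`.
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @param spec A [corruption_spec()].
#' @return Corrupted copy of `x`, same shape.
#' @export
corrupt <- function(x, spec) {
  if (spec$level == 0 && spec$kind == "masking") return(x)
  if (spec$kind == "masking") {
    keep <- stats::runif(length(x)) >= spec$level
    x * keep
  } else {
    if (spec$level == 0) return(x)
    x + stats::rnorm(length(x), 0, spec$level)
  }
}

#' Build a single tied-weight denoising autoencoder layer
#'
#' @param W Encoder weight matrix, `n_hidden x n_visible`. The decoder
#'   weight is its transpose (tied) and never stored.
#' @param b Encoder bias, length `n_hidden`.
#' @param b_prime Decoder bias, length `n_visible`.
#' @return A list of class `dae_layer`.
#' @export
dae_layer <- function(W, b, b_prime) {
  W <- as.matrix(W)
  stopifnot(length(b) == nrow(W), length(b_prime) == ncol(W),
            all(is.finite(W)), all(is.finite(b)), all(is.finite(b_prime)))
  structure(list(W = W, b = as.numeric(b), b_prime = as.numeric(b_prime)),
            class = "dae_layer")
}

#' Encode a batch through a DAE layer
#'
#' `Z = S(W x + b)` applied row-wise to a batch.
#'
#' @param layer A `dae_layer` (or any list with `W`, `b`).
#' @param x Numeric vector (length `n_visible`) or matrix
#'   (`n x n_visible`).
#' @return Hidden activations, `n x n_hidden` matrix (a vector input
#'   yields a 1-row matrix dropped to a vector).
#' @export
encode <- function(layer, x) {
  vec <- is.null(dim(x))
  x <- rbind_batch(x, ncol(layer$W), "encode")
  z <- sigmoid(sweep(x %*% t(layer$W), 2, layer$b, `+`))
  if (vec) drop(z) else z
}

#' Decode a batch through a tied-weight DAE layer
#'
#' `x' = S(W^T z + b')` with the decoder weight tied to the encoder's
#' transpose.
#'
#' @param layer A `dae_layer`.
#' @param z Hidden vector (length `n_hidden`) or batch matrix.
#' @return Reconstruction, `n x n_visible`.
#' @export
decode <- function(layer, z) {
  vec <- is.null(dim(z))
  z <- rbind_batch(z, nrow(layer$W), "decode")
  xr <- sigmoid(sweep(z %*% layer$W, 2, layer$b_prime, `+`))
  if (vec) drop(xr) else xr
}

rbind_batch <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != width)
    stop(sprintf("%s: input width %d does not match layer width %d",
                 what, ncol(x), width), call. = FALSE)
  x
}

#' Analytic gradients of the DAE reconstruction loss
#'
#' Loss is the batch mean of the squared reconstruction error,
#' `E = (1/n) * sum_d 0.5 * ||x_d - x'_d||^2`, where
#' `x' = S(W^T S(W xt + b) + b')` reconstructs the clean `x` from the
#' corrupted `xt`. Because the decoder weight is tied to `W^T`, the
#' gradient for `W` is the sum of the encoder-path and decoder-path terms.
#'
#' @param layer A `dae_layer`.
#' @param x Clean batch, `n x n_visible`.
#' @param xt Corrupted batch, same shape.
#' @return A list with `dW`, `db`, `db_prime` and the scalar `loss`.
#' @export
dae_gradients <- function(layer, x, xt) {
  x <- rbind_batch(x, ncol(layer$W), "dae_gradients")
  xt <- rbind_batch(xt, ncol(layer$W), "dae_gradients")
  if (nrow(x) == 0) stop("empty batch", call. = FALSE)
  n <- nrow(x)
  z <- encode(layer, xt)
  if (is.null(dim(z))) z <- matrix(z, 1)
  xr <- decode(layer, z)
  if (is.null(dim(xr))) xr <- matrix(xr, 1)

  delta_out <- (xr - x) * xr * (1 - xr) / n          # n x v
  delta_hid <- (delta_out %*% t(layer$W)) * z * (1 - z)  # n x h
  list(dW = t(z) %*% delta_out + t(delta_hid) %*% xt,
       db = colSums(delta_hid),
       db_prime = colSums(delta_out),
       loss = mean(0.5 * rowSums((x - xr)^2)))
}
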