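# Central finite-difference gradient of a scalar function of a numeric
# vector; the independent oracle for all analytic-gradient checks.
numeric_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b), 1e-8)
  max(abs(a - b) / denom)
}

# Flatten / unflatten all parameters of a dae_layer for finite differencing.
layer_to_vec <- function(layer) c(as.vector(layer$W), layer$b, layer$b_prime)
vec_to_layer <- function(v, n_hidden, n_visible) {
  nW <- n_hidden * n_visible
  dae_layer(matrix(v[1:nW], n_hidden, n_visible),
            v[nW + seq_len(n_hidden)],
            v[nW + n_hidden + seq_len(n_visible)])
}

# Reconstruction loss exactly as dae_gradients defines it.
dae_loss <- function(layer, x, xt) {
  xr <- decode(layer, encode(layer, xt))
  if (is.null(dim(xr))) xr <- matrix(xr, 1)
  mean(0.5 * rowSums((x - xr)^2))
}

# Flatten all trainable parameters of an sdae model for finite differencing.
model_to_vec <- function(m)
  c(unlist(lapply(m$layers, function(l) c(as.vector(l$W), l$b))), m$v, m$c)
vec_to_model <- function(v, template) {
  m <- template
  pos <- 0
  for (k in seq_along(m$layers)) {
    l <- m$layers[[k]]
    nW <- length(l$W)
    m$layers[[k]]$W <- matrix(v[pos + seq_len(nW)], nrow(l$W), ncol(l$W))
    pos <- pos + nW
    m$layers[[k]]$b <- v[pos + seq_along(l$b)]
    pos <- pos + length(l$b)
  }
  m$v <- v[pos + seq_along(m$v)]
  m$c <- v[pos + length(m$v) + 1]
  m
}

# A simple noise-free two-level test image: dark left half, bright right.
two_level_image <- function(nr = 8, nc = 8, lo = 0.3, hi = 0.7) {
  cbind(matrix(lo, nr, nc %/% 2), matrix(hi, nr, nc - nc %/% 2))
}
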