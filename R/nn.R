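# Minimal convolutional-network engine.
#
# Feature maps are dense arrays in channel-first layout (C, H, W, N),
# channels fastest. The compute-heavy primitives (im2col + GEMM
# convolution, pooling, batch normalization) run in compiled code
# (src/nn_kernels.cpp); composition, activations and dense layers stay in
# R. Backward passes are hand-derived and checked against finite
# differences in the test suite. Trainable parameters live in a flat named
# list so SGD updates, momentum buffers and best-epoch snapshots are plain
# vectorized list operations.

he_uniform <- function(fan_in, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- convolution ------------------------------------------------------------

conv_spec <- function(in_hw, cin, cout, k, stride, pad, name, bias = TRUE) {
  H <- in_hw[1L]; W <- in_hw[2L]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  # a convolution feeding batch norm gets no bias: BN's mean subtraction
  # makes that bias's gradient identically zero
  list(kind = "conv", k = k, s = stride, p = pad, cin = cin, cout = cout,
       H = H, W = W, Ho = Ho, Wo = Wo,
       wname = paste0(name, ".W"),
       bname = if (bias) paste0(name, ".b") else NULL)
}

conv_init <- function(spec) {
  fan_in <- spec$k * spec$k * spec$cin
  par <- list(he_uniform(fan_in, c(spec$cout, spec$k * spec$k * spec$cin)))
  names(par) <- spec$wname
  if (!is.null(spec$bname)) {
    par[[spec$bname]] <- numeric(spec$cout)
  }
  par
}

conv_forward <- function(spec, par, X, keep = TRUE) {
  b <- if (is.null(spec$bname)) numeric(0) else par[[spec$bname]]
  out <- nn_conv_fwd(X, dim(X), par[[spec$wname]], b,
                     spec$k, spec$s, spec$p)
  list(out = out, cache = if (keep) X else NULL)
}

conv_backward <- function(spec, par, cache, dOut) {
  r <- nn_conv_bwd(cache, dim(cache), par[[spec$wname]], dOut,
                   spec$k, spec$s, spec$p, !is.null(spec$bname))
  grads <- list()
  grads[[spec$wname]] <- r$dW
  if (!is.null(spec$bname)) grads[[spec$bname]] <- r$db
  list(dX = r$dx, grads = grads)
}

# ---- batch normalization ----------------------------------------------------

bn_spec <- function(C, name) {
  list(kind = "bn", C = C, gname = paste0(name, ".gamma"),
       bname = paste0(name, ".beta"), sname = name, eps = 1e-5,
       momentum = 0.1)
}

bn_init <- function(spec) {
  par <- list(rep(1, spec$C), rep(0, spec$C))
  names(par) <- c(spec$gname, spec$bname)
  par
}

bn_forward <- function(spec, par, bn_env, X, train, keep = TRUE) {
  d <- dim(X)
  st <- bn_env[[spec$sname]]
  if (is.null(st)) st <- list(mean = numeric(spec$C), var = rep(1, spec$C))
  r <- nn_bn_fwd(X, spec$C, par[[spec$gname]], par[[spec$bname]],
                 st$mean, st$var, spec$eps, train)
  out <- r$y
  dim(out) <- d
  cache <- NULL
  if (train) {
    mom <- bn_env[[".m_override"]] %||% spec$momentum
    st$mean <- (1 - mom) * st$mean + mom * r$mu
    st$var <- (1 - mom) * st$var + mom * r$var
    bn_env[[spec$sname]] <- st
    if (keep) {
      cache <- list(xhat = r$xhat, invstd = 1 / sqrt(r$var + spec$eps),
                    dims = d)
    }
  }
  list(out = out, cache = cache)
}

bn_backward <- function(spec, par, cache, dOut) {
  r <- nn_bn_bwd(dOut, cache$xhat, spec$C, par[[spec$gname]], cache$invstd)
  grads <- list()
  grads[[spec$gname]] <- r$dgamma
  grads[[spec$bname]] <- r$dbeta
  dX <- r$dx
  dim(dX) <- cache$dims
  list(dX = dX, grads = grads)
}

# Fused batch-norm + ReLU: one kernel call each way, no stored xhat or
# activation mask (the backward recomputes xhat from the saved input and
# reads the ReLU gate off the saved output).
bnrelu_spec <- function(C, name) {
  sp <- bn_spec(C, name)
  sp$kind <- "bnrelu"
  sp
}

bnrelu_forward <- function(spec, par, bn_env, X, train, keep = TRUE) {
  d <- dim(X)
  st <- bn_env[[spec$sname]]
  if (is.null(st)) st <- list(mean = numeric(spec$C), var = rep(1, spec$C))
  r <- nn_bnrelu_fwd(X, spec$C, par[[spec$gname]], par[[spec$bname]],
                     st$mean, st$var, spec$eps, train)
  out <- r$y
  dim(out) <- d
  cache <- NULL
  if (train) {
    mom <- bn_env[[".m_override"]] %||% spec$momentum
    st$mean <- (1 - mom) * st$mean + mom * r$mu
    st$var <- (1 - mom) * st$var + mom * r$var
    bn_env[[spec$sname]] <- st
    if (keep) {
      cache <- list(x = X, y = out, mu = r$mu,
                    invstd = 1 / sqrt(r$var + spec$eps))
    }
  }
  list(out = out, cache = cache)
}

bnrelu_backward <- function(spec, par, cache, dOut) {
  r <- nn_bnrelu_bwd(dOut, cache$y, cache$x, spec$C, par[[spec$gname]],
                     cache$mu, cache$invstd)
  grads <- list()
  grads[[spec$gname]] <- r$dgamma
  grads[[spec$bname]] <- r$dbeta
  dX <- r$dx
  dim(dX) <- dim(cache$x)
  list(dX = dX, grads = grads)
}

# ---- activations, pooling, dropout, dense ----------------------------------

relu_forward <- function(X, keep = TRUE) {
  out <- X * (X > 0)
  list(out = out, cache = if (keep) (X > 0) else NULL)
}

relu_backward <- function(cache, dOut) dOut * cache

pool_spec <- function(in_hw, C, k, stride, pad, name, kind = "maxpool") {
  H <- in_hw[1L]; W <- in_hw[2L]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  list(kind = kind, k = k, s = stride, p = pad, C = C, H = H, W = W,
       Ho = Ho, Wo = Wo)
}

maxpool_forward <- function(spec, X, keep = TRUE) {
  r <- nn_maxpool_fwd(X, dim(X), spec$k, spec$s, spec$p)
  list(out = r$y,
       cache = if (keep) list(arg = r$arg, xlen = length(X),
                              xdim = dim(X)) else NULL)
}

maxpool_backward <- function(spec, cache, dOut) {
  dX <- nn_scatter1(dOut, cache$arg, cache$xlen)
  dim(dX) <- cache$xdim
  dX
}

# 2x2 stride-2 average pool (disjoint windows, unpadded; used by the
# downsampling shortcuts)
avgpool_forward <- function(spec, X, keep = TRUE) {
  list(out = nn_avgpool_fwd(X, dim(X), spec$k, spec$s),
       cache = if (keep) dim(X) else NULL)
}

avgpool_backward <- function(spec, cache, dOut) {
  nn_avgpool_bwd(dOut, cache, spec$k, spec$s)
}

gap_forward <- function(X) {
  d <- dim(X)
  hw <- d[2L] * d[3L]
  if (hw == 1L) {
    out <- X
    dim(out) <- c(d[1L], d[4L])
  } else {
    out <- matrix(0, d[1L], d[4L])
    a <- X
    dim(a) <- c(d[1L] * hw, d[4L])
    for (n in seq_len(d[4L])) {
      m <- a[, n]
      dim(m) <- c(d[1L], hw)
      out[, n] <- rowMeans(m)
    }
  }
  list(out = out, cache = d)
}

gap_backward <- function(cache, dOut) {
  hw <- cache[2L] * cache[3L]
  dX <- dOut[, rep(seq_len(cache[4L]), each = hw)] / hw
  dim(dX) <- cache
  dX
}

dropout_forward <- function(X, rate, train, keep = TRUE) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  out <- X * mask
  if (!is.null(dim(X))) dim(out) <- dim(X)
  list(out = out, cache = if (keep) mask else NULL)
}

dropout_backward <- function(cache, dOut) {
  if (is.null(cache)) return(dOut)
  out <- dOut * cache
  if (!is.null(dim(dOut))) dim(out) <- dim(dOut)
  out
}

dense_spec <- function(din, dout, name) {
  list(kind = "dense", din = din, dout = dout,
       wname = paste0(name, ".W"), bname = paste0(name, ".b"))
}

dense_init <- function(spec) {
  par <- list(he_uniform(spec$din, c(spec$dout, spec$din)),
              numeric(spec$dout))
  names(par) <- c(spec$wname, spec$bname)
  par
}

dense_forward <- function(spec, par, X, keep = TRUE) {
  list(out = par[[spec$wname]] %*% X + par[[spec$bname]],
       cache = if (keep) X else NULL)
}

dense_backward <- function(spec, par, cache, dOut) {
  grads <- list()
  grads[[spec$wname]] <- tcrossprod(dOut, cache)
  grads[[spec$bname]] <- rowSums(dOut)
  list(dX = crossprod(par[[spec$wname]], dOut), grads = grads)
}
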