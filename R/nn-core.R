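# Minimal reverse-mode neural-network engine.
#
# Conventions: channel-first arrays. Waveform activations are (channels,
# length, batch); dense activations are (features, batch). Convolution
# weights are stored as (cin*k, cout) matrices whose row index runs over
# input channel fastest, then kernel tap, matching the im2col layout below.
# All gradients are exact (no stochastic estimators inside the engine).

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every source of randomness in the package draws its own seed from a
#' single integer through this function, so that components sharing a master
#' seed see reproducible but decorrelated random streams.
#'
#' @param seed integer master seed
#' @param tag character tag naming the consumer
#' @return an integer in `[0, 2^31)`
#' @export
derive_seed <- function(seed, tag) {
  h <- fnv1a(paste0(tag, ":", as.integer(seed)))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash (doubles arithmetic; exact below 2^53)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256) # xor touches low byte only
    # multiply mod 2^32 in two halves to stay within double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  h
}

# content hash of an R object (used by hand-off manifests)
content_hash <- function(x) {
  s <- paste(utils::capture.output(str(x, vec.len = 1e6, digits.d = 17)),
             collapse = "\n")
  sprintf("fnv1a-%08x", as.integer(fnv1a(s) %% 2^31))
}

## ---- parameter flattening -------------------------------------------------

#' Flatten a nested parameter list into a numeric vector
#' @param params nested list of numeric arrays
#' @return numeric vector (stable ordering given the same structure)
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Restore a flat numeric vector into the shape of a parameter skeleton
#' @param flat numeric vector as produced by [flatten_params()]
#' @param skeleton a parameter list with the desired structure
#' @return nested list with `skeleton`'s shapes and `flat`'s values
#' @export
unflatten_params <- function(flat, skeleton) {
  stopifnot(length(flat) == length(flatten_params(skeleton)))
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  rebuild(skeleton)
}

# Recursively reorder a gradient tree to match a parameter skeleton's field
# order, so that flatten_params() of both aligns index-for-index.
reorder_like <- function(g, skeleton) {
  if (!is.list(skeleton)) return(g)
  out <- vector("list", length(skeleton))
  names(out) <- names(skeleton)
  for (nm in seq_along(skeleton)) {
    key <- if (!is.null(names(skeleton))) names(skeleton)[nm] else nm
    out[[nm]] <- reorder_like(g[[key]], skeleton[[nm]])
  }
  out
}

## ---- primitive layers -----------------------------------------------------

# He-uniform initialization for a (fan_in, fan_out) weight matrix
init_weight <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

conv1d_init <- function(cin, k, cout) {
  list(W = init_weight(cin * k, cout, c(cin * k, cout)), b = numeric(cout))
}

# SAME padding with ceiling output length: out = ceiling(L / stride)
conv1d_fwd <- function(x, W, b, k, stride, cache = TRUE) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  out_len <- ceiling(L / stride)
  pad <- max((out_len - 1L) * stride + k - L, 0L)
  pl <- pad %/% 2L
  xp <- array(0, c(C, L + pad, N))
  xp[, (pl + 1L):(pl + L), ] <- x
  idx <- outer(seq_len(k), (seq_len(out_len) - 1L) * stride, `+`) # k x out
  Xc <- xp[, as.vector(idx), , drop = FALSE]
  dim(Xc) <- c(C * k, out_len * N)
  om <- crossprod(W, Xc) + b                       # (cout, out*N)
  out <- array(om, c(ncol(W), out_len, N))
  cc <- if (cache) list(Xc = Xc, dim_xp = dim(xp), pl = pl, L = L,
                        k = k, stride = stride, out_len = out_len) else NULL
  list(out = out, cache = cc)
}

conv1d_bwd <- function(gout, W, cache) {
  cout <- ncol(W); out_len <- cache$out_len
  d <- dim(gout); N <- d[3]
  gm <- gout; dim(gm) <- c(cout, out_len * N)
  gW <- cache$Xc %*% t(gm)
  gb <- rowSums(gm)
  gXc <- W %*% gm                                  # (cin*k, out*N)
  C <- cache$dim_xp[1]; k <- cache$k
  dim(gXc) <- c(C, k, out_len, N)
  gxp <- array(0, cache$dim_xp)
  for (kk in seq_len(k)) {
    pos <- (seq_len(out_len) - 1L) * cache$stride + kk
    gxp[, pos, ] <- gxp[, pos, ] + gXc[, kk, , ]
  }
  gx <- gxp[, (cache$pl + 1L):(cache$pl + cache$L), , drop = FALSE]
  list(gx = gx, gW = gW, gb = gb)
}

dense_init <- function(din, dout) {
  list(W = init_weight(din, dout, c(din, dout)), b = numeric(dout))
}

dense_fwd <- function(x, W, b) crossprod(W, x) + b

dense_bwd <- function(gout, x, W) {
  list(gx = W %*% gout, gW = x %*% t(gout), gb = rowSums(gout))
}

# Batch norm over the channel (first) dimension; all remaining dims are the
# normalization population. `buffers` carries running statistics.
bn_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))
bn_buffers_init <- function(C) list(mean = numeric(C), var = rep(1, C))

bn_fwd <- function(x, gamma, beta, buffers, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x); C <- d[1]; m <- prod(d[-1])
  xm <- x; dim(xm) <- c(C, m)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var + momentum * v
  } else {
    mu <- buffers$mean; v <- buffers$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  out <- gamma * xhat + beta
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, istd = istd, dims = d, training = training),
       buffers = buffers)
}

bn_bwd <- function(gout, gamma, cache) {
  d <- cache$dims; C <- d[1]; m <- prod(d[-1])
  gm <- gout; dim(gm) <- c(C, m)
  xhat <- cache$xhat
  ggamma <- rowSums(gm * xhat)
  gbeta <- rowSums(gm)
  gxh <- gm * gamma
  if (cache$training) {
    gx <- cache$istd * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
  } else {
    gx <- gxh * cache$istd
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
relu_bwd <- function(gout, mask) gout * mask

lrelu_fwd <- function(x, slope = 0.2) {
  mask <- x > 0
  list(out = ifelse(mask, x, slope * x), mask = mask, slope = slope)
}
lrelu_bwd <- function(gout, mask, slope = 0.2) {
  gout * ifelse(mask, 1, slope)
}

# Adaptive average pooling over the length dimension (torch bin convention).
# Returns the (out_len x L) pooling operator; linear, so backward is the
# transpose.
adaptive_pool_matrix <- function(L, out_len) {
  P <- matrix(0, out_len, L)
  for (o in seq_len(out_len)) {
    a <- floor((o - 1) * L / out_len) + 1L
    b <- ceiling(o * L / out_len)
    P[o, a:b] <- 1 / (b - a + 1L)
  }
  P
}

pool_fwd <- function(x, P) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  xm <- aperm(x, c(2, 1, 3)); dim(xm) <- c(L, C * N)
  ym <- P %*% xm
  y <- array(ym, c(nrow(P), C, N))
  aperm(y, c(2, 1, 3))
}

pool_bwd <- function(gout, P, L) {
  d <- dim(gout); C <- d[1]; out_len <- d[2]; N <- d[3]
  gm <- aperm(gout, c(2, 1, 3)); dim(gm) <- c(out_len, C * N)
  gxm <- crossprod(P, gm)
  gx <- array(gxm, c(L, C, N))
  aperm(gx, c(2, 1, 3))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}
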