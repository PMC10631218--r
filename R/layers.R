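# Layer definitions and backward passes for the 1D convolutional network.
# Batches are dense arrays of shape (batch, length, channels); the hot
# primitives (im2col/col2im, fused batch-norm + ReLU, pooling, flattening)
# live in src/engine.cpp, matrix products go through BLAS.

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# ---- layer constructors -----------------------------------------------------

new_conv_layer <- function(kernel, in_ch, filters, padding) {
  stopifnot(padding %in% c("valid", "same"))
  list(
    type = "conv", kernel = kernel, in_ch = in_ch, filters = filters,
    padding = padding,
    par = list(
      W = matrix(glorot_uniform(kernel * in_ch, kernel * filters,
                                kernel * in_ch * filters),
                 kernel * in_ch, filters),
      b = numeric(filters),
      gamma = rep(1, filters),
      beta = numeric(filters)
    ),
    # batch-norm running statistics (inference mode); momentum 0.9 so the
    # statistics track the weights within a few dozen optimizer steps —
    # desk-scale runs see only 60-700 steps in total
    run_mean = numeric(filters), run_var = rep(1, filters),
    momentum = 0.9, eps = 1e-3
  )
}

new_pool_layer <- function(pool) list(type = "pool", pool = pool)

new_dropout_layer <- function(rate) list(type = "dropout", rate = rate)

new_flatten_layer <- function() list(type = "flatten")

new_dense_layer <- function(in_dim, units, activation) {
  stopifnot(activation %in% c("relu", "sigmoid", "softmax"))
  list(
    type = "dense", in_dim = in_dim, units = units, activation = activation,
    par = list(
      W = matrix(glorot_uniform(in_dim, units, in_dim * units), in_dim, units),
      b = numeric(units)
    )
  )
}

new_embedding_layer <- function(vocab_size, embed_dim) {
  list(
    type = "embedding", vocab_size = vocab_size, embed_dim = embed_dim,
    par = list(E = matrix(runif(vocab_size * embed_dim, -0.05, 0.05),
                          vocab_size, embed_dim))
  )
}

# ---- im2col convolution -----------------------------------------------------

# (B, L, C) -> (B*Lout, kernel*C); column block j holds channels at offset j.
im2col <- function(X, k) im2col_cpp(X, k)

col2im <- function(dM, B, L, C, k) col2im_cpp(dM, B, L, C, k)

pad_zeros <- function(X, left, right) {
  if (left == 0 && right == 0) return(X)
  pad_zeros_cpp(X, left, right)
}

# ---- forward / backward per layer ------------------------------------------

# conv unit = convolution -> batch norm -> ReLU (one catalog entry).
conv_forward <- function(ly, X, training) {
  k <- ly$kernel
  pl <- pr <- 0L
  if (ly$padding == "same") {
    pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl
    X <- pad_zeros(X, pl, pr)
  }
  d <- dim(X); B <- d[1]; L <- d[2]
  Lo <- L - k + 1
  if (Lo < 1) abort("spatial length smaller than kernel; use fewer blocks")
  M <- im2col(X, k)
  Z <- M %*% ly$par$W
  Z <- Z + rep(ly$par$b, each = nrow(Z))
  m <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z * Z) - mu * mu
    v[v < 0] <- 0
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var  <- ly$momentum * ly$run_var  + (1 - ly$momentum) * v
  } else {
    mu <- ly$run_mean; v <- ly$run_var
  }
  bn <- bn_relu_forward_cpp(Z, ly$par$gamma, ly$par$beta, mu, v, ly$eps)
  out <- array(bn$A, c(B, Lo, ly$filters))
  cache <- list(M = M, A = bn$A, Xhat = bn$Xhat, v = v,
                B = B, Lpad = L, C = d[3], Lo = Lo, pl = pl, pr = pr, m = m)
  list(out = out, cache = cache, layer = ly)
}

conv_backward <- function(ly, cache, dOut) {
  m <- cache$m; F_ <- ly$filters
  dA <- matrix(dOut, m, F_)
  bn <- bn_relu_backward_cpp(dA, cache$A, cache$Xhat, ly$par$gamma,
                             cache$v, ly$eps)
  dZ <- bn$dZ
  db <- colSums(dZ)
  dW <- crossprod(cache$M, dZ)
  dM <- tcrossprod(dZ, ly$par$W)
  dX <- col2im(dM, cache$B, cache$Lpad, cache$C, ly$kernel)
  if (cache$pl > 0 || cache$pr > 0) {
    dX <- dX[, (cache$pl + 1):(cache$Lpad - cache$pr), , drop = FALSE]
  }
  list(dX = dX, grads = list(W = dW, b = db,
                             gamma = drop(bn$dgamma), beta = drop(bn$dbeta)))
}

pool_forward <- function(ly, X) {
  p <- ly$pool; d <- dim(X)
  Lo <- d[2] %/% p
  if (Lo < 1) abort("spatial length smaller than pool size; use fewer blocks")
  r <- pool_forward_cpp(X, p)
  list(out = r$out, cache = list(amax = r$amax, Lin = d[2], p = p))
}

pool_backward <- function(ly, cache, dOut) {
  list(dX = pool_backward_cpp(dOut, cache$amax, cache$Lin, cache$p),
       grads = NULL)
}

dropout_forward <- function(ly, X, training) {
  if (!training || ly$rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  keep <- (runif(length(X)) >= ly$rate) / (1 - ly$rate)
  list(out = X * keep, cache = list(keep = keep))
}

dropout_backward <- function(ly, cache, dOut) {
  if (is.null(cache)) return(list(dX = dOut, grads = NULL))
  list(dX = dOut * cache$keep, grads = NULL)
}

# (B, L, C) -> (B, L*C); feature index = (position-1)*C + channel.
flatten_forward <- function(ly, X) {
  d <- dim(X)
  list(out = flatten_cpp(X), cache = list(L = d[2], C = d[3]))
}

flatten_backward <- function(ly, cache, dOut) {
  list(dX = unflatten_cpp(dOut, cache$L, cache$C), grads = NULL)
}

dense_forward <- function(ly, X, training) {
  Z <- X %*% ly$par$W
  Z <- Z + rep(ly$par$b, each = nrow(Z))
  A <- switch(ly$activation,
    relu = {
      mask <- Z > 0
      Z * mask
    },
    sigmoid = 1 / (1 + exp(-Z)),
    softmax = softmax_rows(Z)
  )
  mask <- if (ly$activation == "relu") Z > 0 else NULL
  list(out = A, cache = list(Xin = X, mask = mask))
}

# `wrt = "z"` means dOut is already the gradient of the pre-activation
# (used for the output layer where activation + loss fuse to P - Y).
dense_backward <- function(ly, cache, dOut, wrt = c("act", "z")) {
  wrt <- match.arg(wrt)
  dZ <- if (wrt == "z") dOut else dOut * cache$mask
  list(dX = tcrossprod(dZ, ly$par$W),
       grads = list(W = crossprod(cache$Xin, dZ), b = colSums(dZ)))
}

embedding_forward <- function(ly, X) {
  B <- nrow(X); L <- ncol(X)
  idx <- as.vector(X) + 1L
  out <- array(ly$par$E[idx, , drop = FALSE], c(B, L, ly$embed_dim))
  list(out = out, cache = list(idx = idx, B = B, L = L))
}

embedding_backward <- function(ly, cache, dOut) {
  dM <- matrix(dOut, cache$B * cache$L, ly$embed_dim)
  acc <- rowsum(dM, group = cache$idx)
  dE <- matrix(0, nrow(ly$par$E), ncol(ly$par$E))
  dE[as.integer(rownames(acc)), ] <- acc
  list(dX = NULL, grads = list(E = dE))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(kind, par) {
  st <- lapply(par, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  })
  list(kind = kind, t = 0L, state = st,
       lr = 1e-3, beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-7)
}

opt_step <- function(opt, par, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- opt$state[[nm]]
    if (opt$kind == "adam") {
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      mhat <- st$m / (1 - opt$beta1^opt$t)
      vhat <- st$v / (1 - opt$beta2^opt$t)
      par[[nm]] <- par[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else { # rmsprop
      st$v <- opt$rho * st$v + (1 - opt$rho) * g * g
      par[[nm]] <- par[[nm]] - opt$lr * g / (sqrt(st$v) + opt$eps)
    }
    opt$state[[nm]] <- st
  }
  list(opt = opt, par = par)
}
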