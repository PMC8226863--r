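# Compact convolutional network engine.
#
# Forward/backward passes are written with im2col matrix algebra so the whole
# network runs on BLAS without compiled code. Layout conventions:
#   batch input  X : array(H, W, C, N), values in [0, 1]
#   im2col matrix  : (H*W*N) x (9*C), rows ordered (h, w, n), R column-major
#   conv weights   : (9*C) x F matrix + length-F bias; 3x3 kernels, stride 1,
#                    "same" zero padding
#   block          : conv -> ReLU -> 2x2 max pool (stride 2)
#   head           : global average pool -> dense F_last x K -> softmax

conv_pad <- function(X) {
  d <- dim(X)
  P <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  P[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- X
  P
}

im2col <- function(X) {
  d <- dim(X)  # H W C N
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  P <- conv_pad(X)
  M <- matrix(0, nrow = H * W * N, ncol = 9L * C)
  col <- 0L
  for (c0 in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        M[, col] <- as.vector(P[di + seq_len(H), dj + seq_len(W), c0, ])
      }
    }
  }
  M
}

col2im <- function(dM, H, W, C, N) {
  dP <- array(0, c(H + 2L, W + 2L, C, N))
  col <- 0L
  for (c0 in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        dP[di + seq_len(H), dj + seq_len(W), c0, ] <-
          dP[di + seq_len(H), dj + seq_len(W), c0, ] +
          array(dM[, col], c(H, W, N))
      }
    }
  }
  dP[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv_forward <- function(X, Wm, b) {
  d <- dim(X)
  M <- im2col(X)
  Y <- sweep(M %*% Wm, 2L, b, `+`)       # (H*W*N) x F
  F_ <- length(b)
  A <- aperm(array(Y, c(d[1], d[2], d[4], F_)), c(1, 2, 4, 3))  # H W F N
  list(out = A, cache = list(M = M, dims = d))
}

conv_backward <- function(dA, Wm, cache) {
  d <- cache$dims                        # input H W C N
  F_ <- dim(dA)[3]
  dY <- matrix(aperm(dA, c(1, 2, 4, 3)), ncol = F_)  # rows (h,w,n)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, Wm)               # (H*W*N) x 9C
  dX <- col2im(dM, d[1], d[2], d[3], d[4])
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(A) list(out = pmax(A, 0), cache = A > 0)
relu_backward <- function(dA, cache) dA * cache

# 2x2 max pool, stride 2; H and W must be even.
pool_forward <- function(A) {
  d <- dim(A)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  s1 <- A[io,     jo,     , , drop = FALSE]
  s2 <- A[io + 1, jo,     , , drop = FALSE]
  s3 <- A[io,     jo + 1, , , drop = FALSE]
  s4 <- A[io + 1, jo + 1, , , drop = FALSE]
  M <- pmax(s1, s2, s3, s4)
  # deterministic argmax: first of the four sub-grids that attains the max
  m1 <- s1 == M
  m2 <- (s2 == M) & !m1
  m3 <- (s3 == M) & !(m1 | m2)
  m4 <- (s4 == M) & !(m1 | m2 | m3)
  list(out = M, cache = list(masks = list(m1, m2, m3, m4), dims = d))
}

pool_backward <- function(dM, cache) {
  d <- cache$dims
  dA <- array(0, d)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  ms <- cache$masks
  dA[io,     jo,     , ] <- dM * ms[[1]]
  dA[io + 1, jo,     , ] <- dM * ms[[2]]
  dA[io,     jo + 1, , ] <- dM * ms[[3]]
  dA[io + 1, jo + 1, , ] <- dM * ms[[4]]
  dA
}

gap_forward <- function(A) {
  d <- dim(A)
  list(out = t(apply(A, 4, function(a) colMeans(matrix(a, ncol = d[3])))),
       cache = d)  # N x F
}

gap_backward <- function(dG, d) {
  # dG: N x F -> spread uniformly over the H*W positions
  scale <- 1 / (d[1] * d[2])
  dA <- array(0, d)
  for (n in seq_len(d[4])) {
    dA[, , , n] <- rep(dG[n, ] * scale, each = d[1] * d[2])
  }
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- network --------------------------------------------------------------

cnn_init <- function(filters, in_channels, n_classes, seed) {
  with_local_seed(seed, {
    params <- list()
    cin <- in_channels
    for (l in seq_along(filters)) {
      fan_in <- 9L * cin
      params[[paste0("W", l)]] <- matrix(
        stats::rnorm(fan_in * filters[l], 0, sqrt(2 / fan_in)),
        nrow = fan_in)
      params[[paste0("b", l)]] <- numeric(filters[l])
      cin <- filters[l]
    }
    params$Wd <- matrix(stats::rnorm(cin * n_classes, 0, sqrt(2 / cin)),
                        nrow = cin)
    params$bd <- numeric(n_classes)
    params
  })
}

cnn_forward <- function(params, X, n_blocks, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", n_blocks) else NULL
  A <- X
  for (l in seq_len(n_blocks)) {
    cv <- conv_forward(A, params[[paste0("W", l)]], params[[paste0("b", l)]])
    rl <- relu_forward(cv$out)
    pl <- pool_forward(rl$out)
    if (keep_cache) {
      caches[[l]] <- list(conv = cv$cache, relu = rl$cache, pool = pl$cache)
    }
    A <- pl$out
  }
  gp <- gap_forward(A)
  logits <- sweep(gp$out %*% params$Wd, 2L, params$bd, `+`)
  list(logits = logits, probs = softmax_rows(logits),
       gap = gp, caches = caches)
}

# cross-entropy loss and full gradient for a one-hot target matrix Y (N x K)
cnn_loss_grad <- function(params, X, Y, n_blocks) {
  fw <- cnn_forward(params, X, n_blocks, keep_cache = TRUE)
  N <- nrow(Y)
  eps <- 1e-12
  loss <- -sum(Y * log(fw$probs + eps)) / N
  dZ <- (fw$probs - Y) / N                 # N x K
  grads <- list(Wd = crossprod(fw$gap$out, dZ), bd = colSums(dZ))
  dG <- tcrossprod(dZ, params$Wd)          # N x F_last
  dA <- gap_backward(dG, fw$gap$cache)
  for (l in rev(seq_len(n_blocks))) {
    ch <- fw$caches[[l]]
    dA <- pool_backward(dA, ch$pool)
    dA <- relu_backward(dA, ch$relu)
    cb <- conv_backward(dA, params[[paste0("W", l)]], ch$conv)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    dA <- cb$dX
  }
  list(loss = loss, grads = grads, probs = fw$probs)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}
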