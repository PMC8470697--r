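# Small convolutional network: five 3x3 single-channel convolution layers
# (ReLU, zero-padded so the 40x40 spatial shape is preserved, no pooling),
# flatten, one fully-connected ReLU layer, softmax over the two classes.
# Trained by minibatch SGD with momentum on the cross-entropy loss.
# Convolutions are vectorized over the whole batch (the batch is an
# H x W x n array; each 3x3 tap is one shifted slice multiply).

# 'same' convolution of every image in the batch with a 3x3 kernel
conv2same <- function(A, K) {
  d <- dim(A)
  Ap <- array(0, d + c(2L, 2L, 0L))
  Ap[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- A
  out <- array(0, d)
  for (u in 1:3) for (v in 1:3)
    out <- out + K[u, v] *
      Ap[u:(u + d[1] - 1L), v:(v + d[2] - 1L), , drop = FALSE]
  out
}

# kernel gradient: dK[u,v] = sum(Apad shifted * dZ)
conv2same_gradK <- function(A, dZ) {
  d <- dim(A)
  Ap <- array(0, d + c(2L, 2L, 0L))
  Ap[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- A
  dK <- matrix(0, 3, 3)
  for (u in 1:3) for (v in 1:3)
    dK[u, v] <- sum(Ap[u:(u + d[1] - 1L), v:(v + d[2] - 1L), , drop = FALSE] * dZ)
  dK
}

rot180 <- function(K) K[3:1, 3:1]

cnn_init <- function(input_dim, cfg, seed) {
  p <- prod(input_dim)
  local_seed(seed, {
    # identity-plus-noise kernels: a single-filter ReLU chain with zero-mean
    # random kernels frequently collapses (a negative kernel sum zeroes
    # every activation of an all-positive image); starting near the delta
    # kernel keeps the chain a trainable pass-through
    K <- lapply(seq_len(cfg$n_conv), function(i) {
      k <- matrix(rnorm(9, sd = 0.1), 3, 3)
      k[2, 2] <- k[2, 2] + 1
      k
    })
    bK <- rep(0, cfg$n_conv)
    W1 <- matrix(rnorm(p * cfg$fc_width, sd = sqrt(2 / p)), p, cfg$fc_width)
    b1 <- rep(0, cfg$fc_width)
    W2 <- matrix(rnorm(cfg$fc_width * 2, sd = sqrt(2 / cfg$fc_width)),
                 cfg$fc_width, 2)
    b2 <- rep(0, 2)
    list(K = K, bK = bK, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

cnn_forward <- function(params, A) {
  nC <- length(params$K)
  acts <- vector("list", nC + 1L)   # post-ReLU activations, acts[[1]] = input
  zs <- vector("list", nC)          # pre-activations
  acts[[1]] <- A
  for (l in seq_len(nC)) {
    zs[[l]] <- conv2same(acts[[l]], params$K[[l]]) + params$bK[l]
    acts[[l + 1L]] <- relu(zs[[l]])
  }
  X <- flatten_images(acts[[nC + 1L]])
  z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  h1 <- relu(z1)
  logits <- sweep(h1 %*% params$W2, 2, params$b2, "+")
  probs <- softmax_rows(logits)
  list(acts = acts, zs = zs, X = X, z1 = z1, h1 = h1, probs = probs)
}

# cross-entropy loss and full gradient on one batch (A: H x W x nb array,
# Y: nb x 2 one-hot)
cnn_loss_grad <- function(params, A, Y) {
  fw <- cnn_forward(params, A)
  nb <- dim(A)[3]
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(fw$probs + eps)))
  dlogits <- (fw$probs - Y) / nb
  gW2 <- crossprod(fw$h1, dlogits); gb2 <- colSums(dlogits)
  dh1 <- tcrossprod(dlogits, params$W2) * (fw$z1 > 0)
  gW1 <- crossprod(fw$X, dh1); gb1 <- colSums(dh1)
  dX <- tcrossprod(dh1, params$W1)
  d <- dim(A)
  dA <- array(t(dX), d)
  nC <- length(params$K)
  gK <- vector("list", nC); gbK <- numeric(nC)
  for (l in rev(seq_len(nC))) {
    dZ <- dA * (fw$zs[[l]] > 0)
    gbK[l] <- sum(dZ)
    gK[[l]] <- conv2same_gradK(fw$acts[[l]], dZ)
    if (l > 1L) dA <- conv2same(dZ, rot180(params$K[[l]]))
  }
  list(loss = loss,
       grads = list(K = gK, bK = gbK, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Train the convolutional seal classifier
#'
#' Five single-filter 3x3 convolution layers with ReLU and shape-preserving
#' zero padding (no pooling), a flatten, one fully-connected ReLU layer and
#' a two-class softmax output, trained by minibatch stochastic gradient
#' descent with momentum on the cross-entropy loss. Single-filter layers
#' follow the reference architecture; `channels` is intentionally fixed at
#' one per layer, with depth and widths configurable.
#'
#' @param data an [image_set()] with both classes.
#' @param n_conv number of convolution layers (default 5).
#' @param fc_width width of the fully-connected hidden layer (default 64).
#' @param epochs training epochs (default 100).
#' @param lr learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.5; with a single-filter conv
#'   chain heavier momentum regularly drives the shared conv biases
#'   negative and the ReLU chain into a dead, unrecoverable state).
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed for initialization and shuffling.
#' @param normalize min-max each image to [0, 1] first (default `TRUE`).
#' @return An `hsi_model` of family `"cnn"`; per-epoch mean losses are kept
#'   in `$params$loss_history`.
#' @export
train_cnn <- function(data, n_conv = 5L, fc_width = 64L, epochs = 100L,
                      lr = 0.01, momentum = 0.5, batch_size = 32L,
                      seed = 1L, normalize = TRUE) {
  check_trainable(data)
  cfg <- list(n_conv = n_conv, fc_width = fc_width, epochs = epochs, lr = lr,
              momentum = momentum, batch_size = batch_size, seed = seed)
  images <- if (normalize) normalize_images(data$images) else data$images
  Y <- one_hot(data$labels)
  n <- dim(images)[3]
  params <- cnn_init(dim(images)[1:2], cfg, seed)
  vel <- rapply(params[c("K", "bK", "W1", "b1", "W2", "b2")],
                function(x) x * 0, how = "replace")
  loss_hist <- numeric(epochs)
  local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      eploss <- 0
      for (bi in batches) {
        lg <- cnn_loss_grad(params, images[, , bi, drop = FALSE],
                            Y[bi, , drop = FALSE])
        if (!is.finite(lg$loss))
          stop("cnn training diverged (non-finite loss); lower lr = ", lr)
        eploss <- eploss + lg$loss * length(bi)
        for (nm in c("bK", "W1", "b1", "W2", "b2")) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * lg$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        for (l in seq_len(n_conv)) {
          vel$K[[l]] <- momentum * vel$K[[l]] - lr * lg$grads$K[[l]]
          params$K[[l]] <- params$K[[l]] + vel$K[[l]]
        }
      }
      loss_hist[ep] <- eploss / n
    }
  })
  params$loss_history <- loss_hist
  new_model("cnn", params, cfg, dim(data$images)[1:2], normalize)
}

cnn_scores <- function(model, images) {
  A <- model_input(model, images)
  fw <- cnn_forward(model$params, A)
  colnames(fw$probs) <- class_levels
  fw$probs
}
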